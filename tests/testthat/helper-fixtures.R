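# shared builders for the test suite; everything is generated in code

toy_alignment <- function() {
  rdna_set(id = c("ref", "s2", "s3"),
           residues = c("ACGT----ACGT",
                        "ACGTTTAAACGT",
                        "ACGT----ACGT"),
           aligned = TRUE)
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_temp_primers <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a grammar-true spliceosomal insert assembled by hand (donor + variable +
# branch + CT tract + tail + acceptor), used where a deterministic sequence
# is clearer than a sampled one
handmade_sp_insert <- function(var = strrep("A", 20), tail = strrep("G", 10)) {
  paste0("GTAAGT", var, "TTAAC", "TCTTTCCTCT", tail, "TACAG")
}

# small implant configuration: 5 taxa, introns at one flank for 3 of them
small_spec <- function(flank = 549L, taxa = c("t1", "t2", "t3"),
                       family = "SP", len_min = 96L, len_max = 199L,
                       presence_prob = 1, truncation_prob = 0) {
  df <- data.frame(location_id = 1L, flank5 = flank, family = family,
                   len_min = len_min, len_max = len_max,
                   presence_prob = presence_prob,
                   truncation_prob = truncation_prob,
                   stringsAsFactors = FALSE)
  df$taxa <- I(list(taxa))
  df
}

random_cores <- function(n = 5, L = 1200, prefix = "t") {
  stats::setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)),
    paste0(prefix, seq_len(n)))
}

# independent mismatch count of a pattern (already forward-strand) at one
# offset, straight from the IUPAC code table
oracle_mismatches <- function(pattern, core, s) {
  pc <- strsplit(pattern, "")[[1]]
  cc <- strsplit(substr(core, s, s + nchar(pattern) - 1L), "")[[1]]
  sum(vapply(seq_along(pc), function(j) {
    if (cc[j] == "N") return(FALSE)
    !cc[j] %in% IUPAC_CODES[[pc[j]]]
  }, logical(1)))
}
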
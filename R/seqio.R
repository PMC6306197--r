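# Sequence and table input/output: FASTA (plain and aligned), primer
# configuration tables, the packaged intron-location fixture, and report
# writers.  FASTA parsing is delegated to Biostrings; this layer adds the
# conventions the pipeline relies on (id = header up to first whitespace,
# taxon = remainder, uppercase residues, U -> T).

#' Construct a sequence set
#'
#' @param id character vector of unique record identifiers.
#' @param taxon character vector of taxon labels (may be empty strings).
#' @param residues character vector of residue strings (uppercase, U already
#'   normalized to T); gaps (`-`) only when `aligned = TRUE`.
#' @param aligned logical flag; when `TRUE` all residue strings must have equal
#'   length and the object represents a multiple alignment.
#' @param gene gene tag, one of `"SSU18S"`, `"LSU28S"`, `"other"`.
#' @return An object of class `rdna_set`: a data frame with columns `id`,
#'   `taxon`, `residues` and attributes `aligned`, `gene` and (when aligned)
#'   `n_cols`.
#' @export
rdna_set <- function(id, taxon = rep("", length(id)), residues,
                     aligned = FALSE, gene = c("SSU18S", "LSU28S", "other")) {
  gene <- match.arg(gene)
  stopifnot(length(id) == length(residues), length(taxon) == length(id))
  if (length(id) == 0L) stop("empty sequence set")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(id))) stop("empty sequence id")
  if (any(!nzchar(residues))) {
    stop("record '", id[!nzchar(residues)][1L], "' has empty residues")
  }
  for (i in seq_along(id)) check_alphabet(residues[i], id[i], aligned)
  x <- data.frame(id = id, taxon = taxon, residues = residues,
                  stringsAsFactors = FALSE)
  attr(x, "aligned") <- aligned
  attr(x, "gene") <- gene
  if (aligned) {
    lens <- nchar(residues)
    if (length(unique(lens)) != 1L) {
      off <- id[lens != lens[1L]][1L]
      stop("ragged alignment: record '", off, "' has length ",
           nchar(residues[id == off]), ", expected ", lens[1L])
    }
    attr(x, "n_cols") <- lens[1L]
  }
  class(x) <- c("rdna_set", "data.frame")
  x
}

#' @export
print.rdna_set <- function(x, ...) {
  cat("rdna_set:", nrow(x), "sequence(s),",
      if (isTRUE(attr(x, "aligned"))) paste("aligned,", attr(x, "n_cols"), "columns")
      else "unaligned",
      paste0("(", attr(x, "gene"), ")"), "\n")
  invisible(x)
}

#' Number of alignment columns
#' @param x an aligned `rdna_set`.
#' @return Integer column count.
#' @export
aln_ncols <- function(x) {
  if (!isTRUE(attr(x, "aligned"))) stop("sequence set is not aligned")
  attr(x, "n_cols")
}

# named residue vector
seq_vector <- function(x) stats::setNames(x$residues, x$id)

# character matrix (rows = sequences) of an aligned set
aln_matrix <- function(x) {
  m <- matrix(unlist(strsplit(x$residues, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(x), byrow = TRUE)
  rownames(m) <- x$id
  m
}

#' Read a FASTA file of rDNA sequences
#'
#' Record ids are taken from the header up to the first whitespace; the
#' remainder of the header becomes the taxon label.  Residues are uppercased
#' and `U` is normalized to `T`.
#'
#' @param path path to a FASTA file.
#' @param aligned logical; when `TRUE` the records must be equal length and may
#'   contain `-` gaps.
#' @param gene gene tag stored on the returned set.
#' @return An [rdna_set].
#' @export
read_rdna_fasta <- function(path, aligned = FALSE,
                            gene = c("SSU18S", "LSU28S", "other")) {
  gene <- match.arg(gene)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  taxon <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  residues <- normalize_residues(as.character(ss))
  rdna_set(id = id, taxon = taxon, residues = unname(residues),
           aligned = aligned, gene = gene)
}

#' Write a sequence set to FASTA
#'
#' Headers are `id` or `id taxon` when a taxon label is present.  Round-trips
#' losslessly through [read_rdna_fasta()] for ids and residues.
#'
#' @param x an [rdna_set].
#' @param path output path.
#' @param width line width for wrapped residues.
#' @return Invisibly, `path`.
#' @export
write_rdna_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "rdna_set"))
  hdr <- ifelse(nzchar(x$taxon), paste(x$id, x$taxon), x$id)
  ss <- Biostrings::BStringSet(stats::setNames(x$residues, hdr))
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Load a primer configuration table
#'
#' Expects tab- or comma-delimited text with columns `name`, `orientation`,
#' `sequence`, `critical_window`.  Reverse primers are stored as written
#' (5'->3' as synthesized); the matching machinery reverse-complements them.
#'
#' @param path path to the delimited file.
#' @return A data frame of class `primer_config` with those four columns.
#' @export
load_primer_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("name", "orientation", "sequence", "critical_window")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("primer config lacks column(s): ",
                              paste(miss, collapse = ", "))
  df <- df[, need]
  df$sequence <- toupper(df$sequence)
  for (i in seq_len(nrow(df))) {
    p <- df[i, ]
    if (!p$orientation %in% c("forward", "reverse")) {
      stop("primer '", p$name, "': orientation must be 'forward' or 'reverse', got '",
           p$orientation, "'")
    }
    cs <- chars(p$sequence)
    bad <- which(!cs %in% names(IUPAC_CODES))
    if (length(bad) > 0L) {
      stop("primer '", p$name, "': non-IUPAC character '", cs[bad[1L]],
           "' at position ", bad[1L])
    }
    cw <- p$critical_window
    if (is.na(cw) || cw < 1L || cw > nchar(p$sequence)) {
      stop("primer '", p$name, "': critical_window must be in [1, ",
           nchar(p$sequence), "], got ", cw)
    }
  }
  df$critical_window <- as.integer(df$critical_window)
  class(df) <- c("primer_config", "data.frame")
  df
}

# cell token grammar of the intron-location fixture:
#   "123"      exact length (complete)
#   "123-134"  length range (complete)
#   "123+"     sequenced part of a longer insert (partial)
#   "?"        presence unknown -> omitted
# optional suffixes: "^" single-strain occurrence, "!" possible nested
# spliceosomal intron.  Empty cell = no insert.
parse_length_cell <- function(cell, where) {
  cell <- gsub("–", "-", trimws(cell))  # en-dash -> hyphen
  if (cell == "" || cell == "?") return(NULL)
  m <- regmatches(cell, regexec("^([0-9]+)(?:-([0-9]+))?(\\+)?(\\^)?(!)?$", cell))[[1]]
  if (length(m) == 0L) stop("malformed length cell '", cell, "' at ", where)
  lo <- as.integer(m[2L])
  hi <- if (nzchar(m[3L])) as.integer(m[3L]) else lo
  partial <- nzchar(m[4L])
  if (partial && hi != lo) stop("cell '", cell, "' at ", where,
                                ": a range cannot be partial")
  if (lo > hi) stop("cell '", cell, "' at ", where, ": min exceeds max")
  list(min_len = lo, max_len = hi, complete = !partial,
       strain_restricted = nzchar(m[5L]), nested_note = nzchar(m[6L]))
}

#' Load the packaged intron-location table fixture
#'
#' Reads a delimited transcription of a published intron-location table: one
#' row per insert location (gene, location index, family, flanking core
#' positions) followed by one column per terminal taxon holding length cells
#' (`123`, `123-134`, `123+`, `?` or empty; see the fixture header for the
#' suffix flags).
#'
#' @param path path to the fixture TSV.  Defaults to the copy shipped with the
#'   package.
#' @return An object of class `insert_table`: list with elements `rows` (one
#'   data frame row per location), `cells` (long data frame of parsed,
#'   non-missing length cells) and `taxa` (taxon column order).
#' @export
load_insert_table <- function(path = system.file("extdata", "intron_locations.tsv",
                                                 package = "rdnaintrons")) {
  if (!nzchar(path) || !file.exists(path)) stop("fixture not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  fixed <- c("gene", "location", "family", "flank5", "flank3")
  miss <- setdiff(fixed, names(df))
  if (length(miss) > 0L) stop("fixture lacks column(s): ", paste(miss, collapse = ", "))
  taxa <- setdiff(names(df), fixed)
  rows <- df[, fixed]
  if (!all(rows$family %in% c("SP", "GI"))) stop("fixture family must be SP or GI")
  if (!all(rows$flank3 == rows$flank5 + 1L)) {
    stop("fixture flank pairs must be adjacent core positions")
  }
  if (anyDuplicated(rows[, c("gene", "location")])) {
    stop("duplicate (gene, location) in fixture")
  }
  cells <- list()
  for (i in seq_len(nrow(df))) {
    for (tx in taxa) {
      parsed <- parse_length_cell(as.character(df[i, tx]),
                                  where = paste0("gene ", df$gene[i], " location ",
                                                 df$location[i], ", taxon '", tx, "'"))
      if (!is.null(parsed)) {
        cells[[length(cells) + 1L]] <- data.frame(
          gene = df$gene[i], location = df$location[i], family = df$family[i],
          taxon = tx, min_len = parsed$min_len, max_len = parsed$max_len,
          complete = parsed$complete,
          strain_restricted = parsed$strain_restricted,
          nested_note = parsed$nested_note,
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- if (length(cells) > 0L) do.call(rbind, cells) else
    data.frame(gene = character(), location = integer(), family = character(),
               taxon = character(), min_len = integer(), max_len = integer(),
               complete = logical(), strain_restricted = logical(),
               nested_note = logical(), stringsAsFactors = FALSE)
  structure(list(rows = rows, cells = cells, taxa = taxa),
            class = "insert_table")
}

#' @export
print.insert_table <- function(x, ...) {
  cat("insert_table:", nrow(x$rows), "locations,", length(x$taxa), "taxa,",
      nrow(x$cells), "length cells\n")
  invisible(x)
}

#' Write a tabular report
#'
#' @param rows a data frame of homogeneous records.
#' @param path output path.
#' @param format `"tsv"` (header row, tab-separated, UTF-8) or `"json"`
#'   (top-level array of row objects).
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  # flatten list columns for serialization
  flat <- rows
  for (j in seq_along(flat)) {
    if (is.list(flat[[j]])) {
      flat[[j]] <- vapply(flat[[j]], function(v) paste(v, collapse = ","), "")
    }
  }
  if (format == "tsv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(flat, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is required for JSON reports")
    }
    jsonlite::write_json(flat, path, dataframe = "rows", auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(path)
}
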
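# Shared small helpers: IUPAC alphabet tables and string utilities.

#' IUPAC nucleotide codes and the bases each one stands for
#'
#' Named list mapping every one-letter IUPAC nucleotide code to the set of
#' unambiguous bases (A, C, G, T) it denotes.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# split a single string into its characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# TRUE where the single pattern character admits the target character; target
# must be one of A,C,G,T,N.  n_lenient governs 'N' in the *target*.
iupac_char_match <- function(p, t, n_lenient = FALSE) {
  if (t == "N") {
    if (n_lenient) return(TRUE)
    return(p == "N")
  }
  t %in% IUPAC_CODES[[p]]
}

#' Reverse-complement a (possibly degenerate) IUPAC sequence
#'
#' @param x single DNA string over the IUPAC alphabet (no gaps).
#' @return The reverse complement, degeneracy-aware (e.g. R <-> Y, D <-> H).
#' @export
revcomp_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  cs <- rev(chars(toupper(x)))
  bad <- setdiff(unique(cs), names(comp))
  if (length(bad) > 0L) {
    stop("non-IUPAC character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  paste(comp[cs], collapse = "")
}

# normalize residues: uppercase, U -> T
normalize_residues <- function(x) {
  gsub("U", "T", toupper(x), fixed = TRUE)
}

# validate residue alphabet; gaps allowed only when aligned
check_alphabet <- function(x, id, aligned) {
  allowed <- c(names(IUPAC_CODES), if (aligned) "-")
  cs <- unique(chars(x))
  bad <- setdiff(cs, allowed)
  if (length(bad) > 0L) {
    stop("record '", id, "' contains invalid character(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
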
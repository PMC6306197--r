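# Intron boundary grammar.  Short rDNA inserts are recognized as spliceosomal
# introns by four ordered features: a 5' donor hexamer matching GTDHNN, an
# internal branch-site pentamer matching YTRAC, a pyrimidine-rich (CT) tract,
# and a 3' acceptor pentamer matching YNHAG (28S inserts additionally carry a
# terminal hexamer matching YTAMAG).  Long inserts lacking the grammar are
# group IC1 intron candidates.

#' Match a fixed-length IUPAC pattern against a DNA window
#'
#' @param pattern IUPAC string.
#' @param window DNA string over A,C,G,T,N of the same length.
#' @param n_mode `"strict"`: an `N` in the window only matches pattern `N`;
#'   `"lenient"`: an `N` in the window matches any pattern letter.
#' @return `TRUE` iff every window base is admitted by the corresponding
#'   pattern letter.
#' @export
match_iupac <- function(pattern, window, n_mode = c("strict", "lenient")) {
  n_mode <- match.arg(n_mode)
  pc <- chars(toupper(pattern))
  wc <- chars(toupper(window))
  if (length(pc) != length(wc)) {
    stop("pattern and window lengths differ (", length(pc), " vs ",
         length(wc), ")")
  }
  if (any(!pc %in% names(IUPAC_CODES))) {
    stop("non-IUPAC character in pattern: ",
         pc[!pc %in% names(IUPAC_CODES)][1L])
  }
  if (any(!wc %in% c("A", "C", "G", "T", "N"))) {
    stop("window must be over A,C,G,T,N; got '",
         wc[!wc %in% c("A", "C", "G", "T", "N")][1L], "'")
  }
  lenient <- n_mode == "lenient"
  all(mapply(iupac_char_match, pc, wc, MoreArgs = list(n_lenient = lenient)))
}

#' Pyrimidine (C+T) fraction of a DNA segment
#'
#' @param segment non-empty DNA string.
#' @return Fraction of positions that are C or T, in `[0, 1]`.
#' @export
pyrimidine_fraction <- function(segment) {
  if (!nzchar(segment)) stop("empty segment")
  cs <- chars(toupper(segment))
  sum(cs %in% c("C", "T")) / length(cs)
}

#' Default spliceosomal grammar parameters
#'
#' @param donor donor consensus at the 5' end (offset 0).
#' @param branch branch-site consensus.
#' @param acceptor acceptor consensus at the 3' terminus (18S and 28S).
#' @param acceptor_28s additional terminal hexamer consensus checked in the
#'   28S.
#' @param ct_window width of the pyrimidine-tract window.
#' @param ct_min_pyr minimum pyrimidine fraction within the window.
#' @param min_len minimum insert length the scanner considers.
#' @return Named list of grammar parameters.
#' @export
sp_grammar_params <- function(donor = "GTDHNN", branch = "YTRAC",
                              acceptor = "YNHAG", acceptor_28s = "YTAMAG",
                              ct_window = 10L, ct_min_pyr = 0.6,
                              min_len = 25L) {
  list(donor = donor, branch = branch, acceptor = acceptor,
       acceptor_28s = acceptor_28s, ct_window = as.integer(ct_window),
       ct_min_pyr = ct_min_pyr, min_len = as.integer(min_len))
}

#' Scan an insert for spliceosomal intron features
#'
#' Requires, in order: the donor hexamer at offset 0, a branch-site pentamer
#' strictly between donor and acceptor with room for a pyrimidine tract, a
#' `ct_window`-wide window with pyrimidine fraction at least `ct_min_pyr`
#' between the branch site and the acceptor, and the acceptor pentamer ending
#' at the 3' terminus.  Among branch candidates the 3'-most one satisfying all
#' constraints is chosen.
#'
#' @param insert ungapped DNA string.
#' @param gene `"SSU18S"` or `"LSU28S"`; for the 28S the terminal hexamer is
#'   additionally compared against the 28S acceptor consensus (reported, not
#'   required).
#' @param params grammar parameters from [sp_grammar_params()].
#' @return A list of class `sp_features` (donor, branch offset and sequence,
#'   pyrimidine-tract window and fraction, acceptor, and for the 28S
#'   `acceptor_28s_match`), or `NULL` when the grammar is not satisfied.
#' @export
scan_spliceosomal <- function(insert, gene = c("SSU18S", "LSU28S"),
                              params = sp_grammar_params()) {
  gene <- match.arg(gene)
  s <- toupper(insert)
  L <- nchar(s)
  dl <- nchar(params$donor)
  al <- nchar(params$acceptor)
  bl <- nchar(params$branch)
  if (L < params$min_len) return(NULL)
  donor <- substr(s, 1L, dl)
  if (!match_iupac(params$donor, donor)) return(NULL)
  acceptor <- substr(s, L - al + 1L, L)
  if (!match_iupac(params$acceptor, acceptor)) return(NULL)
  acc_start <- L - al + 1L
  w <- params$ct_window
  # branch start positions: strictly after the donor, leaving room for the
  # pyrimidine window between branch end and acceptor start
  b_max <- acc_start - 1L - w - bl + 1L
  if (b_max < dl + 1L) return(NULL)
  for (b in seq(b_max, dl + 1L)) {
    cand <- substr(s, b, b + bl - 1L)
    if (!match_iupac(params$branch, cand)) next
    lo <- b + bl
    hi <- acc_start - 1L
    win <- find_pyrimidine_window(s, lo, hi, w, params$ct_min_pyr)
    if (is.null(win)) next
    feats <- list(
      donor = donor, donor_offset = 0L,
      branch = cand, branch_offset = b - 1L,
      ct_window = win$interval, ct_fraction = win$fraction,
      acceptor = acceptor, acceptor_offset = acc_start - 1L)
    if (gene == "LSU28S") {
      a6l <- nchar(params$acceptor_28s)
      feats$acceptor_28s_match <- L >= a6l &&
        match_iupac(params$acceptor_28s, substr(s, L - a6l + 1L, L))
    }
    class(feats) <- "sp_features"
    return(feats)
  }
  NULL
}

# first (5'-most) window of width w within [lo, hi] whose pyrimidine fraction
# reaches min_pyr; NULL when none fits
find_pyrimidine_window <- function(s, lo, hi, w, min_pyr) {
  if (hi - lo + 1L < w) return(NULL)
  cs <- chars(substr(s, lo, hi))
  pyr <- as.integer(cs %in% c("C", "T"))
  run <- cumsum(pyr)
  n <- length(pyr)
  for (i in seq_len(n - w + 1L)) {
    cnt <- run[i + w - 1L] - if (i > 1L) run[i - 1L] else 0L
    if (cnt / w >= min_pyr) {
      return(list(interval = c(lo + i - 1L, lo + i + w - 2L),
                  fraction = cnt / w))
    }
  }
  NULL
}

#' Classify an insert as spliceosomal, group I candidate, ambiguous or partial
#'
#' Complete inserts satisfying the full spliceosomal grammar are `SP`.
#' Inserts with a spliceosomal donor but a failed downstream grammar and
#' length above `nested_min_len` are `ambiguous` (possible intron nested
#' inside another).  Remaining long inserts (at least `gi_min_len`) are group
#' I candidates (`GI`); everything else is `ambiguous`.  Truncated inserts are
#' `partial`, with subtype `SP-like` when their available 5' end carries the
#' donor.
#'
#' @param sequence the insert's ungapped residues.
#' @param complete `FALSE` when the insert is truncated.
#' @param gene `"SSU18S"` or `"LSU28S"`.
#' @param params grammar parameters from [sp_grammar_params()].
#' @param gi_min_len minimum length for a group I candidate (default 350,
#'   below the shortest complete group I insert observed and above the longest
#'   spliceosomal ones).
#' @param nested_min_len length above which a donor-bearing grammar failure is
#'   flagged as a possible nested spliceosomal intron (default 300).
#' @return List with elements `family` (one of `"SP"`, `"GI"`, `"ambiguous"`,
#'   `"partial"`), `subtype` (`""`, `"SP-like"` or `"possible nested SP"`) and
#'   `features` (the `sp_features`, for `SP`).
#' @export
classify_insert <- function(sequence, complete = TRUE,
                            gene = c("SSU18S", "LSU28S"),
                            params = sp_grammar_params(),
                            gi_min_len = 350L, nested_min_len = 300L) {
  gene <- match.arg(gene)
  if (!nzchar(sequence)) stop("empty insert sequence")
  s <- toupper(sequence)
  L <- nchar(s)
  dl <- nchar(params$donor)
  donor_ok <- L >= dl && match_iupac(params$donor, substr(s, 1L, dl))
  if (!complete) {
    return(list(family = "partial",
                subtype = if (donor_ok) "SP-like" else "",
                features = NULL))
  }
  feats <- scan_spliceosomal(s, gene = gene, params = params)
  if (!is.null(feats)) {
    return(list(family = "SP", subtype = "", features = feats))
  }
  if (donor_ok && L > nested_min_len) {
    return(list(family = "ambiguous", subtype = "possible nested SP",
                features = NULL))
  }
  if (L >= gi_min_len) {
    return(list(family = "GI", subtype = "", features = NULL))
  }
  list(family = "ambiguous", subtype = "", features = NULL)
}

#' Classify every record of a detected insert table
#'
#' Convenience wrapper applying [classify_insert()] to each insert's residues
#' taken from the alignment.
#'
#' @param inserts data frame from [detect_inserts()].
#' @param aln the aligned [rdna_set] the inserts came from.
#' @param gene `"SSU18S"` or `"LSU28S"`.
#' @param ... passed to [classify_insert()].
#' @return The insert data frame with `family` and `subtype` filled in and an
#'   `insert_seq` column of ungapped insert residues.
#' @export
classify_inserts <- function(inserts, aln, gene = c("SSU18S", "LSU28S"), ...) {
  gene <- match.arg(gene)
  if (nrow(inserts) == 0L) {
    inserts$subtype <- character(0)
    inserts$insert_seq <- character(0)
    return(inserts)
  }
  sv <- seq_vector(aln)
  seqs <- vapply(seq_len(nrow(inserts)), function(i) {
    seg <- substr(sv[[inserts$seq_id[i]]], inserts$col_start[i] + 1L,
                  inserts$col_end[i])
    gsub("-", "", seg, fixed = TRUE)
  }, character(1))
  cls <- lapply(seq_len(nrow(inserts)), function(i) {
    classify_insert(seqs[i], complete = inserts$complete[i], gene = gene, ...)
  })
  inserts$family <- vapply(cls, `[[`, character(1), "family")
  inserts$subtype <- vapply(cls, `[[`, character(1), "subtype")
  inserts$insert_seq <- seqs
  inserts
}

#' Extract conserved blocks from a set of aligned group I insert sequences
#'
#' Computes per-column mean pairwise identity (over pairs where both
#' sequences carry a residue), smooths it with a centred window, and retains
#' maximal runs of columns whose smoothed identity reaches `min_identity`.
#' Columns that are all-gap are dropped.
#'
#' @param seqs named character vector of two or more aligned, equal-length
#'   insert sequences (gaps as `-`).
#' @param window smoothing window width in columns (default 10).
#' @param min_identity minimum smoothed mean pairwise identity for a column to
#'   be retained (default 0.7).
#' @return List with `per_seq` (named character vector: each sequence's
#'   concatenated retained columns), `blocks` (data frame of retained 1-based
#'   column intervals) and `col_identity` (raw per-column identities).
#' @export
extract_conserved_blocks <- function(seqs, window = 10L, min_identity = 0.7) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must be aligned (equal length)")
  nc <- lens[1L]
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
              nrow = length(seqs), byrow = TRUE)
  colid <- vapply(seq_len(nc), function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) < 2L) return(0)
    pairs <- utils::combn(res, 2L)
    mean(pairs[1L, ] == pairs[2L, ])
  }, numeric(1))
  # centred running mean of width `window`
  half_lo <- floor((window - 1L) / 2L)
  half_hi <- ceiling((window - 1L) / 2L)
  smoothed <- vapply(seq_len(nc), function(j) {
    mean(colid[max(1L, j - half_lo):min(nc, j + half_hi)])
  }, numeric(1))
  keep <- smoothed >= min_identity
  all_gap <- colSums(m != "-") == 0L
  keep <- keep & !all_gap
  spans <- runs_to_spans(keep)
  per_seq <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (sum(keep) == 0L) per_seq <- stats::setNames(rep("", length(seqs)), names(seqs))
  names(per_seq) <- names(seqs)
  list(per_seq = per_seq,
       blocks = data.frame(start = spans$start + 1L, end = spans$end),
       col_identity = colid)
}
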
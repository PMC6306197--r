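# In-silico primer auditing: IUPAC-aware best-site search on core sequences,
# mismatch profiling with critical 3'-end flagging, and amplifiability
# classification of a primer pair given a sequence's intron annotations.
# Reverse primers are stored 5'->3' as synthesized and reverse-complemented
# internally; all reported coordinates are forward-strand positions on the
# core sequence.

# lookup matrix: rows = IUPAC pattern letters, cols = target letters
# (A,C,G,T,N); lenient on 'N' in the target (an undetermined base is not
# counted as a mismatch)
.primer_match_lut <- local({
  targets <- c("A", "C", "G", "T", "N")
  lut <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = length(targets),
                dimnames = list(names(IUPAC_CODES), targets))
  for (p in names(IUPAC_CODES)) {
    lut[p, IUPAC_CODES[[p]]] <- TRUE
    lut[p, "N"] <- TRUE
  }
  lut
})

#' Find the best binding site of a primer on a core sequence
#'
#' Scans every offset of the (reverse-complemented, for reverse primers)
#' primer along the core and returns the site with the fewest IUPAC-aware
#' mismatches; ties go to the smallest start coordinate.  An `N` in the core
#' is not counted as a mismatch.  Mismatch positions are reported as offsets
#' from the primer's 3' end (0 = terminal base).
#'
#' @param core ungapped DNA string (the intron-free core sequence).
#' @param primer one row of a [load_primer_config()] table, or a list with
#'   `name`, `orientation`, `sequence`, `critical_window`.
#' @param seq_id optional id recorded on the hit.
#' @return A list of class `primer_hit`: `primer_name`, `seq_id`,
#'   `orientation`, `start`, `end` (1-based closed interval on the forward
#'   strand), `n_mismatch`, `mismatch_offsets`, `critical`.
#' @export
find_primer_site <- function(core, primer, seq_id = NA_character_) {
  core <- toupper(core)
  pat <- toupper(primer$sequence)
  if (primer$orientation == "reverse") pat <- revcomp_iupac(pat)
  k <- nchar(pat)
  L <- nchar(core)
  if (k > L) stop("primer '", primer$name, "' (", k,
                  " nt) is longer than the core sequence (", L, " nt)")
  pc <- chars(pat)
  cc <- chars(core)
  if (any(!cc %in% c("A", "C", "G", "T", "N"))) {
    stop("core must be ungapped DNA over A,C,G,T,N")
  }
  # column index per core char into the lookup
  ci <- match(cc, colnames(.primer_match_lut))
  pi <- match(pc, rownames(.primer_match_lut))
  best_s <- 1L
  best_mm <- k + 1L
  for (s in seq_len(L - k + 1L)) {
    ok <- .primer_match_lut[cbind(pi, ci[s:(s + k - 1L)])]
    mm <- k - sum(ok)
    if (mm < best_mm) {
      best_mm <- mm
      best_s <- s
      if (mm == 0L) break
    }
  }
  ok <- .primer_match_lut[cbind(pi, ci[best_s:(best_s + k - 1L)])]
  mism_j <- which(!ok)  # positions along the scanned (forward-strand) pattern
  offsets <- if (primer$orientation == "reverse") mism_j - 1L else k - mism_j
  cw <- primer$critical_window
  structure(list(primer_name = primer$name, seq_id = seq_id,
                 orientation = primer$orientation,
                 start = best_s, end = best_s + k - 1L,
                 n_mismatch = length(mism_j),
                 mismatch_offsets = sort(offsets),
                 critical = any(offsets < cw)),
            class = "primer_hit")
}

#' Flag critical 3'-end mismatches on a primer hit
#'
#' @param hit a `primer_hit` from [find_primer_site()].
#' @param critical_window number of 3'-terminal primer bases in which a
#'   mismatch is considered critical (default: the window stored on the hit's
#'   primer, i.e. the value already applied).
#' @return `TRUE` iff any mismatch offset (counted from the 3' end, 0 =
#'   terminal base) is smaller than `critical_window`.
#' @export
flag_critical <- function(hit, critical_window = NULL) {
  stopifnot(inherits(hit, "primer_hit"))
  if (is.null(critical_window)) return(hit$critical)
  any(hit$mismatch_offsets < critical_window)
}

#' Audit a primer pair against one sequence and its intron annotations
#'
#' Classifies the sequence as `primer_disrupted` when any intron's flanking
#' pair lies strictly inside either primer's target interval (an insert
#' abutting the interval's outer edge does not block annealing),
#' `critical_mismatch` when either hit has a critical 3'-end mismatch or more
#' than `max_mismatch` mismatches overall, `region_incomplete` when the core
#' lacks a recognizable target for either primer, and `amplifiable` otherwise.
#' The total amplicon length adds the lengths of introns whose flank pairs lie
#' between the two primer intervals.
#'
#' @param core ungapped core DNA string.
#' @param inserts data frame of this sequence's inserts (`flank5`, `flank3`,
#'   `observed_len`; zero rows for none).
#' @param fwd,rev forward and reverse primer rows ([load_primer_config()]).
#' @param max_mismatch maximum tolerated mismatches per primer (default 2).
#' @param absent_frac when a primer's best site mismatches more than this
#'   fraction of its length, the target region is considered missing from the
#'   core (default 0.25).
#' @param seq_id optional id recorded on the result.
#' @return A list of class `amplicon_status`: `seq_id`, `status`,
#'   `fwd_hit`, `rev_hit`, `amplicon_core_len`, `amplicon_total_len`,
#'   `disrupting_locations` (data frame of flank pairs inside primer targets).
#' @export
audit_amplicon <- function(core, inserts, fwd, rev, max_mismatch = 2L,
                           absent_frac = 0.25, seq_id = NA_character_) {
  if (is.null(inserts) || nrow(inserts) == 0L) {
    inserts <- data.frame(flank5 = integer(), flank3 = integer(),
                          observed_len = integer())
  }
  mk <- function(status, fh = NULL, rh = NULL, core_len = NA_integer_,
                 total_len = NA_integer_, disrupting = NULL) {
    structure(list(seq_id = seq_id, status = status, fwd_hit = fh,
                   rev_hit = rh, amplicon_core_len = core_len,
                   amplicon_total_len = total_len,
                   disrupting_locations = disrupting),
              class = "amplicon_status")
  }
  L <- nchar(core)
  if (L < nchar(fwd$sequence) || L < nchar(rev$sequence)) {
    return(mk("region_incomplete"))
  }
  fh <- find_primer_site(core, fwd, seq_id = seq_id)
  rh <- find_primer_site(core, rev, seq_id = seq_id)
  if (fh$n_mismatch > ceiling(absent_frac * nchar(fwd$sequence)) ||
      rh$n_mismatch > ceiling(absent_frac * nchar(rev$sequence))) {
    return(mk("region_incomplete", fh, rh))
  }
  if (rh$start <= fh$end) {
    stop("reverse primer site [", rh$start, ",", rh$end,
         "] is not downstream of the forward site [", fh$start, ",", fh$end, "]")
  }
  inside <- function(p5, int) p5 >= int[1L] & p5 <= int[2L] - 1L
  dis <- inside(inserts$flank5, c(fh$start, fh$end)) |
         inside(inserts$flank5, c(rh$start, rh$end))
  between <- inserts$flank5 >= fh$end & inserts$flank3 <= rh$start
  core_len <- rh$end - fh$start + 1L
  total_len <- core_len + sum(inserts$observed_len[between])
  disrupting <- inserts[dis, c("flank5", "flank3"), drop = FALSE]
  if (any(dis)) {
    return(mk("primer_disrupted", fh, rh, core_len, total_len, disrupting))
  }
  if (fh$critical || rh$critical ||
      fh$n_mismatch > max_mismatch || rh$n_mismatch > max_mismatch) {
    return(mk("critical_mismatch", fh, rh, core_len, total_len, disrupting))
  }
  mk("amplifiable", fh, rh, core_len, total_len, disrupting)
}

#' Extract the marker region between two primer hits
#'
#' @param core ungapped core DNA string.
#' @param fwd_hit,rev_hit `primer_hit` objects with the reverse site
#'   downstream of the forward site.
#' @param include_primers include both primer target intervals (default
#'   `FALSE`: the region strictly between them).
#' @return DNA string of the region.
#' @export
extract_region <- function(core, fwd_hit, rev_hit, include_primers = FALSE) {
  stopifnot(inherits(fwd_hit, "primer_hit"), inherits(rev_hit, "primer_hit"))
  if (rev_hit$start <= fwd_hit$end) {
    stop("reverse primer site is not downstream of the forward site")
  }
  if (include_primers) {
    return(substr(core, fwd_hit$start, rev_hit$end))
  }
  a <- fwd_hit$end + 1L
  b <- rev_hit$start - 1L
  if (a > b) stop("empty region between primer sites")
  substr(core, a, b)
}
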
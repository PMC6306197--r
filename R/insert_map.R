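# Insert detection and coordinate mapping.  An "insert column" is an alignment
# column where the intron-free reference row carries a gap and only a minority
# of rows carry residues; maximal runs of such columns are the insert spans.
# Each insert is mapped to the pair of reference core nucleotides flanking it
# (1-based positions p5 and p3 = p5 + 1), the coordinate convention used to
# index intron locations across taxa.

#' Detect insertions in an alignment relative to an intron-free reference row
#'
#' A column is called an insert column when the reference row has `-` and the
#' fraction of rows with a residue in that column is at most
#' `presence_max_frac`.  Maximal runs of insert columns form spans; every
#' sequence with at least `min_len` residues inside a span yields one insert
#' record.  Runs of reference gaps touching the alignment ends are treated as
#' frayed termini, not inserts.
#'
#' An insert is flagged incomplete (`complete = FALSE`) when its span touches
#' an alignment end or when the nearest residue of the host sequence on either
#' side of the span is an `N` (sequencing ran into, but not through, the
#' insert).
#'
#' @param aln an aligned [rdna_set].
#' @param reference_id id of the reference row, assumed intron-free.
#' @param presence_max_frac maximum fraction of rows that may carry residues in
#'   an insert column (default 0.5).
#' @param min_len minimum number of residues a sequence must have in a span to
#'   be reported (default 1).
#' @return Data frame with one row per (sequence, span): `seq_id`, `taxon`,
#'   `col_start`/`col_end` (0-based half-open alignment columns), `flank5`/
#'   `flank3` (1-based reference core positions flanking the insert),
#'   `observed_len`, `complete`, `family` (`NA`, assigned by the classifier).
#'   Frayed terminal spans, if any, are recorded in the `"frayed"` attribute.
#' @export
detect_inserts <- function(aln, reference_id, presence_max_frac = 0.5,
                           min_len = 1L) {
  stopifnot(inherits(aln, "rdna_set"))
  if (!isTRUE(attr(aln, "aligned"))) stop("detect_inserts requires an aligned set")
  if (!reference_id %in% aln$id) {
    stop("reference id '", reference_id, "' not present in alignment")
  }
  m <- aln_matrix(aln)
  nc <- ncol(m)
  ref <- m[reference_id, ]
  ref_gap <- ref == "-"
  nongap_frac <- colMeans(m != "-")
  candidate <- ref_gap & nongap_frac <= presence_max_frac

  # frayed termini: reference-gap runs touching either alignment end
  frayed <- logical(nc)
  r <- rle(ref_gap)
  if (r$values[1L]) frayed[seq_len(r$lengths[1L])] <- TRUE
  nr <- length(r$values)
  if (r$values[nr]) frayed[(nc - r$lengths[nr] + 1L):nc] <- TRUE
  frayed_spans <- runs_to_spans(frayed)
  candidate <- candidate & !frayed

  if (any(ref_gap & !candidate & !frayed)) {
    warning("reference row '", reference_id,
            "' has gap(s) outside insert columns (",
            sum(ref_gap & !candidate & !frayed), " column(s))")
  }

  spans <- runs_to_spans(candidate)
  ref_res_before <- cumsum(!ref_gap)  # reference residues in columns 1..k

  out <- list()
  taxon_of <- stats::setNames(aln$taxon, aln$id)
  for (s in seq_len(nrow(spans))) {
    a <- spans$start[s]  # 0-based start
    b <- spans$end[s]    # 0-based half-open end
    cols <- (a + 1L):b
    p5 <- if (a == 0L) 0L else ref_res_before[a]
    for (id in aln$id) {
      seg <- m[id, cols]
      obs <- sum(seg != "-")
      if (obs < min_len) next
      incomplete <- a == 0L || b == nc ||
        flank_is_N(m[id, ], a, side = "left") ||
        flank_is_N(m[id, ], b, side = "right")
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, taxon = unname(taxon_of[id]),
        col_start = a, col_end = b,
        flank5 = p5, flank3 = p5 + 1L,
        observed_len = obs, complete = !incomplete,
        family = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(seq_id = character(), taxon = character(),
               col_start = integer(), col_end = integer(),
               flank5 = integer(), flank3 = integer(),
               observed_len = integer(), complete = logical(),
               family = character(), stringsAsFactors = FALSE)
  attr(res, "frayed") <- frayed_spans
  attr(res, "n_cols") <- nc
  res
}

# maximal TRUE runs as 0-based half-open spans
runs_to_spans <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# is the nearest residue of `row` outside column boundary `pos` an 'N'?
# pos is the 0-based boundary: left side looks at columns pos..1 downward,
# right side at columns pos+1..n upward.
flank_is_N <- function(row, pos, side) {
  if (side == "left") {
    idx <- if (pos >= 1L) rev(seq_len(pos)) else integer()
  } else {
    n <- length(row)
    idx <- if (pos < n) (pos + 1L):n else integer()
  }
  for (i in idx) {
    if (row[i] != "-") return(row[i] == "N")
  }
  FALSE
}

#' Group insert records into cross-taxon intron locations
#'
#' One location per distinct flanking pair, ordered by the 5' flank and
#' indexed 1..n.  Adjacent flank pairs remain distinct locations.
#'
#' @param inserts data frame from [detect_inserts()].
#' @param gene gene tag recorded on each location.
#' @return Data frame with columns `gene`, `location`, `flank5`, `flank3`,
#'   `n_members` and a list column `members` of sequence ids.
#' @export
group_locations <- function(inserts, gene = c("SSU18S", "LSU28S", "other")) {
  gene <- match.arg(gene)
  if (nrow(inserts) == 0L) {
    return(data.frame(gene = character(), location = integer(),
                      flank5 = integer(), flank3 = integer(),
                      n_members = integer(), members = I(list()),
                      stringsAsFactors = FALSE))
  }
  key <- paste(inserts$flank5, inserts$flank3)
  groups <- split(inserts, key)
  p5 <- vapply(groups, function(g) g$flank5[1L], integer(1))
  ord <- order(p5)
  groups <- groups[ord]
  data.frame(
    gene = gene,
    location = seq_along(groups),
    flank5 = vapply(groups, function(g) g$flank5[1L], integer(1)),
    flank3 = vapply(groups, function(g) g$flank3[1L], integer(1)),
    n_members = vapply(groups, nrow, integer(1)),
    members = I(unname(lapply(groups, function(g) sort(g$seq_id)))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove insert spans from an alignment and recover core sequences
#'
#' Deletes every insert-column span and returns the core alignment, per-
#' sequence ungapped core sequences, and the removed spans.  Re-inserting the
#' removed segments at their flank pairs reconstructs each original sequence.
#'
#' @param aln the aligned [rdna_set] the inserts were detected in.
#' @param inserts data frame from [detect_inserts()] (or manually built spans;
#'   overlapping spans raise an error).
#' @return List with elements `core_alignment` (an aligned [rdna_set]),
#'   `per_seq_core` (named character vector of ungapped core sequences) and
#'   `removed_spans` (data frame of 0-based half-open column spans).
#' @export
extract_core <- function(aln, inserts) {
  stopifnot(inherits(aln, "rdna_set"))
  if (!isTRUE(attr(aln, "aligned"))) stop("extract_core requires an aligned set")
  nc <- aln_ncols(aln)
  spans <- unique(inserts[, c("col_start", "col_end"), drop = FALSE])
  if (nrow(spans) > 1L) {
    spans <- spans[order(spans$col_start), , drop = FALSE]
    if (any(spans$col_start[-1L] < spans$col_end[-nrow(spans)])) {
      stop("overlapping insert spans")
    }
  }
  drop <- logical(nc)
  for (s in seq_len(nrow(spans))) {
    drop[(spans$col_start[s] + 1L):spans$col_end[s]] <- TRUE
  }
  m <- aln_matrix(aln)
  core_m <- m[, !drop, drop = FALSE]
  core_res <- apply(core_m, 1L, paste, collapse = "")
  core_aln <- rdna_set(id = aln$id, taxon = aln$taxon,
                       residues = unname(core_res), aligned = TRUE,
                       gene = attr(aln, "gene"))
  per_seq <- gsub("-", "", core_res, fixed = TRUE)
  list(core_alignment = core_aln,
       per_seq_core = per_seq,
       removed_spans = data.frame(col_start = spans$col_start,
                                  col_end = spans$col_end))
}

#' Tabulate inserts per taxon and per location
#'
#' Works on either a loaded fixture ([load_insert_table()]) or a detected
#' insert data frame.  Per taxon it reports the number of inserts and the sum
#' of maximum lengths (a length range contributes its upper bound; a partial
#' insert contributes its printed/observed minimum).  Per location it reports
#' the number of carrier taxa and the min/max of complete lengths.
#'
#' @param x an `insert_table` or a data frame from [detect_inserts()].
#' @param gene restrict the per-taxon summary to one gene (default `"SSU18S"`
#'   for fixtures, matching the convention that per-taxon counts are quoted
#'   for the 18S).
#' @return List with data frames `per_taxon` (`taxon`, `n_inserts`,
#'   `sum_max_len`) and `per_location` (`gene`, `location`, `family`,
#'   `n_taxa`, `min_complete_len`, `max_complete_len`).
#' @export
tabulate_inserts <- function(x, gene = "SSU18S") {
  if (inherits(x, "insert_table")) {
    cells <- x$cells
    per_taxon_cells <- cells[cells$gene == gene, , drop = FALSE]
    taxa <- x$taxa
    loc_rows <- x$rows
  } else {
    stopifnot(is.data.frame(x))
    if (nrow(x) == 0L) {
      return(list(
        per_taxon = data.frame(taxon = character(), n_inserts = integer(),
                               sum_max_len = integer()),
        per_location = data.frame(gene = character(), location = integer(),
                                  family = character(), n_taxa = integer(),
                                  min_complete_len = integer(),
                                  max_complete_len = integer())))
    }
    # collapse detected records to per-(taxon, flank pair) maximum lengths
    tx <- ifelse(nzchar(x$taxon), x$taxon, x$seq_id)
    key <- paste(x$flank5, x$flank3)
    locs <- group_locations(x, gene = gene)
    loc_of <- stats::setNames(locs$location, paste(locs$flank5, locs$flank3))
    fam_by_key <- vapply(split(x$family, key), function(f) {
      f <- unique(f[!is.na(f)])
      if (length(f) == 1L) f else if (length(f) == 0L) NA_character_ else "mixed"
    }, character(1))
    locs$family <- unname(fam_by_key[paste(locs$flank5, locs$flank3)])
    cell_idx <- split(seq_len(nrow(x)), paste(tx, key, sep = "\r"))
    cells <- do.call(rbind, lapply(cell_idx, function(ii) {
      k <- key[ii[1L]]
      data.frame(gene = gene, location = unname(loc_of[k]),
                 family = unname(fam_by_key[k]), taxon = tx[ii[1L]],
                 min_len = min(x$observed_len[ii]),
                 max_len = max(x$observed_len[ii]),
                 complete = any(x$complete[ii]), stringsAsFactors = FALSE)
    }))
    rownames(cells) <- NULL
    per_taxon_cells <- cells
    taxa <- sort(unique(tx))
    loc_rows <- locs
  }

  per_taxon <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  per_taxon$n_inserts <- vapply(taxa, function(t) {
    sum(per_taxon_cells$taxon == t)
  }, integer(1))
  per_taxon$sum_max_len <- vapply(taxa, function(t) {
    sel <- per_taxon_cells$taxon == t
    as.integer(sum(per_taxon_cells$max_len[sel]))
  }, integer(1))

  all_cells <- if (inherits(x, "insert_table")) x$cells else per_taxon_cells
  per_location <- do.call(rbind, lapply(seq_len(nrow(loc_rows)), function(i) {
    g <- loc_rows$gene[i]; loc <- loc_rows$location[i]
    sel <- all_cells$gene == g & all_cells$location == loc
    comp <- sel & all_cells$complete
    data.frame(
      gene = g, location = loc,
      family = if ("family" %in% names(loc_rows)) loc_rows$family[i] else NA_character_,
      n_taxa = sum(sel),
      min_complete_len = if (any(comp)) min(all_cells$min_len[comp]) else NA_integer_,
      max_complete_len = if (any(comp)) max(all_cells$max_len[comp]) else NA_integer_,
      stringsAsFactors = FALSE)
  }))
  list(per_taxon = per_taxon, per_location = per_location)
}

#' Render a flank pair in the reporting convention
#'
#' @param flank5,flank3 1-based reference core positions flanking an insert.
#' @return Character like `"385-386"` (5' flank, dash, 3' flank).
#' @export
render_flank <- function(flank5, flank3) paste0(flank5, "–", flank3)
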
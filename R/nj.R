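# Pairwise distances and neighbor-joining.  The NJ implementation follows the
# classical Saitou-Nei agglomeration with a fixed determinism contract: ties
# on the Q criterion are broken by the smallest (i, j) pair in label order,
# and negative branch-length estimates are clamped to zero with a warning.
# Trees are returned as ape "phylo" objects.

#' Proportion of differing sites between two aligned sequences
#'
#' Positions where either sequence carries `-` or `N` are skipped.
#'
#' @param a,b equal-length aligned DNA strings.
#' @return Fraction of compared sites that differ.
#' @export
p_distance <- function(a, b) {
  ca <- chars(toupper(a))
  cb <- chars(toupper(b))
  if (length(ca) != length(cb)) {
    stop("sequence lengths differ (", length(ca), " vs ", length(cb), ")")
  }
  ok <- !(ca %in% c("-", "N")) & !(cb %in% c("-", "N"))
  if (!any(ok)) stop("no comparable sites")
  mean(ca[ok] != cb[ok])
}

#' Pairwise p-distance matrix
#'
#' @param seqs named character vector of aligned, equal-length sequences.
#' @param jc apply the Jukes-Cantor correction `-3/4 log(1 - 4p/3)` to each
#'   distance (default `FALSE`: raw p-distances).
#' @return Symmetric numeric matrix with zero diagonal, labelled by `names(seqs)`.
#' @export
p_distance_matrix <- function(seqs, jc = FALSE) {
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        p <- p_distance(seqs[[i]], seqs[[j]])
        if (jc) {
          if (p >= 0.75) stop("p-distance ", p, " not correctable under Jukes-Cantor")
          p <- -0.75 * log(1 - 4 * p / 3)
        }
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor-joining (Saitou-Nei Q criterion, standard branch-length
#' formulas).  Ties on Q are broken by the smallest (i, j) pair in label
#' order, making the output deterministic; negative branch-length estimates
#' are clamped to zero with a warning.
#'
#' @param dm symmetric numeric matrix with zero diagonal and unique dimnames;
#'   at least 3 labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  ape::read.tree(text = nj_newick(dm))
}

# newick-string core of nj_tree; exposed internally so callers can edit the
# string (e.g. to attach zero-length duplicate leaves) before parsing
nj_newick <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  labels <- rownames(dm)
  if (is.null(labels) || anyDuplicated(labels)) stop("dm needs unique dimnames")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) stop("dm must be symmetric")
  if (any(diag(dm) != 0)) stop("dm must have a zero diagonal")
  if (any(dm < 0)) stop("dm must be non-negative")
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa (got ", n, ")")

  frag <- labels            # newick fragment per active node
  d <- dm
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    # Q criterion; pick the smallest (i, j) in current label order on ties
    best <- NULL
    best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) {
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    d <- d2
  }
  # resolve the final three nodes around the central vertex
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  paste0("(", frag[1L], ":", fmt(la), ",", frag[2L], ":", fmt(lb), ",",
         frag[3L], ":", fmt(lc), ");")
}
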
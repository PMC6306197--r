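# Terminal-taxon delineation and marker-region discriminability.  Terminal
# taxa are groups of identical and near-identical core sequences; a marker
# region discriminates two taxa when their region haplotypes differ.  Region
# trees are built by neighbor-joining over p-distances and compared to
# full-gene trees by clade recovery (bipartition monophyly on unrooted trees).

#' Delineate terminal taxa from near-identical core sequences
#'
#' Sequences are end-trimmed to the shortest length, pairwise Hamming-style
#' differences (skipping positions where either sequence has `N`) are
#' computed, and single-linkage clusters with linkage at `max_diff` or fewer
#' differences become terminal taxa.  Labels `taxon_001`, `taxon_002`, ... are
#' assigned in order of the representative (lexicographically smallest) id.
#'
#' @param cores named character vector of ungapped core sequences of one gene.
#' @param max_diff maximum pairwise difference count for linkage (default 2).
#' @return Data frame with columns `label`, `representative`, `n_members` and
#'   a list column `members`; the member sets partition the input ids.
#' @export
delineate_terminal_taxa <- function(cores, max_diff = 2L) {
  n <- length(cores)
  if (n == 0L) stop("empty input")
  if (is.null(names(cores)) || anyDuplicated(names(cores))) {
    stop("core sequences must have unique names")
  }
  ids <- names(cores)
  len <- min(nchar(cores))
  mat <- matrix(unlist(strsplit(substr(toupper(cores), 1L, len), "",
                                fixed = TRUE)), nrow = n, byrow = TRUE)
  # single-linkage components over the <= max_diff relation
  comp <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- mat[i, ] != "N" & mat[j, ] != "N"
        ndiff <- sum(mat[i, ok] != mat[j, ok])
        if (ndiff <= max_diff) {
          ci <- comp[i]; cj <- comp[j]
          if (ci != cj) comp[comp == cj] <- ci
        }
      }
    }
  }
  groups <- split(ids, comp)
  reps <- vapply(groups, function(g) min(g), character(1))
  groups <- groups[order(reps)]
  reps <- sort(reps)
  data.frame(
    label = sprintf("taxon_%03d", seq_along(groups)),
    representative = reps,
    n_members = vapply(groups, length, integer(1)),
    members = I(unname(lapply(groups, sort))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Report which taxa a marker region fails to discriminate
#'
#' Taxa sharing any identical full-length region haplotype fall into one
#' collapsed group; taxa whose haplotypes are unique are discriminable.
#' Incomplete haplotypes are excluded from equality testing; taxa with only
#' incomplete haplotypes are listed separately.
#'
#' @param regions data frame with columns `taxon`, `haplotype` and optionally
#'   `complete` (default `TRUE`); a taxon may contribute several haplotypes.
#' @param marker marker name recorded on the report.
#' @return A list of class `collapse_report`: `marker`, `groups` (list of
#'   character vectors of taxon labels, each of size >= 2), `n_groups`,
#'   `collapsed_taxa` (number of taxa inside groups), `discriminable_count`
#'   and `incomplete_taxa`.
#' @export
collapse_report <- function(regions, marker = "region") {
  stopifnot(is.data.frame(regions), all(c("taxon", "haplotype") %in% names(regions)))
  if (!"complete" %in% names(regions)) regions$complete <- TRUE
  taxa <- unique(regions$taxon)
  usable <- regions[regions$complete, , drop = FALSE]
  incomplete_taxa <- sort(setdiff(taxa, unique(usable$taxon)))
  utaxa <- unique(usable$taxon)
  # connect taxa sharing any identical haplotype
  comp <- stats::setNames(seq_along(utaxa), utaxa)
  for (h in split(usable$taxon, usable$haplotype)) {
    h <- unique(h)
    if (length(h) > 1L) {
      tgt <- comp[[h[1L]]]
      comp[comp %in% comp[h]] <- tgt
    }
  }
  groups <- split(utaxa, comp[utaxa])
  groups <- lapply(groups, sort)
  collapsed <- groups[vapply(groups, length, integer(1)) >= 2L]
  ord <- order(vapply(collapsed, `[[`, character(1), 1L))
  collapsed <- unname(collapsed[ord])
  n_collapsed <- sum(vapply(collapsed, length, integer(1)))
  structure(list(marker = marker, groups = collapsed,
                 n_groups = length(collapsed),
                 collapsed_taxa = n_collapsed,
                 discriminable_count = length(utaxa) - n_collapsed,
                 incomplete_taxa = incomplete_taxa),
            class = "collapse_report")
}

#' @export
print.collapse_report <- function(x, ...) {
  cat("collapse_report [", x$marker, "]: ", x$n_groups,
      " collapsed group(s), ", x$discriminable_count, " discriminable taxa",
      if (length(x$incomplete_taxa) > 0L)
        paste0(", ", length(x$incomplete_taxa), " incomplete") else "",
      "\n", sep = "")
  invisible(x)
}

# escape a label for use inside a newick string built by nj_newick
sanitize_label <- function(x) gsub("[^A-Za-z0-9_.|-]", "_", x)

#' Neighbor-joining tree of marker-region haplotypes
#'
#' Builds an NJ tree over the distinct haplotypes (p-distances) and attaches
#' taxa sharing a haplotype as zero-length sibling leaves.
#'
#' @param haps named character vector: one aligned region haplotype per taxon
#'   (names are taxon labels).
#' @param jc use Jukes-Cantor corrected distances (default `FALSE`).
#' @return An unrooted `ape::phylo` tree with one leaf per taxon.
#' @export
region_tree <- function(haps, jc = FALSE) {
  if (is.null(names(haps)) || anyDuplicated(names(haps))) {
    stop("haplotypes must be named by unique taxon labels")
  }
  labs <- sanitize_label(names(haps))
  names(haps) <- labs
  groups <- split(labs, unname(haps[labs]))
  reps <- vapply(groups, `[[`, character(1), 1L)
  if (length(groups) < 3L) {
    stop("need at least 3 distinct haplotypes (got ", length(groups), ")")
  }
  dm <- p_distance_matrix(stats::setNames(names(groups), reps), jc = jc)
  nwk <- nj_newick(dm)
  for (g in groups) {
    if (length(g) > 1L) {
      rep <- g[1L]
      sub <- paste0("(", paste0(g, ":0", collapse = ","), "):")
      nwk <- sub(paste0("(?<=[(,])", rep, ":"), sub, nwk, perl = TRUE)
    }
  }
  ape::read.tree(text = nwk)
}

#' Test monophyly of a tip set on an unrooted tree
#'
#' A tip set is monophyletic on an unrooted tree iff some edge splits exactly
#' that set from the remaining leaves; singletons and sets missing at most
#' one leaf qualify trivially.
#'
#' @param tree an `ape::phylo` tree.
#' @param tips character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic_unrooted <- function(tree, tips) {
  all_tips <- tree$tip.label
  stopifnot(all(tips %in% all_tips))
  k <- length(tips)
  n <- length(all_tips)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(match(tips, all_tips))
  comp <- sort(setdiff(seq_len(n), target))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

#' Fraction of groups recovered as monophyletic in both trees
#'
#' Monophyly on the unrooted trees is evaluated as bipartition membership: a
#' group is monophyletic iff some edge splits exactly that group from the
#' remaining leaves.
#'
#' @param reference_tree,test_tree `ape::phylo` trees over the same leaf set.
#' @param groups named list of character vectors of leaf labels.
#' @return List with `recovered_fraction` and a named logical vector
#'   `per_group` (`TRUE` when the group is monophyletic in both trees).
#' @export
clade_recovery <- function(reference_tree, test_tree, groups) {
  a <- sort(reference_tree$tip.label)
  b <- sort(test_tree$tip.label)
  if (!identical(a, b)) {
    stop("leaf sets differ: ",
         paste(union(setdiff(a, b), setdiff(b, a)), collapse = ", "))
  }
  per_group <- vapply(groups, function(g) {
    is_monophyletic_unrooted(reference_tree, g) &&
      is_monophyletic_unrooted(test_tree, g)
  }, logical(1))
  list(recovered_fraction = mean(per_group), per_group = per_group)
}
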
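test_that("terminal taxa cluster identical and near-identical sequences", {
  same <- setNames(rep(strrep("ACGT", 25), 3), c("b", "a", "c"))
  tt <- delineate_terminal_taxa(same)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$representative, "a")
  expect_equal(tt$members[[1]], c("a", "b", "c"))

  far <- same
  s <- strsplit(far[["c"]], "")[[1]]
  s[seq(1, 80, 2)] <- "T"
  far[["c"]] <- paste(s, collapse = "")
  tt <- delineate_terminal_taxa(far, max_diff = 2)
  expect_equal(nrow(tt), 2L)
  expect_equal(tt$label, c("taxon_001", "taxon_002"))
  expect_error(delineate_terminal_taxa(character(0)), "empty")
})

test_that("single-linkage chains merge through intermediates", {
  base <- strrep("A", 100)
  mut <- function(x, pos, to) { substr(x, pos, pos) <- to; x }
  cores <- c(a = base, b = mut(base, 10, "C"), c = mut(mut(base, 10, "C"), 50, "G"))
  # a~b 1 diff, b~c 1 diff, a~c 2 diffs: max_diff 1 still merges all three
  tt <- delineate_terminal_taxa(cores, max_diff = 1)
  expect_equal(nrow(tt), 1L)
  # brute-force single-linkage oracle: transitive closure of the <= 1 relation
  diffs <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  adj <- outer(cores, cores, Vectorize(diffs)) <= 1
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(apply(adj, 1, function(r) paste(sort(names(cores)[r]), collapse = "")))
  expect_equal(length(comps), nrow(tt))
})

test_that("taxon delineation partitions the input and coarsens monotonically", {
  set.seed(202)
  tree <- clade_tree(4, 3, stem_length = 0.1, within_length = 0.0005)
  sim <- simulate_core(tree, core_length = 1200)
  prev <- Inf
  for (md in c(0, 2, 5, 20, 1000)) {
    tt <- delineate_terminal_taxa(sim$seqs, max_diff = md)
    members <- sort(unlist(tt$members))
    expect_equal(members, sort(names(sim$seqs)))       # partition
    expect_lte(nrow(tt), prev)                         # monotone coarsening
    prev <- nrow(tt)
  }
  # clades separated far beyond max_diff resolve to exactly k taxa
  tt <- delineate_terminal_taxa(sim$seqs, max_diff = 5)
  expect_equal(nrow(tt), 4L)
})

test_that("collapse reports group taxa sharing a haplotype", {
  reg <- data.frame(taxon = c("diadema1", "diadema2", "rotosporus", "x", "y"),
                    haplotype = c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG"))
  cr <- collapse_report(reg, marker = "V9")
  expect_equal(cr$n_groups, 1L)
  expect_equal(cr$groups[[1]], c("diadema1", "diadema2", "rotosporus"))
  expect_equal(cr$discriminable_count, 2L)
  expect_equal(cr$collapsed_taxa, 3L)

  uniq <- data.frame(taxon = letters[1:4], haplotype = c("A", "C", "G", "T"))
  cu <- collapse_report(uniq)
  expect_equal(cu$n_groups, 0L)
  expect_equal(cu$discriminable_count, 4L)

  # incomplete haplotypes are excluded, their taxa listed separately
  inc <- rbind(reg, data.frame(taxon = "z", haplotype = "AA"))
  inc$complete <- c(rep(TRUE, 5), FALSE)
  ci <- collapse_report(inc)
  expect_equal(ci$incomplete_taxa, "z")
  expect_equal(ci$n_groups, 1L)
})

test_that("region trees dereplicate haplotypes into zero-length siblings", {
  haps <- c(A = "AAAAAAAAAA", B = "CCCCCAAAAA", C = "GGGGGGGGAA",
            D = "AAAAAAAAAA")
  tr <- region_tree(haps)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  blen <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(blen["A"]), 0)
  expect_equal(unname(blen["D"]), 0)
  # A and D must be sisters
  expect_true(is_monophyletic_unrooted(tr, c("A", "D")))
  expect_error(region_tree(haps[c(1, 2, 4)]), "3 distinct")
})

test_that("three-haplotype region trees carry closed-form branch lengths", {
  # pairwise p-distances: d(A,B)=0.2, d(A,C)=0.3, d(B,C)=0.4 over 10 sites
  haps <- c(A = "AAAAAAAAAA", B = "CCAAAAAAAA", C = "AGGGAAAAAA")
  d <- p_distance_matrix(haps)
  expect_equal(unname(d["A", "B"]), 0.2)
  tr <- region_tree(haps)
  blen <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(blen["A"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(blen["B"]), 0.15, tolerance = 1e-12)
  expect_equal(unname(blen["C"]), 0.25, tolerance = 1e-12)
})

test_that("clade recovery tests bipartition monophyly in both trees", {
  ref <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  same <- ape::read.tree(text = "((c:1,d:1):1,(a:1,b:1):1,(f:1,e:1):1);")
  groups <- list(g1 = c("a", "b"), g2 = c("c", "d"), g3 = c("e", "f"))
  cr <- clade_recovery(ref, same, groups)
  expect_equal(cr$recovered_fraction, 1.0)

  # split a group across the test tree
  test <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1,(e:1,f:1):1);")
  cr <- clade_recovery(ref, test, groups)
  expect_false(cr$per_group[["g1"]])
  expect_false(cr$per_group[["g2"]])
  expect_true(cr$per_group[["g3"]])
  # singleton groups are always monophyletic
  expect_true(clade_recovery(ref, test, list(s = "a"))$per_group[["s"]])
  expect_error(clade_recovery(ref, ape::drop.tip(test, "a"), groups),
               "leaf sets differ")
})

test_that("unrooted monophyly agrees with a rooted oracle on random trees", {
  set.seed(404)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(7))
    tips <- sample(tr$tip.label, sample(2:5, 1))
    out <- setdiff(tr$tip.label, tips)[1]
    oracle <- ape::is.monophyletic(ape::root(tr, outgroup = out,
                                             resolve.root = TRUE), tips)
    expect_equal(is_monophyletic_unrooted(tr, tips), oracle)
  }
})

test_that("region trees on generated clades recover the generating structure", {
  set.seed(505)
  tree <- clade_tree(4, 3, stem_length = 0.12, within_length = 0.002)
  sim <- simulate_core(tree, core_length = 1500)
  region <- substr(sim$seqs, 201, 590)   # V4-like width
  rt <- region_tree(region)
  full_tree <- ape::unroot(tree)
  groups <- split(tree$tip.label, sub("t[0-9]+$", "", tree$tip.label))
  cr <- clade_recovery(full_tree, rt, groups)
  expect_equal(cr$recovered_fraction, 1.0)
})
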
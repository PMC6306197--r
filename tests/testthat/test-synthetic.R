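test_that("zero-length branches copy the root; negative branches error", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  sim <- simulate_core(tr, core_length = 500)
  expect_equal(length(unique(sim$seqs)), 1L)
  bad <- ape::read.tree(text = "((a:0.1,b:-0.1):0.1,c:0.1);")
  expect_error(simulate_core(bad, core_length = 100), "negative branch")
})

test_that("default core length falls in the observed 18S range", {
  set.seed(91)
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,c:0.01);")
  sim <- simulate_core(tr)
  expect_gte(sim$core_length, 1669L)
  expect_lte(sim$core_length, 1703L)
  expect_equal(unique(nchar(sim$seqs)), sim$core_length)
})

test_that("observed divergence matches the Jukes-Cantor expectation", {
  # two tips, branch length t each: expected p = 3/4 (1 - exp(-8 t / 3))
  t <- 0.1
  L <- 1000L
  expected <- 0.75 * (1 - exp(-8 * t / 3))
  set.seed(314)
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t, t))
  ps <- replicate(50, {
    sim <- simulate_core(tr, core_length = L)
    p_distance(sim$seqs[["a"]], sim$seqs[["b"]])
  })
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("sampled spliceosomal introns always satisfy the scanner grammar", {
  set.seed(1000)
  for (gene in c("SSU18S", "LSU28S")) {
    draws <- replicate(250, sample_spliceosomal_intron(gene = gene))
    lens <- nchar(draws)
    expect_true(all(lens >= 96 & lens <= 199))
    expect_true(all(startsWith(draws, "GT")))
    expect_true(all(endsWith(draws, "AG")))
    ok <- vapply(draws, function(s) !is.null(scan_spliceosomal(s, gene = gene)),
                 logical(1))
    expect_true(all(ok))
  }
  expect_error(sample_spliceosomal_intron(len_range = c(10, 20)),
               "grammar minimum")
})

test_that("group I draws share template blocks and never match the SP grammar", {
  set.seed(1001)
  tpl <- gi_template()
  draws <- replicate(100, as.character(sample_group1_intron(template = tpl)))
  lens <- nchar(draws)
  expect_true(all(lens >= 399 & lens <= 547))
  expect_true(all(vapply(draws, function(s) is.null(scan_spliceosomal(s)),
                         logical(1))))
  # two draws from the same template agree closely over the first block
  b1 <- nchar(tpl$blocks[1])
  id <- mean(strsplit(substr(draws[1], 1, b1), "")[[1]] ==
               strsplit(substr(draws[2], 1, b1), "")[[1]])
  expect_gte(id, 0.7)
})

test_that("implanting no introns returns the cores unchanged", {
  set.seed(120)
  cores <- random_cores(n = 3, L = 600)
  spec <- small_spec()[0, ]
  ds <- implant_introns(cores, spec)
  expect_equal(setNames(ds$aligned$residues, ds$aligned$id), cores)
  expect_equal(nrow(ds$truth), 0L)
})

test_that("implanted introns are recovered at their configured flank pair", {
  set.seed(121)
  cores <- random_cores(n = 5, L = 1200)
  ds <- implant_introns(cores, small_spec(flank = 549L, taxa = c("t1", "t2", "t3")),
                        reference_id = "t5")
  # carriers are 3 of 5 rows, so allow insert columns up to 3/5 occupancy
  ins <- detect_inserts(ds$aligned, "t5", presence_max_frac = 0.6)
  expect_equal(nrow(ins), 3L)
  expect_setequal(ins$seq_id, c("t1", "t2", "t3"))
  expect_true(all(ins$flank5 == 549L & ins$flank3 == 550L))
  # implant-then-extract returns the pre-implant cores exactly
  ce <- extract_core(ds$aligned, ins)
  expect_equal(ce$per_seq_core[names(cores)], cores)
  # carriers cannot include the reference
  expect_error(implant_introns(cores, small_spec(taxa = c("t5")),
                               reference_id = "t5"), "cannot carry")
})

test_that("presence polymorphism emits per-copy truth that the detector matches", {
  set.seed(122)
  cores <- random_cores(n = 4, L = 900)
  spec <- small_spec(flank = 400L, taxa = c("t1", "t2"), presence_prob = 0.5)
  ds <- implant_introns(cores, spec, reference_id = "t4")
  # two copies per polymorphic carrier
  expect_setequal(ds$aligned$id[startsWith(ds$aligned$id, "t1")],
                  c("t1_c1", "t1_c2"))
  ins <- detect_inserts(ds$aligned, "t4")
  truth <- ds$truth
  expect_setequal(ins$seq_id, truth$seq_id[truth$present])
})

test_that("truncated implants are 5'-anchored, flagged, and masked with N", {
  set.seed(123)
  cores <- random_cores(n = 4, L = 900)
  spec <- small_spec(flank = 500L, taxa = c("t1", "t2"), truncation_prob = 1)
  ds <- implant_introns(cores, spec, reference_id = "t4")
  truth <- ds$truth
  expect_true(all(!truth$complete))
  ins <- detect_inserts(ds$aligned, "t4")
  expect_true(all(!ins$complete))
  expect_equal(sort(ins$observed_len), sort(truth$length))
})

test_that("the default scenario carries 19 18S and 1 28S locations in two clades", {
  ds <- build_synthetic_rdna(default_generator_config(seed = 5))
  ssu_locs <- unique(ds$ssu$truth$flank5)
  expect_length(ssu_locs, 19L)
  expect_length(unique(ds$lsu$truth$flank5), 1L)
  carrier_clades <- unique(sub("t[0-9]+(_c[0-9]+)?$", "", ds$ssu$truth$taxon))
  expect_setequal(carrier_clades, c("c1", "c7"))
  expect_equal(sort(unique(ds$ssu$truth$family)), c("GI", "SP"))
})

test_that("full recovery: detect + classify + tabulate reproduce the truth table", {
  for (seed in c(7, 8, 9)) {
    ds <- build_synthetic_rdna(default_generator_config(seed = seed))
    truth <- ds$ssu$truth[ds$ssu$truth$present, ]
    ins <- detect_inserts(ds$ssu$aligned, "REF")
    cl <- classify_inserts(ins, ds$ssu$aligned, gene = "SSU18S")
    # locations
    locs <- group_locations(cl)
    expect_equal(locs$flank5, sort(unique(truth$flank5)))
    # per-record lengths and completeness
    got <- sort(paste(cl$seq_id, cl$flank5, cl$observed_len, cl$complete))
    want <- sort(paste(truth$seq_id, truth$flank5, truth$length, truth$complete))
    expect_equal(got, want)
    # families of complete inserts
    m <- merge(cl[cl$complete, ], truth, by = c("seq_id", "flank5"))
    expect_equal(m$family.x, m$family.y)
    # truncated inserts come back as partial
    expect_true(all(cl$family[!cl$complete] == "partial"))
    # conservation of total length per copy
    orig_len <- nchar(gsub("-", "", ds$ssu$aligned$residues, fixed = TRUE))
    names(orig_len) <- ds$ssu$aligned$id
    core_len <- nchar(ds$ssu$cores[[1]])
    for (sid in ds$ssu$aligned$id) {
      expect_equal(unname(orig_len[sid]),
                   core_len + sum(cl$observed_len[cl$seq_id == sid]))
    }
    # per-taxon counts (one cell per taxon and location, as in the published table)
    tab <- tabulate_inserts(cl)
    want_counts <- vapply(split(truth$flank5, truth$taxon),
                          function(v) length(unique(v)), integer(1))
    for (tx in names(want_counts)) {
      expect_equal(tab$per_taxon$n_inserts[tab$per_taxon$taxon == tx],
                   want_counts[[tx]], info = tx)
    }
  }
})

test_that("the same seed reproduces byte-identical dataset files", {
  d1 <- file.path(tempdir(), "gen_a")
  d2 <- file.path(tempdir(), "gen_b")
  generate_dataset(default_generator_config(seed = 77), d1)
  generate_dataset(default_generator_config(seed = 77), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and the files round-trip through the readers
  aln <- read_rdna_fasta(file.path(d1, "ssu_aligned.fasta"), aligned = TRUE)
  expect_s3_class(aln, "rdna_set")
  primers <- load_primer_config(file.path(d1, "primers.tsv"))
  expect_equal(nrow(primers), 4L)
})

test_that("GI introns cluster by location on conserved blocks", {
  set.seed(2024)
  tpl_a <- gi_template()
  tpl_b <- gi_template()
  # fixed length so draws from both templates are trivially aligned
  draw <- function(tpl) as.character(sample_group1_intron(c(460, 460), tpl))
  seqs <- c(setNames(replicate(3, draw(tpl_a)), paste0("loc4_", 1:3)),
            setNames(replicate(3, draw(tpl_b)), paste0("loc12_", 1:3)))
  cb <- extract_conserved_blocks(seqs, window = 10, min_identity = 0.45)
  dm <- p_distance_matrix(cb$per_seq)
  tr <- nj_tree(dm)
  expect_true(is_monophyletic_unrooted(tr, paste0("loc4_", 1:3)))
  expect_true(is_monophyletic_unrooted(tr, paste0("loc12_", 1:3)))
})

test_that("a short marker region collapses at least as much as a long one (aggregate)", {
  res <- t(vapply(1:24, function(s) {
    r <- region_collapse_contrast(seed = 9000 + s)
    c(sg = r$short$n_groups, lg = r$long$n_groups,
      st = r$short$collapsed_taxa, lt = r$long$collapsed_taxa)
  }, numeric(4)))
  expect_gte(sum(res[, "sg"]), sum(res[, "lg"]))
  expect_gt(sum(res[, "st"]), sum(res[, "lt"]))
})
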
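fwd_primer <- function(seq, name = "F", cw = 3L) {
  list(name = name, orientation = "forward", sequence = seq, critical_window = cw)
}
rev_primer <- function(seq, name = "R", cw = 3L) {
  list(name = name, orientation = "reverse", sequence = seq, critical_window = cw)
}

test_that("an exact substring is a mismatch-free hit at the right interval", {
  core <- paste0(strrep("A", 30), "GGTTCCAAGGTTCC", strrep("C", 30))
  hit <- find_primer_site(core, fwd_primer("GGTTCCAAGGTTCC"))
  expect_equal(c(hit$start, hit$end), c(31L, 44L))
  expect_equal(hit$n_mismatch, 0L)
  expect_false(hit$critical)
  # degenerate base over its own set is not a mismatch
  hit2 <- find_primer_site(core, fwd_primer("RGTTCCAAGGTTCC"))
  expect_equal(hit2$n_mismatch, 0L)
  expect_error(find_primer_site("ACG", fwd_primer("ACGT")), "longer than")
})

test_that("the best of several candidate sites wins; ties go left", {
  #           1-mismatch site            3-mismatch site
  core <- paste0("TTTT", "GGAACC", "TTTTTTTTTT", "GCCACG", "TTTT")
  hit <- find_primer_site(core, fwd_primer("GGATCC"))
  expect_equal(hit$start, 5L)
  expect_equal(hit$n_mismatch, 1L)
  # two equal sites: smallest start
  core2 <- paste0("AACCGG", strrep("T", 10), "AACCGG")
  hit2 <- find_primer_site(core2, fwd_primer("AACCGG"))
  expect_equal(hit2$start, 1L)
})

test_that("reverse primers are reverse-complemented and offsets count from 3' end", {
  target <- "GGTTCCAAGGTTCC"
  core <- paste0(strrep("A", 20), target, strrep("C", 20))
  # reverse primer as synthesized = revcomp of its forward-strand target
  hit <- find_primer_site(core, rev_primer(revcomp_iupac(target)))
  expect_equal(c(hit$start, hit$end), c(21L, 34L))
  expect_equal(hit$n_mismatch, 0L)

  # mutate the leftmost target base: for a reverse primer that is its 3' end
  core3 <- core
  substr(core3, 21, 21) <- "T"
  hit3 <- find_primer_site(core3, rev_primer(revcomp_iupac(target)))
  expect_equal(hit3$mismatch_offsets, 0L)
  expect_true(hit3$critical)
  # same mutation for a forward primer is at the 5' end: offset 13, not critical
  hit4 <- find_primer_site(core3, fwd_primer(target))
  expect_equal(hit4$mismatch_offsets, 13L)
  expect_false(flag_critical(hit4, critical_window = 3L))
  expect_true(flag_critical(hit4, critical_window = 14L))
})

test_that("reported mismatches agree with a brute-force recount (200 random cases)", {
  set.seed(55)
  for (i in 1:200) {
    core <- paste(sample(c("A", "C", "G", "T", "N"), sample(60:120, 1),
                         replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                  collapse = "")
    k <- sample(12:20, 1)
    pseq <- paste(sample(names(IUPAC_CODES), k, replace = TRUE,
                         prob = c(rep(.22, 4), rep(.012, 11))), collapse = "")
    orient <- sample(c("forward", "reverse"), 1)
    p <- list(name = "p", orientation = orient, sequence = pseq,
              critical_window = 3L)
    hit <- find_primer_site(core, p)
    pat <- if (orient == "reverse") revcomp_iupac(pseq) else pseq
    counts <- vapply(seq_len(nchar(core) - k + 1L), function(s) {
      oracle_mismatches(pat, core, s)
    }, integer(1))
    expect_equal(hit$n_mismatch, min(counts))
    expect_equal(hit$start, which.min(counts))
  }
})

test_that("auditing a sequence and its reverse complement swap cleanly", {
  set.seed(66)
  core <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ftarget <- substr(core, 50, 67)
  rtarget <- substr(core, 300, 317)
  fwd <- fwd_primer(ftarget, "F")
  rev <- rev_primer(revcomp_iupac(rtarget), "R")
  st1 <- audit_amplicon(core, NULL, fwd, rev)
  # on the reverse complement, the old reverse primer acts as the forward one
  rc <- revcomp_iupac(core)
  fwd2 <- fwd_primer(revcomp_iupac(rtarget), "R")
  rev2 <- rev_primer(ftarget, "F")
  st2 <- audit_amplicon(rc, NULL, fwd2, rev2)
  expect_equal(st1$status, st2$status)
  expect_equal(st1$amplicon_core_len, st2$amplicon_core_len)
})

test_that("amplicon classification: disruption, criticals, lengths, missing regions", {
  set.seed(71)
  core <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  fwd <- fwd_primer(substr(core, 101, 118), "F")
  rev <- rev_primer(revcomp_iupac(substr(core, 501, 518)), "R")

  # perfect primers, no introns
  st <- audit_amplicon(core, NULL, fwd, rev)
  expect_equal(st$status, "amplifiable")
  expect_equal(st$amplicon_core_len, 418L)
  expect_equal(st$amplicon_total_len, st$amplicon_core_len)

  # an intron between the primers adds its length to the total only
  mid <- data.frame(flank5 = 300L, flank3 = 301L, observed_len = 124L)
  st <- audit_amplicon(core, mid, fwd, rev)
  expect_equal(st$status, "amplifiable")
  expect_equal(st$amplicon_total_len, 418L + 124L)

  # an intron strictly inside the reverse target disrupts
  ins <- data.frame(flank5 = 510L, flank3 = 511L, observed_len = 91L)
  st <- audit_amplicon(core, ins, fwd, rev)
  expect_equal(st$status, "primer_disrupted")
  expect_equal(st$disrupting_locations$flank5, 510L)

  # an intron abutting the target's outer edge does not
  edge <- data.frame(flank5 = 518L, flank3 = 519L, observed_len = 91L)
  expect_equal(audit_amplicon(core, edge, fwd, rev)$status, "amplifiable")

  # critical 3'-end mismatch on the reverse primer
  core2 <- core
  substr(core2, 501, 501) <- setdiff(c("A", "C", "G", "T"),
                                     substr(core, 501, 501))[1]
  expect_equal(audit_amplicon(core2, NULL, fwd, rev)$status, "critical_mismatch")

  # region missing entirely
  st <- audit_amplicon(substr(core, 1, 300), NULL, fwd, rev)
  expect_equal(st$status, "region_incomplete")
})

test_that("region extraction is the span strictly between hits by default", {
  core <- paste0("AAAA", "GGGG", "TTTT")
  fh <- find_primer_site(core, fwd_primer("AAAA"))
  rh <- find_primer_site(core, rev_primer(revcomp_iupac("TTTT")))
  expect_equal(extract_region(core, fh, rh), "GGGG")
  expect_equal(extract_region(core, fh, rh, include_primers = TRUE), core)
  # abutting hits leave nothing between
  core2 <- paste0("AAAA", "TTTT")
  fh2 <- find_primer_site(core2, fwd_primer("AAAA"))
  rh2 <- find_primer_site(core2, rev_primer(revcomp_iupac("TTTT")))
  expect_error(extract_region(core2, fh2, rh2), "empty region")
})

test_that("implanted introns inside engineered primer targets disrupt exactly as recorded", {
  ds <- build_synthetic_rdna(default_generator_config(seed = 11))
  truth <- ds$ssu$truth
  primers <- ds$ssu$primers
  cores <- ds$ssu$cores
  ins_all <- detect_inserts(ds$ssu$aligned, "REF")
  pair <- function(fn, rn) list(f = primers[primers$name == fn, ],
                                r = primers[primers$name == rn, ])
  for (pp in list(pair("V4f", "V4r"), pair("V9f", "V9r"))) {
    for (sid in unique(truth$seq_id[truth$present])) {
      tx <- truth$taxon[truth$seq_id == sid][1]
      ins <- ins_all[ins_all$seq_id == sid, ]
      st <- audit_amplicon(cores[[tx]], ins, pp$f, pp$r, seq_id = sid)
      truthy <- truth[truth$seq_id == sid & truth$present, ]
      hit_names <- unlist(strsplit(truthy$affected_primers, ","))
      expected <- any(hit_names %in% c(pp$f$name, pp$r$name))
      expect_equal(st$status == "primer_disrupted", expected, info = sid)
    }
  }
})
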
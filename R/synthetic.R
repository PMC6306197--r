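# Synthetic rDNA generator.  Emulates chaetocerotacean-like reference data at
# desk scale: core sequences evolved under Jukes-Cantor along a known tree
# (no indels, so every insertion in the output is attributable to an
# implant), spliceosomal introns sampled from the boundary grammar, group
# IC1-like introns built from per-location ancestral templates (conserved
# blocks alternating with random spacers, no spliceosomal donor), partial
# (truncated) inserts, intra-individual presence polymorphism, and primer
# targets embedded at fixed coordinates.  Every implant is recorded in a
# machine-readable truth table for recovery testing.

# sample one concrete realization of an IUPAC consensus
expand_iupac_sample <- function(pattern) {
  paste(vapply(chars(pattern), function(p) {
    opts <- IUPAC_CODES[[p]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

# uniform integer in [lo, hi], safe for degenerate ranges (sample() would
# misread a length-1 vector as 1:n)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a balanced clade tree
#'
#' Constructs a tree of `n_clades` clades of `taxa_per_clade` tips each
#' (pectinate within clades), attached to the root by stem branches, plus an
#' optional outgroup tip.  Tip labels are `c<i>t<j>`.
#'
#' @param n_clades,taxa_per_clade clade structure.
#' @param stem_length branch length (expected substitutions/site) of each
#'   clade stem.
#' @param within_length branch length of branches inside clades.
#' @param outgroup label of an outgroup tip attached at the root (`NULL` for
#'   none).
#' @param outgroup_length branch length of the outgroup tip.
#' @return An `ape::phylo` tree.
#' @export
clade_tree <- function(n_clades, taxa_per_clade, stem_length = 0.1,
                       within_length = 0.01, outgroup = NULL,
                       outgroup_length = 0.15) {
  sub <- function(labels, wl) {
    if (length(labels) == 1L) return(paste0(labels, ":", wl))
    paste0("(", sub(labels[-length(labels)], wl), ",",
           labels[length(labels)], ":", wl, "):", wl)
  }
  clades <- vapply(seq_len(n_clades), function(i) {
    labs <- paste0("c", i, "t", seq_len(taxa_per_clade))
    if (taxa_per_clade == 1L) {
      paste0(labs, ":", stem_length)
    } else {
      paste0("(", sub(labs[-length(labs)], within_length), ",",
             labs[length(labs)], ":", within_length, "):", stem_length)
    }
  }, character(1))
  parts <- c(clades, if (!is.null(outgroup)) paste0(outgroup, ":", outgroup_length))
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Evolve core sequences along a tree under Jukes-Cantor
#'
#' The root sequence is uniform random over A,C,G,T; on each branch a
#' Poisson(`length * branch_length`) number of substitution events is placed
#' uniformly over sites, each replacing the current base by one of the other
#' three (so branch lengths are expected substitutions per site).  No indels:
#' the tip sequences are trivially aligned.
#'
#' @param tree an `ape::phylo` tree with non-negative branch lengths.
#' @param core_length sequence length; by default sampled uniformly from
#'   1669..1703, the typical length range of the diatom 18S core.
#' @return List with `seqs` (named character vector of tip sequences),
#'   `tree` and `core_length`.
#' @export
simulate_core <- function(tree, core_length = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(core_length)) core_length <- sample_range(1669L, 1703L)
  L <- as.integer(core_length)
  ntip <- length(tree$tip.label)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  root <- ntip + 1L
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (e in seq_len(nrow(tree_cw$edge))) {
    par <- tree_cw$edge[e, 1L]
    chd <- tree_cw$edge[e, 2L]
    s <- node_seq[[par]]
    nsub <- stats::rpois(1L, tree_cw$edge.length[e] * L)
    if (nsub > 0L) {
      pos <- sample.int(L, nsub, replace = TRUE)
      for (p in pos) {
        s[p] <- sample(bases[bases != s[p]], 1L)
      }
    }
    node_seq[[chd]] <- s
  }
  seqs <- vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""),
                 character(1))
  names(seqs) <- tree$tip.label
  list(seqs = seqs, tree = tree, core_length = L)
}

#' Sample a spliceosomal intron from the boundary grammar
#'
#' Layout: donor hexamer (80% the modal GTAAGT, else uniform over GTDHNN),
#' variable region, branch pentamer (80% TTAAC, else uniform over YTRAC),
#' a 12-nt pyrimidine tract (C/T only), and the acceptor (18S: pentamer, 80%
#' TACAG, else uniform over YNHAG; 28S: terminal hexamer, 80% TTAAAG, else
#' uniform over YTAMAG).  Total length uniform in `len_range`.
#'
#' @param len_range integer length range (default 96..199, the typical short-
#'   insert lengths).
#' @param gene `"SSU18S"` or `"LSU28S"`.
#' @param modal_prob probability of the modal motif realization (default 0.8).
#' @return DNA string; every draw satisfies [scan_spliceosomal()].
#' @export
sample_spliceosomal_intron <- function(len_range = c(96L, 199L),
                                       gene = c("SSU18S", "LSU28S"),
                                       modal_prob = 0.8) {
  gene <- match.arg(gene)
  ct_len <- 12L
  acc_len <- if (gene == "LSU28S") 6L else 5L
  min_feasible <- 6L + 5L + ct_len + acc_len
  if (len_range[1L] < min_feasible) {
    stop("len_range minimum ", len_range[1L], " below grammar minimum span ",
         min_feasible)
  }
  L <- sample_range(len_range[1L], len_range[2L])
  pick <- function(modal, consensus) {
    if (stats::runif(1L) < modal_prob) modal else expand_iupac_sample(consensus)
  }
  donor <- pick("GTAAGT", "GTDHNN")
  branch <- pick("TTAAC", "YTRAC")
  acceptor <- if (gene == "LSU28S") pick("TTAAAG", "YTAMAG")
              else pick("TACAG", "YNHAG")
  ct <- paste(sample(c("C", "T"), ct_len, replace = TRUE), collapse = "")
  var_len <- L - nchar(donor) - nchar(branch) - ct_len - nchar(acceptor)
  paste0(donor, random_dna(var_len), branch, ct, acceptor)
}

#' Create an ancestral template for a group I intron location
#'
#' @param n_blocks number of conserved blocks.
#' @param block_len length of each block.
#' @return List with a `blocks` character vector; the first block starts with
#'   `AA`, so no draw from the template can carry a spliceosomal donor.
#' @export
gi_template <- function(n_blocks = 4L, block_len = 60L) {
  blocks <- vapply(seq_len(n_blocks), function(i) random_dna(block_len),
                   character(1))
  blocks[1L] <- paste0("AA", substr(blocks[1L], 3L, block_len))
  list(blocks = blocks)
}

#' Sample a group IC1-like intron from an ancestral template
#'
#' Conserved blocks are copied from the template with a low per-base mutation
#' probability and alternate with fully random spacers; the total length is
#' uniform in `len_range`.  The first two bases are forced to `AA`, so the
#' draw can never match the spliceosomal donor consensus.
#'
#' @param len_range integer length range (default 399..547, the observed
#'   complete group I insert lengths).
#' @param template a [gi_template()]; a fresh one is created when `NULL`.
#' @param block_mut per-base mutation probability within conserved blocks.
#' @return DNA string with a `template` attribute.
#' @export
sample_group1_intron <- function(len_range = c(399L, 547L), template = NULL,
                                 block_mut = 0.05) {
  if (is.null(template)) template <- gi_template()
  blocks <- template$blocks
  total_block <- sum(nchar(blocks))
  if (len_range[1L] < total_block + length(blocks) - 1L) {
    stop("len_range minimum too small for the template's conserved blocks")
  }
  L <- sample_range(len_range[1L], len_range[2L])
  mut <- function(b) {
    cs <- chars(b)
    hit <- which(stats::runif(length(cs)) < block_mut)
    for (i in hit) {
      cs[i] <- sample(setdiff(c("A", "C", "G", "T"), cs[i]), 1L)
    }
    paste(cs, collapse = "")
  }
  mblocks <- vapply(blocks, mut, character(1), USE.NAMES = FALSE)
  n_spacer <- length(blocks) - 1L
  spacer_total <- L - total_block
  cuts <- sort(sample.int(spacer_total - n_spacer + 1L, n_spacer - 1L,
                          replace = TRUE)) + seq_len(n_spacer - 1L) - 1L
  spacer_lens <- diff(c(0L, cuts, spacer_total))
  pieces <- character(2L * n_spacer + 1L)
  pieces[seq(1L, by = 2L, length.out = length(mblocks))] <- mblocks
  pieces[seq(2L, by = 2L, length.out = n_spacer)] <-
    vapply(spacer_lens, random_dna, character(1))
  s <- paste(pieces, collapse = "")
  s <- paste0("AA", substr(s, 3L, nchar(s)))
  attr(s, "template") <- template
  s
}

#' Implant introns into core sequences and build the truthful alignment
#'
#' Introns are inserted between the stated core positions; alignment columns
#' are added per location (width = longest implanted intron there), with gaps
#' for non-carriers.  Rows of `intron_spec` with `presence_prob < 1` make
#' their carrier taxa polymorphic: two sequence copies (`_c1`, `_c2`) are
#' emitted per carrier and each copy carries the intron independently with
#' that probability (mirroring PCR products with and without the insert).
#' With `truncation_prob > 0`, an implanted intron may be truncated to a
#' 5'-anchored prefix (flagged incomplete) and the following `n_mask` core
#' bases of that copy are masked with `N`, emulating a sequencing run that
#' entered but never exited the insert.
#'
#' @param cores named character vector of equal-length ungapped core
#'   sequences.
#' @param intron_spec data frame with columns `location_id`, `flank5`,
#'   `family` (`"SP"`/`"GI"`), `taxa` (list column of carrier ids),
#'   `len_min`, `len_max`, and optionally `presence_prob` (default 1),
#'   `truncation_prob` (default 0), `template` (list column of
#'   [gi_template()]s for GI rows).
#' @param gene gene tag of the output sets.
#' @param reference_id id of a row that must remain intron-free (the
#'   detection reference); an error is raised if it is listed as a carrier.
#' @param n_mask number of core bases masked with `N` after a truncated
#'   insert.
#' @param trunc_min minimum retained prefix length of a truncated insert.
#' @return List with `aligned` (an aligned [rdna_set]), `unaligned`
#'   ([rdna_set] of gap-stripped sequences), and `truth` (data frame: one row
#'   per carrier copy and location with `seq_id`, `taxon`, `location_id`,
#'   `flank5`, `flank3`, `family`, `length`, `complete`, `present`).
#' @export
implant_introns <- function(cores, intron_spec, gene = "SSU18S",
                            reference_id = NULL, n_mask = 8L,
                            trunc_min = 30L) {
  L <- unique(nchar(cores))
  if (length(L) != 1L) stop("core sequences must have equal length")
  spec <- intron_spec
  if (!"presence_prob" %in% names(spec)) spec$presence_prob <- 1
  if (!"truncation_prob" %in% names(spec)) spec$truncation_prob <- 0
  if (!"template" %in% names(spec)) spec$template <- I(vector("list", nrow(spec)))
  if (anyDuplicated(spec$flank5)) stop("duplicate implant site (flank5)")
  if (any(spec$flank5 < 1L | spec$flank5 > L - 1L)) {
    stop("implant flank positions must lie in [1, core_length - 1]")
  }
  spec <- spec[order(spec$flank5), , drop = FALSE]
  carriers_all <- unique(unlist(spec$taxa))
  if (!all(carriers_all %in% names(cores))) {
    stop("unknown carrier id(s): ",
         paste(setdiff(carriers_all, names(cores)), collapse = ", "))
  }
  if (!is.null(reference_id) && reference_id %in% carriers_all) {
    stop("reference '", reference_id, "' cannot carry introns")
  }

  poly_taxa <- unique(unlist(spec$taxa[spec$presence_prob < 1]))
  copies <- list()
  for (id in names(cores)) {
    if (id %in% poly_taxa) {
      copies[[length(copies) + 1L]] <- data.frame(
        seq_id = paste0(id, c("_c1", "_c2")), taxon = id,
        stringsAsFactors = FALSE)
    } else {
      copies[[length(copies) + 1L]] <- data.frame(
        seq_id = id, taxon = id, stringsAsFactors = FALSE)
    }
  }
  copies <- do.call(rbind, copies)

  # per copy: decide presence, draw introns, record masks
  n_loc <- nrow(spec)
  intron_of <- matrix(list(), nrow = nrow(copies), ncol = n_loc)
  truth <- list()
  mask_at <- vector("list", nrow(copies))  # core positions to mask with N
  for (ci in seq_len(nrow(copies))) {
    tx <- copies$taxon[ci]
    for (li in seq_len(n_loc)) {
      row <- spec[li, ]
      if (!tx %in% row$taxa[[1L]]) next
      present <- row$presence_prob >= 1 ||
        stats::runif(1L) < row$presence_prob
      len <- NA_integer_
      complete <- NA
      if (present) {
        intron <- if (row$family == "GI") {
          sample_group1_intron(c(row$len_min, row$len_max),
                               template = row$template[[1L]])
        } else {
          sample_spliceosomal_intron(c(row$len_min, row$len_max),
                                     gene = if (gene == "LSU28S") "LSU28S" else "SSU18S")
        }
        intron <- as.character(intron)
        complete <- TRUE
        if (row$truncation_prob > 0 && stats::runif(1L) < row$truncation_prob) {
          keep <- sample_range(trunc_min, nchar(intron) - 1L)
          intron <- substr(intron, 1L, keep)
          complete <- FALSE
          mask_at[[ci]] <- c(mask_at[[ci]],
                             (row$flank5 + 1L):min(L, row$flank5 + n_mask))
        }
        len <- nchar(intron)
        intron_of[[ci, li]] <- intron
      }
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = copies$seq_id[ci], taxon = tx,
        location_id = row$location_id, gene = gene,
        flank5 = row$flank5, flank3 = row$flank5 + 1L,
        family = row$family, length = len, complete = complete,
        present = present, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(seq_id = character(), taxon = character(),
               location_id = integer(), gene = character(),
               flank5 = integer(), flank3 = integer(), family = character(),
               length = integer(), complete = logical(), present = logical(),
               stringsAsFactors = FALSE)

  # assemble aligned rows
  block_w <- vapply(seq_len(n_loc), function(li) {
    lens <- vapply(seq_len(nrow(copies)), function(ci) {
      v <- intron_of[[ci, li]]
      if (is.null(v)) 0L else nchar(v)
    }, integer(1))
    max(lens)
  }, integer(1))
  bounds <- c(spec$flank5, L)
  aligned <- character(nrow(copies))
  for (ci in seq_len(nrow(copies))) {
    s <- cores[[copies$taxon[ci]]]
    if (length(mask_at[[ci]]) > 0L) {
      cs <- chars(s)
      cs[unique(mask_at[[ci]])] <- "N"
      s <- paste(cs, collapse = "")
    }
    parts <- character(0)
    prev <- 0L
    for (li in seq_len(n_loc)) {
      parts <- c(parts, substr(s, prev + 1L, bounds[li]))
      v <- intron_of[[ci, li]]
      ins <- if (is.null(v)) "" else v
      parts <- c(parts, paste0(ins, strrep("-", block_w[li] - nchar(ins))))
      prev <- bounds[li]
    }
    parts <- c(parts, substr(s, prev + 1L, L))
    aligned[ci] <- paste(parts, collapse = "")
  }
  aligned_set <- rdna_set(id = copies$seq_id, taxon = copies$taxon,
                          residues = aligned, aligned = TRUE, gene = gene)
  unaligned_set <- rdna_set(id = copies$seq_id, taxon = copies$taxon,
                            residues = gsub("-", "", aligned, fixed = TRUE),
                            aligned = FALSE, gene = gene)
  list(aligned = aligned_set, unaligned = unaligned_set, truth = truth)
}

#' Default generator configuration
#'
#' Desk-scale study conditions: seven clades of three taxa plus an
#' intron-free reference outgroup; 18S cores of 1669..1703 nt carrying 19
#' intron locations (17 spliceosomal, 2 group I) restricted to clades 1 and
#' 7; a 28S set with one spliceosomal location; one polymorphic location
#' (presence probability 0.5) and one location where sequencing truncates
#' every insert; and two engineered primer pairs bracketing a long (V4-like)
#' and a short (V9-like) marker region, with one location inside each
#' reverse/forward primer target.
#'
#' @param seed integer seed; fixed seed implies byte-identical
#'   [generate_dataset()] output.
#' @return Configuration list consumed by [build_synthetic_rdna()] and
#'   [generate_dataset()].
#' @export
default_generator_config <- function(seed = 1L) {
  taxa18 <- function(k) paste0("c", rep(c(1L, 7L), each = 3L), "t", 1:3)[k]
  spec18 <- data.frame(
    location_id = 1:19,
    flank5 = c(385L, 442L, 548L, 549L, 888L, 889L, 891L, 981L, 989L, 1011L,
               1147L, 1151L, 1195L, 1257L, 1274L, 1414L, 1490L, 1520L, 1630L),
    family = c("SP", "SP", "SP", "GI", "SP", "SP", "SP", "SP", "SP", "SP",
               "SP", "GI", "SP", "SP", "SP", "SP", "SP", "SP", "SP"),
    len_min = 96L, len_max = 199L,
    presence_prob = 1, truncation_prob = 0,
    stringsAsFactors = FALSE)
  spec18$len_min[spec18$family == "GI"] <- 399L
  spec18$len_max[spec18$family == "GI"] <- 547L
  spec18$taxa <- I(list(
    taxa18(c(1, 2)), taxa18(c(4, 5, 6)), taxa18(c(2, 3)), taxa18(c(1, 4, 5)),
    taxa18(c(4, 6)), taxa18(c(5)), taxa18(c(1, 3)), taxa18(c(5, 6)),
    taxa18(c(2, 4)), taxa18(c(4, 5)), taxa18(c(1, 6)), taxa18(c(2, 5)),
    taxa18(c(4, 6)), taxa18(c(3, 5)), taxa18(c(1, 2, 6)), taxa18(c(4)),
    taxa18(c(2, 6)), taxa18(c(5, 6)), taxa18(c(1, 4, 5))))
  spec18$presence_prob[spec18$location_id == 11L] <- 0.5
  spec18$truncation_prob[spec18$location_id == 19L] <- 1
  spec28 <- data.frame(
    location_id = 1L, flank5 = 558L, family = "SP",
    len_min = 96L, len_max = 199L, presence_prob = 1, truncation_prob = 0,
    stringsAsFactors = FALSE)
  spec28$taxa <- I(list(c("c7t1", "c7t2")))
  list(
    seed = as.integer(seed),
    n_clades = 7L, taxa_per_clade = 3L,
    stem_length = 0.08, within_length = 0.004,
    reference_id = "REF", outgroup_length = 0.12,
    core_length_range = c(1669L, 1703L),
    lsu_core_length_range = c(700L, 765L),
    spec18 = spec18, spec28 = spec28,
    # engineered primer targets on the 18S core (1-based closed intervals)
    # geometry gives a 390-column V4-like and a 125-column V9-like region
    # between the primer target intervals
    primer_sites = data.frame(
      name = c("V4f", "V4r", "V9f", "V9r"),
      orientation = c("forward", "reverse", "forward", "reverse"),
      start = c(592L, 1000L, 1480L, 1623L),
      end = c(609L, 1017L, 1497L, 1640L),
      critical_window = 3L,
      stringsAsFactors = FALSE),
    regions = data.frame(
      name = c("V4", "V9"),
      start = c(610L, 1498L), end = c(999L, 1622L),
      stringsAsFactors = FALSE))
}

#' Build a synthetic rDNA dataset in memory
#'
#' Runs the full generator under the configuration's seed: simulates 18S and
#' 28S cores on the clade tree, embeds the engineered primer targets in every
#' 18S core, implants the configured introns, and annotates the truth table
#' with the primers and marker regions each implant disrupts or lengthens.
#'
#' @param config a [default_generator_config()]-style list.
#' @return List with elements `ssu` and `lsu`, each holding `aligned`,
#'   `unaligned`, `truth`, `cores` (pre-implant core sequences) and `tree`;
#'   the `ssu` element also carries `primers` (a [load_primer_config()]-style
#'   data frame with 5'->3' sequences) and `primer_sites`.
#' @export
build_synthetic_rdna <- function(config = default_generator_config()) {
  set.seed(config$seed)
  tree <- clade_tree(config$n_clades, config$taxa_per_clade,
                     stem_length = config$stem_length,
                     within_length = config$within_length,
                     outgroup = config$reference_id,
                     outgroup_length = config$outgroup_length)
  Lr <- config$core_length_range
  sim <- simulate_core(tree, core_length = sample_range(Lr[1L], Lr[2L]))
  cores <- sim$seqs

  # embed identical primer-target motifs in every row
  ps <- config$primer_sites
  ps$target <- vapply(seq_len(nrow(ps)), function(i) {
    random_dna(ps$end[i] - ps$start[i] + 1L)
  }, character(1))
  for (i in seq_len(nrow(ps))) {
    substr(cores, ps$start[i], ps$end[i]) <- ps$target[i]
  }
  primers <- data.frame(
    name = ps$name, orientation = ps$orientation,
    sequence = ifelse(ps$orientation == "reverse",
                      vapply(ps$target, revcomp_iupac, character(1)),
                      ps$target),
    critical_window = ps$critical_window, stringsAsFactors = FALSE)

  # GI templates, one per GI location
  spec18 <- config$spec18
  spec18$template <- I(lapply(seq_len(nrow(spec18)), function(i) {
    if (spec18$family[i] == "GI") gi_template() else NULL
  }))
  ssu <- implant_introns(cores, spec18, gene = "SSU18S",
                         reference_id = config$reference_id)
  ssu$truth <- annotate_truth_effects(ssu$truth, ps, config$regions)
  ssu$cores <- cores
  ssu$tree <- tree
  ssu$primers <- primers
  ssu$primer_sites <- ps

  Lr2 <- config$lsu_core_length_range
  sim2 <- simulate_core(tree, core_length = sample_range(Lr2[1L], Lr2[2L]))
  lsu <- implant_introns(sim2$seqs, config$spec28, gene = "LSU28S",
                         reference_id = config$reference_id)
  lsu$cores <- sim2$seqs
  lsu$tree <- tree
  list(ssu = ssu, lsu = lsu)
}

# annotate truth rows with the primers whose target interval contains the
# flank pair and the marker regions the implant sits in
annotate_truth_effects <- function(truth, primer_sites, regions) {
  if (nrow(truth) == 0L) {
    truth$affected_primers <- character(0)
    truth$affected_regions <- character(0)
    return(truth)
  }
  truth$affected_primers <- vapply(seq_len(nrow(truth)), function(i) {
    p5 <- truth$flank5[i]
    hit <- primer_sites$name[p5 >= primer_sites$start &
                               p5 <= primer_sites$end - 1L]
    paste(hit, collapse = ",")
  }, character(1))
  truth$affected_regions <- vapply(seq_len(nrow(truth)), function(i) {
    p5 <- truth$flank5[i]
    hit <- regions$name[p5 >= regions$start - 1L & p5 <= regions$end]
    paste(hit, collapse = ",")
  }, character(1))
  truth
}

#' Generate a synthetic dataset on disk
#'
#' Writes, deterministically for a given seed: plain and aligned FASTA for
#' the 18S and 28S sets, the truth table TSV, and the primer configuration
#' TSV.
#'
#' @param config a [default_generator_config()]-style list.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the [build_synthetic_rdna()] object.
#' @export
generate_dataset <- function(config = default_generator_config(),
                             outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- build_synthetic_rdna(config)
  write_rdna_fasta(ds$ssu$aligned, file.path(outdir, "ssu_aligned.fasta"))
  write_rdna_fasta(ds$ssu$unaligned, file.path(outdir, "ssu.fasta"))
  write_rdna_fasta(ds$lsu$aligned, file.path(outdir, "lsu_aligned.fasta"))
  write_rdna_fasta(ds$lsu$unaligned, file.path(outdir, "lsu.fasta"))
  truth <- rbind(ds$ssu$truth,
                 cbind(ds$lsu$truth,
                       affected_primers = "", affected_regions = ""))
  write_report(truth, file.path(outdir, "truth.tsv"), format = "tsv")
  write_report(ds$ssu$primers, file.path(outdir, "primers.tsv"), format = "tsv")
  invisible(ds)
}

#' Marker-length contrast experiment on synthetic taxa
#'
#' Simulates one set of core sequences on a clade tree and compares the
#' discriminatory power of a short and a long marker region cut from the same
#' cores (disjoint intervals, mirroring a V9-like ~125-column region versus a
#' V4-like ~390-column region).
#'
#' @param seed integer seed.
#' @param n_clades,taxa_per_clade clade structure (default 6 clades of 4).
#' @param core_length core length.
#' @param stem_length,within_length branch lengths of the clade tree.
#' @param short_width,long_width region widths in columns.
#' @return List with `short` and `long` [collapse_report()]s over the same
#'   taxa (each simulated tip is one taxon).
#' @export
region_collapse_contrast <- function(seed, n_clades = 6L, taxa_per_clade = 4L,
                                     core_length = 1700L,
                                     stem_length = 0.08,
                                     within_length = 0.0009,
                                     short_width = 125L, long_width = 390L) {
  set.seed(seed)
  tree <- clade_tree(n_clades, taxa_per_clade, stem_length = stem_length,
                     within_length = within_length)
  sim <- simulate_core(tree, core_length = core_length)
  stopifnot(core_length >= 200L + long_width + short_width)
  long_int <- c(101L, 100L + long_width)
  short_int <- c(core_length - short_width + 1L, core_length)
  cut <- function(int) substr(sim$seqs, int[1L], int[2L])
  mk <- function(int, marker) {
    collapse_report(data.frame(taxon = names(sim$seqs),
                               haplotype = unname(cut(int)),
                               stringsAsFactors = FALSE),
                    marker = marker)
  }
  list(short = mk(short_int, "short"), long = mk(long_int, "long"))
}
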
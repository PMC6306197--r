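#!/usr/bin/env Rscript
# Generate the desk-scale synthetic rDNA dataset the downstream analyses run
# on: 21 taxa in 7 clades plus an intron-free reference outgroup, 18S cores
# (1669-1703 nt) carrying 19 intron locations restricted to clades 1 and 7
# (17 spliceosomal, 2 group I), a 28S set with one location, engineered
# V4/V9-style primer targets, and the truth table of every implant.
# Large sequence files land in scratch/ (regenerable); the truth table and
# primer configuration are the inputs the later analyses audit against.

suppressPackageStartupMessages(library(rdnaintrons))

data_dir <- "scratch/synthetic"
seed <- 1L

ds <- generate_dataset(default_generator_config(seed = seed), data_dir)

n_copies <- nrow(ds$ssu$aligned)
message("Wrote ", data_dir, ": ", n_copies, " 18S sequence copies (",
        aln_ncols(ds$ssu$aligned), " alignment columns), ",
        nrow(ds$lsu$aligned), " 28S copies, ",
        sum(ds$ssu$truth$present), " implanted 18S introns at ",
        length(unique(ds$ssu$truth$flank5)), " locations.")
message("Polymorphic copies: ",
        sum(grepl("_c[0-9]+$", ds$ssu$aligned$id)),
        "; truncated implants: ",
        sum(!ds$ssu$truth$complete, na.rm = TRUE), ".")
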
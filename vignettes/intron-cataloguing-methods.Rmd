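---
title: "Cataloguing rDNA introns and auditing metabarcode regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing rDNA introns and auditing metabarcode regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaintrons)
```

## The problem

Nuclear rDNA reference barcodes for planktonic diatoms (notably the
Chaetocerotaceae) are complicated by insertions in the 18S and 28S genes:
short spliceosomal introns and long group IC1 introns that occur in some
clades, vary between conspecific strains, sometimes show intra-individual
presence/absence polymorphism, and — when they land inside a primer target —
abort PCR with that primer. Any pipeline that curates such references needs
to (i) find the insertions in a multiple alignment, (ii) map them to a
stable coordinate system so the "same" intron can be recognised across taxa,
(iii) classify them by family, and (iv) quantify what they, and sequence
divergence generally, do to the V4 and V9 metabarcode markers. This package
implements those four steps plus a synthetic-data generator that makes every
step testable without any external sequence download.

## Coordinates and insert detection

The coordinate convention is the flanking-pair convention used in published
intron tables: an insert lives *between* two adjacent nucleotides of the
intron-free core sequence, and is identified by that 1-based pair
(`flank5`–`flank3`, with `flank3 = flank5 + 1`). Distinct pairs are distinct
locations even when they sit one position apart; `detect_inserts()` never
merges adjacent locations.

Detection needs an intron-free reference row in the alignment (an outgroup
or curated reference). A column is an *insert column* when the reference row
carries a gap there **and** at most `presence_max_frac` of the rows carry a
residue. The published analyses state only the limiting rule (positions that
are gaps in all but one sequence were excluded), not a numeric threshold for
their own alignment, so the fraction is an exposed parameter; the default
0.5 ("insert columns are gaps in the majority") is deliberately permissive
compared to the all-but-one rule and should be raised when more than half of
the sequences carry an insert at one site. Maximal runs of insert columns
become spans; each sequence with at least `min_len` residues in a span
yields one record.

Two practical rules come directly from how such alignments fail at the
edges:

* runs of reference gaps touching either alignment end are *frayed termini*,
  reported separately and never called as inserts;
* an insert is flagged incomplete (`complete = FALSE`, the "+" convention of
  the published table) when its span touches an alignment end or the nearest
  host-sequence residue beside the span is an `N` — the signature of a
  sequencing read that entered the insert but never exited it.

`extract_core()` removes the spans and returns both the core alignment and
per-sequence ungapped cores; re-inserting the removed segments reconstructs
every input sequence, and the suite checks this round trip plus the length
conservation `core + Σ inserts = original` on every generated dataset.

## The spliceosomal grammar

Short rDNA inserts are recognised by four ordered features:

| feature  | consensus | position |
|----------|-----------|----------|
| donor    | `GTDHNN`  | offset 0 |
| branch   | `YTRAC`   | internal, 3'-most candidate |
| CT tract | window of `ct_window` nt with pyrimidine fraction ≥ `ct_min_pyr` | between branch and acceptor |
| acceptor | `YNHAG` (28S also reports the terminal hexamer vs `YTAMAG`) | ends at the 3' terminus |

`GTDHNN` admits exactly 1·1·3·3·4·4 = 144 of the 4096 hexamers; the test
suite verifies this by brute-force enumeration, which also pins down the
IUPAC matcher. The sources describe the tract only as "CT-rich"; the window
width (10 nt) and threshold (0.6) are package choices, exposed in
`sp_grammar_params()`. The branch search takes the 3'-most `YTRAC` that
still leaves room for a pyrimidine window before the acceptor, because
biological branch points sit near the 3' end and the 3'-most rule makes the
scan deterministic. Sequences shorter than `min_len` (25 nt: donor + branch
+ window + acceptor cannot fit below that) are rejected outright.

`classify_insert()` then assigns families:

* complete insert passing the full grammar → `SP`;
* donor present, downstream grammar failed, length > 300 → `ambiguous`
  with the note "possible nested SP" (long donor-bearing inserts of this
  kind are plausibly an intron within an intron and should not be silently
  binned as group I);
* otherwise length ≥ `gi_min_len` → `GI`;
* otherwise `ambiguous`.
* truncated inserts are `partial` (subtype `SP-like` when the surviving 5'
  end carries the donor); no length or downstream-grammar claim is made for
  them.

`gi_min_len = 350` sits below the shortest complete group I insert observed
in the reference catalogue (399 nt) and above its longest spliceosomal
lengths; it is a tunable argument, not a biological constant. Group IC1
confirmation by database search is out of scope; length plus grammar absence
is the candidate rule, and callers can supply their own conserved-block
profiles for stricter matching.

## Group I conserved blocks and neighbor joining

Group I introns at one location share conserved blocks separated by
unalignable spacers. `extract_conserved_blocks()` computes per-column mean
pairwise identity (over pairs where both sequences have a residue), smooths
it with a centred window (default 10 columns) and keeps maximal runs at or
above `min_identity`. The default 0.7 suits introns from a single location;
when mixing locations whose spacers are mutually random (identity near the
0.25 baseline of uniform DNA) a threshold between the two regimes — the
analysis scripts use 0.45 — separates blocks from spacers. The published
work states no identity threshold; both values are documented package
choices.

Dissimilarities between block sequences are p-distances (positions with `-`
or `N` in either sequence are skipped). The sources say only "pairwise
dissimilarities"; p-distance is the minimal choice and a Jukes–Cantor
correction is available via `p_distance_matrix(jc = TRUE)`.

`nj_tree()` is classical Saitou–Nei neighbor joining with a fixed
determinism contract: ties on the Q criterion are broken by the smallest
(i, j) pair in label order, and negative branch-length estimates are clamped
to zero with a warning. The implementation is validated three ways: the
closed-form three-taxon solution to 1e-12, exact topology and path-length
recovery on additive matrices built from random trees, and topological
agreement with the independent `ape::nj()` on random non-additive matrices.

## Primer auditing

Primers are stored 5'→3' as synthesized; reverse primers are
reverse-complemented internally (degeneracy-aware) and all coordinates are
reported on the forward strand. `find_primer_site()` scans every offset and
returns the site with the fewest IUPAC-aware mismatches (an `N` in the
target is never a mismatch; ties go to the smallest start). Mismatch
positions are counted from the primer's 3' end, offset 0 being the terminal
base, and a mismatch within `critical_window` bases of the 3' end flags the
hit as critical. The window defaults to 3 because polymerase extension is
most sensitive there; the sources flag "critical" mismatches without
defining a window, and one passage places them at the reverse primer's
5' end while the results place them at the 3' end — the package standardizes
on the 3' end.

`audit_amplicon()` classifies a sequence for a primer pair, in precedence
order: `primer_disrupted` when an intron's flank pair lies strictly inside
either target interval (a pair abutting the interval's outer edge does not
block annealing), `critical_mismatch` when a hit is critical or exceeds
`max_mismatch` (default 2), `region_incomplete` when a target cannot be
found at all (best hit mismatching more than a quarter of the primer), else
`amplifiable`. The total amplicon length adds the lengths of introns lying
between the two targets, reproducing the "short core, long PCR product"
effect intron-bearing V4 regions show.

## Terminal taxa and marker discriminability

A terminal taxon is a group of identical and near-identical sequences.
`delineate_terminal_taxa()` end-trims to the shortest sequence, counts
pairwise differences (skipping `N`), and forms single-linkage clusters at
`max_diff` (default 2 — the published notion of "near-identical" is
informal, so the numeric tolerance is ours and exposed). Labels are
deterministic (`taxon_001`… ordered by representative id), output partitions
the input, and increasing `max_diff` can only coarsen the partition; both
properties are tested.

`collapse_report()` asks whether a marker region separates the taxa: taxa
sharing any identical full-length region haplotype collapse into one group;
incomplete haplotypes are excluded from equality testing (not padded) and
their taxa listed separately. `region_tree()` builds an NJ tree over
distinct haplotypes and attaches duplicates as zero-length sibling leaves;
`clade_recovery()` scores groups monophyletic in both a reference and a test
tree, with monophyly on unrooted trees evaluated as bipartition membership.

## The synthetic generator: what it emulates and what it does not

`build_synthetic_rdna()` produces data with known truth under one seed:

* cores evolved by Jukes–Cantor along a known clade tree — Poisson-placed
  substitution events, no indels, so every insertion in the output is
  attributable to an implant; the two-lineage divergence
  `p = 3/4(1 − e^(−8t/3))` is verified against simulation;
* core lengths drawn from 1669–1703 nt (18S) and 700–765 nt (28S), the
  observed ranges;
* spliceosomal introns sampled from the grammar above, 96–199 nt, with
  motifs drawn 80% modal / 20% uniform over the consensus class
  (sources say "usually"/"commonly" without frequencies);
* group I introns 399–547 nt built from per-location ancestral templates
  (four 60-nt conserved blocks, 5% per-base mutation, random spacers) and
  constructed to start `AA`, so they can never satisfy the donor consensus;
* the default scenario: seven clades of three taxa plus an intron-free
  reference outgroup; 19 18S locations (17 SP, 2 GI) confined to clades 1
  and 7, echoing the published flanking coordinates where they fit inside
  the simulated core; one location with presence probability 0.5 whose
  carriers are emitted as two copies (the two-band PCR observation); one
  location where sequencing truncates every insert (5'-anchored prefix, the
  following 8 core bases masked `N`); and engineered primer targets whose
  geometry leaves a 390-column V4-like and a 125-column V9-like region.

The generator does **not** emulate alignment error (its alignment is exact
by construction), rRNA secondary structure or covariation, indels in the
core, homing-endonuclease ORFs inside group I introns, or chimeras. Passing
round-trip tests therefore show that detection, mapping, classification and
tabulation are mutually consistent and exact *given a correct alignment*;
they do not show robustness to realignment noise, which real data would add
upstream of this pipeline.

## Numerical choices and degenerate inputs

* `U` is normalized to `T` at ingest; one alphabet downstream.
* Grouping by flank pair needs no tie-break; location indices are assigned
  by ascending 5' flank.
* NJ ties and negative branches: see above. Distance matrices must be
  symmetric with a zero diagonal; fewer than three labels is an error.
* `scan_spliceosomal` returns `NULL` (not an error) for grammar absence;
  empty insert sequences error.
* `p_distance` errors when no comparable sites remain.
* Primer-site ties go to the smallest start; among equally good reverse
  sites the amplicon uses the one found first (leftmost), i.e. nearest the
  forward site.
* `sample()`'s length-one surprise is avoided everywhere a range can be
  degenerate (`sample_range()`).

## Problem sizes

The shipped analyses and the acceptance script run at desk scale, chosen as
sizes a reviewer can re-run casually: 20 generated datasets of 24 sequence
copies and ~5,400 alignment columns for the round-trip suite, 1000-draw
sampler/scanner checks, 20 random 5–8-taxon trees for NJ recovery, 200
random primer/core pairs for the mismatch recount, and 24 seeds of the
6-clade × 4-taxon marker-length contrast. All are arguments, not constants.

## Known limitations

* Inserts shared by *all* sequences (including the reference) are invisible
  — detection is relative to an intron-free row by design.
* Family classification of truncated inserts is deliberately conservative
  (`partial`), since acceptor and tract cannot be assessed.
* The marker-length contrast is a statistical statement across simulations:
  in any single dataset a short region can, by chance, separate a pair the
  long region merges.
* The published table's internal inconsistencies (a printed column sum that
  disagrees with its own cells) are transcribed as printed; tabulation
  always recomputes from cells.
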
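---
title: "Methods: simulating and analysing ChIP-seq enrichment at repetitive centromeres"
author: "centrochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing ChIP-seq enrichment at repetitive centromeres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrochip)
```

## The problem

Kinetoplastid genomes (the *Trypanosoma brucei* pattern) carry regional
centromeres made of AT-rich tandem repeat arrays on their megabase
chromosomes, and a population of small minichromosomes whose cores are
palindromic arrays of a 177 bp repeat. Mapping kinetochore proteins onto
such genomes by ChIP-seq is dominated by one technical fact: short reads
(49 bp single-end tags) from a repeat array are consistent with many
positions, so a mapper that assigns multi-mapping reads uniformly at random
spreads centromeric signal across *every* sufficiently similar copy of the
repeat — including near-identical copies that sit outside any centromere,
which then show up as false-positive peaks.

`centrochip` implements the full analysis as a reusable, seeded pipeline,
and — because no public accessions exist for the original libraries — pairs
it with a synthetic-data generator so that every claim the analysis makes
can be tested against planted ground truth.

## The enrichment statistic

Reads from a ChIP library and a matched input (non-immunoprecipitated)
library are cleaned, mapped, and counted in nonoverlapping 150 bp windows;
a read increments every window its 49 bp interval overlaps. The per-window
statistic is the input-normalised proportion ratio

$$ r_w \;=\; \frac{c_w / C}{i_w / I}, $$

where $c_w$ and $i_w$ are the window's ChIP and input counts and $C$, $I$
the libraries' mapped-read totals. Windows with fewer than 10 raw input
reads are masked and excluded from all summaries (a noise guard, applied to
raw counts before normalisation). The background level is the arithmetic
mean of unmasked ratios over a designated non-centromeric reference
interval, and a peak is a run of unmasked windows with $r_w$ at least 3
times background, merged across gaps of at most one window. Neither the
peak threshold nor the merge gap has a published definition; both are
parameters (`fold_threshold`, `merge_gap`) with the defaults above, chosen
so that ten-fold planted occupancy is called cleanly while calibrated noise
(see below) is not.

Two properties of the ratio are worth noting. It is invariant to uniform
rescaling of either library (depth invariance). And its genome-wide mean
under enrichment is *below* 1 in the arms: enriched regions absorb a large
share of the ChIP library's fixed sequencing mass, so the normalised arm
signal is depressed. Background levels well below 1 are therefore expected
behaviour of the statistic, not a defect.

## The synthetic genome

`build_genome()` assembles:

* **Chromosome arms** — i.i.d. sequence at a configurable GC fraction
  (default 0.5). Real arms contain genes and degenerate retroelements, but
  the enrichment statistic only needs mappable, non-repetitive context;
  anything repeat-like can be represented explicitly as a planted
  duplicate.
* **Centromeric arrays** — tandem copies of a seeded master unit
  (default 177 bp, AT fraction 0.7, 240 copies) each independently mutated
  at a per-base substitution rate (default 0.04, giving copies at roughly
  96 % identity to the master — the regime in which 49 bp reads with a
  2-mismatch allowance cannot tell copies apart).
* **Planted duplicates** — copies of an interval of finished chromosome
  (typically centromeric sequence) pasted into an arm at a target percent
  identity. The default fixtures use 1,208 bp, the scale of the observed
  false-positive interval, with 100 % identity for the indistinguishable
  case and 90 % for the distinguishable one (the published
  indistinguishability statements are "higher than 96 %" and "less than
  93 %"; the fixtures sit clearly on either side).
* **The minichromosome contig** — 42,529 bp of tandem 177 bp repeats with
  an inversion point in the middle; the sequence left of the inversion
  point is the reverse complement of the sequence right of it, which is the
  construction invariant the tests assert directly.

Divergence is modelled as substitutions only — no indels — so percent
identity is Hamming identity, and every identity figure the package reports
or tests is exact under that model. Indel-aware identity (the general
`unit_similarity()` alignment path exists for unequal lengths) is not part
of the tested generator.

All coordinates are 0-based half-open internally and in BED output.

## The read simulator and cleaning rules

Fragments are sampled with start probability proportional to a
piecewise-constant occupancy profile (fold 1 outside features); lengths are
normal (mean 200 bp, sd 50 bp — only fragment-scale locality matters at
150 bp resolution). One 49 bp read is taken from the 5' end of a uniformly
chosen strand. Substitution errors are applied per base (default 0.005)
and the base quality encodes that rate.

Artifacts mirror the three cleaning rules, which are applied in a fixed
order (adapter, then N content, then quality) with first-match-wins
attribution:

1. reads containing the adapter are removed (removal, not trimming);
2. reads with strictly more than 5 % unknown nucleotides are removed —
   at 49 bp that means 3 or more Ns (3/49 = 6.1 %), while 2 Ns (4.1 %)
   survive;
3. reads with strictly more than 20 % of bases below Q10 are removed —
   10 bases (20.4 %) fail, 9 (18.4 %) survive.

The N rule is read as a fraction of read length, as stated, not as an
absolute count. Quality strings are Phred+33 throughout.

## The mapper

Reads are placed ungapped on both strands, keeping all placements at the
*minimum* achievable mismatch count when that minimum is within the
allowance (default 2). Completeness comes from the pigeonhole principle:
the read is split into `max_mismatches + 1` non-overlapping partitions
(17/16/16 bp at the defaults), so any valid placement leaves at least one
partition error-free and discoverable by exact k-mer lookup; candidates
are then verified by direct Hamming comparison. N bases mismatch every
reference base, consistent with the QC rule that lets at most 2 Ns
survive — such reads remain mappable.

Multi-mapping reads are resolved by a uniform random draw among the best
stratum, with the multiplicity recorded. Best-stratum-only reporting (a
0-mismatch hit suppresses 1–2-mismatch hits) matches the default behaviour
of the aligner family the analysis models; sampling among all placements
within the allowance would change which repeat copies receive signal, so
it is deliberately not offered.

The test suite holds the mapper to an independent oracle — a brute-force
scan via `Biostrings::matchPattern` on both strands — with exact equality
of best-hit strata, plus adversarial two-error placements in every pair of
read positions to exercise the pigeonhole guarantee.

## Cross-mapping diagnostics

`cross_map_rate()` enumerates every 49-mer of a feature (exhaustively up
to 5,000 k-mers, then a seeded sample of 10,000) and reports the fraction
whose best-stratum placements also fall in a second feature. Because an
exact k-mer of A always matches A itself with 0 mismatches, the rate
equals the fraction of A's k-mers with an exact counterpart in B: 1 for
identical copies, decaying roughly like $(1-d)^{49}$ with per-base
divergence $d$. `annotate_false_positive_peaks()` screens each
non-centromeric peak for an ungapped counterpart inside any truth
centromere at or above the indistinguishability bound (default 96 %) and
labels it `likely_artifact`; peaks overlapping a truth centromere are
labelled `centromeric` and are never marked as artifacts; everything else
is `independent`.

## AP-MS subcomplex deduction

Peptide evidence is filtered by the two-peptide inclusion rule
(`min_peptides = 2`, a strict boundary: 1 peptide is dropped, 2 kept) and
binarised into a bait × protein matrix. Baits are joined by an edge when
detection is reciprocal, and connected components are the candidate
subcomplexes. The published deduction was expert judgement over the
purification tables; the graph formalisation is this package's
reconstruction of it, and it is documented as such.

One refinement is applied on top of plain components: every member of a
group of size ≥ 2 must be detected in at least `support_threshold`
(default 0.75) of the group's bait purifications. Components violating
this are refined by removing the weakest-supported member and re-grouping
the removed members among themselves. On noise-free block-structured
evidence this changes nothing; its purpose is robustness — a single pair
of reciprocal false-positive cells would otherwise fuse two coherent
subcomplexes, and at a 5 % false-positive cell rate such a pair arises in
roughly one run in ten. Prey-only proteins attach to the group that
detects them at or above the same threshold, else remain singletons. An
optional frequency filter (`contaminant_fraction`) drops proteins present
in more than a given share of all purifications — a stand-in for the
informal "apparently specific" criterion, which has no published
quantitative form.

## Study conditions used by the tests

The heavyweight checks run at fixed, documented problem sizes, chosen once
as realistic desk-scale versions of the modelled experiment:

* **Demo genome** — four 400 kb chromosomes, each with a 42,480 bp
  centromere (240 × 177 bp at 4 % per-copy divergence) starting at
  position 180,000, plus the 42,529 bp minichromosome. ChIP occupancy is
  10-fold over centromeres and 3-fold over the minichromosome; the input
  is unenriched. Per-library coverage is 10× (mean input window count
  ≈ 40, comfortably above the 10-read mask). The background interval is
  positions 250,000–390,000 of the last chromosome — a scaled-down
  analogue of the published chromosome-4 reference interval, placed
  outside the centromere by construction and enforced by
  `validate_config()`.
* **Calibration runs** — one 400 kb chromosome, both libraries flat, 20×
  coverage, 20 seeds: the genome-wide mean unmasked ratio must sit within
  1.0 ± 0.05 with ≥ 95 % of unmasked windows in [0.5, 2.0].
* **False-positive fixture** — one 250 kb chromosome, a 21,240 bp
  centromere, and a 1,208 bp duplicate of centromeric sequence planted in
  the arm at 100 % (indistinguishable) or 90 % (distinguishable)
  identity, 20 seeds per condition.

What passing these tests shows — and does not show. The generator
emulates repeat architecture, multi-mapping ambiguity, sequencing error
and library artifacts; it does not emulate GC/PCR bias, chromatin
accessibility structure, fragment-size selection effects, gene content,
or indel variation. Recovery of planted centromeres here demonstrates
that the statistic, masking, background and peak rules behave as designed
under the stated model, not that any particular real-data peak is
correct.

## Numerical and design choices

* One global seed drives every stage through sub-seeds derived by hashing
  the seed with the stage name (`derive_seed()`), so a single stage can be
  re-run reproducibly and two identical runs are byte-identical.
* Masked windows carry `NA` ratios and are excluded from background,
  peaks and contig summaries; an interval with no unmasked windows is an
  error instructing the caller to pick another, rather than a silent 0.
* The final partial window of each chromosome is retained with its true
  width.
* Ties in multi-mapper assignment are broken by one uniform draw over the
  best stratum; ties in per-chromosome top-peak flagging resolve to the
  first maximum in coordinate order.
* Degenerate inputs are rejected early with field-named errors
  (`validate_config()`), including a background interval overlapping the
  configured centromere.

## Known limitations

Ungapped mapping only (no indels anywhere in the model); no statistical
significance testing on peaks (none exists in the modelled analysis); no
paired-end or PCR-duplicate modelling; the AP-MS deduction is a
formalisation of a published judgement call, not a reimplementation of
it; and the cross-map enumeration treats reads as error-free k-mers,
which is the conservative lower bound on ambiguity relative to
error-bearing reads.
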
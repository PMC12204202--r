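---
title: "Mining and measuring bacterial force-transduction systems with tolton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and measuring bacterial force-transduction systems with tolton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolton)
```

## The problem

Double-membraned bacteria couple energized processes at the outer membrane
to the proton-motive force of the inner membrane through envelope-spanning
machines. Two homologous machines dominate: the Tol-Pal system, a
seven-gene unit (in *E. coli*: *ybgC-tolQ-tolR-tolA-tolB-pal-cpoB*) that
stabilizes the outer membrane during division, and the Ton system
(ExbB-ExbD motor, TonB transducer, TonB-dependent transporters) that
energizes nutrient import. Their force transducers, TolA and TonB, share a
three-domain architecture — a transmembrane helix (domain I), a
periplasm-spanning region (domain II), and a globular C-terminal domain
(domain III) — but are nearly indistinguishable from sequence: TolA can be
short and proline-rich, TonB long and helical. Function must therefore be
inferred from genomic context: a transducer sitting in a locus that also
carries a motor, *tolB* and *pal* is TolA; a transducer with no such
neighborhood is TonB.

`tolton` implements this inference as a deterministic pipeline over
domain-annotated genomes: Pfam hits are mapped to functional roles, role
genes are clustered by proximity into loci, each genome receives a tol-pal
and a Ton status, transducers are assigned identities, and their
secondary-structure profiles are segmented and quantified. A synthetic-data
generator plants known systems and known compositions so that every stage
can be verified against ground truth without any database download or
external predictor.

## Role assignment

Each gene's HMMER domain hits (per-domain tabular layout; the dialect is an
explicit assumption, surfaced in the parser) are filtered at
`evalue_max = 1e-5` — no threshold is canonical for this screen, so it is a
configurable knob — and mapped through an editable catalog of fifteen Pfam
accessions to roles: `motor_pentamer` (PF01618), `motor_dimer` (PF02472),
`transducer` (PF06519/PF03544/PF13103/PF16031), the TolB β-propeller and
Rossmann domains (PF07676/PF04052), `pal` (PF00691), `cpoB_tpr`
(PF16331/PF13432/PF13174), `ybgC` (PF03061) and the TBDT barrel/plug
(PF00593/PF07715).

Two composite rules resolve multi-domain proteins. A TolB call requires the
β-propeller, and by default both TolB domains: a propeller-only gene is
reported as `tolB_like` and excluded from the minimal complement, since a
lone propeller is a common fold with many non-TolB owners. Likewise a TBDT
call requires barrel *and* plug (configurable to barrel-only). Genes whose
hits still support several roles are flagged ambiguous and resolved
deterministically — best bitscore, ties by lexicographically smallest
accession. Real curation would resolve such conflicts by structure
inspection; the deterministic rule is this package's reproducible stand-in
and the `ambiguous` flag preserves the information.

Two properties are enforced by construction and tested: role assignment is
invariant to input row order, and tightening `evalue_max` can only remove
roles.

## Locus clustering and system classification

Role-bearing genes on the same replicon are linked when their rank distance
is at most `max_intervening + 1` genes **and** their intergenic gap is at
most `max_gap_bp` bases; loci are the connected components of this graph.
The source analyses state only that constituent genes were detected "by
proximity", so the defaults — 3 intervening genes, 5 kb — are this
package's choice: wide enough to absorb small insertions, tight enough to
keep an *E. coli*-style operon from annexing its chromosomal neighborhood.
Both are exposed, and the test suite checks the clustering against a
brute-force transitive-closure oracle and verifies monotonicity (widening
thresholds can only merge loci, never split them). Strand is recorded but
ignored for clustering: curated loci are usually co-oriented, but this is
not asserted, so proximity is strand-agnostic. Replicons are treated as
linear; circular closure was considered and rejected as a default because
gene tables rarely carry replicon lengths.

A genome is then classified:

* **complete** — one locus carries the minimal complement
  {motor pentamer, motor dimer, transducer, tolB, pal};
* **split** — only a union of two or more loci does (each contributing at
  least one complement role); the split-partner search is genome-wide, with
  no maximum separation, matching curated split systems where *tolQRAB*
  and *pal-cpoB* lie distally;
* **partial** — some but not all complement roles exist genome-wide;
* **absent** — none do.

Ton classification imposes **no proximity requirement** — the Ton motor and
transducer co-occur only loosely on real chromosomes — and needs three
components anywhere in the genome: a transducer not claimed as TolA, a
TBDT, and the motor pair. A non-empty proper subset yields `incomplete`.

Transducer identity follows: a transducer inside a complement-satisfying
locus (or a member of a split union) is TolA, all others are TonB
candidates. At most one TolA is assigned per genome, mirroring the
biological expectation of a single *tolA*; when a complete locus carries
two transducers, the one closest in rank to *tolB* is picked and the rest
are flagged rather than silently assigned. The representative TonB per
genome is the first candidate (by replicon, then start) whose profile
admits all three domains.

"Directly adjacent" for the CpoB statistic means rank distance ≤ 1 to a
complement gene — deliberately distinct from locus membership, since the
narrative distinguishes CpoB being *found* from being *adjacent* without
defining either. Percentages over "genomes with detectable tol-pal
systems" use `complete` or `split` as the denominator; `partial` genomes
are not counted as detectable. Both choices are explicit because the
source leaves them open.

## Domain segmentation and composition

Segmentation is rule-exact: domain I is the predicted TMH; domain II runs
from the residue after the TMH to the residue before the final 100; domain
III is the final 100 residues, by convention, even where the real fold
boundary differs. If the TMH ends within 100 residues of the C-terminus,
domain II is empty and the record is flagged and excluded from cohort
statistics — no TMH is ever guessed.

The composition metrics are plain arithmetic: `helix_pct` is the
percentage of domain II residues predicted helical (H), `proline_pct` the
percentage of domain II residues that are proline — counted from the
amino-acid sequence, not the structure string, because proline is the
minimal proxy for polyproline-II content and three-state predictors do not
emit a PPII state. PPII propensity, when per-residue scores are supplied,
is summarized separately as the fraction of domain II residues at or above
`ppii_cutoff = 0.5`; how per-residue PPII output should be reduced to a
per-protein value is not standardized, so the cutoff-fraction is this
package's definition and an explicit knob.

Composition classes use a dominance ratio `r = 2` and a floor of 10%:
alpha-dominant when helix ≥ 2 × proline and helix ≥ 10%, proline-dominant
symmetrically, disordered when both sit below the floor, mixed otherwise.
The thresholds are descriptive bins for reporting, not biological claims,
and are configurable.

The **motor box** — a short predicted β-strand in the disordered region
just after the TMH — has no quantitative published definition (neither the
hosting "disordered region" nor a minimum strand length), so detection is
parameterized explicitly: the first run of ≥ `min_strand = 3` consecutive
E states beginning within the first `motor_box_window = 75` residues of
domain II, flanked on both sides by ≥ `min_coil_flank = 3` coil states.
The window sweep test verifies detection flips exactly at the boundary.

Lipoprotein classification passes an external signal-peptide prediction
through when present; otherwise a minimal lipobox heuristic
(`[LIV][ASTVI][GAS]C` with the cysteine in residues 10–40) is applied.
The heuristic exists so synthetic tests need no external predictor; an
external call always wins.

## Cohort statistics

* Length summaries use the midpoint median and Tukey hinges (`fivenum`),
  matching common spreadsheet/statistical defaults; the convention is
  stated because none is given in the source. Extremes carry species
  labels.
* The paired TolA/TonB length correlation is the standard Pearson
  coefficient; species lacking a TonB representative are dropped, not
  imputed.
* The Mann-Whitney U test is two-sided throughout (sidedness is never
  stated in the source, and two-sided is the conservative default). The
  p-value is exact — full null distribution of U — when `n1*n2 ≤ 400` and
  the pooled sample is tie-free, and otherwise uses the tie-corrected
  normal approximation with continuity correction. The exact path is
  checked against full permutation enumeration for all `n1, n2 ≤ 6`, and
  the null distribution of p is checked for uniformity by simulation.
* Reported percentages are rounded to integers, mirroring the reporting
  style of the quantities they emulate; raw fractions are retained in the
  outputs. No multiple-testing correction is applied, matching the source
  analyses; the tests here are few and descriptive.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions:

* **Genomes** (`generate_genome`, `generate_study`): planted clusters of
  catalog genes among decoy genes (default 40) on a 4 Mb replicon,
  intergenic gaps uniform on 50–400 bp (typical bacterial spacing, well
  inside the 5 kb threshold), clusters separated by ≥ 10 decoy genes so
  distinct clusters never satisfy the default proximity predicate. Five
  kinds are planted: complete, split, partial, Ton-only and none. In
  multi-genome studies CpoB is planted in 86% of detectable tol-pal
  genomes and adjacent in 92% of those — the reported cohort rates.
  Truth labels are derived from the planted design by set logic,
  independent of the locus engine.
* **Profiles** (`generate_profile`): count-exact placement of H states and
  prolines in domain II — the composition assertions are therefore
  zero-tolerance, with no probabilistic slack to tune — plus an optional
  motor-box strand built to satisfy the default detection parameters, and
  near-miss decoys (short CTD-only transducers) to exercise the
  three-domain filter.
* **Cohorts** (`generate_cohort`): paired log-normal domain II lengths
  with medians 192 (TolA) and 113 (TonB) residues and spreads chosen so
  the central 95% approximates the observed ranges (roughly 110–335 and
  40–245), coupled by a Gaussian copula with ρ = 0.28 — the reported
  weak positive pairing.

What the generator does **not** emulate: real sequence evolution, HMMER
score distributions, annotation noise, mis-called gene boundaries, or the
error modes of secondary-structure predictors. Passing the planted-truth
tests therefore demonstrates that the pipeline's logic is exact at zero
noise; it does not certify recall on real genomes, where curation
resolved the hard cases by structure prediction — a step explicitly out of
scope here.

## Numerical and degenerate-input choices

* ss2 parsing re-derives the state as the maximum-confidence state per
  residue; confidence ties break by the fixed precedence H > E > C, so
  parsing is deterministic.
* Empty domain II yields `NA` metrics and a flag, never a 0/0.
* Zero-variance margins make the correlation an error, not an `NA`
  silently propagated.
* Proportions over an empty denominator report `NA`.
* All outputs are deterministic functions of inputs, configuration and
  seed; `write_tables` records the configuration, seed and table
  checksums in a JSON manifest, and re-running reproduces byte-identical
  TSVs.

## Problem sizes

The test suite verifies clustering against the O(n²) oracle on 200 random
genomes of up to 50 genes, planted-truth recovery on 60 genomes across all
five kinds, monotonicity on 100 genomes, Mann-Whitney exactness over all
36 size pairs up to 6 × 6 plus a 500-replicate null simulation, and
composition exactness over a 36-point target grid. The analysis scripts
use 60 genomes, 113 profiles and 70 paired species — the scale of the
curated cohorts they emulate. The whole suite runs in well under a minute
on one CPU.

## Known limitations

* Real curation validated candidate loci by structure prediction
  (AlphaFold screens); this pipeline's stand-in is the secondary-structure
  plausibility check (`is_full_transducer`), which is strictly weaker.
* Conflicting-role resolution by bitscore is a reproducible convention,
  not a claim about how a human curator would decide.
* The proximity thresholds, motor-box parameters and composition bins are
  knobs with sensible defaults, not inferred quantities; conclusions that
  depend on them should be checked under perturbation (the monotonicity
  property makes threshold sensitivity predictable for locus calls).
* Cohort statistics are not phylogenetically corrected; related species
  count as independent observations, as in the analyses this package
  reproduces.
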
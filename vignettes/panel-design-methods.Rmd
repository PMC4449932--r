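---
title: "Methods: simulating, calling, and selecting a SNP fingerprinting panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, calling, and selecting a SNP fingerprinting panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsnp)
```

## The problem

Fixed SNP panels for maize variety fingerprinting are assembled by screening
a large source array against an evaluation panel of inbred lines and hybrids.
A candidate marker must cluster cleanly in two-channel intensity space, call
reliably, be polymorphic across the germplasm of interest, sit in a single-copy
genic region, and be designable as an assay probe. `panelsnp` implements that
whole workflow — simulation of the evaluation experiment, genotype calling
through a curated cluster file, locus quality control, staged selection, and
panel evaluation — so that every stage can be exercised and validated against
a known ground truth.

## The intensity model

A genotyping array reports two channel signals per (sample, locus) pair:
`x` for allele A, `y` for allele B. These are transformed to polar
coordinates

- theta `= (2/pi) * atan(y/x)`, the normalized angular deviation from the
  pure-A axis: 0 for a pure A signal, 1.0 for pure B, 0.5 for equal signals;
- R, the total signal, taken as the Manhattan magnitude `x + y` by the
  array-platform convention (a Euclidean option exists behind
  `cluster_config(r_metric=)`).

AA homozygotes cluster near low theta, BB near high theta, heterozygotes in
between. A point with `x = y = 0` has no angle and is treated as a failed
measurement.

## The synthetic-data generator

The generator emulates the structure of an array-evaluation experiment, not
any particular dataset:

- **Loci.** Markers are laid on 10 chromosomes with strictly increasing
  positions (inter-marker gaps uniform on 5–150 kb). Genic categories follow
  the proportions 0.43/0.21/0.22/0.09/0.05 for
  exon/promoter/3'UTR/5'UTR/intron; designability scores follow a
  three-interval mixture (1.5 % in [0.40, 0.60], 27.5 % in (0.60, 0.80],
  71 % in (0.80, 1.00]) matching the published spectrum of a curated
  fingerprinting panel.
- **Allele frequencies.** Each locus has an ancestral minor allele frequency
  (uniform on [0.25, 0.5] for ordinary loci, [0.02, 0.10] for planted
  low-MAF loci); per-group frequencies are drawn from a Balding–Nichols
  model with divergence `F` (default 0.15). The published work only states
  that heterotic groups exist, so `F` is exposed, not calibrated — a mid
  single-digit to low double-digit percent differentiation is a realistic
  ballpark for maize breeding pools.
- **Samples.** Inbred lines are homozygous draws from their group's
  frequencies; a `purity` knob (default 1.0, i.e. off — impure lines are an
  observed nuisance but no rate is reported) introduces off-type homozygous
  calls. F1 hybrids combine one allele from each parent; 22 recorded
  triplets mirror the evaluation design. Similar-line series clone a base
  line and mutate a configured fraction of loci: 0 for a radiation-mutant
  series, 0.02 for a backcross series (emulating ">97 % similarity").
  Duplicates copy a sample exactly.
- **Defect classes.** Six planted classes perturb the intensity emission the
  way real defective markers misbehave: `weak_signal` (total signal scaled
  to 10 % of nominal), `high_missing` (8 % of samples pushed into the failed
  zone), `pedigree_fail` (Mendelian-inconsistent F1 signal in 5 triplets),
  `het_inbred` (heterozygous signal in 8 inbreds), `shifted` (all centers
  displaced +0.2 theta), and `multicopy_compressed` (theta span compressed
  toward 0.5 by factor 0.8, the intermediate-cluster signature of a
  two-copy locus, which also carries `copy_number = 2`).

`simulate_study()` fixes the study composition: 4/5/3/3/4/6 % for the six
defect classes, 30 % planted low-MAF loci, 10 % low-designability loci,
remainder clean. Those masses were chosen once to echo the published summary
statistics of the source array (average MAF 0.17 implies a large
low-polymorphism mass; roughly a third of source loci fail cluster-quality
screening) and are not tuned thereafter.

All randomness flows from one explicit seed through named substreams
(`substream_seed()`), so the universe, population, and intensities can be
regenerated independently and reproducibly.

### What the generator does and does not emulate

It reproduces the *statistical* structure the selection procedure assumes:
cluster geometry per genotype, defect signatures, group-structured allele
frequencies, pedigree and duplicate relationships. It does not simulate
probe chemistry, per-channel affine scanner normalization, batch effects,
position-dependent intensity gradients, or linkage disequilibrium between
loci (loci are independent). Passing tests therefore demonstrate that the
*procedure* is correct and well-calibrated on data obeying its assumptions —
not that any particular real array meets those assumptions.

### The planted-good guarantee

`planted_good_loci` must satisfy every selection criterion *by
construction*, so that pipeline output can be compared to truth exactly.
Quality, missing-rate, defect, copy-number, and designability criteria are
guaranteed by the class assignment at default noise. The MAF criterion is
the delicate one: a locus whose realised inbred MAF falls near the 0.20 gate
could land on either side of it after calling noise. The generator therefore
rejection-resamples the inbred draws of any locus whose realised MAF lands
inside the narrow band (0.18, 0.215) around the gate — escape to either side
is accepted — and defines planted-good from the *realised* MAF (at or above
0.215). Call-based MAF stays within about 0.01 of truth MAF at default
noise (miscalls are vanishingly rare; only no-calls perturb the
denominator), so the band guarantees agreement between the truth-side
definition and the call-side gate. Allele-frequency estimation uses distinct
inbred lines only; duplicate re-assays of the same DNA are excluded.

## Cluster-file construction and calling

Per locus, points below the signal floor are excluded and the remaining
thetas are clustered by one-dimensional Lloyd iterations seeded at 0, 0.5,
and 1.0 — the canonical AA/AB/BB positions — vectorized across all loci. The
construction follows four principles: region boundaries are disjoint; the
missing rate is minimized subject to that; centers default to canonical
positions; and a center shifts to the observed cluster mean when the panel
provides enough evidence. Numerical choices:

- **Signal floor**: `max(0.2 × locus median R, 0.3)` on the nominal
  total-signal scale of 1.0. The absolute component matters: a purely
  relative floor scales down with the signals and can never recognize a
  weak-signal locus, whose defining property is that its *whole* signal
  distribution sits below a usable level.
- **Evidence threshold for a center shift**: 3 points. Clusters with fewer
  points keep default regions flagged `occupied = FALSE` at centers
  0.05/0.50/0.95 with halfwidth 0.05, so a genotype unobserved during
  construction (the rare-heterozygote problem) remains callable later.
- **Region geometry**: halfwidth `max(3 × cluster SD, 0.05)`, truncated at
  midpoints between adjacent centers to enforce disjointness.
- **Tie-breaks**: a point on a shared boundary goes to the nearer center; an
  exact midpoint resolves to the lower-theta region. Both are deterministic,
  and calling is permutation-equivariant in the sample order.
- **Degenerate input**: a locus with every point under the floor is recorded
  as weak with all regions unoccupied; every point at that locus calls NC.

Confidence is `1 − min(|theta − center|/halfwidth, 1)`. Calling against
uncurated default regions (`default_cluster_file()`) is retained as the
baseline: on the simulated study it roughly doubles the missing rate
relative to the curated file, which is the entire motivation for building
one.

## Locus quality and defect detection

The composite quality score is the geometric mean of four subscores in
[0, 1], mirroring the four characteristics a cluster-quality score is built
from:

- *angle separation* — minimum gap between adjacent occupied centers,
  normalized by the canonical 0.45 spacing;
- *dispersion* — `1 − mean within-cluster theta SD / 0.1` (the cap is the SD
  at which clusters visibly smear; exposed in `qc_config()`);
- *overlap* — one minus the fraction of points falling inside another
  occupied region's untruncated interval;
- *intensity* — fraction of points above the signal floor.

The score is comparable within this package only; no attempt is made to
match any proprietary score numerically. Defect rules use strict
inequalities, matching their "more than" phrasing: more than
`ceiling(0.05 × n)` failed samples (more than 5 of 96 — the count form
reconciles the 5 % rate wording with a 96-sample panel, where 5/96 already
exceeds 5 %), more than 3 inconsistent triplets, more than 5 heterozygous
inbreds, any occupied center more than 0.15 theta from canonical, median
signal below the floor.

## Staged selection

Four gates, each with the boundary semantics of its source wording:
quality ≥ 0.70 (inclusive — "between 0.70 and 1.00"); data quality (missing
data within bounds, no defect flags, perfect duplicate reproducibility among
informative pairs — whether any discordance was tolerated is unstated, so
this package requires perfection); population (copy number < 2, MAF ≥ 0.20 —
"under 0.2" is strict — and one locus per genic region by priority
exon > promoter > 3'UTR > 5'UTR > intron, inferred from the dominance of
exonic loci in the published panel, ties broken by quality then position);
designability ≥ 0.40 ("below 0.4" is strict). If survivors exceed the target
panel size the trim repeatedly removes the lowest-ranked locus from the
densest 1000-kb window (rank: good designability ≥ 0.60 first, then quality,
then designability) — the original reduction to a round panel size is not
described, so this evenness-preserving policy is the package's own. Removed
loci carry exactly one first-failure label and surviving sets are nested.

## Evaluation statistics

MAF is computed by allele counting on distinct inbred lines. Pedigree
consistency uses only loci scorable in all three triplet members; any
genotype mismatch counts as a difference in pairwise comparisons (no
half-weight for homozygote/heterozygote mismatches — "percentage of
different loci" does not weight), and pairs are complete-case. Genetic
similarity is defined as the complement of the differential rate (the term
is never defined at source; this is the natural reading). Histogram bins are
5 % wide. Cross-platform concordance is complete-case over shared entries —
whether NC-vs-call disagreements belonged in the published denominator is
unstated, so they are excluded here. Genomic windows are half-open,
`[(k−1)·w + 1, k·w]` on 1-based positions.

## Problem sizes and determinism

The bundled analysis scripts and tests run the full chain at 5,000 loci ×
96 samples (480,000 intensity points), which completes in seconds; the
planted-truth recovery check, the caller-accuracy check (≥ 99 % accuracy,
< 1 % missing on clean loci), the corruption-rate recovery over 20 seeds,
and the MAF-floor check over 10 seeds all use sizes in the hundreds-to-
thousands of loci, where every binomial acceptance band is computed at
3 SD. Fixed seeds make every output bit-identical across runs.

## Known limitations

- The quality composite is an analog, not a reimplementation, of any
  commercial score; absolute values are not transferable.
- Designability is locus metadata, not computed from flanking sequence.
- The generator draws loci independently; selection behaviour under strong
  LD or pervasive batch effects is untested.
- The copy-number gate consumes the simulated ground-truth copy number; the
  compressed-geometry signature is detected but advisory only.
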
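---
title: "Methods: spatial pattern analysis of cryosliced embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial pattern analysis of cryosliced embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicepattern)
```

## The measurement this package models

Cryosectioning a blastoderm-stage *Drosophila* embryo along the
anteroposterior (AP) axis and sequencing the mRNA of each slice yields, per
embryo, a genes × slices matrix of FPKM values — a coarse but genome-wide
picture of where along the axis each gene is expressed.  Comparing such
atlases between wild type and maternal-factor mutants (*bcd* depletion and
2.4× over-expression, maternal *hb* depletion, *zld* germline clones) asks
which genes lose, gain, shift or flatten their spatial patterns when an
upstream regulator is perturbed.

Two practical features drive all methodological choices here:

* **Embryos have different slice counts** (roughly 25–30), so profiles
  cannot be compared column-by-column.
* **Absolute levels are noisy and confounded** (staging, library depth),
  so position changes should be scored independently of level changes.

## Earth Mover's Distance on slice profiles

Each gene's profile in one embryo is turned into a probability
distribution on the unit interval: a point mass at each slice center
$(i - 0.5)/N$, proportional to the slice FPKM, renormalized to total mass
1 (`to_distribution()`).  The distance between two such distributions is
the exact 1-D Wasserstein-1 metric with ground distance $|x - y|$,

$$\mathrm{EMD}(a, b) = \int_0^1 |F_a(x) - F_b(x)|\,dx,$$

computed as the integral of the absolute CDF difference (`emd()`).  This
handles unequal atom counts naturally, is symmetric, satisfies the
triangle inequality, and lies in $[0, 1]$; translating a pattern by one
slice of an $N$-slice embryo scores exactly $1/N$ ($\approx 0.037$ at
$N = 27$), which anchors the intuition that distances of a few percent
correspond to one-to-two-slice shifts.

**Mass convention.**  Display normalization divides by the per-embryo
maximum (or 10 FPKM, whichever is greater; `max_normalize()`), but a
transport distance needs equal total masses, so EMD always uses
unit-mass renormalization.  This makes EMD invariant to uniform
rescaling of a profile — deliberately blind to pure level changes, which
are counted separately (`level_response()`, 1.5-fold in both dosage
directions, boundary inclusive).

**Oracle.**  `emd_lp_oracle()` solves the underlying transportation
problem by the north-west-corner rule on position-sorted atoms.  For
costs $|x-y|$ on the line this plan is already optimal (Monge property),
so the oracle is exact while sharing no code path with the CDF integral;
the test suite holds the two to within $10^{-9}$ on thousands of random
instances.

**QC imputation.**  A slice that failed sequencing QC is replaced by the
mean of its nearest usable neighbor on each side; a failed terminal
slice copies its nearest usable neighbor (the interior rule is forced by
the field's convention, the edge rule is this package's choice — an
average is undefined with one neighbor).

## Classification and transitions

Per genotype, a gene is

* `low_expression` if it never reaches **15 FPKM** in any slice of any
  replicate;
* otherwise `uniform` if its replicate-averaged EMD to a uniform
  distribution is **< 0.04**, `patterned` if **> 0.08**, `ambiguous` in
  between.

The ambiguous band is excluded from transition counting; the transition
table reports the four canonical cells (low→patterned,
patterned→uniform, patterned→low, uniform→patterned) plus a remainder,
over the universe of genes expressed in at least one of the two
genotypes compared.

Replicate aggregation is the **mean** over cross pairs throughout
(min/median are available as options); the underlying data do not
determine this choice, and the mean keeps estimators linear.

## The differential-response statistic ΔD

For one wild type and two mutants,

$$\Delta D \;=\; \mathrm{EMD}(M_1, M_2) \;-\;
  \bigl|\mathrm{EMD}(M_1, WT) - \mathrm{EMD}(M_2, WT)\bigr|,$$

with every EMD the replicate-averaged cross-pair distance.  By the
reverse triangle inequality $0 \le \Delta D \le \mathrm{EMD}(M_1, M_2)$:
a gene that both mutants push the same way scores near 0 even if both
changes are large, while a gene that responds *differently* to the two
perturbations scores high.  Genes in the top tail of a change
distribution are flagged by the empirical order statistic: the top
$\lfloor n(1-q) \rfloor$ values ($q = 0.8$, i.e. top 20%), inclusive of
boundary ties — inclusive so that an integer cutoff is reproducible and
no tied gene is arbitrarily dropped.

## Binding enrichment

A gene is "bound" by a TF if any ChIP peak of that factor overlaps the
±10 kb window around its TSS (any-overlap, strand-agnostic; peak-summit
alternatives would only shrink the bound set).  Three designs are
implemented:

* **category enrichment** — per-TF Pearson χ² (no continuity
  correction, matching the named test) of binding in a transition
  category versus the remaining expressed genes, Bonferroni-corrected
  over the 10-TF panel;
* **ΔD-rank enrichment** — top 50 genes by ΔD versus the 200 genes
  closest to the median ΔD of the co-changing universe (the top set is
  excluded from the control candidates so the designs cannot overlap);
  odds ratios use the Haldane–Anscombe 0.5 correction only when a zero
  cell occurs, and are flagged when they do;
* **binding-signature KS tests** — genes sharing an exact binary
  binding signature (groups of ≥ 30) compared to all expressed genes by
  two-sample Kolmogorov–Smirnov on summed EMD scores.

A combinatorial-binding curve bins rank-sorted genes into windows of 50
and regresses the fraction bound by ≥ k factors on the window mean ΔD.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` draws, per gene, a wild-type pattern from parametric
archetypes — flat, exponential AP gradients (decay length 0.08–0.25 of
embryo length), Gaussian domains (width 0.05–0.12, anterior / central /
posterior), raised-cosine stripe patterns (3–7 stripes) — with FPKM
amplitudes log-normal around ~60 and ~10% of genes kept below the
15 FPKM floor.  Mutant genotypes apply effect operators (loss to low,
uniformize with mass conservation, shifts of 0.08–0.20, ectopic domain
gain, 1.6–3× level scaling) to a shared "responsive" gene set (20% of
genes, hit with probability 0.7 per mutant versus 2% background), which
reproduces the observation that genes changing in one mutant tend to
change in others.  Slices are interval means of the continuous pattern
(midpoint rule, 32 sub-samples) times per-gene, per-slice multiplicative
lognormal noise (σ = 0.15 by default); slice counts are drawn per embryo
from 25–30; slices fail QC independently at 3%.

Values not printed in the source study and fixed here once: the noise
law and σ, the QC failure rate, the family mix and parameter ranges, and
the responsiveness structure.  The slice-count default (25–30) follows
from the stated equivalence "one slice ≈ 3.5% of length", implying ~27
slices.

A green recovery test therefore establishes that the *pipeline
machinery* — distances, thresholds, tables, tests — recovers a known
truth in a world with the stated design geometry and realistic
noise.  It does not establish anything about read-level artifacts,
staging variability between embryos, DV-axis contamination, or
time-continuous dynamics, none of which are simulated.

One emergent subtlety: `uniformize` conserves a gene's mean expression,
so uniformizing a narrow, high domain can land *below* the 15 FPKM
floor.  The truth table records the class the perturbed pattern actually
has (low-expression), and such genes correctly appear in the
patterned→low cell, alongside explicit losses.

## Numerical and design choices

* EMD is computed on merged sorted breakpoints; the only floating-point
  work is one cumulative sum, so agreement with the LP oracle at 1e-9 is
  routine.
* Genomic intervals are 0-based half-open (BED native); TSS are 1-based
  points; the conversion happens once, at the overlap boundary.
* Clustering sorts genes lexicographically before building the distance
  matrix, making merges invariant to input row order; gene pairs never
  co-expressed in any embryo get the maximal distance 1.
* The pipeline writes every intermediate as TSV with values at 6
  significant digits; reruns with the same seed are byte-identical
  (checked over all analysis outputs).
* In small cohorts the "top 50 vs 200 near-median" ΔD-enrichment design
  can exceed the number of co-changing genes; the operation itself
  errors (the design is infeasible), and the pipeline shrinks the
  control set with a logged notice rather than silently re-ranking a
  different universe.

## Known limitations

* Classification at a fixed stage; no cross-time-point alignment or
  interpolation.
* The EMD mass convention intentionally ignores level-only changes;
  a gene that doubles everywhere scores 0.
* Stripe patterns near the slice width cannot be resolved — as in the
  real measurement.
* Enrichment p-values assume independent genes; co-regulation makes
  them optimistic, which is why recovery tests use planted effects
  rather than nominal calibration alone.
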
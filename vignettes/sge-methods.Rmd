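---
title: "Statistical methods for saturation genome editing screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for saturation genome editing screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sgemap)
```

## The assay and its generative model

A saturation genome editing (SGE) screen introduces every designed variant
of a gene into an endogenous locus of an essential-gene cell model and
follows each variant's abundance over a culture time course. The design
this package targets has two guide/HDR libraries per exon, three
biological replicates and five sampling days (4, 7, 11, 15, 21), with
Day 4 the post-selection baseline. Each guide library carries a
guide-specific synonymous PAM/protospacer edit to block re-cutting;
designed variants overlapping the PAM codon are multi-nucleotide changes
on that background and are excluded for that guide, the other guide's
library providing the measurement.

The abundance of variant $v$ in sample $s$ is modelled as negative
binomial with mean $\mu_{vs} = N_{0v}\,2^{\beta_v d_s}\,c_s$ and variance
$\mu + \alpha\mu^2$: $N_{0v}$ the baseline abundance, $\beta_v$ the
kinetic slope in log2 units per day, $d_s$ the elapsed days since
baseline, $c_s$ a sample depth factor, and $\alpha$ the dispersion. The
synthetic generator (`simulate_counts()`) draws from exactly this model.

## The synthetic-data generator

`sge_scenario()` fixes the study conditions. Defaults:

- design: 2 guides/exon, 3 replicates, days 4/7/11/15/21; the default toy
  gene (4 exons x 120 nt plus 25 nt / 15 nt intronic flanks) yields about
  two thousand designed variants — every coding SNV, every in-frame
  single-codon deletion, and every intronic SNV in the flank window, with
  canonical splice sites defined as the 2 intronic bp at internal exon
  boundaries. Deeper flank positions are labelled intronic.
- class slopes (log2/day): unchanged 0, enriched +0.15, slow-depleting
  −0.15, fast-depleting −0.45. These per-class kinetic rates are
  *synthetic repository defaults chosen for separability* — the source
  assay reports classes, not rates — and are tunable.
- per-variant kinetic deviation `slope_sd` = 0.04 log2/day around the
  class slope, applied only to classes with non-zero slope: functionally
  neutral variants have no fitness effect, so giving them kinetic drift
  would contradict the meaning of "unchanged" (and early development runs
  confirmed the calibrated test then flags them as real effects — the
  generator, not the test, was wrong).
- `guide_effect_correlation` = 0.9: the fraction of the kinetic-deviation
  variance shared between the two guides, mirroring the high per-guide
  concordance of real screens (trend correlation ≈ 0.9).
- `nb_dispersion` α = 0.05 (variance μ + αμ²), baseline abundance
  log-normal around 500 counts (log-sd 0.5), per-sample depth factors
  log-normal (log-sd 0.1). These are typical magnitudes for amplicon
  screens at ≥10,000x library coverage.
- class-conditional consequence probabilities
  (`default_class_probabilities()`) mirror the reported structure of such
  screens: ~95% of nonsense variants depleted (mostly fast), ~98% of
  synonymous variants unchanged, ~74% of canonical splice variants
  depleted, ~16% of missense depleted, intronic variants mostly
  unchanged.

What the generator does *not* emulate: HDR efficiency differences between
loci, sequencing error, positional biases within amplicons, linked
selection between variants, or real splice-regulatory sequence effects.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not performance on any real screen;
real-data quantities (e.g. absolute depleted/enriched counts) require the
deposited data and are out of scope.

The toy CDS avoids adjacent identical codons, because deleting either of
two identical adjacent codons yields the same oligo sequence and
exact-match counting would be ambiguous. When a PAM edit makes two
designs sequence-identical, the PAM-flagged design (excluded from
analysis anyway) is dropped from the library.

## Counting and filtering

`count_reads()` trims each read to the window between the two primer
flanks (full primer match required — partial matches are reported, not
guessed at) and exact-matches against the designed sequences;
mismatching reads are tallied separately. Mismatch-tolerant matching is
deliberately excluded to keep counts unambiguous. `filter_low_abundance()`
drops, per guide, variants whose total count across replicates and
timepoints is ≤ 10 (the boundary is inclusive).

## Effect estimation

`size_factors()` scales each sample by its total count divided by the
within-guide geometric mean of totals. Median-ratio scaling is avoided on
purpose: an SGE screen of an essential gene violates the assumption that
most features are unchanged.

`fit_lfc()` fits, per (variant, guide), a negative binomial log-link
model with the timepoint as a two-level factor (baseline vs target day)
and log size factor as offset; `fit_lfc_trend()` replaces the factor with
the numeric covariate $d \in \{0,3,7,11,17\}$ so the slope is log2 change
per day. Dispersion is estimated per variant by the method of moments on
normalised counts, pooled across all observed timepoints
($\hat\alpha = \sum_d (s^2_d - \bar m_d) / \sum_d \bar m_d^2$, floored at
$10^{-8}$), with no empirical-Bayes shrinkage — a documented
simplification relative to DESeq2-style machinery; correctness is
established by simulation calibration rather than bit-level matching.

Numerical choices:

- Wald statistics are referenced to a *t* distribution with the
  dispersion residual degrees of freedom (timepoints × (replicates − 1)).
  With three replicates, the plug-in dispersion makes the normal
  reference anticonservative (measured type-I ≈ 0.08 at nominal 0.05);
  the t reference restores calibration (≈ 0.05), which the test suite
  asserts on a 2000-variant null.
- A group that is entirely zero receives a half-count pseudocount to keep
  the MLE finite (flagged in the output); variants all-zero in both
  groups are excluded and reported.
- Estimates are reported in log2 units (natural-log coefficient / ln 2).

## Centering, combination, classification

`median_center()` subtracts, per guide library and effect kind, the
median estimate of synonymous + intronic controls (standard errors
unchanged). `combine_guides()` uses the inverse-variance-weighted average
for the point estimate and the weighted sum of z-scores
($w_i = 1/\mathrm{se}_i$) for significance; single-guide variants pass
through. `merge_pam_codon()` excludes PAM-flagged measurements first and
reports the rescue bookkeeping.

`bh_fdr()` applies Benjamini-Hochberg step-up across all variants within
an effect kind — a single global stratum. The per-exon alternative was
considered (controls are exon-matched in the source assay) but a single
genome-wide FDR column is what downstream consumers read, and the
correction stratum is configurable in principle; the global choice is the
default and the one tested.

`assign_classes()`: FDR > 0.01 → unchanged; significant and positive
Day-15 cLFC → enriched (the sign is taken from the Day-15 level, not the
trend); otherwise depleted, then split fast/slow by a two-component
full-covariance Gaussian mixture on (Day-7, Day-15) cLFC fitted *to
depleted variants only* (the depleted kinetic substructure is the
question; fitting all variants would let the unchanged mass dominate).
EM details: deterministic initialisation at the data points nearest the
10th and 60th percentile of Day-15 cLFC, pooled covariance start, equal
weights, relative log-likelihood tolerance $10^{-6}$, at most 500
iterations, covariance ridge $10^{-8}$. The component with the more
negative Day-7 mean is fast; hard assignment by maximum posterior with a
posterior of exactly 1/2 broken toward slow (conservative). Fewer than
10 depleted variants skips the mixture ("depleting", unsplit, with a
warning).

## The supervised classifier

`train_ndd_classifier()` is a 500-tree random forest on combined LFC at
days 7, 11 and 15 (default mtry = √p, unlimited depth — defaults, since
tuning did not help in the source analysis), trained on a stratified 80%
split of the truth set. Prediction is the mean class probability across
trees; a variant is called abnormal at posterior ≥ 0.5 (the boundary
case goes to abnormal), with confidence tiers high (> 0.9), intermediate
(0.5–0.9 inclusive) and normal (< 0.5) — posterior exactly 0.9 is
intermediate. Linear baselines exist in the field but only the forest is
on the tested path here. Confusion metrics are percentages at one
decimal; ROC AUC is the rank (Mann-Whitney) statistic. In-silico
benchmarking supports the published supporting-evidence thresholds
(SIFT < 1e-4, PolyPhen2 > 0.978, REVEL > 0.773, CADD > 25.3) and
developer defaults; the SIFT band [1e-4, 1e-3), which the published rule
leaves undefined, is treated as test-negative.

## The interpretation engine

All gene-level constants live in `acmg_gene_config()` so the engine is
not hard-coded to one gene: coding length, last coding junction, critical
domain intervals, NMD windows (first 200 coding bp; beyond
last-junction − 55 bp), the frequency threshold (3.25e-7) and the 10%
truncation threshold. Evidence strengths map to Tavtigian points
(supporting/moderate/strong/very strong = 1/2/4/8, benign negative) with
tiers at ≥ 10 / 6–9 / 0–5 / −6…−1 / ≤ −7.

Decisions worth noting:

- "Not observed in the population" is implemented as pathogenic-moderate
  evidence with code `PM2_like`; the source guidance labels it under BS1,
  which the output preserves in a note.
- The published frequency threshold 3.25e-7 is shipped as a constant. It
  does not follow from the stated prevalence (1/27700), allelic
  heterogeneity (0.09) and penetrance (0.5) under the standard
  maximum-credible-AF formula, which gives ≈ 3.25e-6;
  `af_threshold_derivation()` surfaces both numbers rather than guessing
  which is intended.
- PP3/BP4 are never applied to canonical splice variants (the PVS1 logic
  already encodes the splice prediction); a missing splice delta score is
  treated as "no predicted splice impact", so BP4 remains reachable for
  missense variants scored only by REVEL/CADD.
- PS2-supporting (non-de-novo with a prior de novo report) and PP5 can
  co-apply; both are emitted.

## Burden and structure analyses

The trinucleotide mutation-rate table is pluggable; a synthetic,
strand-complement-symmetric table ships for tests. Class probabilities
sum rates over SNVs within 10 bp of an exon-intron boundary (exome
coverage comparability) and expected counts allocate the total
observations by those probabilities, with exact Poisson CIs on the
observed counts. The pathogenic missense fraction is
$(\mathrm{obs_{mis}}/\mathrm{obs_{non}})/R_{exp}$ with a seeded
parametric bootstrap CI on independent Poisson counts (the source's CI
method is unstated; the bootstrap is declared). Cancer driver
stratification uses per-class 2x2 chi-squared tests without continuity
correction plus the overall stratum-by-class test.

Structure summaries consume SASA tables (no SASA computation from
coordinates): burial at accessible proportion < 25% (strict). Side-chain
centroids fall back to C-alpha for glycine (how residues with missing
side-chain atoms were handled upstream is unstated; the fallback is
declared and logged). The modal class per residue breaks ties by severity
fast > slow > enriched > unchanged — a repository decision, asserted as
such in the tests.

## Orchestration and problem sizes

`run_sge_pipeline()` chains the stages with per-stage seeds derived from
one master seed; `sge_config()` exposes every threshold. This package's
interface is its functions and this vignette — the natural shape for an R
analysis package of this kind; no shell entry point is shipped beyond the
reproducibility script (`scripts/acceptance.R`).

Default problem sizes, chosen as the package's own test conditions: the
synthetic screen uses a ~2,000-variant gene (4 exons × 120 nt), which
exercises every stage in about half a minute; the null-calibration
property uses 2,000 variants; the bootstrap CI uses 1e5 draws. The suite
asserts ≥ 90% four-way class recovery on the default scenario, ≤ 2%
non-unchanged calls on the null scenario at FDR ≤ 0.01, and held-out
classifier AUC ≥ 0.95; measured values are ≈ 98%, ≈ 0.3–0.5% and ≈ 0.98.

## Known limitations

- No empirical-Bayes dispersion shrinkage; very low-count variants rely
  on the pooled method-of-moments estimate and the low-abundance filter.
- The mixture is fixed at two depleted components; screens with more
  kinetic classes would need a model-selection step.
- The interpretation engine implements only the enumerated criteria (no
  PM1/PM4/BP7, co-segregation or case counts) and is not a general ACMG
  engine.
- Synthetic truth sets inherit the generator's class structure; external
  validity of the classifier must come from real curated variants.
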
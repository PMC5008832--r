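---
title: "Discovering and validating progression biomarkers for Barrett's esophagus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating progression biomarkers for Barrett's esophagus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beprog)
```

## The problem

Barrett's esophagus (BE) is the precursor lesion of esophageal
adenocarcinoma (EA), yet only a small fraction of BE patients ever
progress. Surveillance is endoscopic, biopsy-based and expensive, and no
molecular marker for risk stratification is in routine use. Because
progression is rare, individual expression-profiling studies of
progressor BE are tiny; discovery therefore has to pool several small
public microarray datasets — samples from patients whose BE later
progressed (P-BE), samples from patients who never progressed (nonP-BE),
and EA samples — into one meta-cohort, and then validate whatever the
meta-analysis proposes in an independent clinical cohort with long
follow-up.

`beprog` implements this discovery funnel and its validation statistics
as a tested, reusable package, and pairs it with a synthetic-cohort
generator with planted ground truth so that every stage can be exercised
and audited end to end without any external data.

## The discovery funnel

### Frozen-reference normalization

Arrays from different labs differ by shifts and distortions that would
swamp a cross-dataset contrast. `normalize_frozen()` quantile-maps each
sample, independently of every other sample, onto a *frozen* vector of
reference intensities (`frozen_reference()`): the value of within-sample
rank *r* is replaced by the reference quantile of the same relative rank,
with linear interpolation between reference quantiles and ties receiving
the average of the tied quantiles. Nothing is estimated from the cohort
being normalized, so single arrays and whole datasets become comparable
against the same target.

This is a deliberate, loudly-documented simplification of probe-level
frozen normalization methods, which freeze probe effects and
batch-specific variances learned from a large reference corpus. The
funnel's downstream stages consume only gene-level intensities and frozen
cutoffs, so the package freezes exactly the two things those stages need:
a reference quantile vector (for normalization) and per-gene
unexpressed-distribution parameters (for barcoding). Consequences: the
mapping is exact about rank structure (it preserves within-sample ranks
and is idempotent) but cannot correct probe-level artifacts, and it
assumes the reference distribution is appropriate for every dataset being
mapped.

### Moderated differential expression with a log-odds score

With 8 progressor samples against 25 non-progressors, per-gene variance
estimates are unstable. `fit_moderated()` uses the standard hierarchical
model for gene-wise variances: the pooled residual variance
$s_g^2$ (on $d_g = n_a + n_b - 2$ degrees of freedom) is assumed drawn
from a scaled inverse-chi-square prior with parameters $(d_0, s_0^2)$,
estimated by matching the mean and variance of
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ to their theoretical
values ($\psi$, $\psi'$ are the digamma/trigamma functions):
$\psi'(d_0/2) = \widehat{\mathrm{var}}(e) - \psi'(d_g/2)$, solved with a
Newton iteration on the inverse trigamma. The moderated statistic is
$\tilde t_g = \hat\beta_g / (\tilde s_g \sqrt{1/n_a + 1/n_b})$ with
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, referred to a t
distribution on $d_0 + d_g$ df.

Each gene is scored by the log posterior odds of differential expression
(the *B*-statistic, here `lods`), given a prior proportion `p_de`
(default 0.01) of differential genes and a prior variance for the
standardized effect estimated by quantile-matching the largest |t|
statistics against the two-component mixture. `lods` is strictly
increasing in $|\tilde t|$ at fixed df, is floored at $-10^6$, and shifts
by a constant when `p_de` changes — which is why the *threshold* on it is
calibrated empirically rather than read as an absolute posterior
probability.

Numerical choices worth recording:

* **Degenerate variance dispersion.** When the between-gene spread of
  $\log s_g^2$ does not exceed its sampling variability the moment
  equation has no positive solution; the package sets $d_0 = \infty$ and
  estimates the single shared variance as $\bar{s^2} = \mathrm{mean}(s_g^2)$,
  which is unbiased under the common-variance model this limit implies.
  The log-scale plug-in $\exp(\overline{e})$ would carry a Jensen bias
  factor and would break the identity that, with identical gene
  variances, the moderated t *equals* the ordinary pooled two-sample t —
  an identity the test suite asserts to $10^{-9}$.
* **Zero-variance genes** are floored at machine epsilon and flagged in
  the result (`zero_var`), never silently dropped.
* **Prior effect variance floor.** The quantile-matching estimate of the
  effect's prior variance can be exactly zero on pure-null data, which
  would make `lods` constant; it is floored at $10^{-8}(1/n_a + 1/n_b)$
  so the score remains strictly monotone in |t|.
* `log2fc` is the difference of group means of log2 intensities — the
  natural reading of a log2-ratio threshold.

### Calibrating the selection threshold on negative controls

The selection rule (`select_candidates()`) keeps genes with
`lods >= 5` and `|log2fc| >= 0.58` (both inclusive). The log-odds cutoff
is not a theory-derived constant: it is chosen so that a contrast in
which *no* differential expression is expected — EA samples from two
different datasets, compared by dataset of origin — yields zero genes
above the threshold. `calibrate_null()` packages exactly this check and
reports how many genes exceed a candidate threshold and the maximum
`lods` observed. The acceptance suite verifies that on null synthetic
splits the default threshold is clean in at least 95% of 20 seeded
replicates, and that an uncorrected global shift between the halves (a
batch effect left unnormalized) drives genes above it — the failure mode
the calibration exists to catch.

The selection keeps both directions of change by default; an `up_only`
flag restricts to over-expression. The package leaves directionality to
the barcode-exclusivity step, which by construction retains genes
*expressed* in progressors and absent elsewhere.

### The expression barcode

Microarray intensity is only interpretable relative to a gene's
unexpressed distribution. `binarize()` calls a gene expressed in a sample
iff its intensity is at least `z_cut` standard deviations above the
frozen per-gene unexpressed location — an inclusive rule at the boundary.
The default `z_cut = 5` is conservative: with the generator's default
separation (unexpressed N(4, 0.5), expressed N(9, 1) on the log2 scale)
it makes false "expressed" calls negligible while keeping true expressed
intensities comfortably above the cutoff. It is exposed in the reference
and in the pipeline config.

Dataset barcodes then demand consistency: a gene enters a P-BE dataset
barcode only if expressed in **100%** of that dataset's samples, and a
nonP-BE or EA dataset barcode if expressed in **>= 75%** (both
inclusive; `dataset_barcode()`). Group barcodes intersect the dataset
barcodes (`group_barcode()`), and the progressor-exclusive set is the set
difference P-BE minus nonP-BE (`exclusive_genes()`). An EA barcode is
computed and reported, but does not enter the default exclusivity rule —
the exclusive set is defined against the non-progressor background; a
`subtract_ea` switch enables the stricter variant. Intersecting the
exclusive set with the DE candidates (`intersect_candidates()`) yields
the final marker candidates, each carrying its filter provenance.

### Enrichment and network prioritization

`hypergeom_enrich()` tests over-representation of each gene set in the
candidate list against the universe of all genes on the pooled matrix,
by exact summation of the hypergeometric upper tail, with
Benjamini–Hochberg adjustment across sets (`bh_adjust()`, a validated
wrapper over the standard step-up procedure). Only over-representation
(one-sided) is tested.

`propagate_labels()` ranks network genes by guilt-by-association: scores
solve $(I + \lambda L)f = y$ with $L$ the symmetric-normalized graph
Laplacian of a user-supplied weighted network and $y$ the indicator of
the seed set. The solution is non-negative, zero on components with no
seed, and invariant to node relabeling; isolated nodes are given a zero
Laplacian row. `expand_neighbors()` adds the top-`k` (default 100)
non-seed genes by this score. The multi-network weighting of web-based
association tools is out of scope by design: the package takes one
pre-combined weighted network as input and implements the propagation
step itself, so the ranking is reproducible offline. The solver is dense,
which is appropriate for the desk-scale networks (hundreds to a few
thousand nodes) this stage is meant for.

### Orchestration

`run_funnel()` drives all stages from one config (R list or YAML) and
writes every intermediate as TSV with a provenance header carrying the
package version, a deterministic config hash and the seed. The funnel
summary is rewritten as stages complete, so a failed stage leaves a
partial, reportable run directory; `report_funnel()` renders either. All
randomness flows from the single `seed` field — reruns are
byte-identical.

## The validation arm

* `delta_delta_ct()` implements relative quantification: replicate Ct
  values are averaged *first*, then per patient and timepoint
  $\Delta Ct = Ct_{target} - Ct_{calibrator}$,
  $\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}$ (control
  mean taken within the same timepoint), and fold change
  $2^{-\Delta\Delta Ct}$. The construction makes the result invariant to
  any per-patient shift common to target and calibrator (input amount).
  Group summaries report the geometric mean of fold changes (ratios) as
  primary and the arithmetic mean alongside, since "average fold change"
  is ambiguous between the two.
* `fit_standard_curve()` fits Ct against log10 input mass over a
  dilution series (default grid 100 ng down to 0.0001 ng in 10-fold
  steps) and reports slope, $r^2$ and amplification efficiency
  $10^{-1/slope} - 1$.
* `wilcoxon_rank_sum()` uses the exact enumeration null when
  $n + m \le 20$ with no ties — the regime of a 9-vs-10 patient cohort —
  and the tie/continuity-corrected normal approximation otherwise.
* `chi_squared()` is Pearson's test on group-by-score contingency tables
  (`score_table()` keeps zero-count score levels so the table shape is
  the marker's alphabet); the Yates correction is applied by default on
  2x2 tables, with a flag to disable.
* `read_clinical()` validates the cohort schema: qPCR calls in
  {Low, High}, CYR61 IHC scores in {-, +, ++, +++}, TAZ IHC scores in
  {-, +, ++}, non-negative follow-up, ages consistent with follow-up.
  The packaged fixture `table2_clinical.csv` transcribes the 19-patient
  validation cohort; `summarize_followup()` on it reproduces the
  published group means (4.6 and 9.4 years) and ranges (1–13, 3–17).

## What the synthetic generator emulates — and what it does not

`generate_meta_cohort()` draws each (gene, sample) intensity from a
two-component normal mixture on the log2 scale: unexpressed
N($\mu_u = 4$, $\sigma_u = 0.5$), expressed N($\mu_e = 9$,
$\sigma_e = 1$) — typical microarray magnitudes, with the two components
separated well beyond the barcode cutoff. A gene's baseline
expressed/unexpressed state is decided once (baseline expressed fraction
0.5); planted *exclusive* genes are expressed in every P-BE sample and
nowhere else; planted *DE* effects are added to P-BE samples. Each
dataset receives an additive gene-wise batch shift (SD 0.5 log2 units by
default) — the simplest corruption that makes naive pooling fail and
frozen normalization succeed. The default dataset layout is the
discovery meta-cohort's: one P-BE series of 8 samples and nonP-BE series
of 7 and 18, pooling to 33.

The generator is a pure function of (config, seed): no hidden global RNG
state, identical output on identical input. The frozen reference is
built from the *generating* parameters, not re-estimated — the reference
quantiles are the analytic mixture quantiles (grid-inverted CDF) and the
per-gene unexpressed parameters are the true ones.

What it deliberately does not model: probe-level effects and annotation
ambiguity, intensity-dependent variance, correlated gene modules,
dropout or sample quality gradients, and multiplicative (slope-like)
batch distortions. Passing the planted-recovery and null-calibration
suites therefore demonstrates that the *pipeline logic* is correct and
well calibrated under a clean bimodal model — it does not certify
performance on real arrays, where normalization quality and annotation
drift dominate.

Problem sizes used by the test and acceptance suites — 2000 genes,
8/7/18 samples, 20 planted markers with a +2 log2 effect, 20 replicate
null calibrations — were chosen as the smallest sizes at which the
planted-recovery and calibration properties are statistically
comfortable, and run in seconds.

## Known limitations and open choices

* Gene-level frozen normalization stands in for probe-level frozen
  methods (above): adequate for the funnel's consumption of gene-level
  values, not a re-implementation of the corpus-trained original.
* The DE contrast pools all normalized datasets into a single two-group
  comparison. Per-dataset contrasts merged afterwards would be an
  alternative when dataset-specific effect heterogeneity is suspected;
  pooling was chosen because the frozen mapping removes the additive
  dataset shifts the generator (and the method's rationale) are
  concerned with.
* Duplicate gene rows, when requested, are collapsed by keeping the
  highest mean-intensity row — a deterministic, conventional rule; by
  default duplicates are an error so silent collapses cannot occur.
* The `lods` threshold transfers across cohorts only as far as the
  negative-control calibration does; recalibrate with
  `calibrate_null()` whenever the dataset mix changes.
* Efficiency-corrected qPCR quantification is not implemented; the
  standard curve is fitted and reported so departures from perfect
  doubling are visible, but fold changes use the exponent-2 model.
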
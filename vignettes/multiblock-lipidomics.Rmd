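---
title: "Multi-block PLS analysis of a two-arm plasma lipidomics intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block PLS analysis of a two-arm plasma lipidomics intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidblocks` analyses two-arm, baseline-controlled plasma lipidomics
studies — the motivating setting is a fish-oil (FO) versus high-oleic
sunflower-oil (HOSO) supplementation trial sampled at weeks 0, 3 and 7 —
with a pipeline built around one scientific question: does the intervention
change *how much* lipid each class carries, or does it *remodel the
composition within classes* while class totals stay put? This vignette is
the package's account of the models and the choices behind them.

## The data model

The unit of data is a samples × species matrix of LC-MS peak intensities
with sample metadata (subject, arm, week) and parsed species annotations.
Species are named in sum-composition shorthand — `PC(38:4)` is a
phosphatidylcholine with 38 acyl carbons and 4 double bonds; a `d` prefix
marks a sphingoid base (`SM(d18:1/16:0)`), an `e` suffix an ether linkage
(`PE(38:7e)`), and names joined by `+` or `/` record unresolved alternative
identities, of which the first listed is used as the primary (a
deterministic rule; the alternatives are retained but do not affect block
assignment). Identity is always the peak id: the same shorthand can label
two distinct chromatographic peaks, and does in real tables.

Intensities become concentrations through class-specific spiked internal
standards: `conc = raw / IS_intensity × IS_concentration`, with monoacyl
glycerophospholipids normalized against PC(17:0/0:0), diacyl
glycerophospholipids other than PE against PC(17:0/17:0), diacyl PE against
PE(17:0/17:0), ceramides against Cer(d18:1/17:0), and TG against
TG(17:0/17:0/17:0). The convention leaves the sphingomyelin standard
unstated, so `sm_standard` is an explicit argument (default PC(17:0/17:0))
rather than a silent guess.

## The block structure

Species are organized into eleven blocks in a fixed order: ceramides,
lysoPC, lysoPE, PA, PC, PE, PG, PS, SM, TG (blocks 1–10), and a final
"sums of lipids" block holding the ten class totals together with the PI
species, which are too few to form a block of their own. Two normalizations
make the remodeling question separable:

* **class shares.** Within each class block, every concentration is divided
  by its sample's class total. A share matrix carries only composition;
  a uniform up- or down-regulation of a whole class is invisible here.
* **sums block.** The class totals themselves enter as their own block, so
  any change in total class abundance is visible there and only there.

Both are computed on the concentration scale at each timepoint, and the
baseline adjustment — `log2(value_week / value_week0)` per subject — is
then taken on shares and totals alike. The reverse order (per-species
baseline ratios first, then division by the class total of ratios) is
available behind `ratio_then_share = TRUE`; the default order was chosen
because it makes "composition changed, totals did not" an exact algebraic
decomposition rather than an approximate one.

Each block is mean-centered and divided by the square root of its total sum
of squares, so every block enters the model with identical total variance
(sum of squares 1). This is the simplest reading of putting blocks "on the
same footing": without it the largest classes (PC and TG, with dozens of
species) would dominate every component. A block that turns out constant
gets factor 1 with a warning; an empty class drops its block with a warning
and the model dimension adjusts.

## The multi-block PLS regression

The response is the arm indicator (FO = +1, HOSO = −1, centered). The model
is a sequential NIPALS PLS1 on the concatenated block-scaled matrix; per
component: weight vector $w = X^\top y / \|X^\top y\|$, super score
$t = Xw$, y-loading $q = t^\top y / t^\top t$, X-loadings
$p = X^\top t / t^\top t$, then deflation of $X$ and $y$ by $t$. Deflation
is by the super score, *not* block-wise: the block layer is a readout of
one global model, so super scores and predictions are identical to a
standard PLS on the concatenation — a property the test suite asserts
against an independently written NIPALS implementation to 10⁻⁸ and against
`mixOmics::pls`. Block weights are the block's slice of $w$ renormalized to
unit length, block scores are the deflated block matrix projected on them,
and per-block explained X- and Y-variances are bookkeeping on the same fit.
Weight vectors are signed so their largest-magnitude entry is positive,
which fixes the otherwise arbitrary component signs across runs and
implementations. Only the single-response case is implemented.

## Validation

Cross-validation defaults to leave-one-subject-out (after baseline
adjustment each row *is* a subject); a stratified k-fold option exists. The
essential hygiene rule, which a dedicated test enforces by demonstrating
its violation changes the answer: column centers and block scaling factors
are recomputed on the training fold only, and held-out samples are
projected with the training parameters. The RMSECV curve starts at
component 0 (the null mean predictor, whose RMSECV is the SD of centered
y), and the component count is chosen as the arg-min, ties toward fewer,
with an explicit override argument for a choice made by eye. Plain arg-min
selection overfits by one component a fraction of the time on any noisy
design; the package documents rather than patches this, since the rule is
part of the method.

The contribution of each block is measured on the *validated* scale: each
held-out prediction decomposes into per-block contributions (the block's
share of the super score times the y-loading, accumulated over components),
and 1 − PRESS_b/TSS gives a per-block validated explained Y-variance. This
per-block readout is one defensible interpretation of validating "per
block", and it is the quantity the analysis scripts compare against a
permutation band (y reshuffled, 95th percentile) to call a block
informative or not.

Variable significance follows the chemometric jack-knife: refit the model
on every cross-validation segment, express each segment's regression
coefficients on the original variable scale (dividing by that segment's
block scaling factors, so segments are comparable), and form
$s_j^2 = \frac{K-1}{K}\sum_k (b_j^{(k)} - b_j)^2$ against the full-model
coefficient $b_j$, then $t_j = b_j / s_j$ with $K-1$ degrees of freedom,
two-sided. Degenerate cases are resolved explicitly: zero spread with a
zero coefficient is $p = 1$; zero spread with a nonzero coefficient is
flagged degenerate with $p = 0$. Under permuted responses the flag rate at
$p<0.05$ sits at or slightly below nominal — the jack-knife is mildly
conservative, which is its known character. At two components on data whose
true signal is one-dimensional, the second component inflates coefficient
spread and costs sensitivity relative to a one-component model; this is a
property of the estimator that users should weigh when fixing the component
count.

Sample outliers are advisory only: Hotelling T² on the super scores against
the F-based 95% control limit. Exclusion is never automatic — the pipeline
reruns with an explicit `exclude_subjects` argument, and the exclusion is
logged in the artifacts.

## The univariate screen

Per species, the fold change from baseline is the geometric mean over an
arm's subjects of the per-subject ratio (i.e. `2^mean(log2 ratio)` —
coherent with the log2 analysis; an arithmetic option exists). Arms are
compared by a pooled-variance two-sample Student's t on the baseline-
adjusted log2 ratios (Welch optional), and multiplicity is handled with
Storey q-values: $\hat\pi_0$ estimated on the λ grid 0.05–0.90, smoothed
with a cubic smoothing spline (df = 3) and read off at λ = 0.90, then the
step-up $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. With
$\pi_0 = 1$ this reproduces Benjamini–Hochberg exactly, which the tests
assert against `stats::p.adjust`. A lipid is "increased" when its FO fold
change from baseline exceeds 1 — the rule that reproduces the published
51/23 split of the 74-row example table exactly, whereas classifying by
the FO-versus-HOSO contrast would give 50/24.

## The synthetic study generator

No raw data accompany the motivating study, so the generator is a
first-class module: every downstream stage is tested against data with
known truth. It works on the log2 concentration scale:

$$\log_2 c_{sjw} = \mu_j + b_s + \mathbb{1}[\mathrm{FO}, w>0]\,\delta_j
  + \mathbb{1}[\mathrm{HOSO}, w>0]\,\eta_{jw} + \varepsilon_{sjw}$$

with per-species baselines $\mu_j \sim N(3, 1)$ (log2 µM), subject offsets
$b_s \sim N(0, 0.3^2)$, residual noise $\varepsilon \sim N(0, 0.3^2)$, and
an optional control-arm drift $\eta$ (default SD 0: a stable control arm;
any positive value plants genuine group differences in every species and
is for stress-testing only). Arm sizes default to 16 FO / 17 HOSO, weeks
to 0/3/7, and the 260 species split across the 11 classes roughly as a
plasma lipidome does (PC and TG largest, one PI species) — simulation
defaults, not measurements.

Effects: 28% of each class responds (the published worked example flags
74 of 260 species), with magnitudes $|\delta| \sim N(0.94, 0.60^2)$
truncated at 0.29 and positive with probability 0.68 — these three numbers
are computed from the packaged 74-row table (the distribution of
$|\log_2(\mathrm{FC_{FO}}/\mathrm{FC_{HOSO}})|$ and its sign split), so
"published effect scale" is literal. Being the *detected* set, these
magnitudes are if anything selection-biased upward; simulations using them
are a favorable regime for any detector. The week-7 effect defaults to the
week-3 effect (a decay multiplier is available).

With `remodeling = TRUE` (the default, matching the motivating finding),
each FO sample's post-effect concentrations are rescaled within each class
so the class total equals its pre-effect value: composition changes,
totals do not. Three consequences matter for interpretation. Shares are
invariant to the rescale, so the block analysis behaves identically with
remodeling on or off. Class totals carry no group signal, which is exactly
what the sums-block check detects. And the *concentrations* of
non-responders in affected classes genuinely change (they absorb the
compensation), so ground-truth-based false-discovery accounting for the
univariate screen is only meaningful on `remodeling = FALSE` data — the
recovery simulations use that setting, while the sums-block simulations
use the remodeling default. A responder in a single-species class is
unobservable under remodeling (the rescale cancels it); the generator
warns.

Raw intensities are built by inverting the normalization
(`conc × IS_intensity / IS_concentration`, standards log-normal per sample
with CV 0.2 around 10⁵ counts), so `normalize_intensities()` recovers the
generated concentrations to machine precision — an exact end-to-end test
of the normalization stage. All randomness derives from one seed;
identical designs and seeds give bit-identical datasets.

What the generator does *not* emulate: heteroscedastic intensity noise
(noise lives on the log2 concentration scale, since the analysis operates
on ratios), missing peaks, retention-time drift, correlated noise between
co-eluting species, and multi-component group structure (the planted
signal is one-dimensional; a separate latent-structure simulator,
`simulate_latent_blocks()`, covers rank questions such as component
selection). Passing tests on this generator therefore demonstrate the
statistical machinery, not robustness to every artifact of real LC-MS
data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full study size
(33 subjects × 260 species) with tens of seeds per simulation suite —
50 seeds for recovery, 20 null replicates, 50 permutations for the band,
100 seeds for component selection — sizes at which the Monte-Carlo error
of the reported rates is a small fraction of the margins being asserted.
Oracle agreement is asserted at 10⁻⁸ on random instances up to n = 40,
p = 300. Degenerate inputs are resolved rather than left to chance:
non-positive concentrations at baseline are an error unless an explicit
floor is supplied; zero-variance variables get `NA` correlation loadings,
not 0; constant blocks scale by 1 with a warning; component counts
truncate to the training rank with a warning.

## Known limitations

The per-block validated explained variance is one reading of per-block
validation; other decompositions (e.g. refitting single-block models)
answer slightly different questions. The jack-knife's conservatism and its
sensitivity loss from noise components are inherited from the method. The
Hotelling limit assumes approximately Gaussian scores. And the pipeline
analyses one week at a time against baseline; week 3 and week 7 are
separate fits that share nothing but the data, which mirrors the
motivating analysis but discards longitudinal correlation.
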
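---
title: "Stacked encoding models for naturalistic fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked encoding models for naturalistic fMRI: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackenc)
```

## The model

An encoding model predicts a brain response time series from stimulus
features. Here each grayordinate (a cortical-surface vertex or subcortical
voxel in the CIFTI convention) gets its own model per *feature space* —
e.g. low-level audio (loudness, cochleagram components), high-level audio
(collapsed sound-category tags), low-level visual (brightness, motion
energy), high-level visual (faces, bodies). For feature space $k$ with
design matrix $X_k$ (time $\times$ features, HRF-convolved and z-scored) and
response $y$:

1. **Base models.** Ridge regression per space,
   $\hat\beta_k = (X_k^\top X_k + \lambda I)^{-1} X_k^\top y$, with the
   penalty chosen per grayordinate and space by inner cross-validation.
2. **Stacking.** The per-space held-out predictions $\hat y_k$ are combined
   with convex weights
   $\alpha = \arg\min_{\alpha \ge 0,\ \sum_k \alpha_k = 1}
   \lVert y - \sum_k \alpha_k \hat y_k \rVert^2$,
   solved exactly as a quadratic program on the probability simplex.
3. **Derived metrics.** Held-out stacked $R^2$; unique explained variance by
   clipped subtraction, $R^2_{u,\text{low}} = R^2_{\text{stacked}} -
   \mathrm{clip}(R^2_{\text{high}}, 0, R^2_{\text{stacked}})$; and
   weight-difference preference indices $W_H - W_L$ and $W_V - W_A$, each in
   $[-1, 1]$ with positive values indicating a high-level (or visual)
   preference.

Because the weights live on the simplex, $\alpha_k \in [0, 1]$ and the
preference indices are bounded by construction.

### Cross-validation layout

Time is split into 5 contiguous outer folds (sizes differing by at most one;
remainder to the earliest folds). Contiguity matters: BOLD noise is
autocorrelated, and contiguous held-out blocks are far closer to independent
than randomly interleaved samples. Within each outer training block, a
4-fold inner cross-validation serves two purposes: it selects the ridge
penalty (log-spaced grid $10^{-2} \ldots 10^{5}$, 20 points, configurable)
per grayordinate and space, and its out-of-fold predictions are the data on
which the stacking weights are solved. The stacking stage therefore never
sees its own evaluation data; base models are then refit on the full
training block and the weighted combination is evaluated on the outer
held-out block. Reported weights are the average over outer folds — a convex
combination of simplex points, hence still on the simplex.

### The stacking solver

The simplex-constrained least-squares problem is solved exactly by support
enumeration: for every candidate active set the equality-constrained KKT
system is solved and primal/dual feasibility checked. With at most four
spaces this is at most 15 tiny linear systems per grayordinate. A ridge term
of relative size $10^{-10}$ pulling toward the uniform vector makes the
objective strictly convex; its only practical effect is the tie-break —
when several weight vectors fit equally well (e.g. two spaces with identical
predictions), the uniform one is returned. An exhaustive simplex grid search
(`simplex_grid_search()`, step 0.005) is retained both as a numerical
fallback and as the independent oracle in the test suite.

**Prediction scaling.** By default the base-model predictions are scaled to
unit variance (on the stacking-training segment; the same per-space scale is
applied to outer-test predictions) before the weights are solved. Without
this, stacking weights confound a space's *mixing proportion* with its
*prediction amplitude*: if $y = \sum_k w_k z_k$ with standardized signals
$z_k$, the raw per-space prediction is already $\approx w_k z_k$, and the
unconstrained least-squares solution is $\alpha \equiv 1$ regardless of
$w$. Scaling restores the identification $\alpha \approx w$, which is what
makes weights comparable across grayordinates and groups and what the
synthetic-recovery tests quantify. `scale_predictions = FALSE` gives the
raw-prediction behaviour.

### Significance, pooling, ceilings

Grayordinate significance uses a temporal permutation null: the response
order is fully shuffled, the entire fit repeated, and
$p = (1 + \#\{R^2_{\text{null}} \ge R^2_{\text{obs}}\}) / (1 + n_{\text{perm}})$.
Full shuffling follows the primary analysis convention; it is
anticonservative under autocorrelated noise, so a block scheme
(`scheme = "block"`) is provided. Benjamini–Hochberg FDR is applied across
grayordinates within subject and model (q = 0.05), and per-subject parcel
summaries are unweighted means over significant grayordinates. Noise
ceilings are split-half: subjects are randomly halved (50 splits), parcel
mean time series correlated between half-averages, Spearman–Brown corrected
($r_{sb} = 2r/(1+r)$), and converted to an $R^2$ bound as $r_{sb}^2$ — the
standard reliability-to-variance conversion, made explicit here because the
correlation-vs-variance scale choice is often left implicit.

### Group statistics

Parcel-wise mixed models: metric ~ focal + age + sex + SES + (1 | site),
with focal ∈ {group, SRS, SSS, age, age×group, age×SRS}, group coded
0 = nonASD / 1 = ASD and sex 0 = F / 1 = M, fit with `lmerTest`
(Satterthwaite p values), BH-corrected across parcels within one
(metric, focal) family. A logit link on outcomes that are not probabilities
is under-determined, so two code paths are exposed: the default identity
link, and `link = "logit"`, which first maps the metric affinely into
$(\epsilon, 1-\epsilon)$ ($R^2$-type metrics clipped to $[0,1]$; preference
indices mapped by $(x+1)/2$; $\epsilon = 10^{-3}$) and logit-transforms.
Every result row records which was used. Single-site data refit without the
random term (with a warning); IQ is deliberately not a covariate.

The demographic cascade mirrors standard practice: within-group normality
(Shapiro–Wilk below n = 50, D'Agostino's $K^2$ above — implemented from the
standard $Z_{skew}/Z_{kurt}$ transformations since no installed package
provides it), then Levene's test, routing to Student's t, Welch's t, or
Mann–Whitney U; sex via continuity-corrected $\chi^2$ with Fisher's exact
substituted when any expected cell is below five; BH over the comparison
family.

## The synthetic-data generator

Real naturalistic fMRI of this kind cannot be redistributed, so the
generator produces data with the statistical structure the analysis
assumes, with known ground truth:

- **Features.** Low-level spaces are AR(1) Gaussian processes (lag-1
  autocorrelation = `ar1_coef`, default 0.5) scaled to unit SD — smooth and
  temporally autocorrelated like luminance or loudness. High-level spaces
  are blockwise binary indicators from a two-state Markov chain (stationary
  on-probability `sparsity` = 0.3, mean block length 8 TRs) — sparse and
  event-like, like face-presence or speech tags. Default dimensionalities
  (6/8/2/2 for audio-low/audio-high/visual-low/visual-high) copy the
  analysis feature counts so overfitting behaviour is comparable.
- **Responses.** Each grayordinate's response is a convex mixture (its
  ground-truth simplex weights) of the standardized per-space predictions
  $X_k \beta_k$, plus a per-site offset and AR(1) Gaussian noise scaled so
  signal SD / noise SD equals `snr`. Standardizing inside the generator
  mirrors the pipeline's z-scoring, putting true mixing weights and
  estimated stacking weights on the same scale. The construction implies a
  population stacked $R^2$ of $\mathrm{snr}^2/(1+\mathrm{snr}^2)$, which the
  tests verify by simulation.
- **Cohort.** Two groups across 3 sites (round-robin). In the designated
  "pSTS-like" parcels, simulated-ASD subjects have mass moved from the
  visual-high to the visual-low weight so that the group mean difference in
  $W_H - W_L$ equals `group_pref_shift` exactly; the per-subject shift
  multiplier is $1 + 0.25 z_i$ with $z_i$ standardized within group, and the
  same $z_i$ drives the SRS-like severity score, so severity covaries with
  the deficit. Baseline weights in designated parcels keep the visual-high
  coordinate at 0.30–0.40 so the default shift never leaves the simplex;
  when a larger shift does, weights are clipped at zero and renormalized
  with a warning. Motion is Gamma-distributed FD whose mean decreases with
  age (`motion_age_slope`), reproducing the age–motion confound that
  motivates the FD threshold sweep.

Defaults (`simulation_config()`): 30 subjects per group, 120 grayordinates
in 12 parcels (2 designated), 2000 timepoints at TR 0.8 s, snr 1, AR(1)
0.5, shift 0.3, site SD 0.1. The cohort sizes and snr are the reference
conditions under which the recovery guarantees below are stated; grid sizes
are calibration choices — large enough for stable parcel pooling, small
enough that a full cohort fit is an interactive-scale computation.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: hemodynamic nonlinearity and HRF variability
(responses are generated directly at TR resolution), spatial noise
correlations and cortical geometry, feature-space correlations induced by
real movie structure (simulated spaces are independent), scanner drift, and
any model misspecification of the feature spaces themselves. Recovery
results certify the estimator, not the feature engineering.

## Numerical choices and degenerate inputs

- Ridge is solved in closed form through one SVD per training block and
  vectorized across grayordinates; the penalty is unpenalized-intercept
  (train-fold centering).
- Zero-variance responses are flagged and return `NA` metrics; constant
  feature columns are dropped with a warning naming them.
- $R^2$ uses the evaluated segment's own mean in the total sum of squares
  and may be negative; negative-$R^2$ grayordinates are retained in maps and
  excluded from parcel pooling only via the significance filter.
- Unique-$R^2$ clipping satisfies `unique + clipped component = stacked`
  identically on every branch.
- Fraction-based FD exclusion uses strict inequality ("greater than"), so a
  run exactly at a threshold passes; pass flags are nested across the
  40/60/80% sweep.
- Permutation seeds derive as master seed + grayordinate index, so batched
  or parallel execution reproduces the per-grayordinate streams.
- The preference sign convention is $W_H - W_L$ / $W_V - W_A$ with positive
  = high-level/visual throughout.

## Worked example

```{r, eval = FALSE}
cfg <- simulation_config(n_timepoints = 600, n_grayordinates = 24,
                         n_parcels = 6, seed = 42)
designs <- simulate_design_set(cfg)
cohort <- simulate_cohort(cfg)
bold <- cohort_bold(cohort, designs, 1)
fit <- fit_encoding(designs, bold)
pref <- preference_index(fit, "high_vs_low_visual")
perm <- permutation_test(designs, bold, n_perm = 99, seed = cfg$seed)
atlas <- data.frame(grayordinate = seq_len(cfg$n_grayordinates),
                    parcel = cohort$truth$parcel, hemisphere = "L")
pool_parcels(cbind(pref = pref), perm$significant, atlas)
```

## Problem sizes used in the validation suite

The test suite exercises the full pipeline at reduced scale: weight
recovery at the reference conditions (snr 1, T = 2000, 120 grayordinates;
mean absolute error of $\alpha$ against truth ≤ 0.05), permutation-p
uniformity on 300 white-noise grayordinates at 99 permutations, FDR control
over 500 replicates of 200 tests, and an 8-replicate detection study
(30 subjects per group, T = 400, 48 grayordinates, 8 parcels) verifying
that an injected preference shift of 0.3 is flagged (q < 0.05, correct
sign) in designated parcels with ≥ 90% sensitivity and ≤ 5% false-positive
parcels elsewhere. These sizes are the package's own calibration choices
for a validation suite that a developer can run routinely.

## Known limitations

- Full temporal shuffling is anticonservative under autocorrelated noise;
  use the block scheme when that matters.
- Stacking weights from scaled predictions are mixing proportions, not
  variance shares; a space can carry a sizeable weight while adding little
  unique variance (that is what unique $R^2$ is for).
- The estimator mildly polarizes weight differences at low snr (simplex
  solutions are sparse), so group *differences* in preference indices can
  exceed the generative shift at short T; detection and sign are unaffected,
  which is why the validation focuses on recovery error at reference T and
  on detection calibration.
- CIFTI-2 containers are not read directly; responses travel in the
  documented plain-matrix TSV container with JSON sidecars.
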
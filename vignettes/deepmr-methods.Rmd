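---
title: "Estimating causal effects between genomic marks with deepmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects between genomic marks with deepmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Multi-task sequence-to-function models predict several genomic marks —
transcription factor (TF) binding signals, accessibility, histone
modifications — from DNA sequence at once.  Do such models, by learning to
predict marks jointly, also internalize the *causal* relationships between
them?  `deepmr` implements deep Mendelian randomization: it treats single
in-silico point mutations as instrumental variables and asks how much a
model-predicted change in an *exposure* mark moves a model-predicted
*outcome* mark, per sequence region and globally.

## The procedure

For each exposure/outcome pair the pipeline runs seven steps:

1. sample reference sequence regions;
2. enumerate every single-base substitution of each region
   (`L × 3` mutants for a 4-letter alphabet, `enumerate_mutants()`);
3. predict exposure and outcome for reference and mutants with every
   member of a deep ensemble (`predict_members()`);
4. form per-mutation effect sizes
   `beta = E[task | mutant] − E[task | reference]` with
   covariance-corrected Monte-Carlo standard errors
   `var(beta) = var_m + var_r − 2 cov(m, r)` over the paired member
   predictions (`variant_effects()`) — ignoring the covariance term would
   badly inflate the errors because all predictions share the same member
   weights;
5. keep mutations strongly associated with the exposure,
   `|beta_x / se_x| ≥ z` (`filter_instruments()`; default `z = 2`, the
   conventional two-sigma cutoff — the threshold is a tunable argument
   everywhere it appears);
6. estimate one local causal effect per region (`local_ces()`), by a
   Wald-ratio baseline (mean of `beta_y / beta_x`, interval from their
   SD) and by MR-Egger (intercept-plus-slope regression of outcome on
   exposure effects, weighted by `1 / se_y²`, instruments oriented to
   `beta_x ≥ 0`; the intercept absorbs directional pleiotropy);
7. pool local effects with a DerSimonian–Laird random-effects
   meta-analysis (`random_effects_meta()`), reporting the global mean,
   its standard error σ and the between-region SD τ.

The ensemble interface is a single generic, `predict_members()`: any
object returning per-member predictions for named tasks can be plugged
in, so externally trained models enter at step 3, or pre-computed effect
tables can enter at step 6 via the TSV boundary format.

### MR-Egger details

Instruments are oriented so that exposure effects are nonnegative — the
standard convention without which the pleiotropy intercept is
meaningless.  Exposure standard errors are not propagated into the
weights (the usual no-measurement-error simplification).  Two design
points deserve emphasis:

* **Robust fitting.**  The default fit is a Huber M-estimate (tuning
  constant 1.345, residuals scaled by their weighted MAD) with sandwich
  standard errors, to resist invalid instruments; plain WLS is available
  with `robust = FALSE`.
* **Dispersion floor.**  Standard errors follow the multiplicative
  random-effects convention of published MR-Egger implementations: the
  residual dispersion is floored so the slope SE never undercuts the
  fixed-effect SE implied by the per-instrument outcome standard errors.
  This matters here more than in GWAS practice: all effects are computed
  from the *same* model, so within-region residual scatter can be nearly
  zero even when the instruments' own uncertainty is substantial, and an
  un-floored SE collapses and destroys interval coverage.

### Uncertainty calibration

Deep-ensemble spread understates predictive uncertainty.
`calibrate_ensemble()` fits, per task, an isotonic-regression map from
nominal to empirical predictive CDF values of standardized validation
residuals, and derives a standard-error multiplier
`q_emp(|z|, 0.95) / 1.96` which the mutagenesis step applies to effect
standard errors.  In the built-in study pathway calibration is **on** by
default (`study_protocol(calibrate = TRUE)`): with raw ensemble spread,
local 95% CI coverage is far below nominal, and the instrument filter
passes many weakly supported mutations; calibration restores both.

## The simulation harness

The package ships a generative model of TF binding used as a validation
harness.  Each region is an `L = 100` bp sequence, uniform background;
for each of three TFs (exposure GATA, outcome TAL1 E-box, confounder
SOX2 — synthetic PWMs with field-typical information content built
around the canonical consensus of each factor), a motif instance sampled
from its PWM is implanted at a random position with probability 0.5.

Binding probabilities come from a PWM scan: each window `w` is scored by
the posterior probability that it is a binding site,
`s_w = π L_w / (π L_w + 1 − π)`, with `L_w` the likelihood ratio of the
window under the PWM versus uniform background, combined across windows
with the soft-or `p = 1 − Π(1 − s_w)`.  The per-window prior is
`π = 0.01` — about one expected motif-like window per 100 — chosen so
that implanted instances bind strongly but variably (median `p ≈ 0.87`)
while random sequence keeps low but nonzero background binding.  With a
flat `π = 0.5` the soft-or over ~94 windows would saturate at `p ≈ 1`
for every sequence and the generator would carry no signal at all; the
prior is exposed as `scenario_config(window_prior = )` and alternative
window-score conventions can be substituted through
`binding_probability()`.

Expected read counts (affinities) follow

```
c_e = α p_e + η p_c + τ z + 1
c_o = α γ p_o p_e + ν p_c + τ z + 1
```

with `α ~ N(100, 3)` and the causal coefficient
`γ ~ 0.5 N(10, 0.5) + 0.5 N(1, 0.5)` drawn once per run (two widely
separated clusters of effect strength), and fixed confounder weights
`η = 20`, `ν = 30`, `τ = 25`.  The multiplicative `p_o p_e` term encodes
that outcome binding requires exposure binding.  `z ~ Bernoulli(0.5)` is
a sequence-independent confounder.  Four scenarios toggle the two
confounding pathways (`unconfounded`, `random`, `sequence`, `both`);
motifs and `z` are always generated so that scenarios differing only in
their flags share sequences under the same seed.  Observed counts are
Poisson at the affinity (no negative binomial: the random sequence
process already induces overdispersion across regions) and are
variance-stabilized with the Anscombe transform `y = 2 √(x + 3/8)`.
Affinities are floored at zero so the count model stays defined for the
rare negative draws of `γ` (about 4% of runs).

**Ground truth.**  For a region carrying the exposure implant, every
point mutation within the implant footprint (width × 3) is applied, the
noiseless affinities recomputed and Anscombe transformed, and the true
local causal effect is the no-intercept least-squares slope of outcome
deltas on exposure deltas (no intercept because both deltas vanish at
the reference).  Note the truth is defined in Anscombe space, not `γ`
itself.  Coordinates are 0-based half-open throughout; scanning is
forward-strand by default (`both_strands = TRUE` adds the reverse
complement).

## The model

The built-in predictor is a deliberately small multi-task CNN: three
same-padded convolution layers (15 filters, width 7, ReLU), global max
pooling, two 30-unit hidden layers, and a linear 2-task head trained
with Adam (lr 1e-3, batch 128) under an MSE loss on the
Anscombe-transformed exposure and outcome counts, with early stopping
(patience 10) on a 10% held-out split within at most 100 epochs.
Unstated architecture details were fixed as defaults: ReLU activations,
'same' padding, global max pool, batch size 128, He-normal
initialization with the output bias started at the target means.  The
trainer is implemented in compiled code (im2col + GEMM) and is exact,
seeded and deterministic: members differ only by their seed-derived
initialization and minibatch order.  A deep ensemble of 5 members is
the default (`ensemble_spec()`); the validation studies below use 3 to
keep runtimes reasonable — the ensemble mean changes little, while
uncertainty estimates get noisier, which the calibration step absorbs.

## What the validation studies show

`run_study()` repeats, per round: fresh dataset (fresh `α`, `γ`), fresh
ensemble, saturation mutagenesis of the exposure-implant test regions,
both MR methods, meta-analysis, and ground truth.  Reported metrics are

* **global accuracy** — squared Pearson correlation between estimated
  global effects and the per-round means of true local effects across
  rounds (a regression-R² variant is available via `r_squared(method =
  "ss")`); the bimodal `γ` makes this a test of separating strong from
  weak causal coupling;
* **global coverage** — fraction of rounds whose `mean ± 2τ` interval
  captures the round's true global effect;
* **local coverage** — per-round fraction of regions whose
  `estimate ± 1.96 se` interval captures the region's truth.

The shipped test suite exercises the four scenarios at a reduced scale
chosen to keep the whole suite within a practical runtime: 4000 training
/ 400 test regions per round, 3-member ensembles, at most 40 epochs, 25
mutagenized regions per round, and 4/3/3/4 rounds for the
unconfounded/random/sequence/both scenarios (master seed 1).  The
acceptance script (`scripts/acceptance.R`) instead trains at the full
10000/1000 scale.  All mutagenized regions are exposure-implant regions
of the test set (the truth is only defined there); the cap on their
number is configurable (`study_protocol(max_regions = )`).

One interval caveat surfaced by the studies: DerSimonian–Laird `τ²`
clamps to zero whenever the (calibrated) per-region standard errors
exceed the between-region spread of the local estimates, which happens
readily in weak-effect and confounded rounds.  The `mean ± 2τ` interval
then degenerates to a point, so its coverage of the true global effect
is fragile even when the estimate itself is accurate to a few
hundredths; the `± 2σ` interval remains informative in that regime, and
both are always reported (`ce_interval()`).

What passing these studies does *not* show: the generator draws
i.i.d. background sequence with at most one implanted instance per TF,
has no reverse-strand binding, no base-resolution profiles, no
chromatin context, and its binding probability convention is one
defensible choice among several.  Real enhancer sequences violate all
of these, so transfer of the coverage numbers to real models should not
be assumed — the harness validates the estimation machinery, not any
particular biological model.

## Numerical and degenerate-input conventions

* Variant-effect variances are clamped at zero (floating-point
  cancellation in the covariance correction); clamp counts are recorded.
* Instruments with `se_x = 0` are kept only when `beta_x ≠ 0`.
* Wald baseline drops `beta_x = 0` instruments; a single-instrument
  region reports an `NA` standard error and is excluded from pooling.
* MR-Egger needs ≥ 3 instruments and spread in the oriented exposure
  effects; otherwise the region is skipped and counted.
* Meta-analysis with a single region warns and returns `τ = 0`.
* `τ²` is clamped at zero before `τ = √τ²` is reported.
* Calibration refuses fewer than 50 validation points (warning,
  `NULL` = identity).
* The literal SD (not SD/√k) is the Wald-baseline interval half-width
  basis; `se_of_mean = TRUE` switches to the standard error of the mean.

## Reproducibility

Every stochastic step is seeded: datasets by `scenario_config(seed = )`,
members by seeds derived from `ensemble_spec(seed = )`, study rounds by
`seed_for_round(master_seed, round)`.  Identical seeds give bit-identical
datasets, ensembles and summaries.  The command-line front end
(`inst/cli/deepmr.R`, subcommands `simulate`, `run`, `study`) writes a
JSON manifest next to every output so a run can be traced from its
output directory alone.
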
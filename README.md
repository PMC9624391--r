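# deepmr

Do multi-task sequence-to-function models learn the *causal*
relationships between the genomic marks they predict?  `deepmr`
implements deep Mendelian randomization for asking exactly that: it
combines saturation in-silico mutagenesis over a deep ensemble with
Mendelian randomization (MR) to estimate local (per sequence region) and
global causal effects between a model's output marks — for example,
between the binding signals of two transcription factors (TFs).

It is aimed at computational genomics researchers who have (or can
train) a multi-task predictor of genomic marks and want quantitative,
uncertainty-aware statements like "an increase of one unit in predicted
GATA binding raises predicted TAL1 binding by θ".

## Method

For an exposure mark X, an outcome mark Y and a trained ensemble with
members θ⁽¹⁾…θ⁽ᴺ⁾, every single-base mutation *m* of a reference
sequence *r* yields an instrument with effect sizes

    β̂_ZX = E[X | m] − E[X | r],   E[X | Z] ≈ (1/N) Σᵢ f_X(Z, θ⁽ⁱ⁾)

and covariance-corrected Monte-Carlo variance
`var(β̂) = var_m + var_r − 2 cov(m, r)` over the paired member
predictions.  Mutations strongly associated with the exposure
(|β̂_ZX/se| ≥ z) are the instruments for one MR fit per region:

* **Wald-ratio baseline** — mean of β̂_ZY/β̂_ZX with their SD as the
  interval basis;
* **MR-Egger** — weighted regression of outcome on exposure effects
  with a directional-pleiotropy intercept; robust (Huber) variant by
  default.

Local effects are pooled across regions with a DerSimonian–Laird
random-effects meta-analysis, giving a global causal effect with
standard error σ and between-region SD τ.

The package also ships a PWM-based TF-binding simulator (exposure →
outcome coupling of strength γ, optional sequence and non-sequence
confounders, Poisson counts, Anscombe transform), a ground-truth
causal-effect oracle, a small multi-task CNN ensemble trainer (compiled,
seeded, deterministic), and a study harness reporting accuracy and
coverage of the recovered effects across the four confounding scenarios.
Any external model can be plugged in through the one-generic adapter
`predict_members()` or by supplying effect tables in the documented TSV
format.

## Worked example

```r
library(deepmr)

cfg <- scenario_config("unconfounded", n_train = 4000, n_test = 400,
                       seed = 3947399)
ds  <- generate_dataset(cfg)
ds
#> deepmr_dataset: unconfounded scenario; 4000 train / 400 test regions of 100 bp
#> alpha = 97.72, gamma = 10.221

spec <- ensemble_spec(n_members = 3, max_epochs = 40, seed = 3947399)
ens  <- train_ensemble(ds$train$sequence,
                       as.matrix(ds$train[, c("y_e", "y_o")]), spec)
cal  <- calibrate_ensemble(ens, ds$train$sequence[ens$val_idx],
                           as.matrix(ds$train[ens$val_idx, c("y_e", "y_o")]))

regions <- head(ds$test[!is.na(ds$test$e_start), ], 25)
effects <- mutagenize_regions(ens, regions, cal)
lce     <- local_ces(effects, method = "egger", z_threshold = 2)
random_effects_meta(lce)
#> global CE: 2.3858 (sigma 0.2317, tau 0.7661) over 17 regions

tt <- true_ce_table(ds)
mean(tt$true_ce[tt$id %in% regions$id])
#> [1] 2.8163
```

The global estimate says: in this simulated run the model believes a
unit increase in (Anscombe-transformed) exposure binding raises the
outcome by ≈ 2.4, with substantial region-to-region spread (τ ≈ 0.77);
the generator's true region-averaged effect over the same regions is
≈ 2.8 (17 of the 25 regions kept enough strong instruments for an
MR-Egger fit).  A multi-round,
multi-scenario version of this comparison — accuracy and coverage
tables per MR method — is produced by `run_study()` / `cmd_study()`.

A thin command-line front end is included:

```sh
Rscript inst/cli/deepmr.R simulate --config config.yaml --out out/
Rscript inst/cli/deepmr.R run      --config config.yaml --out out/
Rscript inst/cli/deepmr.R study    --config config.yaml --out out/
```

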
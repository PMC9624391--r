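#' Study protocol
#'
#' Collects everything a causal-recovery round needs beyond the scenario:
#' dataset sizes, ensemble settings, instrument threshold and MR options.
#' Defaults follow the full-scale study protocol (10000 training / 1000
#' test regions, 5-member ensembles, up to 100 epochs); reduced values
#' are used for quick runs.
#'
#' @param n_train,n_test Dataset sizes per round.
#' @param n_members Ensemble members per round.
#' @param max_epochs,patience,lr,batch_size Training settings (see
#'   [ensemble_spec()]).
#' @param z_threshold Instrument-strength cutoff.
#' @param mr_method `"egger"`, `"baseline"` or `"both"`.
#' @param robust Robust MR-Egger?
#' @param max_regions Cap on the number of exposure-implant test regions
#'   mutagenized per round (`Inf` = all).
#' @param calibrate Apply isotonic recalibration of ensemble standard
#'   errors, fitted on the early-stopping validation split?  Default
#'   `TRUE`: deep-ensemble spread understates predictive uncertainty,
#'   and uncalibrated standard errors give badly undercovered local
#'   confidence intervals.
#' @return List of class `study_protocol`.
#' @export
study_protocol <- function(n_train = 10000L, n_test = 1000L,
                           n_members = 5L, max_epochs = 100L,
                           patience = 10L, lr = 1e-3, batch_size = 128L,
                           z_threshold = 2, mr_method = "both",
                           robust = TRUE, max_regions = Inf,
                           calibrate = TRUE) {
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_members = as.integer(n_members),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 batch_size = as.integer(batch_size),
                 z_threshold = z_threshold, mr_method = mr_method,
                 robust = isTRUE(robust), max_regions = max_regions,
                 calibrate = isTRUE(calibrate)),
            class = "study_protocol")
}

#' Deterministic per-round seed
#'
#' @param master Master seed of the study.
#' @param round Round number (1-based).
#' @return Integer seed below 2^31.
#' @export
seed_for_round <- function(master, round) {
  s <- (as.numeric(master) * 48271 + as.numeric(round) * 1299709) %% 2147483647
  as.integer(s) + 1L
}

#' Run one causal-recovery round
#'
#' One round of the simulation study: draw a fresh dataset (fresh `alpha`
#' and `gamma`), train a fresh ensemble, mutagenize the exposure-implant
#' test regions, estimate local causal effects with the configured MR
#' method(s), pool them by random-effects meta-analysis and compute the
#' ground truth for every mutagenized region.
#'
#' @param scenario Scenario name (see [scenario_config()]).
#' @param round_seed Seed for this round.
#' @param protocol A [study_protocol()].
#' @param pwms Named list of `pwm` objects.
#' @return List of class `round_result`: `round_seed`, `scenario`,
#'   `alpha`, `gamma`, `val_r2`, `true_global`, `global` (per-method
#'   data.frame with `mean`, `sigma`, `tau`, `n_regions`), and `regions`
#'   (per region x method: `estimate`, `se`, `truth`).
#' @export
run_round <- function(scenario, round_seed, protocol = study_protocol(),
                      pwms = deepmr_motifs()) {
  cfg <- scenario_config(scenario, n_train = protocol$n_train,
                         n_test = protocol$n_test, seed = round_seed)
  ds <- generate_dataset(cfg, pwms)
  spec <- ensemble_spec(n_members = protocol$n_members,
                        max_epochs = protocol$max_epochs,
                        patience = protocol$patience, lr = protocol$lr,
                        batch_size = protocol$batch_size,
                        seed = round_seed)
  ens <- train_ensemble(ds$train$sequence,
                        as.matrix(ds$train[, c("y_e", "y_o")]), spec)
  val_r2 <- validation_r2(ens, ds$test$sequence,
                          as.matrix(ds$test[, c("y_e", "y_o")]))
  calib <- NULL
  if (protocol$calibrate) {
    vi <- ens$val_idx
    calib <- calibrate_ensemble(ens, ds$train$sequence[vi],
                                as.matrix(ds$train[vi, c("y_e", "y_o")]))
  }

  regions <- ds$test[!is.na(ds$test$e_start), , drop = FALSE]
  if (is.finite(protocol$max_regions) && nrow(regions) > protocol$max_regions)
    regions <- regions[seq_len(protocol$max_regions), , drop = FALSE]
  if (nrow(regions) == 0L) stop("no exposure-implant regions in the test set")

  effects <- mutagenize_regions(ens, regions, calib)
  lce <- local_ces(effects, method = protocol$mr_method,
                   z_threshold = protocol$z_threshold,
                   robust = protocol$robust)

  truth <- vapply(seq_len(nrow(regions)), function(i)
    true_local_ce(regions[i, ], pwms, ds$config)$estimate, numeric(1))
  names(truth) <- regions$id
  lce$truth <- truth[lce$region_id]

  global <- do.call(rbind, lapply(unique(lce$method), function(m) {
    g <- random_effects_meta(lce[lce$method == m, ])
    data.frame(method = m, mean = g$mean, sigma = g$sigma, tau = g$tau,
               n_regions = g$n_regions, stringsAsFactors = FALSE)
  }))
  structure(list(round_seed = round_seed, scenario = scenario,
                 alpha = ds$alpha, gamma = ds$gamma, val_r2 = val_r2,
                 true_global = mean(truth), global = global,
                 regions = lce),
            class = "round_result")
}

#' Global causal-effect accuracy across rounds
#'
#' Coefficient of determination of the estimated global causal effects
#' against the per-round averages of the true local effects (squared
#' Pearson correlation by default).
#'
#' @param estimates,truths Numeric vectors, one entry per round.
#' @param method See [r_squared()].
#' @return Scalar R-squared (`NA` when the truths have no variance).
#' @export
global_accuracy <- function(estimates, truths, method = "pearson") {
  if (length(estimates) < 3L)
    warning("fewer than 3 rounds: accuracy is unreliable")
  r_squared(truths, estimates, method)
}

#' Global +/- 2 tau coverage across rounds
#'
#' @param means,taus,truths Numeric vectors, one entry per round.
#' @return Fraction of rounds whose `mean +/- 2 tau` interval contains
#'   the round's true global causal effect.
#' @export
global_coverage <- function(means, taus, truths) {
  mean(truths >= means - 2 * taus & truths <= means + 2 * taus)
}

#' Local 95% confidence-interval coverage
#'
#' @param estimates,ses,truths Per-region local effects, standard errors
#'   and ground truths.
#' @param multiplier CI half-width in standard errors (1.96 for 95%).
#' @return Fraction of regions with `|estimate - truth| <= multiplier *
#'   se`, over regions with finite positive `se`.
#' @export
local_coverage <- function(estimates, ses, truths, multiplier = 1.96) {
  ok <- is.finite(ses) & ses > 0 & is.finite(estimates) & is.finite(truths)
  mean(abs(estimates[ok] - truths[ok]) <= multiplier * ses[ok])
}

#' Run a multi-round causal-recovery study
#'
#' Repeats [run_round()] with per-round seeds derived from a master seed
#' and summarizes accuracy and coverage per MR method.  Rounds whose
#' model training fails are excluded and counted.
#'
#' @param scenario Scenario name.
#' @param n_rounds Number of simulation rounds.
#' @param protocol A [study_protocol()].
#' @param master_seed Master seed; round `r` uses
#'   [seed_for_round()]`(master_seed, r)`.
#' @param pwms Named list of `pwm` objects.
#' @return List of class `study_result`: `scenario`, `rounds` (list of
#'   `round_result`), `summary` (per-method accuracy / coverage
#'   data.frame), `per_round` (long table) and `n_failed`.
#' @export
run_study <- function(scenario, n_rounds, protocol = study_protocol(),
                      master_seed = 1L, pwms = deepmr_motifs()) {
  rounds <- list()
  n_failed <- 0L
  for (r in seq_len(n_rounds)) {
    res <- tryCatch(
      run_round(scenario, seed_for_round(master_seed, r), protocol, pwms),
      error = function(e) {
        message("round ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) n_failed <- n_failed + 1L else
      rounds[[length(rounds) + 1L]] <- res
  }
  if (length(rounds) == 0L) stop("all rounds failed")
  structure(c(summarize_rounds(rounds, scenario), list(n_failed = n_failed)),
            class = "study_result")
}

summarize_rounds <- function(rounds, scenario) {
  per_round <- do.call(rbind, lapply(seq_along(rounds), function(i) {
    rr <- rounds[[i]]
    g <- rr$global
    g$round <- i
    g$true_global <- rr$true_global
    g$gamma <- rr$gamma
    g$local_coverage <- vapply(g$method, function(m) {
      sub <- rr$regions[rr$regions$method == m, ]
      local_coverage(sub$estimate, sub$se, sub$truth)
    }, numeric(1))
    g
  }))
  summary <- do.call(rbind, lapply(unique(per_round$method), function(m) {
    sub <- per_round[per_round$method == m, ]
    data.frame(scenario = scenario, method = m,
               global_accuracy = if (nrow(sub) >= 3L)
                 global_accuracy(sub$mean, sub$true_global) else NA_real_,
               global_coverage = global_coverage(sub$mean, sub$tau,
                                                 sub$true_global),
               local_coverage = mean(sub$local_coverage),
               n_rounds = nrow(sub), stringsAsFactors = FALSE)
  }))
  list(scenario = scenario, rounds = rounds, summary = summary,
       per_round = per_round)
}

#' @export
print.study_result <- function(x, ...) {
  cat("study:", x$scenario, "scenario,", length(x$rounds), "rounds",
      if (x$n_failed) paste0("(", x$n_failed, " failed)"), "\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
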
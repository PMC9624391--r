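#' Scenario configuration for the TF-binding simulation
#'
#' Bundles every knob of the synthetic binding model: sequence length,
#' affinity coefficients, which confounding pathways are active, dataset
#' sizes and the RNG seed.  The generative model for one `L`-bp region is
#'
#' \deqn{c_e = \alpha p_e + \eta p_c + \tau z + 1}
#' \deqn{c_o = \alpha \gamma p_o p_e + \nu p_c + \tau z + 1}
#'
#' where `p_e`, `p_o`, `p_c` are the soft-or binding probabilities of the
#' exposure, outcome and confounder TFs on the region, and `z ~ Bern(0.5)`
#' is a sequence-independent confounder.  The `eta`/`nu` terms enter only
#' when `confound_sequence = TRUE` and the `tau_conf` term only when
#' `confound_random = TRUE`.  Observed counts are Poisson with these means
#' and are Anscombe transformed before modelling.
#'
#' @param scenario Shorthand for the two confounding flags: one of
#'   `"unconfounded"`, `"random"`, `"sequence"`, `"both"`.  Ignored if the
#'   flags are given explicitly.
#' @param L Sequence length in bp.
#' @param alpha Scale coefficient linking binding probability to expected
#'   counts; `NULL` (default) means draw once per run from `N(100, 3)`.
#' @param gamma Causal coefficient of exposure binding on outcome counts;
#'   `NULL` means draw once per run from the bimodal mixture
#'   `0.5 N(10, 0.5) + 0.5 N(1, 0.5)` (see [sample_gamma()]).
#' @param eta,nu Confounder-TF weights on exposure and outcome counts.
#' @param tau_conf Weight of the sequence-independent binary confounder.
#' @param insertion_prob Per-TF probability that a motif instance is
#'   implanted into a region.
#' @param confound_sequence,confound_random Logical flags enabling the
#'   sequence-dependent and sequence-independent confounding pathways.
#' @param n_train,n_test Number of training / held-out test regions.
#' @param seed Mandatory RNG seed for the run.
#' @param exposure,outcome,confounder Names of the motifs (in the PWM list
#'   passed to [generate_dataset()]) playing each causal role.
#' @param both_strands Scan the reverse complement as well when computing
#'   binding probabilities?  Default `FALSE` (forward strand only).
#' @param window_prior Prior probability that any single window is a
#'   binding site, used in the per-window match score (see
#'   [binding_probability()]).  Default 0.01.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("unconfounded", "random", "sequence", "both"),
                            L = 100L, alpha = NULL, gamma = NULL,
                            eta = 20, nu = 30, tau_conf = 25,
                            insertion_prob = 0.5,
                            confound_sequence = NULL, confound_random = NULL,
                            n_train = 10000L, n_test = 1000L,
                            seed,
                            exposure = "GATA", outcome = "TAL1",
                            confounder = "SOX2",
                            both_strands = FALSE,
                            window_prior = 0.01) {
  scenario <- match.arg(scenario)
  flags <- switch(scenario,
                  unconfounded = c(FALSE, FALSE),
                  random       = c(FALSE, TRUE),
                  sequence     = c(TRUE, FALSE),
                  both         = c(TRUE, TRUE))
  if (is.null(confound_sequence)) confound_sequence <- flags[1]
  if (is.null(confound_random))   confound_random   <- flags[2]
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory in scenario_config()")
  if (insertion_prob < 0 || insertion_prob > 1)
    stop("insertion_prob must lie in [0, 1]")
  for (nm in c("eta", "nu", "tau_conf"))
    if (get(nm) < 0) stop(nm, " must be nonnegative")
  if (!is.null(alpha) && alpha < 0) stop("alpha must be nonnegative")
  if (L < 1) stop("L must be a positive integer")
  if (window_prior <= 0 || window_prior >= 1)
    stop("window_prior must lie in (0, 1)")
  structure(list(L = as.integer(L), alpha = alpha, gamma = gamma,
                 eta = eta, nu = nu, tau_conf = tau_conf,
                 insertion_prob = insertion_prob,
                 confound_sequence = isTRUE(confound_sequence),
                 confound_random = isTRUE(confound_random),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed),
                 exposure = exposure, outcome = outcome,
                 confounder = confounder,
                 both_strands = isTRUE(both_strands),
                 window_prior = window_prior),
            class = "scenario_config")
}

scenario_name <- function(config) {
  if (config$confound_sequence && config$confound_random) "both"
  else if (config$confound_sequence) "sequence"
  else if (config$confound_random) "random"
  else "unconfounded"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw the causal coefficient gamma
#'
#' One draw per simulation run from the equal-proportion mixture
#' `0.5 N(10, 0.5) + 0.5 N(1, 0.5)` (variances, not SDs).  The two widely
#' separated components create two clusters of true causal effects, so
#' that a study over many runs probes the ability to tell strong from
#' weak causal coupling apart.
#'
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_gamma <- function(n = 1L) {
  comp <- sample(c(10, 1), n, replace = TRUE)
  stats::rnorm(n, mean = comp, sd = sqrt(0.5))
}

#' Draw the affinity scale alpha
#'
#' One draw per simulation run from `N(100, 3)` (variance 3).
#'
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_alpha <- function(n = 1L) {
  stats::rnorm(n, mean = 100, sd = sqrt(3))
}

## ---- sequences ----

seq_to_codes <- function(x) {
  if (is.character(x)) {
    codes <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
    if (anyNA(codes)) stop("sequence contains non-ACGT characters")
    codes
  } else as.integer(x)
}

codes_to_seq <- function(codes) paste(DNA_BASES[codes], collapse = "")

#' Sample background sequences with motif implants
#'
#' Background bases are i.i.d. uniform over A/C/G/T.  For each TF
#' independently, with probability `config$insertion_prob` a motif
#' instance sampled column-wise from its PWM replaces a contiguous block
#' at a uniformly chosen valid start.  Implants are placed in the order
#' confounder, exposure, outcome, so a later implant overwrites any
#' earlier overlapping bases; the record keeps the realized start (0-based)
#' and the implanted subsequence of every TF.
#'
#' Implantation is performed for all three TFs regardless of the
#' confounding flags, so datasets that differ only in their scenario flags
#' share identical sequences under the same seed.
#'
#' @param n Number of regions to sample.
#' @param config A [scenario_config()].
#' @param pwms Named list of `pwm` objects covering the configured
#'   exposure, outcome and confounder motifs.
#' @return A data.frame with columns `id`, `sequence`, and per-role
#'   implant columns `e_start`, `e_seq`, `o_start`, `o_seq`, `c_start`,
#'   `c_seq` (`NA` when the motif was not implanted).
#' @export
sample_sequences <- function(n, config, pwms = deepmr_motifs()) {
  roles <- c(c = config$confounder, e = config$exposure, o = config$outcome)
  for (r in roles) {
    if (is.null(pwms[[r]])) stop("PWM '", r, "' not found in pwms")
    if (pwm_width(pwms[[r]]) > config$L)
      stop("motif '", r, "' is wider than L = ", config$L)
  }
  L <- config$L
  seqs <- matrix(sample.int(4L, n * L, replace = TRUE), nrow = n, ncol = L)
  rec <- list()
  for (role in names(roles)) {
    p <- pwms[[roles[[role]]]]
    w <- pwm_width(p)
    ins <- stats::runif(n) < config$insertion_prob
    starts0 <- sample.int(L - w + 1L, n, replace = TRUE) - 1L # 0-based
    inst <- matrix(0L, n, w)
    for (j in seq_len(w))
      inst[, j] <- sample.int(4L, n, replace = TRUE, prob = p[j, ])
    for (i in which(ins))
      seqs[i, (starts0[i] + 1L):(starts0[i] + w)] <- inst[i, ]
    rec[[paste0(role, "_start")]] <- ifelse(ins, starts0, NA_integer_)
    rec[[paste0(role, "_seq")]] <- ifelse(
      ins, apply(inst, 1L, function(r) paste(DNA_BASES[r], collapse = "")),
      NA_character_)
  }
  data.frame(id = sprintf("r%05d", seq_len(n)),
             sequence = apply(seqs, 1L, function(r) paste(DNA_BASES[r], collapse = "")),
             e_start = rec$e_start, e_seq = rec$e_seq,
             o_start = rec$o_start, o_seq = rec$o_seq,
             c_start = rec$c_start, c_seq = rec$c_seq,
             stringsAsFactors = FALSE)
}

## ---- binding probability ----

window_scores <- function(codes, p, background, prior = 0.01) {
  w <- nrow(p)
  L <- length(codes)
  if (L < w) stop("sequence shorter than motif width")
  nw <- L - w + 1L
  logp <- log(pmax(unclass(p), 1e-12))
  logb <- log(background)
  lp <- numeric(nw)
  lb <- numeric(nw)
  for (j in seq_len(w)) {
    b <- codes[j:(j + nw - 1L)]
    lp <- lp + logp[j, b]
    lb <- lb + logb[b]
  }
  # posterior P(site | window) under prior odds prior/(1-prior)
  stats::plogis(lp - lb + log(prior) - log1p(-prior))
}

#' Sequence-level binding probability of a TF
#'
#' Scans the PWM across every window of the sequence, scores each window
#' with the posterior probability that it is a binding site,
#' `s_w = pi L_w / (pi L_w + 1 - pi)` where `L_w = P(w|PWM) / P(w|bg)`
#' is the window likelihood ratio and `pi` (`window_prior`) the prior
#' probability that any given window is a site, and combines the window
#' scores with the soft-or function `p = 1 - prod_w (1 - s_w)` — the
#' probability of the TF binding anywhere on the sequence if windows
#' were independent.
#'
#' @param sequence Character string or integer code vector (1 = A .. 4 = T).
#' @param pwm A `pwm` object.
#' @param background Background base frequencies (length 4, A/C/G/T);
#'   default uniform.
#' @param both_strands Also scan the reverse complement and soft-or over
#'   both strands' windows.
#' @param window_prior Per-window prior site probability `pi` in (0, 1).
#' @return Binding probability in `[0, 1]`; deterministic in its inputs.
#' @export
binding_probability <- function(sequence, pwm, background = rep(0.25, 4),
                                both_strands = FALSE, window_prior = 0.01) {
  codes <- seq_to_codes(sequence)
  s <- window_scores(codes, pwm, background, window_prior)
  if (both_strands) {
    rc <- rev(5L - codes)
    s <- c(s, window_scores(rc, pwm, background, window_prior))
  }
  1 - exp(sum(log1p(-pmin(s, 1))))
}

## vectorized over a codes matrix (n x L); returns length-n vector
binding_probability_matrix <- function(codes, pwm, background = rep(0.25, 4),
                                       both_strands = FALSE,
                                       window_prior = 0.01) {
  w <- nrow(pwm)
  L <- ncol(codes)
  nw <- L - w + 1L
  logp <- log(pmax(unclass(pwm), 1e-12))
  logb <- log(background)
  lprior <- log(window_prior) - log1p(-window_prior)
  one_strand <- function(cm) {
    lp <- matrix(0, nrow(cm), nw)
    lb <- matrix(0, nrow(cm), nw)
    for (j in seq_len(w)) {
      b <- cm[, j:(j + nw - 1L), drop = FALSE]
      lp <- lp + matrix(logp[j, b], nrow(cm), nw)
      lb <- lb + matrix(logb[b], nrow(cm), nw)
    }
    s <- stats::plogis(lp - lb + lprior)
    rowSums(log1p(-s))
  }
  acc <- one_strand(codes)
  if (both_strands)
    acc <- acc + one_strand(t(apply(codes, 1L, function(r) rev(5L - r))))
  1 - exp(acc)
}

## ---- affinities, counts, transform ----

#' Exposure and outcome binding affinities
#'
#' Expected (Poisson-mean) counts for the exposure and outcome TFs:
#' `c_e = alpha p_e + eta p_c + tau z + 1` and
#' `c_o = alpha gamma p_o p_e + nu p_c + tau z + 1`, with the confounder
#' terms zeroed when the corresponding scenario flag is off.  The product
#' `p_o p_e` encodes that without exposure binding there is no outcome
#' binding.  Affinities are floored at zero so the count model stays
#' defined for the rare negative draws of `gamma`.
#'
#' @param p_e,p_o,p_c Binding probabilities in `[0, 1]` (vectorized).
#' @param z Binary sequence-independent confounder (0/1).
#' @param config A [scenario_config()] whose `alpha` (and for the outcome
#'   `gamma`) has been realized.
#' @return Numeric vector of affinities, `>= 1` whenever `gamma >= 0`.
#' @export
exposure_affinity <- function(p_e, p_c, z, config) {
  check_affinity_inputs(p_e, p_c, z, config)
  eta <- if (config$confound_sequence) config$eta else 0
  tau <- if (config$confound_random) config$tau_conf else 0
  pmax(config$alpha * p_e + eta * p_c + tau * z + 1, 0)
}

#' @rdname exposure_affinity
#' @export
outcome_affinity <- function(p_o, p_e, p_c, z, config) {
  check_affinity_inputs(p_e, p_c, z, config)
  if (is.null(config$gamma)) stop("config$gamma has not been realized")
  nu <- if (config$confound_sequence) config$nu else 0
  tau <- if (config$confound_random) config$tau_conf else 0
  pmax(config$alpha * config$gamma * p_o * p_e + nu * p_c + tau * z + 1, 0)
}

check_affinity_inputs <- function(p_e, p_c, z, config) {
  if (is.null(config$alpha)) stop("config$alpha has not been realized")
  if (config$alpha < 0 || config$eta < 0 || config$nu < 0 || config$tau_conf < 0)
    stop("affinity coefficients must be nonnegative")
  if (any(p_e < 0 | p_e > 1) || any(p_c < 0 | p_c > 1))
    stop("binding probabilities must lie in [0, 1]")
  if (any(z != 0 & z != 1)) stop("z must be binary")
  invisible(TRUE)
}

#' Poisson read counts at a given affinity
#'
#' @param affinity Nonnegative Poisson mean(s).
#' @return One integer draw per affinity.
#' @export
sample_counts <- function(affinity) {
  if (any(affinity < 0)) stop("affinity must be nonnegative")
  stats::rpois(length(affinity), affinity)
}

#' Anscombe variance-stabilizing transform
#'
#' `y = 2 sqrt(x + 3/8)`; maps Poisson counts to approximately
#' unit-variance values for moderate and large means.
#'
#' @param x Nonnegative counts (or affinities).
#' @return Transformed values.
#' @export
anscombe <- function(x) {
  if (any(x < 0)) stop("anscombe() requires nonnegative input")
  2 * sqrt(x + 3 / 8)
}

## ---- dataset generation ----

#' Generate a synthetic TF-binding dataset
#'
#' Draws `alpha` and `gamma` once for the run (unless fixed in the
#' config), samples `n_train + n_test` regions with motif implants,
#' computes binding probabilities and affinities, adds Poisson noise and
#' Anscombe-transforms the counts.  Fully reproducible under
#' `config$seed`; datasets generated with the same seed but different
#' confounding flags share sequences, implants and `z`, and differ only
#' in confounder-dependent quantities.
#'
#' @param config A [scenario_config()].
#' @param pwms Named list of `pwm` objects (default: bundled motifs).
#' @return An object of class `deepmr_dataset`: list with `train` and
#'   `test` region data.frames, the realized `alpha` and `gamma`, the
#'   realized `config` and the `pwms` used.  Region columns: `id`,
#'   `sequence`, implant annotations (`e_start`, `e_seq`, ... 0-based),
#'   `p_e`, `p_o`, `p_c`, `z`, `c_e`, `c_o`, `counts_e`, `counts_o`,
#'   `y_e`, `y_o`.
#' @export
generate_dataset <- function(config, pwms = deepmr_motifs()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  alpha <- config$alpha %||% sample_alpha(1L)
  gamma <- config$gamma %||% sample_gamma(1L)
  config$alpha <- alpha
  config$gamma <- gamma

  n <- config$n_train + config$n_test
  regions <- sample_sequences(n, config, pwms)
  z <- stats::rbinom(n, 1L, 0.5)

  codes <- t(vapply(regions$sequence,
                    function(s) seq_to_codes(s), integer(config$L),
                    USE.NAMES = FALSE))
  p_e <- binding_probability_matrix(codes, pwms[[config$exposure]],
                                    both_strands = config$both_strands,
                                    window_prior = config$window_prior)
  p_o <- binding_probability_matrix(codes, pwms[[config$outcome]],
                                    both_strands = config$both_strands,
                                    window_prior = config$window_prior)
  p_c <- binding_probability_matrix(codes, pwms[[config$confounder]],
                                    both_strands = config$both_strands,
                                    window_prior = config$window_prior)

  c_e <- exposure_affinity(p_e, p_c, z, config)
  c_o <- outcome_affinity(p_o, p_e, p_c, z, config)
  counts_e <- sample_counts(c_e)
  counts_o <- sample_counts(c_o)

  regions <- cbind(regions,
                   data.frame(p_e = p_e, p_o = p_o, p_c = p_c, z = z,
                              c_e = c_e, c_o = c_o,
                              counts_e = counts_e, counts_o = counts_o,
                              y_e = anscombe(counts_e), y_o = anscombe(counts_o)))
  idx_train <- seq_len(config$n_train)
  structure(list(train = regions[idx_train, , drop = FALSE],
                 test = regions[-idx_train, , drop = FALSE],
                 alpha = alpha, gamma = gamma,
                 config = config, pwms = pwms),
            class = "deepmr_dataset")
}

#' @export
print.deepmr_dataset <- function(x, ...) {
  cat("deepmr_dataset:", scenario_name(x$config), "scenario;",
      nrow(x$train), "train /", nrow(x$test), "test regions of",
      x$config$L, "bp\n")
  cat(sprintf("alpha = %.2f, gamma = %.3f\n", x$alpha, x$gamma))
  invisible(x)
}

## ---- ground-truth causal effect ----

#' True local causal effect of a simulated region
#'
#' For a region carrying an exposure-motif implant, every point mutation
#' inside the implant footprint (motif width x 3 substitutions) is
#' applied to the sequence, the noiseless affinities are recomputed under
#' the region's confounder state, and both are Anscombe transformed.  The
#' true causal effect is the slope of the no-intercept least-squares
#' regression of the outcome deltas on the exposure deltas (both deltas
#' are exactly zero at the unmutated reference, hence no intercept).
#'
#' @param region One region (single-row data.frame or list) with fields
#'   `sequence`, `e_start` and `z`.
#' @param pwms Named list of `pwm` objects.
#' @param config Realized [scenario_config()] (with `alpha` and `gamma`).
#' @return List with `id`, `estimate` (Anscombe-space slope) and
#'   `n_instruments` (= exposure motif width x 3).
#' @export
true_local_ce <- function(region, pwms, config) {
  e_start <- region$e_start
  if (is.null(e_start) || is.na(e_start))
    stop("true causal effect is defined only for regions with an exposure implant")
  codes <- seq_to_codes(region$sequence)
  w <- pwm_width(pwms[[config$exposure]])
  z <- region$z

  affin <- function(cd) {
    pe <- binding_probability(cd, pwms[[config$exposure]],
                              both_strands = config$both_strands,
                              window_prior = config$window_prior)
    po <- binding_probability(cd, pwms[[config$outcome]],
                              both_strands = config$both_strands,
                              window_prior = config$window_prior)
    pc <- binding_probability(cd, pwms[[config$confounder]],
                              both_strands = config$both_strands,
                              window_prior = config$window_prior)
    c(exposure_affinity(pe, pc, z, config),
      outcome_affinity(po, pe, pc, z, config))
  }
  ref <- anscombe(affin(codes))
  dx <- dy <- numeric(0)
  for (pos in (e_start + 1L):(e_start + w)) {       # 1-based indices
    for (alt in setdiff(1:4, codes[pos])) {
      mut <- codes
      mut[pos] <- alt
      ya <- anscombe(affin(mut))
      dx <- c(dx, ya[1] - ref[1])
      dy <- c(dy, ya[2] - ref[2])
    }
  }
  sxx <- sum(dx^2)
  if (sxx == 0)
    stop("degenerate region: no mutation changes the exposure affinity")
  list(id = region$id, estimate = sum(dx * dy) / sxx, n_instruments = 3L * w)
}

#' Table of true local causal effects for a dataset
#'
#' @param dataset A `deepmr_dataset`.
#' @param which `"test"` (default) or `"train"`.
#' @return data.frame with `id`, `true_ce`, `n_instruments` for every
#'   region carrying an exposure implant.
#' @export
true_ce_table <- function(dataset, which = c("test", "train")) {
  which <- match.arg(which)
  regions <- dataset[[which]]
  regions <- regions[!is.na(regions$e_start), , drop = FALSE]
  out <- lapply(seq_len(nrow(regions)), function(i)
    true_local_ce(regions[i, ], dataset$pwms, dataset$config))
  data.frame(id = vapply(out, `[[`, character(1), "id"),
             true_ce = vapply(out, `[[`, numeric(1), "estimate"),
             n_instruments = vapply(out, `[[`, integer(1), "n_instruments"),
             stringsAsFactors = FALSE)
}
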
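# Independent oracle implementations used to pin the main code paths.
# These deliberately use naive, literal formulations (explicit loops,
# closed forms) so that agreement with the package is informative.

# window-by-window soft-or, products only (no logs)
oracle_binding_probability <- function(sequence, p, prior = 0.01) {
  bases <- strsplit(sequence, "")[[1]]
  codes <- match(bases, c("A", "C", "G", "T"))
  w <- nrow(p)
  nw <- length(codes) - w + 1
  one_minus <- 1
  for (st in seq_len(nw)) {
    lik_pwm <- 1
    for (j in seq_len(w)) lik_pwm <- lik_pwm * p[j, codes[st + j - 1]]
    lik_bg <- 0.25^w
    s <- prior * lik_pwm / (prior * lik_pwm + (1 - prior) * lik_bg)
    one_minus <- one_minus * (1 - s)
  }
  as.numeric(1 - one_minus)
}

# brute-force true causal effect: explicit loop over all exposure-motif
# point mutations, closed-form no-intercept OLS slope
oracle_true_ce <- function(region, pwms, config) {
  stopifnot(!is.na(region$e_start))
  bases <- strsplit(region$sequence, "")[[1]]
  alphabet <- c("A", "C", "G", "T")
  w <- nrow(pwms[[config$exposure]])
  eta <- if (config$confound_sequence) config$eta else 0
  nu <- if (config$confound_sequence) config$nu else 0
  tau <- if (config$confound_random) config$tau_conf else 0
  aff <- function(b) {
    s <- paste(b, collapse = "")
    pe <- oracle_binding_probability(s, pwms[[config$exposure]],
                                     config$window_prior)
    po <- oracle_binding_probability(s, pwms[[config$outcome]],
                                     config$window_prior)
    pc <- oracle_binding_probability(s, pwms[[config$confounder]],
                                     config$window_prior)
    ce <- config$alpha * pe + eta * pc + tau * region$z + 1
    co <- config$alpha * config$gamma * po * pe + nu * pc + tau * region$z + 1
    c(max(ce, 0), max(co, 0))
  }
  ref <- 2 * sqrt(aff(bases) + 0.375)
  dx <- dy <- c()
  for (pos in (region$e_start + 1):(region$e_start + w)) {
    for (alt in setdiff(alphabet, bases[pos])) {
      mb <- bases
      mb[pos] <- alt
      y <- 2 * sqrt(aff(mb) + 0.375)
      dx <- c(dx, y[1] - ref[1])
      dy <- c(dy, y[2] - ref[2])
    }
  }
  sum(dx * dy) / sum(dx * dx)
}

# classical DerSimonian-Laird pooling, written straight from the formulas
oracle_dl_meta <- function(y, se) {
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (length(y) - 1)) / cc)
  ws <- 1 / (se^2 + tau2)
  list(mean = sum(ws * y) / sum(ws), sigma = sqrt(1 / sum(ws)),
       tau = sqrt(tau2))
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (sum(x * y) - n * mean(x) * mean(y)) /
    (sum(x^2) - n * mean(x)^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# mock multi-task predictor implementing the predict_members() contract
mock_predictor <- function(fn) {
  structure(list(fn = fn), class = "mock_predictor")
}
predict_members.mock_predictor <- function(object, sequences, ...) {
  object$fn(sequences)
}
registerS3method("predict_members", "mock_predictor",
                 predict_members.mock_predictor,
                 envir = asNamespace("deepmr"))

toy_pwm <- function(name = "toy", w = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(w * 4, 1), w, 4)
  pwm(name, m / rowSums(m))
}
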
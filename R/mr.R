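#' Wald-ratio baseline causal effect for one region
#'
#' Each instrument contributes the Wald ratio `beta_y / beta_x`
#' (instrument-to-outcome over instrument-to-exposure effect).  The local
#' causal effect is the mean of the ratios and its interval basis is
#' their sample standard deviation (literal SD, not SD/sqrt(k); set
#' `se_of_mean = TRUE` for the latter).  Instruments with `beta_x = 0`
#' are dropped.
#'
#' @param instruments Filtered variant-effect data.frame with columns
#'   `beta_x`, `beta_y`.
#' @param se_of_mean Divide the SD by `sqrt(k)`?  Default `FALSE`.
#' @return List of class `local_ce` with `method = "baseline"`,
#'   `estimate`, `se`, `n_instruments`, `n_dropped`.
#' @export
wald_baseline <- function(instruments, se_of_mean = FALSE) {
  usable <- instruments$beta_x != 0
  n_dropped <- sum(!usable)
  bx <- instruments$beta_x[usable]
  by <- instruments$beta_y[usable]
  if (length(bx) == 0L)
    stop("no instruments with nonzero exposure effect")
  r <- by / bx
  se <- if (length(r) >= 2L) stats::sd(r) else NA_real_
  if (isTRUE(se_of_mean) && is.finite(se)) se <- se / sqrt(length(r))
  structure(list(method = "baseline", estimate = mean(r), se = se,
                 n_instruments = length(r), n_dropped = n_dropped,
                 intercept = NA_real_, intercept_se = NA_real_),
            class = "local_ce")
}

#' MR-Egger causal effect for one region
#'
#' Regresses outcome effects on exposure effects with an intercept (the
#' directional-pleiotropy term), weighting by `1 / se_y^2`, after
#' orienting every instrument so that `beta_x >= 0` (the standard
#' MR-Egger convention; exposure standard errors are not propagated into
#' the weights, the usual no-measurement-error simplification).  The
#' slope is the causal-effect estimate.
#'
#' By default the fit is a robust M-estimate: iteratively reweighted
#' least squares with a Huber psi (tuning constant 1.345, residuals
#' scaled by their weighted MAD) and heteroskedasticity-robust sandwich
#' standard errors, guarding against invalid instruments.  `robust =
#' FALSE` gives the plain weighted-least-squares MR-Egger.  Either way
#' the standard errors follow the multiplicative random-effects
#' convention: the dispersion is floored so that the slope SE never
#' undercuts the fixed-effect SE implied by the per-instrument outcome
#' standard errors.
#'
#' @param instruments Filtered variant-effect data.frame with columns
#'   `beta_x`, `beta_y`, `se_y`.
#' @param robust Use the Huber-robust fit?  Default `TRUE`.
#' @param min_instruments Minimum number of instruments (>= 3).
#' @return List of class `local_ce` with `method = "egger"`, `estimate`
#'   (slope), `se`, `intercept`, `intercept_se`, `n_instruments`.
#' @export
mr_egger <- function(instruments, robust = TRUE, min_instruments = 3L) {
  k <- nrow(instruments)
  if (k < max(3L, min_instruments))
    stop("MR-Egger needs at least ", max(3L, min_instruments), " instruments")
  flip <- sign(instruments$beta_x)
  flip[flip == 0] <- 1
  bx <- flip * instruments$beta_x
  by <- flip * instruments$beta_y
  sey <- instruments$se_y
  if (stats::sd(bx) == 0)
    stop("singular fit: no spread in exposure effects after orientation")
  if (any(sey <= 0)) {
    pos <- sey[sey > 0]
    sey[sey <= 0] <- if (length(pos)) min(pos) else 1
  }
  w <- 1 / sey^2

  X <- cbind(1, bx)
  fit <- wls_fit(X, by, w)
  u <- rep(1, k)
  if (robust) {
    huber_k <- 1.345
    for (iter in seq_len(50L)) {
      res <- by - X %*% fit$coef
      t_i <- res * sqrt(w)
      s <- stats::mad(t_i, center = 0)
      if (s <= 0) break # (near-)exact fit: WLS solution stands
      u <- pmin(1, huber_k / pmax(abs(t_i / s), 1e-300))
      new <- wls_fit(X, by, w * u)
      if (max(abs(new$coef - fit$coef)) < 1e-10 * (1 + max(abs(fit$coef)))) {
        fit <- new
        break
      }
      fit <- new
    }
    vs <- sandwich_vcov(X, as.vector(by - X %*% fit$coef), w * u)
    # floor at the fixed-effect variance implied by the instrument SEs
    vf <- solve(crossprod(X * (w * u), X))
    fit$vcov <- diag(pmax(diag(vs), diag(vf)))
  }
  se <- sqrt(diag(fit$vcov))
  structure(list(method = "egger",
                 estimate = fit$coef[2], se = se[2],
                 intercept = fit$coef[1], intercept_se = se[1],
                 n_instruments = k, n_dropped = 0L),
            class = "local_ce")
}

wls_fit <- function(X, y, w) {
  A <- crossprod(X * w, X)
  coef <- solve(A, crossprod(X * w, y))
  res <- as.vector(y - X %*% coef)
  df <- nrow(X) - ncol(X)
  # multiplicative random-effects dispersion, floored at 1 so the slope SE
  # can never undercut what the instruments' own standard errors imply
  sigma2 <- if (df > 0) max(1, sum(w * res^2) / df) else NA_real_
  list(coef = as.vector(coef), vcov = sigma2 * solve(A))
}

sandwich_vcov <- function(X, res, w) {
  A <- crossprod(X * w, X)
  Ainv <- solve(A)
  score <- X * (w * res)
  Ainv %*% crossprod(score) %*% Ainv
}

#' @export
print.local_ce <- function(x, ...) {
  cat(sprintf("local CE [%s]: %.4f (se %.4f), %d instruments\n",
              x$method, x$estimate, x$se, x$n_instruments))
  if (x$method == "egger")
    cat(sprintf("  egger intercept: %.4f (se %.4f)\n",
                x$intercept, x$intercept_se))
  invisible(x)
}

#' Per-region causal effects from a variant-effect table
#'
#' Filters instruments per region and fits the requested MR method(s).
#' Regions with too few surviving instruments for a method (3 for
#' MR-Egger, 1 for the baseline), or with a singular MR-Egger design,
#' are skipped; the number skipped is recorded in the `skipped`
#' attribute.
#'
#' @param effects Variant-effect data.frame covering one or more regions.
#' @param method `"egger"`, `"baseline"` or `"both"`.
#' @param z_threshold Instrument-strength cutoff (see
#'   [filter_instruments()]).
#' @param robust Robust MR-Egger?  See [mr_egger()].
#' @return data.frame with one row per region x method: `region_id`,
#'   `method`, `estimate`, `se`, `n_instruments`, `intercept`,
#'   `intercept_se`.
#' @export
local_ces <- function(effects, method = c("egger", "baseline", "both"),
                      z_threshold = 2, robust = TRUE) {
  method <- match.arg(method)
  methods <- if (method == "both") c("egger", "baseline") else method
  rows <- list()
  skipped <- 0L
  for (rid in unique(effects$region_id)) {
    inst <- filter_instruments(effects[effects$region_id == rid, ],
                               z_threshold)
    for (m in methods) {
      fit <- tryCatch(
        if (m == "egger") mr_egger(inst, robust = robust)
        else wald_baseline(inst),
        error = function(e) NULL)
      if (is.null(fit)) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = rid, method = m,
                   estimate = fit$estimate, se = fit$se,
                   n_instruments = fit$n_instruments,
                   intercept = fit$intercept,
                   intercept_se = fit$intercept_se,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(), method = character(),
               estimate = numeric(), se = numeric(),
               n_instruments = integer(), intercept = numeric(),
               intercept_se = numeric())
  attr(out, "skipped") <- skipped
  out
}
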
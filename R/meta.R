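#' Random-effects meta-analysis of per-region causal effects
#'
#' Pools local causal effects across sequence regions under the classical
#' random-effects model: each region's true effect is drawn from a global
#' Gaussian whose mean is the global causal effect and whose SD `tau`
#' captures between-region heterogeneity; each local estimate observes
#' its region's effect with known variance `se^2`.  Estimation is
#' DerSimonian-Laird (between-study variance from the Q statistic,
#' clamped at zero; inverse-variance weights `1 / (se^2 + tau^2)`),
#' delegated to [metafor::rma.uni()]; `method = "REML"` is available.
#'
#' @param estimates Numeric vector of local causal effects (or a
#'   data.frame from [local_ces()] restricted to one method, in which
#'   case `ses` is taken from it).
#' @param ses Standard errors of the local effects.
#' @param method `"DL"` (default) or `"REML"`.
#' @param knha Apply the Hartung-Knapp adjustment?  Default `FALSE`.
#' @return List of class `global_ce`: `mean` (global effect), `sigma`
#'   (standard error of the mean), `tau` (between-region SD),
#'   `n_regions`, `weights`.
#' @export
random_effects_meta <- function(estimates, ses = NULL, method = "DL",
                                knha = FALSE) {
  if (is.data.frame(estimates)) {
    if (length(unique(estimates$method)) > 1L)
      stop("pass local CEs from a single MR method")
    ses <- estimates$se
    estimates <- estimates$estimate
  }
  ok <- is.finite(estimates) & is.finite(ses) & ses > 0
  estimates <- estimates[ok]
  ses <- ses[ok]
  k <- length(estimates)
  if (k == 0L) stop("no usable local causal effects")
  if (k == 1L) {
    warning("single region: degenerate meta-analysis (tau = 0)")
    return(structure(list(mean = estimates, sigma = ses, tau = 0,
                          n_regions = 1L, weights = 1),
                     class = "global_ce"))
  }
  fit <- metafor::rma.uni(yi = estimates, sei = ses, method = method,
                          test = if (knha) "knha" else "z")
  tau2 <- max(fit$tau2, 0)
  w <- 1 / (ses^2 + tau2)
  structure(list(mean = as.numeric(fit$b), sigma = as.numeric(fit$se),
                 tau = sqrt(tau2), n_regions = k, weights = w / sum(w)),
            class = "global_ce")
}

#' @export
print.global_ce <- function(x, ...) {
  cat(sprintf("global CE: %.4f (sigma %.4f, tau %.4f) over %d regions\n",
              x$mean, x$sigma, x$tau, x$n_regions))
  invisible(x)
}

#' Interval bounds of a global causal effect
#'
#' Reports both interval flavours used to summarize a global effect:
#' `mean +/- k sigma` (uncertainty of the mean) and `mean +/- k tau`
#' (spread of region-level effects).
#'
#' @param global_ce A `global_ce` object.
#' @param k Half-width multiplier (default 2).
#' @return data.frame with rows `sigma` and `tau` and columns `lower`,
#'   `upper`.
#' @export
ce_interval <- function(global_ce, k = 2) {
  data.frame(type = c("sigma", "tau"),
             lower = global_ce$mean - k * c(global_ce$sigma, global_ce$tau),
             upper = global_ce$mean + k * c(global_ce$sigma, global_ce$tau))
}
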
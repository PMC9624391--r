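#' Deep ensemble specification
#'
#' Architecture and optimization settings for the multi-task CNN used in
#' the simulation study: 3 same-padded convolutional layers (ReLU), a
#' global max pool, and two hidden layers feeding a 2-task linear output
#' (exposure and outcome, both in Anscombe-transformed count space).
#' Members of the ensemble share the architecture and training data and
#' differ only by their random seed.
#'
#' @param n_members Number of ensemble members (>= 2 for uncertainty
#'   estimates; default 5).
#' @param filters Convolution filters per layer.
#' @param filter_width Width of every convolution filter (odd).
#' @param hidden Widths of the two fully connected hidden layers.
#' @param max_epochs Maximum training epochs per member.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction Fraction of the training data held out for early
#'   stopping.
#' @param seed Base seed; member `i` trains with a seed derived from it.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_members = 5L, filters = 15L, filter_width = 7L,
                          hidden = c(30L, 30L), max_epochs = 100L,
                          lr = 1e-3, batch_size = 128L, patience = 10L,
                          val_fraction = 0.1, seed = 1L) {
  stopifnot(n_members >= 1, filters >= 1, filter_width %% 2 == 1,
            length(hidden) == 2, max_epochs >= 1, lr > 0,
            batch_size >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(n_members = as.integer(n_members),
                 filters = as.integer(filters),
                 filter_width = as.integer(filter_width),
                 h1 = as.integer(hidden[1]), h2 = as.integer(hidden[2]),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "ensemble_spec")
}

member_seed <- function(base, i) {
  as.integer((as.numeric(base) * 48271 + i * 7919) %% 2147483647)
}

#' Encode DNA sequences as integer base codes
#'
#' @param sequences Character vector of equal-length ACGT sequences, or an
#'   integer code matrix (passed through).
#' @return Integer matrix, one row per sequence, values 1 (A) to 4 (T).
#' @export
encode_sequences <- function(sequences) {
  if (is.matrix(sequences)) return(matrix(as.integer(sequences),
                                          nrow(sequences), ncol(sequences)))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("all sequences must have equal length")
  codes <- match(unlist(strsplit(toupper(sequences), "", fixed = TRUE)),
                 DNA_BASES)
  if (anyNA(codes)) stop("sequences contain non-ACGT characters")
  matrix(codes, nrow = length(sequences), ncol = lens[1], byrow = TRUE)
}

#' Train a deep ensemble of multi-task CNNs
#'
#' Trains `spec$n_members` networks from distinct random initializations
#' on the same data, with per-member Adam optimization, MSE loss over
#' both tasks and early stopping on a shared held-out split.  Training is
#' fully seeded: repeating a call reproduces the ensemble bit for bit,
#' and two members given identical seeds produce identical predictions.
#'
#' @param sequences Character vector (or code matrix) of training
#'   sequences.
#' @param targets Numeric matrix with one row per sequence and two
#'   columns: Anscombe-transformed exposure and outcome counts.
#' @param spec An [ensemble_spec()].
#' @return Object of class `deepmr_ensemble`: member weight sets plus
#'   training histories and the spec.
#' @export
train_ensemble <- function(sequences, targets, spec = ensemble_spec()) {
  X <- encode_sequences(sequences)
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(X) || ncol(targets) != 2L)
    stop("targets must be an n x 2 matrix aligned with sequences")
  n <- nrow(X)
  set.seed(spec$seed)
  n_val <- max(1L, round(spec$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  hyper <- list(filters = spec$filters, filter_width = spec$filter_width,
                h1 = spec$h1, h2 = spec$h2, lr = spec$lr,
                batch_size = spec$batch_size, max_epochs = spec$max_epochs,
                patience = spec$patience)
  members <- lapply(seq_len(spec$n_members), function(i) {
    fit <- cnn_train_cpp(X[-val_idx, , drop = FALSE],
                         targets[-val_idx, , drop = FALSE],
                         X[val_idx, , drop = FALSE],
                         targets[val_idx, , drop = FALSE],
                         hyper, member_seed(spec$seed, i))
    fit$seed <- member_seed(spec$seed, i)
    fit
  })
  structure(list(members = members, spec = spec, L = ncol(X),
                 val_idx = val_idx),
            class = "deepmr_ensemble")
}

#' @export
print.deepmr_ensemble <- function(x, ...) {
  cat("deepmr_ensemble:", length(x$members), "members, input length",
      x$L, "bp\n")
  v <- vapply(x$members, `[[`, numeric(1), "best_val_mse")
  e <- vapply(x$members, `[[`, numeric(1), "best_epoch")
  cat(sprintf("best validation MSE %.4f-%.4f (best epochs %d-%d)\n",
              min(v), max(v), min(e), max(e)))
  invisible(x)
}

#' Per-member predictions for named tasks
#'
#' Generic adapter contract between any multi-task ensemble and the
#' mutagenesis machinery: given sequences, return each member's
#' prediction for the exposure and outcome tasks.  Any model object
#' implementing a method for this generic (for example a wrapper around
#' an externally trained ensemble) can be used wherever a
#' `deepmr_ensemble` is accepted.
#'
#' @param object A fitted ensemble-like object.
#' @param sequences Character vector or integer code matrix.
#' @param ... Passed to methods.
#' @return List with elements `exposure` and `outcome`, each an
#'   `n x n_members` matrix of member predictions.
#' @export
predict_members <- function(object, sequences, ...) {
  UseMethod("predict_members")
}

#' @export
predict_members.deepmr_ensemble <- function(object, sequences, ...) {
  X <- encode_sequences(sequences)
  if (ncol(X) != object$L)
    stop("sequence length ", ncol(X), " does not match the trained length ",
         object$L)
  preds <- lapply(object$members, function(m) cnn_forward_cpp(m$weights, X))
  list(exposure = vapply(preds, function(p) p[, 1], numeric(nrow(X))) |>
         matrix(nrow = nrow(X)),
       outcome = vapply(preds, function(p) p[, 2], numeric(nrow(X))) |>
         matrix(nrow = nrow(X)))
}

#' Ensemble predictive distribution
#'
#' Ensemble mean (the Monte-Carlo posterior expectation) and population
#' variance across members, per task, retaining the member-level
#' predictions needed downstream for covariance-corrected variant-effect
#' standard errors.
#'
#' @param object Any object with a [predict_members()] method.
#' @param sequences Character vector or integer code matrix.
#' @return List of class `predictive_distribution` with `member`
#'   (list of `n x N` matrices), `mean` and `var` (`n x 2` matrices with
#'   columns exposure, outcome), and `n_members`.
#' @export
predict_ensemble <- function(object, sequences) {
  mem <- predict_members(object, sequences)
  nmem <- ncol(mem$exposure)
  mn <- cbind(exposure = rowMeans(mem$exposure),
              outcome = rowMeans(mem$outcome))
  pop_var <- function(m) rowMeans(m^2) - rowMeans(m)^2
  vr <- cbind(exposure = pmax(pop_var(mem$exposure), 0),
              outcome = pmax(pop_var(mem$outcome), 0))
  structure(list(member = mem, mean = mn, var = vr, n_members = nmem),
            class = "predictive_distribution")
}

#' Validation R-squared of an ensemble
#'
#' @param object Any object with a [predict_members()] method.
#' @param sequences Held-out sequences.
#' @param targets Held-out `n x 2` target matrix.
#' @param method `"pearson"` (squared Pearson correlation, default) or
#'   `"ss"` (`1 - SS_res / SS_tot`).
#' @return Named numeric vector with elements `exposure` and `outcome`.
#' @export
validation_r2 <- function(object, sequences, targets, method = "pearson") {
  pred <- predict_ensemble(object, sequences)$mean
  targets <- as.matrix(targets)
  c(exposure = r_squared(targets[, 1], pred[, 1], method),
    outcome = r_squared(targets[, 2], pred[, 2], method))
}

#' Coefficient of determination
#'
#' @param truth,estimate Numeric vectors.
#' @param method `"pearson"` for squared Pearson correlation (default) or
#'   `"ss"` for `1 - SS_res / SS_tot`.
#' @return Scalar R-squared; `NA` if the truth has zero variance.
#' @export
r_squared <- function(truth, estimate, method = c("pearson", "ss")) {
  method <- match.arg(method)
  if (stats::var(truth) == 0) return(NA_real_)
  if (method == "pearson") stats::cor(truth, estimate)^2
  else 1 - sum((truth - estimate)^2) / sum((truth - mean(truth))^2)
}

## ---- calibration ----

#' Quantile recalibration of ensemble uncertainty
#'
#' Deep-ensemble spread tends to understate predictive uncertainty.
#' This fits, per task, a monotone (isotonic-regression) map from nominal
#' to empirical predictive CDF values of the standardized validation
#' residuals `z = (y - mean) / sd`, plus a standard-error multiplier
#' `q_emp(|z|, 0.95) / qnorm(0.975)` so that recalibrated 95% intervals
#' achieve nominal empirical coverage.  The multiplier is what the
#' mutagenesis step applies to variant-effect standard errors.
#'
#' @param object Any object with a [predict_members()] method.
#' @param sequences Validation sequences.
#' @param targets Validation `n x 2` target matrix.
#' @return Object of class `deepmr_calibration` (per-task `multiplier`
#'   and monotone `map` function), or `NULL` with a warning when fewer
#'   than 50 validation points are supplied.
#' @export
calibrate_ensemble <- function(object, sequences, targets) {
  targets <- as.matrix(targets)
  if (nrow(targets) < 50L) {
    warning("fewer than 50 validation points; refusing to calibrate")
    return(NULL)
  }
  pred <- predict_ensemble(object, sequences)
  fit_task <- function(col) {
    sd <- pmax(sqrt(pred$var[, col]), 1e-8)
    z <- (targets[, col] - pred$mean[, col]) / sd
    p <- sort(stats::pnorm(z))
    emp <- seq_along(p) / length(p)
    iso <- stats::isoreg(p, emp)
    map <- stats::approxfun(c(0, iso$x, 1), c(0, iso$yf, 1),
                            rule = 2, ties = max)
    mult <- as.numeric(stats::quantile(abs(z), 0.95) / stats::qnorm(0.975))
    list(multiplier = mult, map = map, n = length(z))
  }
  structure(list(exposure = fit_task(1L), outcome = fit_task(2L)),
            class = "deepmr_calibration")
}

#' Apply a calibration map to standard errors
#'
#' @param calibration A `deepmr_calibration` or `NULL` (identity).
#' @param se Numeric vector of standard errors.
#' @param task `"exposure"` or `"outcome"`.
#' @return Recalibrated standard errors.
#' @export
calibrate_se <- function(calibration, se, task = c("exposure", "outcome")) {
  task <- match.arg(task)
  if (is.null(calibration)) return(se)
  se * calibration[[task]]$multiplier
}

#' Write per-member predictions as a long TSV
#'
#' One row per (sequence, task, member) with the member's prediction —
#' the interchange format for inspecting or exporting raw ensemble
#' output.
#'
#' @param object Any object with a [predict_members()] method.
#' @param sequences Character vector of sequences.
#' @param path Output TSV path.
#' @param ids Sequence identifiers (default `seq_along(sequences)`).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(object, sequences, path,
                              ids = as.character(seq_along(sequences))) {
  mem <- predict_members(object, sequences)
  rows <- do.call(rbind, lapply(c("exposure", "outcome"), function(task) {
    m <- mem[[task]]
    data.frame(sequence_id = rep(ids, ncol(m)),
               task = task,
               member = rep(seq_len(ncol(m)), each = nrow(m)),
               prediction = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save / load a trained ensemble
#'
#' Weights are written with a JSON manifest describing the spec and
#' member seeds alongside the binary weight file.
#'
#' @param object A `deepmr_ensemble`.
#' @param dir Directory to write to / read from.
#' @return `save_ensemble`: `dir`, invisibly. `load_ensemble`: the
#'   restored `deepmr_ensemble`.
#' @export
save_ensemble <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(object, file.path(dir, "ensemble.rds"))
  manifest <- list(n_members = length(object$members),
                   seeds = vapply(object$members, `[[`, numeric(1), "seed"),
                   spec = unclass(object$spec), L = object$L)
  jsonlite::write_json(manifest, file.path(dir, "ensemble_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  readRDS(file.path(dir, "ensemble.rds"))
}
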
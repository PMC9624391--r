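#' Enumerate all single-base substitutions of a sequence
#'
#' Saturation in-silico mutagenesis: every position is substituted by the
#' three non-reference bases exactly once, giving `L x 3` mutants, each
#' at Hamming distance 1 from the reference.
#'
#' @param sequence Reference DNA sequence (ACGT string).
#' @return data.frame with columns `position` (0-based), `ref`, `alt`
#'   and `sequence` (the mutated sequence).
#' @export
enumerate_mutants <- function(sequence) {
  codes <- seq_to_codes(sequence)
  L <- length(codes)
  pos <- rep(seq_len(L), each = 3L)
  alt <- unlist(lapply(codes, function(r) setdiff(1:4, r)))
  seqs <- vapply(seq_along(pos), function(i) {
    m <- codes
    m[pos[i]] <- alt[i]
    codes_to_seq(m)
  }, character(1))
  data.frame(position = pos - 1L,
             ref = DNA_BASES[codes[pos]],
             alt = DNA_BASES[alt],
             sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Variant effect sizes and covariance-corrected standard errors
#'
#' For every single-base mutant of the reference, the effect size on a
#' task is the difference of ensemble-mean predictions,
#' `beta = E[task | mutant] - E[task | reference]`.  Its variance is the
#' Monte-Carlo estimate
#' `var(beta) = var_m + var_r - 2 cov(m, r)` over the paired member
#' predictions — the covariance term removes the spurious inflation that
#' ignoring the shared member weights would cause; it is algebraically
#' the population variance of the per-member differences.  Negative
#' values arising from floating-point cancellation are clamped at zero
#' (count reported in the `clamped` attribute).
#'
#' @param object Any object with a [predict_members()] method exposing at
#'   least 2 members.
#' @param sequence Reference sequence.
#' @param region_id Identifier copied into the output rows.
#' @param calibration Optional `deepmr_calibration` applied to the
#'   standard errors.
#' @return data.frame (one row per position/alt pair, `L x 3` rows) with
#'   `region_id`, `position`, `ref`, `alt`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `z_x`.
#' @export
variant_effects <- function(object, sequence, region_id = "region",
                            calibration = NULL) {
  muts <- enumerate_mutants(sequence)
  mem <- predict_members(object, c(if (is.matrix(sequence))
    stop("pass the reference as a string") else sequence, muts$sequence))
  if (ncol(mem$exposure) < 2L)
    stop("at least 2 ensemble members are needed to estimate covariances")

  task_stats <- function(M) {
    ref <- M[1L, ]
    mut <- M[-1L, , drop = FALSE]
    beta <- rowMeans(mut) - mean(ref)
    var_m <- rowMeans(mut^2) - rowMeans(mut)^2
    var_r <- mean(ref^2) - mean(ref)^2
    cov_mr <- rowMeans(mut * rep(ref, each = nrow(mut))) -
      rowMeans(mut) * mean(ref)
    v <- var_m + var_r - 2 * cov_mr
    list(beta = beta, var = pmax(v, 0), clamped = sum(v < 0))
  }
  sx <- task_stats(mem$exposure)
  sy <- task_stats(mem$outcome)
  se_x <- calibrate_se(calibration, sqrt(sx$var), "exposure")
  se_y <- calibrate_se(calibration, sqrt(sy$var), "outcome")
  out <- data.frame(region_id = region_id,
                    position = muts$position, ref = muts$ref, alt = muts$alt,
                    beta_x = sx$beta, se_x = se_x,
                    beta_y = sy$beta, se_y = se_y,
                    z_x = sx$beta / se_x,
                    stringsAsFactors = FALSE)
  attr(out, "clamped") <- sx$clamped + sy$clamped
  out
}

#' Filter instruments by exposure association strength
#'
#' Keeps mutations strongly associated with the exposure:
#' `|z_x| >= z_threshold`.  Records with a zero standard error are kept
#' when their effect is nonzero (infinitely strong instrument) and
#' dropped otherwise.  Only exposure statistics are used; the outcome
#' never influences instrument selection.
#'
#' @param records A variant-effect data.frame (see [variant_effects()]).
#' @param z_threshold Nonnegative z-score cutoff (default 2).
#' @return The subset of `records` passing the filter.
#' @export
filter_instruments <- function(records, z_threshold = 2) {
  if (z_threshold < 0) stop("z_threshold must be nonnegative")
  z <- records$beta_x / records$se_x
  keep <- ifelse(records$se_x == 0,
                 records$beta_x != 0,
                 abs(z) >= z_threshold)
  records[keep, , drop = FALSE]
}

#' Saturation mutagenesis over a set of regions
#'
#' Runs [variant_effects()] for each region and binds the results into
#' the long effect table that forms the boundary between the prediction
#' and the Mendelian-randomization stages.  Externally computed effect
#' tables in the same format can be substituted for this output.
#'
#' @param object Any object with a [predict_members()] method.
#' @param regions data.frame with columns `id` and `sequence`.
#' @param calibration Optional `deepmr_calibration`.
#' @return Combined variant-effect data.frame.
#' @export
mutagenize_regions <- function(object, regions, calibration = NULL) {
  out <- lapply(seq_len(nrow(regions)), function(i)
    variant_effects(object, regions$sequence[i], regions$id[i], calibration))
  do.call(rbind, out)
}

#' Read and write variant-effect tables
#'
#' Tab-separated with columns `region_id`, `position`, `ref`, `alt`,
#' `beta_x`, `se_x`, `beta_y`, `se_y`, `z_x`, `kept`.
#'
#' @param records Variant-effect data.frame.
#' @param path File path.
#' @param z_threshold Threshold used to fill the `kept` column on write.
#' @return `write_effects`: `path` invisibly; `read_effects`: data.frame.
#' @export
write_effects <- function(records, path, z_threshold = 2) {
  kept_ids <- rownames(filter_instruments(records, z_threshold))
  records$kept <- rownames(records) %in% kept_ids
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
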
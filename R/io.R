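#' Write a simulated dataset to disk
#'
#' Writes `train.fa` / `test.fa` (FASTA), `train.tsv` / `test.tsv`
#' (region annotations, binding probabilities, affinities, counts and
#' Anscombe values), `truth.tsv` (true local causal effects of the
#' exposure-implant test regions) and `dataset_manifest.json` (realized
#' config including the drawn `alpha` and `gamma`).
#'
#' @param dataset A `deepmr_dataset`.
#' @param dir Output directory (created if needed).
#' @param truth Also compute and write the true-CE table?  Default
#'   `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "test")) {
    df <- dataset[[part]]
    ss <- Biostrings::DNAStringSet(df$sequence)
    names(ss) <- df$id
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(part, ".fa")))
    utils::write.table(df, file.path(dir, paste0(part, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (truth)
    utils::write.table(true_ce_table(dataset),
                       file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  manifest <- c(unclass(cfg),
                list(scenario = scenario_name(cfg),
                     alpha_realized = dataset$alpha,
                     gamma_realized = dataset$gamma))
  jsonlite::write_json(manifest, file.path(dir, "dataset_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated dataset written by [write_dataset()]
#'
#' @param dir Directory containing the dataset files.
#' @param pwms PWMs to attach (default: bundled motifs).
#' @return A `deepmr_dataset`.
#' @export
read_dataset <- function(dir, pwms = deepmr_motifs()) {
  manifest <- jsonlite::read_json(file.path(dir, "dataset_manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- scenario_config(manifest$scenario, L = manifest$L,
                         alpha = manifest$alpha_realized,
                         gamma = manifest$gamma_realized,
                         eta = manifest$eta, nu = manifest$nu,
                         tau_conf = manifest$tau_conf,
                         insertion_prob = manifest$insertion_prob,
                         n_train = manifest$n_train,
                         n_test = manifest$n_test, seed = manifest$seed,
                         exposure = manifest$exposure,
                         outcome = manifest$outcome,
                         confounder = manifest$confounder,
                         both_strands = manifest$both_strands,
                         window_prior = manifest$window_prior)
  rd <- function(part) utils::read.delim(file.path(dir, paste0(part, ".tsv")),
                                         stringsAsFactors = FALSE)
  structure(list(train = rd("train"), test = rd("test"),
                 alpha = manifest$alpha_realized,
                 gamma = manifest$gamma_realized,
                 config = cfg, pwms = pwms),
            class = "deepmr_dataset")
}

#' Write per-region and global causal-effect tables
#'
#' @param lce Per-region causal effects from [local_ces()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_local_ces <- function(lce, path) {
  utils::write.table(lce, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_local_ces
#' @param globals data.frame of per-method global effects (columns
#'   `method`, `mean`, `sigma`, `tau`, `n_regions`).
#' @export
write_global_ces <- function(globals, path) {
  utils::write.table(globals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
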
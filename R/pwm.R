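#' Position weight matrices
#'
#' A PWM is stored as a `width x 4` numeric matrix of per-position base
#' probabilities with columns `A`, `C`, `G`, `T`.  Every row must be a
#' probability distribution (nonnegative, summing to 1 within `1e-9`).
#'
#' @param name Character label for the motif (e.g. the TF name).
#' @param matrix Numeric `width x 4` matrix of base probabilities; columns
#'   are taken in A, C, G, T order (column names, if present, are checked).
#' @return An object of class `pwm`: the probability matrix with a `name`
#'   attribute.
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01), 1, 4)
#' pwm("Apos", m)
#' @export
pwm <- function(name, matrix) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L)
    stop("a PWM must have 4 columns (A, C, G, T)")
  if (nrow(matrix) < 1L)
    stop("a PWM must have width >= 1")
  cn <- toupper(colnames(matrix) %||% character())
  if (setequal(cn, DNA_BASES) && !identical(cn, DNA_BASES))
    matrix <- matrix[, match(DNA_BASES, cn), drop = FALSE]
  if (any(matrix < 0))
    stop("PWM probabilities must be nonnegative")
  sums <- rowSums(matrix)
  if (any(abs(sums - 1) > 1e-9))
    stop("each PWM position must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  dimnames(matrix) <- list(NULL, DNA_BASES)
  structure(matrix, name = as.character(name), class = "pwm")
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", attr(x, "name"), "width", nrow(x), "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  print(unclass(x), digits = 3)
  invisible(x)
}

#' @rdname pwm
#' @param x A `pwm` object.
#' @export
pwm_width <- function(x) nrow(x)

#' @rdname pwm
#' @export
pwm_name <- function(x) attr(x, "name")

#' Consensus sequence of a PWM
#'
#' @param x A `pwm` object.
#' @return Single character string, the highest-probability base at each
#'   position (ties broken towards A < C < G < T).
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(unclass(x), 1L, which.max)], collapse = "")
}

#' Sample motif instances from a PWM
#'
#' Draws each position independently from the PWM's per-position base
#' distribution, the process used to implant motif instances into
#' simulated sequences.
#'
#' @param x A `pwm` object.
#' @param n Number of instances to draw.
#' @return Character vector of `n` motif instances of width `pwm_width(x)`.
#' @export
pwm_sample <- function(x, n = 1L) {
  w <- nrow(x)
  out <- character(n)
  for (i in seq_len(n)) {
    idx <- vapply(seq_len(w),
                  function(j) sample.int(4L, 1L, prob = x[j, ]),
                  integer(1))
    out[i] <- paste(DNA_BASES[idx], collapse = "")
  }
  out
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses the letter-probability matrices of a MEME (version 4) minimal
#' motif file.  Only the fields needed for simulation are read: motif
#' names and probability matrices.
#'
#' @param path Path to a MEME minimal format motif file.
#' @return Named list of `pwm` objects.
#' @seealso [read_pwm_matrix()] for plain 4-column matrices,
#'   [deepmr_motifs()] for the bundled exposure/outcome/confounder motifs.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  motif_idx <- grep("^MOTIF\\s+", lines)
  if (length(motif_idx) == 0L)
    stop("no MOTIF blocks found in ", path)
  out <- list()
  for (i in motif_idx) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[i])), "\\s+")[[1]][1]
    hdr <- i + which(grepl("letter-probability matrix", lines[(i + 1):length(lines)]))[1]
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    out[[name]] <- pwm(name, mat)
  }
  out
}

#' Write motifs to a MEME minimal-format file
#'
#' @param pwms Named list of `pwm` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", pwm_name(p)), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       pwm_width(p)), con)
    writeLines(apply(unclass(p), 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a PWM from a plain whitespace-delimited matrix file
#'
#' Expects one row per motif position with four columns of probabilities
#' in A, C, G, T order; lines starting with `#` are ignored.
#'
#' @param path Path to the matrix file.
#' @param name Motif name to attach; defaults to the file base name.
#' @return A `pwm` object.
#' @export
read_pwm_matrix <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  mat <- as.matrix(utils::read.table(path, comment.char = "#"))
  pwm(name, mat)
}

#' Bundled transcription factor motifs
#'
#' Returns the three synthetic PWMs shipped with the package and used as
#' defaults by the simulator: a GATA motif (exposure TF), a TAL1 E-box
#' motif (outcome TF) and a SOX2 motif (confounder TF).  The matrices are
#' synthetic: they were constructed around the canonical consensus of each
#' factor with information content typical of curated motif databases, and
#' are not copies of any database record.
#'
#' @return Named list of `pwm` objects with elements `GATA`, `TAL1`, `SOX2`.
#' @export
deepmr_motifs <- function() {
  read_meme(system.file("extdata", "motifs_synthetic.meme",
                        package = "deepmr", mustWork = TRUE))
}
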
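random_seqs <- function(n, L = 40) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    character(1))
}

test_that("sequence encoding is the inverse of the alphabet", {
  X <- encode_sequences(c("ACGT", "TTAA"))
  expect_equal(X, matrix(c(1L, 4L, 2L, 4L, 3L, 1L, 4L, 1L), 2, 4))
  expect_error(encode_sequences(c("ACGT", "ACG")), "equal length")
  expect_error(encode_sequences("ACGN"), "non-ACGT")
})

test_that("a constant target is learned by every member", {
  set.seed(1)
  seqs <- random_seqs(300)
  y <- matrix(5, 300, 2)
  spec <- ensemble_spec(n_members = 2, max_epochs = 100, patience = 100,
                       batch_size = 64, seed = 7)
  ens <- train_ensemble(seqs, y, spec)
  pred <- predict_ensemble(ens, seqs[1:50])
  expect_lt(mean(abs(pred$mean - 5)), 0.05)
  for (m in ens$members) expect_lt(m$best_val_mse, 0.01)
})

test_that("training is deterministic in the seed", {
  set.seed(2)
  seqs <- random_seqs(200)
  y <- cbind(rnorm(200, 10), rnorm(200, 3))
  spec <- ensemble_spec(n_members = 1, max_epochs = 3, patience = 3,
                        batch_size = 64, seed = 42)
  e1 <- train_ensemble(seqs, y, spec)
  e2 <- train_ensemble(seqs, y, spec)
  p1 <- predict_ensemble(e1, seqs[1:20])$mean
  p2 <- predict_ensemble(e2, seqs[1:20])$mean
  expect_identical(p1, p2)
  # a different seed gives different weights
  e3 <- train_ensemble(seqs, y, ensemble_spec(n_members = 1, max_epochs = 3,
                                              patience = 3, batch_size = 64,
                                              seed = 43))
  expect_false(identical(predict_ensemble(e3, seqs[1:20])$mean, p1))
})

test_that("predictive distribution arithmetic is exact", {
  mock <- mock_predictor(function(seqs) {
    n <- length(seqs)
    list(exposure = matrix(c(2, 4), n, 2, byrow = TRUE),
         outcome = matrix(c(1, 1), n, 2, byrow = TRUE))
  })
  pd <- predict_ensemble(mock, c("AA", "CC"))
  expect_equal(pd$mean[, 1], c(3, 3))
  expect_equal(pd$var[, 1], c(1, 1)) # population variance of {2, 4}
  expect_equal(pd$var[, 2], c(0, 0))

  single <- mock_predictor(function(seqs)
    list(exposure = matrix(7, length(seqs), 1),
         outcome = matrix(1, length(seqs), 1)))
  expect_equal(predict_ensemble(single, "AC")$var[1, ], c(exposure = 0,
                                                          outcome = 0))
})

test_that("ensemble mean is invariant to member order and matches two-pass variance", {
  set.seed(3)
  M <- matrix(rnorm(50 * 6), 50, 6)
  mk <- function(m) mock_predictor(function(seqs)
    list(exposure = m[seq_along(seqs), , drop = FALSE],
         outcome = m[seq_along(seqs), , drop = FALSE]))
  seqs <- random_seqs(50, 10)
  pd1 <- predict_ensemble(mk(M), seqs)
  pd2 <- predict_ensemble(mk(M[, sample(6)]), seqs)
  expect_equal(pd1$mean, pd2$mean)
  # independent two-pass population variance
  v2 <- apply(M, 1, function(r) mean((r - mean(r))^2))
  expect_equal(pd1$var[, 1], v2, tolerance = 1e-8)
})

test_that("prediction rejects sequences of the wrong length", {
  set.seed(4)
  seqs <- random_seqs(120, 30)
  spec <- ensemble_spec(n_members = 1, max_epochs = 2, patience = 2,
                        batch_size = 64, seed = 1)
  ens <- train_ensemble(seqs, cbind(rnorm(120), rnorm(120)), spec)
  expect_error(predict_ensemble(ens, random_seqs(3, 31)), "length")
})

test_that("per-member predictions export as a long TSV", {
  mock <- mock_predictor(function(seqs) {
    n <- length(seqs)
    list(exposure = matrix(1:(2 * n), n, 2),
         outcome = matrix(-(1:(2 * n)), n, 2))
  })
  path <- tempfile(fileext = ".tsv")
  write_predictions(mock, c("AC", "GT", "TT"), path, ids = c("a", "b", "c"))
  tab <- read.delim(path)
  expect_equal(nrow(tab), 3 * 2 * 2)
  expect_setequal(unique(tab$task), c("exposure", "outcome"))
  expect_equal(tab$prediction[tab$task == "exposure" & tab$member == 2 &
                                tab$sequence_id == "b"], 5)
})

test_that("ensembles survive a save/load round trip", {
  set.seed(5)
  seqs <- random_seqs(100, 20)
  spec <- ensemble_spec(n_members = 2, max_epochs = 2, patience = 2,
                        batch_size = 64, seed = 9)
  ens <- train_ensemble(seqs, cbind(rnorm(100), rnorm(100)), spec)
  dir <- tempfile()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "ensemble_manifest.json")))
  back <- load_ensemble(dir)
  expect_equal(predict_ensemble(back, seqs[1:10])$mean,
               predict_ensemble(ens, seqs[1:10])$mean)
})
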
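cfg0 <- function(...) scenario_config(seed = 1, ...)

test_that("gamma draws follow the bimodal mixture", {
  set.seed(42)
  g <- sample_gamma(1e5)
  # mixture mean (10 + 1) / 2; variance 0.5 + (10 - 1)^2 / 4
  expect_equal(mean(g), 5.5, tolerance = 3 * sqrt(20.75 / 1e5))
  expect_equal(var(g), 20.75, tolerance = 0.6)
  # the gap between the two clusters is essentially empty
  expect_lt(mean(g > 4 & g < 7), 0.01)
  expect_equal(mean(g > 7), 0.5, tolerance = 0.02)
})

test_that("sampled sequences have the right length and implant rate", {
  cfg <- cfg0(n_train = 10, n_test = 1)
  regions <- sample_sequences(200, cfg)
  expect_true(all(nchar(regions$sequence) == 100))

  set.seed(3)
  big <- sample_sequences(4000, cfg)
  frac <- mean(!is.na(big$e_start))
  expect_equal(frac, 0.5, tolerance = 3 * sqrt(0.25 / 4000))
  # implanted subsequence really sits at the recorded position
  i <- which(!is.na(big$e_start))[1]
  expect_equal(substr(big$sequence[i], big$e_start[i] + 1,
                      big$e_start[i] + 7), big$e_seq[i])

  cfg_none <- scenario_config(seed = 1, insertion_prob = 0)
  none <- sample_sequences(100, cfg_none)
  expect_true(all(is.na(none$e_start)) && all(is.na(none$o_start)) &&
                all(is.na(none$c_start)))

  expect_error(sample_sequences(5, scenario_config(seed = 1, L = 5)),
               "wider than L")
})

test_that("binding probability matches brute-force window enumeration", {
  set.seed(11)
  for (rep in 1:40) {
    p <- toy_pwm(w = 3)
    s <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    expect_equal(binding_probability(s, p),
                 oracle_binding_probability(s, p), tolerance = 1e-12)
  }
  # longer sequences and the vectorized path used by the generator
  motifs <- deepmr_motifs()
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    character(1))
  for (s in seqs[1:5])
    expect_equal(binding_probability(s, motifs$GATA),
                 oracle_binding_probability(s, motifs$GATA),
                 tolerance = 1e-12)
})

test_that("binding probability is bounded and hits its edge cases", {
  set.seed(12)
  for (rep in 1:200) {
    p <- toy_pwm(w = sample(2:8, 1))
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
               collapse = "")
    b <- binding_probability(s, p)
    expect_gte(b, 0)
    expect_lte(b, 1)
  }
  # a motif that cannot match anywhere: p ~ 0
  panti <- pwm("onlyA", matrix(rep(c(1, 0, 0, 0), each = 3), 3, 4))
  expect_lt(binding_probability("TTTTTTTT", panti), 1e-8)
  expect_error(binding_probability("ACG", deepmr_motifs()$GATA),
               "shorter than motif")
})

test_that("affinity formulas reproduce hand substitutions", {
  cfg <- scenario_config("both", seed = 1, alpha = 100, gamma = 10)
  expect_equal(exposure_affinity(1, 0, 0, cfg), 101)
  expect_equal(exposure_affinity(0, 0, 0, cfg), 1)
  expect_equal(exposure_affinity(0.5, 1, 1, cfg), 96) # 50 + 20 + 25 + 1
  expect_equal(outcome_affinity(1, 1, 0, 0, cfg), 1001)
  expect_equal(outcome_affinity(0, 0, 1, 0, cfg), 31) # nu = 30
  expect_equal(outcome_affinity(0.9, 0, 0, 0, cfg), 1) # no exposure binding

  un <- scenario_config("unconfounded", seed = 1, alpha = 100, gamma = 10)
  expect_equal(exposure_affinity(0, 1, 1, un), 1) # confounders inactive
  expect_error(exposure_affinity(1.5, 0, 0, cfg), "\\[0, 1\\]")
  cfg_bad <- cfg
  cfg_bad$alpha <- -5
  expect_error(exposure_affinity(1, 0, 0, cfg_bad), "nonnegative")
})

test_that("anscombe transform is the canonical closed form", {
  expect_equal(anscombe(0), 2 * sqrt(0.375))
  expect_equal(anscombe(1), 2 * sqrt(1.375))
  x <- 0:1000
  expect_true(all(diff(anscombe(x)) > 0))
  expect_error(anscombe(-1), "nonnegative")
  expect_error(sample_counts(-2), "nonnegative")
})

test_that("anscombe stabilizes Poisson variance near 1", {
  set.seed(5)
  for (lam in c(20, 100, 500)) {
    v <- var(anscombe(rpois(2e4, lam)))
    expect_gt(v, 0.8)
    expect_lt(v, 1.2)
  }
})

test_that("dataset generation is reproducible and correctly sized", {
  cfg <- scenario_config("unconfounded", n_train = 300, n_test = 50, seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$train, d2$train)
  expect_identical(d1$test, d2$test)
  expect_equal(nrow(d1$train), 300)
  expect_equal(nrow(d1$test), 50)
  # unconfounded: affinity reduces to alpha p_e + 1
  expect_equal(d1$train$c_e, d1$alpha * d1$train$p_e + 1)
  expect_equal(d1$train$y_e, anscombe(d1$train$counts_e))
})

test_that("affinities never drop below 1 for nonnegative gamma", {
  cfg <- scenario_config("both", n_train = 400, n_test = 50, seed = 21,
                         gamma = 10)
  ds <- generate_dataset(cfg)
  expect_gte(min(ds$train$c_e, ds$test$c_e), 1)
  expect_gte(min(ds$train$c_o, ds$test$c_o), 1)
})

test_that("confounding flags change only confounder-dependent fields", {
  base <- scenario_config("unconfounded", n_train = 150, n_test = 30,
                          seed = 31)
  both <- scenario_config("both", n_train = 150, n_test = 30, seed = 31)
  d1 <- generate_dataset(base)
  d2 <- generate_dataset(both)
  for (col in c("sequence", "e_start", "e_seq", "o_start", "c_start",
                "z", "p_e", "p_o", "p_c"))
    expect_identical(d1$train[[col]], d2$train[[col]])
  expect_identical(d1$alpha, d2$alpha)
  expect_identical(d1$gamma, d2$gamma)
  # and the confounded run really moves the affinities
  expect_false(isTRUE(all.equal(d1$train$c_e, d2$train$c_e)))
})

test_that("true causal effect matches the exhaustive mutation oracle", {
  cfg <- scenario_config("both", n_train = 60, n_test = 60, seed = 13)
  ds <- generate_dataset(cfg)
  regions <- rbind(ds$train, ds$test)
  regions <- regions[!is.na(regions$e_start), ]
  regions <- regions[seq_len(min(100, nrow(regions))), ]
  for (i in seq_len(nrow(regions))) {
    got <- true_local_ce(regions[i, ], ds$pwms, ds$config)
    expect_equal(got$estimate, oracle_true_ce(regions[i, ], ds$pwms,
                                              ds$config),
                 tolerance = 1e-10)
    expect_equal(got$n_instruments, 21L) # GATA width 7 x 3
  }
})

test_that("true causal effect is zero without an exposure->outcome path", {
  cfg <- scenario_config("unconfounded", n_train = 40, n_test = 10,
                         seed = 17, gamma = 0)
  ds <- generate_dataset(cfg)
  regions <- ds$train[!is.na(ds$train$e_start), ]
  tce <- true_local_ce(regions[1, ], ds$pwms, ds$config)
  expect_equal(tce$estimate, 0)
  # regions without the implant are rejected
  no_impl <- ds$train[is.na(ds$train$e_start), ][1, ]
  expect_error(true_local_ce(no_impl, ds$pwms, ds$config),
               "exposure implant")
})

test_that("regions where mutations cannot move the exposure are degenerate", {
  flat <- pwm("FLAT", matrix(0.25, 5, 4))
  pwms <- deepmr_motifs()
  pwms$FLAT <- flat
  cfg <- scenario_config("unconfounded", seed = 2, alpha = 100, gamma = 5,
                         exposure = "FLAT")
  region <- list(id = "x", sequence = paste(rep("ACGT", 25), collapse = ""),
                 e_start = 10L, z = 0L)
  expect_error(true_local_ce(region, pwms, cfg), "degenerate")
})
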
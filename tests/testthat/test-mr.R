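inst_df <- function(bx, by, sey = rep(1, length(bx))) {
  data.frame(region_id = "r", beta_x = bx, beta_y = by,
             se_x = 0.1, se_y = sey)
}

test_that("wald baseline reproduces hand arithmetic", {
  one <- wald_baseline(inst_df(2, 6))
  expect_equal(one$estimate, 3)
  expect_true(is.na(one$se))

  two <- wald_baseline(inst_df(c(1, 1), c(2, 4)))
  expect_equal(two$estimate, 3)
  expect_equal(two$se, sqrt(2)) # literal SD of the ratios
  expect_equal(wald_baseline(inst_df(c(1, 1), c(2, 4)),
                             se_of_mean = TRUE)$se, 1)

  # noiseless linear truth: identical ratios, zero spread
  bx <- seq(0.5, 2, length.out = 20)
  exact <- wald_baseline(inst_df(bx, 2.5 * bx))
  expect_equal(exact$estimate, 2.5)
  expect_equal(exact$se, 0)

  # zero-exposure instruments are dropped, empty set errors
  dropped <- wald_baseline(inst_df(c(0, 1), c(5, 4)))
  expect_equal(dropped$n_instruments, 1)
  expect_equal(dropped$n_dropped, 1)
  expect_error(wald_baseline(inst_df(0, 5)), "no instruments")
})

test_that("mr-egger recovers exact affine data with its pleiotropy intercept", {
  bx <- c(0.5, 1, 1.5, 2, 3)
  for (robust in c(TRUE, FALSE)) {
    fit <- mr_egger(inst_df(bx, 4 * bx + 0.7), robust = robust)
    expect_equal(fit$estimate, 4, tolerance = 1e-10)
    expect_equal(fit$intercept, 0.7, tolerance = 1e-10)
  }
  expect_error(mr_egger(inst_df(bx[1:2], bx[1:2])), "at least 3")
  expect_error(mr_egger(inst_df(rep(1, 5), rnorm(5))), "singular")
})

test_that("plain mr-egger equals the closed-form OLS oracle at equal weights", {
  set.seed(1)
  for (rep in 1:20) {
    bx <- abs(rnorm(10, 2))
    by <- 3 * bx + rnorm(10)
    fit <- mr_egger(inst_df(bx, by), robust = FALSE)
    o <- oracle_ols(bx, by)
    expect_equal(fit$estimate, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("both MR methods are scale and sign equivariant in the outcome", {
  set.seed(2)
  bx <- abs(rnorm(12, 2))
  by <- 2 * bx + rnorm(12, sd = 0.3)
  sey <- runif(12, 0.5, 1.5)
  k <- 2.5
  for (robust in c(TRUE, FALSE)) {
    f1 <- mr_egger(inst_df(bx, by, sey), robust = robust)
    f2 <- mr_egger(inst_df(bx, k * by, k * sey), robust = robust)
    expect_equal(f2$estimate, k * f1$estimate, tolerance = 1e-8)
    expect_equal(f2$se, k * f1$se, tolerance = 1e-8)
    f3 <- mr_egger(inst_df(bx, -by, sey), robust = robust)
    expect_equal(f3$estimate, -f1$estimate, tolerance = 1e-8)
  }
  w1 <- wald_baseline(inst_df(bx, by))
  w2 <- wald_baseline(inst_df(bx, k * by))
  expect_equal(w2$estimate, k * w1$estimate)
  expect_equal(w2$se, k * w1$se)
})

test_that("mr-egger is invariant to pre-flipping instrument orientations", {
  set.seed(3)
  bx <- rnorm(15, 1)
  by <- 1.5 * bx + rnorm(15, sd = 0.2)
  sey <- runif(15, 0.5, 2)
  base <- mr_egger(inst_df(bx, by, sey))
  for (rep in 1:5) {
    fl <- sample(c(-1, 1), 15, TRUE)
    flipped <- mr_egger(inst_df(fl * bx, fl * by, sey))
    expect_equal(flipped$estimate, base$estimate, tolerance = 1e-8)
    expect_equal(flipped$intercept, base$intercept, tolerance = 1e-8)
  }
})

test_that("egger intercept is consistent with zero under valid instruments", {
  set.seed(4)
  hits <- 0
  for (rep in 1:100) {
    k <- 20
    bx <- abs(rnorm(k, 1.5, 0.5))
    sey <- runif(k, 0.2, 0.4)
    by <- 3 * bx + rnorm(k, sd = sey)
    fit <- mr_egger(inst_df(bx, by, sey))
    if (abs(fit$intercept) < 3 * fit$intercept_se) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("local_ces fits per region and logs skipped regions", {
  set.seed(5)
  strong <- data.frame(region_id = "big", position = 1:8, ref = "A",
                       alt = "C", beta_x = abs(rnorm(8, 2)),
                       se_x = 0.1, beta_y = NA, se_y = 0.3)
  strong$beta_y <- 2 * strong$beta_x + rnorm(8, sd = 0.3)
  strong$z_x <- strong$beta_x / strong$se_x
  weak <- data.frame(region_id = "small", position = 1:2, ref = "A",
                     alt = "C", beta_x = c(3, 4), se_x = 0.1,
                     beta_y = c(6, 8), se_y = 0.3, z_x = c(30, 40))
  eff <- rbind(strong, weak)
  out <- local_ces(eff, method = "both", z_threshold = 2)
  expect_setequal(out$method[out$region_id == "big"],
                  c("egger", "baseline"))
  # the 2-instrument region supports the baseline but not egger
  expect_equal(out$method[out$region_id == "small"], "baseline")
  expect_equal(attr(out, "skipped"), 1L)
  expect_true(all(out$n_instruments[out$region_id == "big"] == 8))
})
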
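test_that("HOMA-IR arithmetic and unit conversion", {
  expect_identical(homa_ir(1.0, 22.5, "mmol/L"), 1.0)
  expect_equal(homa_ir(90, 10, "mg/dL"), 10 * (90 / 18.0182) / 22.5,
               tolerance = 1e-12)
  expect_equal(homa_ir(90, 10, "mg/dL"), 2.220, tolerance = 1e-3)
  # unit invariance: mg/dL input equal to 18.0182 x mmol/L input
  g_mmol <- 5.3
  expect_equal(homa_ir(g_mmol * 18.0182, 12, "mg/dL"),
               homa_ir(g_mmol, 12, "mmol/L"), tolerance = 1e-12)
  expect_error(homa_ir(0, 10), "glucose")
  expect_error(homa_ir(90, -1), "insulin")
  expect_error(homa_ir(90, 10, "g/L"), "unknown glucose unit")
})

test_that("BMI arithmetic and the inclusive obesity threshold", {
  expect_identical(bmi(100, 200), 25)
  expect_equal(bmi(91.66, 169.48), 31.91, tolerance = 1e-3)
  expect_true(is_obese(30.0))
  expect_false(is_obese(29.999))
  expect_error(bmi(-1, 170), "weight")
  expect_error(bmi(80, 0), "height")
})

test_that("partial Spearman with no covariates is ordinary Spearman", {
  set.seed(101)
  for (i in 1:20) {
    x <- sample(rnorm(40))
    y <- rnorm(40) + 0.5 * x
    r <- spearman_partial(x, y)
    expect_equal(r$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  }
  # strictly monotone transform: exact rho = 1
  x <- rnorm(25)
  expect_identical(spearman_partial(x, exp(x))$rho, 1)
})

test_that("matrix-inversion partial rho equals the rank-residualization oracle", {
  set.seed(202)
  worst <- 0
  for (i in 1:200) {
    n <- 50L
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    k <- sample(0:2, 1)
    z <- if (k > 0) matrix(c(rnorm(n), sample(0:1, n, TRUE))[seq_len(n * k)], n) else NULL
    if (i %% 3 == 0) x <- round(x, 1)   # induce ties
    r <- spearman_partial(x, y, z)
    rx <- rank(x); ry <- rank(y)
    if (k > 0) {
      rz <- apply(z, 2, rank)
      ex <- resid(lm(rx ~ rz)); ey <- resid(lm(ry ~ rz))
      worst <- max(worst, abs(r$rho - cor(ex, ey)))
    } else {
      worst <- max(worst, abs(r$rho - cor(rx, ry)))
    }
    expect_identical(r$df, n - 2L - k)
  }
  expect_lt(worst, 1e-10)
})

test_that("partial Spearman degenerate and undersized inputs are refused", {
  expect_error(spearman_partial(rep(1, 10), rnorm(10)), "zero variance")
  x <- rnorm(10)
  expect_error(spearman_partial(x, rnorm(10), cbind(x, x)), "singular|collinearity")
  expect_error(spearman_partial(rnorm(5), rnorm(5), matrix(rnorm(10), 5)),
               "complete observations")
  # listwise deletion reduces n_effective
  x <- c(rnorm(20), NA); y <- c(rnorm(20), 1)
  expect_identical(spearman_partial(x, y)$n_effective, 20L)
})

test_that("BH step-up matches hand execution and edge cases", {
  fam <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(fam$rejected))        # p(4) = 0.04 <= 4*0.05/4
  one <- bh_adjust(0.04, q = 0.05)
  expect_true(one$rejected)
  expect_identical(one$adjusted_p, 0.04)
  empty <- bh_adjust(numeric(0))
  expect_identical(nrow(empty), 0L)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(0.5, q = 1), "q must lie")
})

test_that("BH rejections are monotone in q and adjusted p is monotone in raw p", {
  set.seed(7)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))^2
    r1 <- bh_adjust(p, q = 0.02); r2 <- bh_adjust(p, q = 0.10)
    expect_true(all(!r1$rejected | r2$rejected))
    o <- order(p)
    expect_true(all(diff(r1$adjusted_p[o]) >= -1e-15))
    expect_identical(r1$rejected, r1$adjusted_p <= 0.02)
  }
})

test_that("linear regression summary on exact and null relationships", {
  x <- 1:20
  r <- suppressWarnings(linreg_summary(x, 2 * x + 1))  # perfect fit warns in summary.lm
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  x2 <- c(-2, -1, 0, 1, 2)
  y2 <- c(1, -2, 0, 2, -1)   # constructed orthogonal to x2
  expect_equal(sum(x2 * y2), 0)
  expect_equal(linreg_summary(x2, y2)$r_squared, 0, tolerance = 1e-12)
  expect_error(linreg_summary(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("R-squared converges to the squared population correlation", {
  m <- list(x = list(family = "normal", mean = 0, sd = 1),
            y = list(family = "normal", mean = 0, sd = 1))
  rho_s <- 6 / pi * asin(0.6 / 2)  # Spearman target whose Pearson copula r is 0.6
  R <- matrix(c(1, rho_s, rho_s, 1), 2, dimnames = list(names(m), names(m)))
  tab <- generate_cohort(cohort_spec(10000, m, R, seed = 11))
  expect_lt(abs(linreg_summary(tab$x, tab$y)$r_squared - 0.36), 0.02)
})
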
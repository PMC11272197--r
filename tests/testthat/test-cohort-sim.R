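test_that("identity target yields near-zero pairwise rank correlations at large n", {
  tab <- generate_cohort(cohort_spec(10000, seed = 3))
  S <- cor(sapply(tab, rank))
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
})

test_that("cohort table has the declared shape and columns even at the minimum n", {
  tab <- generate_cohort(cohort_spec(4, seed = 1))
  expect_equal(nrow(tab), 4L)
  expect_setequal(names(tab), names(default_cohort_marginals()))
  expect_error(cohort_spec(3), "at least 4")
})

test_that("copula calibration recovers a planted Spearman rho of 0.55", {
  m <- list(vat_ratio = list(family = "lognormal", meanlog = log(0.45), sdlog = 0.5),
            suvr = list(family = "lognormal", meanlog = log(1.1), sdlog = 0.15))
  R <- matrix(c(1, 0.55, 0.55, 1), 2, dimnames = list(names(m), names(m)))
  tab <- generate_cohort(cohort_spec(20000, m, R, seed = 7))
  rho <- cor(tab$vat_ratio, tab$suvr, method = "spearman")
  expect_lt(abs(rho - 0.55), 0.02)
})

test_that("same seed reproduces the table; different seed does not", {
  sp <- cohort_spec(50, seed = 9)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  expect_false(identical(generate_cohort(sp),
                         generate_cohort(cohort_spec(50, seed = 10))))
})

test_that("an indefinite target is repaired towards the nearest PSD correlation", {
  m <- list(a = list(family = "normal", mean = 0, sd = 1),
            b = list(family = "normal", mean = 0, sd = 1),
            c = list(family = "normal", mean = 0, sd = 1))
  R <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3,
              dimnames = list(names(m), names(m)))  # not PSD
  tab <- generate_cohort(cohort_spec(5000, m, R, seed = 2))
  expect_equal(nrow(tab), 5000L)
  S <- cor(sapply(tab, rank))
  # repaired matrix keeps the signs of the requested structure
  expect_gt(S["a", "b"], 0.3)
  expect_lt(S["a", "c"], -0.3)
})

test_that("a sex effect shifts the targeted variables for males only", {
  m <- default_cohort_marginals()
  sp <- cohort_spec(4000, m, sex_effect = c(vat_cm3 = 800), seed = 5)
  tab <- generate_cohort(sp)
  base <- generate_cohort(cohort_spec(4000, m, seed = 5))
  expect_identical(tab$vat_cm3[tab$sex == 0], base$vat_cm3[base$sex == 0])
  expect_identical(tab$vat_cm3[tab$sex == 1], base$vat_cm3[base$sex == 1] + 800)
})

test_that("malformed cohort specs are rejected", {
  m <- default_cohort_marginals()
  R <- diag(length(m)) ; R[1, 2] <- 0.5   # asymmetric
  expect_error(cohort_spec(10, m, R), "symmetric")
  expect_error(cohort_spec(10, m, sex_effect = c(nope = 1)), "sex_effect")
  bad <- m; bad$age$family <- "cauchy"
  expect_error(generate_cohort(cohort_spec(10, bad)), "unknown marginal family")
})
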
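screen_cohort <- function(n = 60, seed = 31, rho = 0.5, n_out = 4) {
  vars <- c("age", "sex", "vat_sat_ratio", paste0("out", seq_len(n_out)))
  m <- c(list(age = list(family = "uniform", min = 40, max = 60),
              sex = list(family = "binary", p = 0.5),
              vat_sat_ratio = list(family = "lognormal", meanlog = log(0.45),
                                   sdlog = 0.5)),
         setNames(rep(list(list(family = "normal", mean = 0, sd = 1)), n_out),
                  paste0("out", seq_len(n_out))))
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  R["vat_sat_ratio", "out1"] <- R["out1", "vat_sat_ratio"] <- rho
  generate_cohort(cohort_spec(n, m, R, seed = seed))
}

test_that("a single predictor-outcome pair reduces to spearman_partial with m = 1 BH", {
  tab <- screen_cohort()
  sc <- correlation_screen(tab, "vat_sat_ratio", "out1", c("age", "sex"))
  ref <- spearman_partial(tab$vat_sat_ratio, tab$out1, tab[, c("age", "sex")])
  expect_identical(nrow(sc), 1L)
  expect_equal(sc$rho, ref$rho)
  expect_equal(sc$raw_p, ref$p_value)
  expect_equal(sc$adjusted_p, ref$p_value)   # m = 1: adjusted equals raw
  expect_identical(sc$rejected, ref$p_value <= 0.05)
})

test_that("the planted association is detected and flagged across the outcome family", {
  tab <- screen_cohort(n = 200, rho = 0.6, n_out = 8)
  sc <- correlation_screen(tab, "vat_sat_ratio", paste0("out", 1:8))
  expect_true(sc$rejected[sc$outcome == "out1"])
  expect_gt(sc$rho[sc$outcome == "out1"], 0.4)
})

test_that("stratified runs split by the stratum variable and drop it from covariates", {
  tab <- screen_cohort(n = 120)
  sc <- correlation_screen(tab, "vat_sat_ratio", "out1", c("age", "sex"),
                           stratify_by = "sex")
  expect_setequal(unique(sc$stratum), c("0", "1"))
  expect_identical(attr(sc, "covariates"), "age")
  expect_identical(nrow(sc), 2L)
})

test_that("adjust = FALSE leaves adjusted p empty and flags by raw p", {
  tab <- screen_cohort(n = 80)
  sc <- correlation_screen(tab, "vat_sat_ratio", paste0("out", 1:4),
                           adjust = FALSE, q = 0.05)
  expect_true(all(is.na(sc$adjusted_p)))
  expect_identical(sc$rejected, sc$raw_p <= 0.05)
})

test_that("the linear method and Shapiro-Wilk reporting are explicit configuration", {
  tab <- screen_cohort(n = 80)
  sc <- correlation_screen(tab, "vat_sat_ratio", "out1",
                           method = "linear", shapiro = TRUE)
  fit <- summary(lm(out1 ~ vat_sat_ratio + age + sex, data = tab))
  expect_equal(sc$rho, fit$coefficients[2, 1])
  expect_equal(sc$raw_p, fit$coefficients[2, 4])
  expect_true(is.finite(sc$shapiro_w))
})

test_that("missing or empty column sets are configuration errors", {
  tab <- screen_cohort()
  expect_error(correlation_screen(tab, "vat_sat_ratio", character()), "empty")
  expect_error(correlation_screen(tab, "nope", "out1"), "nope")
})

test_that("derive_measures appends BMI, HOMA-IR and the VAT/SAT ratio", {
  tab <- data.frame(weight = c(100, 80), height = c(200, 160),
                    fasting_glucose = c(90, 110), fasting_insulin = c(10, 15),
                    vat_cm3 = c(1000, 500), sat_cm3 = c(2000, 0))
  out <- derive_measures(tab, "mg/dL")
  expect_equal(out$bmi, c(25, 31.25))
  expect_equal(out$homa_ir[1], homa_ir(90, 10, "mg/dL"))
  expect_equal(out$vat_sat_ratio, c(0.5, NA))
})

test_that("a male location shift on VAT yields a higher VAT/SAT ratio in males", {
  m <- default_cohort_marginals()
  tab <- generate_cohort(cohort_spec(400, m, sex_effect = c(vat_cm3 = 600),
                                     seed = 13))
  tab <- derive_measures(tab)
  expect_gt(median(tab$vat_sat_ratio[tab$sex == 1]),
            median(tab$vat_sat_ratio[tab$sex == 0]))
})
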
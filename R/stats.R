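#' Homeostatic Model Assessment of Insulin Resistance (HOMA-IR)
#'
#' `HOMA-IR = fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5`.
#' Glucose given in mg/dL is converted to mmol/L by dividing by 18.0182
#' (the molar mass of glucose in mg/mmol, per dL-to-L scaling).
#'
#' @param fasting_glucose fasting glucose value(s).
#' @param fasting_insulin fasting insulin in uU/mL.
#' @param glucose_unit `"mg/dL"` or `"mmol/L"`.
#' @return Numeric HOMA-IR value(s).
#' @examples
#' homa_ir(90, 10, "mg/dL")     # ~2.22
#' homa_ir(1.0, 22.5, "mmol/L") # exactly 1
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin,
                    glucose_unit = c("mg/dL", "mmol/L")) {
  if (length(glucose_unit) != 1L && !is.character(glucose_unit))
    stopf("homa_ir: glucose_unit must be a single string")
  glucose_unit <- glucose_unit[1]
  if (!glucose_unit %in% c("mg/dL", "mmol/L"))
    stopf("homa_ir: unknown glucose unit '%s'", glucose_unit)
  bad <- !is.na(fasting_glucose) & fasting_glucose <= 0
  if (any(bad)) stopf("homa_ir: fasting glucose must be positive")
  bad <- !is.na(fasting_insulin) & fasting_insulin <= 0
  if (any(bad)) stopf("homa_ir: fasting insulin must be positive")
  glucose_mmol <- if (glucose_unit == "mg/dL") {
    fasting_glucose / 18.0182
  } else {
    fasting_glucose
  }
  fasting_insulin * glucose_mmol / 22.5
}

#' Body mass index and the obesity predicate
#'
#' `BMI = weight (kg) / height (m)^2`; obesity is a BMI of 30 kg/m2 or
#' higher (the threshold is inclusive).
#'
#' @param weight_kg body weight in kg.
#' @param height_cm standing height in cm.
#' @return For `bmi()`, BMI in kg/m2; for `is_obese()`, a logical.
#' @examples
#' bmi(100, 200)   # 25
#' is_obese(30.0)  # TRUE
#' @export
bmi <- function(weight_kg, height_cm) {
  bad <- !is.na(weight_kg) & weight_kg <= 0
  if (any(bad)) stopf("bmi: weight must be positive")
  bad <- !is.na(height_cm) & height_cm <= 0
  if (any(bad)) stopf("bmi: height must be positive")
  weight_kg / (height_cm / 100)^2
}

#' @param bmi_value BMI in kg/m2.
#' @rdname bmi
#' @export
is_obese <- function(bmi_value) bmi_value >= 30

#' Partial Spearman correlation
#'
#' Spearman rank correlation between `x` and `y` after removing the
#' rank-linear contribution of covariates: all variables are rank
#' transformed (average ranks for ties), the joint Pearson correlation
#' matrix of the ranked data is inverted, and the partial correlation is
#' read off the precision matrix:
#' \eqn{\rho_{xy.z} = -P_{xy} / \sqrt{P_{xx} P_{yy}}}. With no covariates
#' this is exactly the ordinary Spearman correlation. The p-value uses the
#' t approximation \eqn{t = \rho \sqrt{(n-2-k)/(1-\rho^2)}} on
#' \eqn{n - 2 - k} degrees of freedom (k covariates), two-sided.
#'
#' Rows with a missing value in `x`, `y` or any covariate are dropped
#' (listwise deletion); at least `k + 4` complete rows are required.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector, matrix or data.frame of
#'   covariate columns.
#' @return A list of class `spearman_partial` with `rho`, `p_value`,
#'   `n_effective`, `df` and `covariates` (names).
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  keep <- !is.na(x) & !is.na(y)
  if (k > 0L) keep <- keep & stats::complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < k + 4L)
    stopf("spearman_partial: only %d complete observations; need at least %d",
          n, k + 4L)
  if (var(x) == 0 || var(y) == 0)
    stopf("spearman_partial: zero variance in x or y after deletion")
  rx <- rank(x); ry <- rank(y)
  if (k == 0L) {
    rho <- cor(rx, ry)
  } else {
    rz <- apply(covariates[keep, , drop = FALSE], 2, rank)
    if (any(apply(rz, 2, var) == 0))
      stopf("spearman_partial: a covariate has zero variance after deletion")
    R <- cor(cbind(rx, ry, rz))
    P <- tryCatch(solve(R),
                  error = function(e)
                    stopf("spearman_partial: covariate matrix is singular (collinearity)"))
    rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  df <- n - 2L - k
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    2 * pt(abs(tstat), df, lower.tail = FALSE)
  }
  structure(list(rho = rho, p_value = max(p, .Machine$double.xmin),
                 n_effective = n, df = df,
                 covariates = if (k) colnames(covariates) else character()),
            class = "spearman_partial")
}

#' @export
print.spearman_partial <- function(x, ...) {
  cat(sprintf("Partial Spearman: rho = %.4f, p = %.4g (n = %d%s)\n",
              x$rho, x$p_value, x$n_effective,
              if (length(x$covariates))
                paste0(", covariates: ", paste(x$covariates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure at FDR level `q`: with ordered p-values p(1) <= ... <=
#' p(m), reject hypotheses 1..i* where i* is the largest i with
#' p(i) <= i q / m. Adjusted p-values are `min_{j >= i} m p(j) / j`, capped
#' at 1, and a hypothesis is rejected iff its adjusted p is at most `q`.
#'
#' @param raw_p p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @param labels optional labels for the hypotheses.
#' @return A data.frame of class `fdr_family` (input order preserved) with
#'   columns `label`, `raw_p`, `adjusted_p`, `rejected`, plus attribute `q`.
#' @export
bh_adjust <- function(raw_p, q = 0.05, labels = NULL) {
  if (q <= 0 || q >= 1) stopf("bh_adjust: q must lie in (0, 1)")
  if (length(raw_p) == 0L) {
    out <- data.frame(label = character(), raw_p = numeric(),
                      adjusted_p = numeric(), rejected = logical())
    attr(out, "q") <- q
    class(out) <- c("fdr_family", "data.frame")
    return(out)
  }
  if (any(is.na(raw_p)) || any(raw_p <= 0 | raw_p > 1))
    stopf("bh_adjust: p-values must lie in (0, 1]")
  if (is.null(labels)) labels <- paste0("H", seq_along(raw_p))
  adj <- p.adjust(raw_p, method = "BH")
  out <- data.frame(label = labels, raw_p = raw_p, adjusted_p = adj,
                    rejected = adj <= q, stringsAsFactors = FALSE)
  attr(out, "q") <- q
  class(out) <- c("fdr_family", "data.frame")
  out
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` with intercept; reports the squared
#' Pearson correlation as R2, the slope, and the two-sided slope p-value
#' from the t distribution on n - 2 degrees of freedom.
#'
#' @param x predictor; `y` response. Rows with missing values are dropped.
#' @param y response.
#' @return A list with `r_squared`, `slope`, `intercept`, `p_value`, `n`.
#' @export
linreg_summary <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stopf("linreg_summary: need at least 3 observations")
  if (var(x) == 0) stopf("linreg_summary: zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       p_value = unname(sm$coefficients[2, 4]),
       n = length(x))
}
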
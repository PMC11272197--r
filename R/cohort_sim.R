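#' Specification of a synthetic study cohort
#'
#' Describes a tabular cohort with a prescribed pairwise Spearman correlation
#' structure among its variables, generated through a Gaussian copula:
#' correlated standard normals are transformed through each variable's
#' marginal quantile function, which preserves ranks. The target Spearman
#' matrix is converted to the copula's Pearson scale with the exact bivariate
#' normal relation \eqn{r = 2 \sin(\pi \rho_s / 6)} and projected to the
#' nearest positive semi-definite correlation matrix when needed.
#'
#' Marginal families supported: `normal(mean, sd)`, `lognormal(meanlog,
#' sdlog)`, `gamma(shape, rate)`, `uniform(min, max)` and `binary(p)` (used
#' for sex; realized by thresholding the copula normal, which preserves the
#' latent rank structure).
#'
#' @param n_subjects number of rows; at least 4 (the minimum for a partial
#'   correlation with two covariates).
#' @param marginals named list, one entry per variable:
#'   `list(family = "normal", mean = 50, sd = 6)` etc. Variable order here
#'   fixes the row/column order of `target_rank_correlation`.
#' @param target_rank_correlation symmetric matrix of pairwise Spearman
#'   correlations with unit diagonal (defaults to the identity).
#' @param sex_effect named numeric: additive location shifts applied to the
#'   named variables for rows with `sex == 1` (e.g. a higher VAT/SAT ratio
#'   in males). Default none.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects,
                        marginals = default_cohort_marginals(),
                        target_rank_correlation = NULL,
                        sex_effect = NULL,
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 4L)
    stopf("cohort_spec: n_subjects must be at least 4")
  vars <- names(marginals)
  if (is.null(vars) || any(!nzchar(vars)))
    stopf("cohort_spec: marginals must be a fully named list")
  k <- length(vars)
  if (is.null(target_rank_correlation)) {
    target_rank_correlation <- diag(k)
    dimnames(target_rank_correlation) <- list(vars, vars)
  }
  tr <- as.matrix(target_rank_correlation)
  if (!isTRUE(all.equal(tr, t(tr))) || any(abs(diag(tr) - 1) > 1e-12))
    stopf("cohort_spec: target_rank_correlation must be symmetric with unit diagonal")
  if (nrow(tr) != k)
    stopf("cohort_spec: target_rank_correlation dimension does not match marginals")
  if (is.null(dimnames(tr))) dimnames(tr) <- list(vars, vars)
  if (!is.null(sex_effect)) {
    if (is.null(names(sex_effect)) || !all(names(sex_effect) %in% vars))
      stopf("cohort_spec: sex_effect must name variables present in marginals")
    if (!"sex" %in% vars)
      stopf("cohort_spec: sex_effect requires a 'sex' variable")
  }
  structure(list(n_subjects = n_subjects, marginals = marginals,
                 target_rank_correlation = tr, sex_effect = sex_effect,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default marginal distributions for a midlife imaging cohort
#'
#' Age ~ 40-60 years, roughly balanced sex, overweight-to-obese BMI range,
#' abdominal fat volumes on the litre scale, fasting glucose in mg/dL,
#' fasting insulin in uU/mL, plus one cortical-thickness and one SUVR
#' outcome. Values are chosen to be physiologically plausible for a midlife
#' obesity-enriched sample; they are conventions of the simulator, not fits.
#'
#' @return Named list of marginal specifications for [cohort_spec()].
#' @export
default_cohort_marginals <- function() {
  list(
    age = list(family = "uniform", min = 40, max = 60),
    sex = list(family = "binary", p = 0.47),
    weight = list(family = "normal", mean = 91.7, sd = 18.1),
    height = list(family = "normal", mean = 169.5, sd = 9.6),
    bmi = list(family = "normal", mean = 32.3, sd = 6.4),
    vat_cm3 = list(family = "lognormal", meanlog = log(1000), sdlog = 0.5),
    sat_cm3 = list(family = "lognormal", meanlog = log(2700), sdlog = 0.4),
    fasting_glucose = list(family = "lognormal", meanlog = log(95), sdlog = 0.18),
    fasting_insulin = list(family = "lognormal", meanlog = log(12), sdlog = 0.6),
    thickness_precuneus = list(family = "normal", mean = 2.4, sd = 0.15),
    suvr_precuneus = list(family = "lognormal", meanlog = log(1.1), sdlog = 0.15)
  )
}

marginal_quantile <- function(m, u) {
  switch(m$family,
         normal = stats::qnorm(u, m$mean, m$sd),
         lognormal = stats::qlnorm(u, m$meanlog, m$sdlog),
         gamma = stats::qgamma(u, shape = m$shape, rate = m$rate),
         uniform = stats::qunif(u, m$min, m$max),
         binary = as.numeric(u > 1 - m$p),
         stopf("unknown marginal family '%s'", m$family))
}

#' Generate a synthetic cohort table
#'
#' Draws `n_subjects` rows from the Gaussian copula described by `spec`.
#' Realized pairwise Spearman correlations converge to
#' `spec$target_rank_correlation` as the sample grows. Identical specs give
#' identical tables.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame`, one row per subject, with attribute
#'   `glucose_unit = "mg/dL"` for the default marginals.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vars <- names(spec$marginals)
  k <- length(vars)
  # exact Spearman -> Pearson conversion for the normal copula
  P <- 2 * sin(pi * spec$target_rank_correlation / 6)
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    P <- as.matrix(Matrix::nearPD(P, corr = TRUE)$mat)
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stopf("generate_cohort: target correlation is not positive semi-definite, even after adjustment")
  }
  L <- chol_psd(P)
  tab <- with_seed(spec$seed, {
    Z <- matrix(rnorm(spec$n_subjects * k), spec$n_subjects, k) %*% L
    U <- stats::pnorm(Z)
    out <- as.data.frame(lapply(seq_len(k), function(j) {
      marginal_quantile(spec$marginals[[j]], U[, j])
    }))
    names(out) <- vars
    out
  })
  if (!is.null(spec$sex_effect)) {
    males <- tab$sex == 1
    for (v in names(spec$sex_effect)) {
      tab[[v]][males] <- tab[[v]][males] + spec$sex_effect[[v]]
    }
  }
  attr(tab, "glucose_unit") <- "mg/dL"
  tab
}

# Cholesky-like factor tolerating a PSD (possibly singular) matrix
chol_psd <- function(P) {
  e <- eigen(P, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}
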
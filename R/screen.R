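#' Append derived subject-level measures to a cohort table
#'
#' Adds `bmi` (from weight/height, unless already present), `homa_ir` (from
#' fasting glucose and insulin) and `vat_sat_ratio` (from `vat_cm3` /
#' `sat_cm3`, undefined where SAT is 0 or missing) columns.
#'
#' @param cohort a cohort data.frame.
#' @param glucose_unit unit of the `fasting_glucose` column; defaults to the
#'   table's `glucose_unit` attribute, else `"mg/dL"`.
#' @return The cohort with derived columns appended.
#' @export
derive_measures <- function(cohort, glucose_unit = NULL) {
  if (is.null(glucose_unit))
    glucose_unit <- attr(cohort, "glucose_unit") %||% "mg/dL"
  if (!"bmi" %in% names(cohort) &&
      all(c("weight", "height") %in% names(cohort)))
    cohort$bmi <- bmi(cohort$weight, cohort$height)
  if (all(c("fasting_glucose", "fasting_insulin") %in% names(cohort)))
    cohort$homa_ir <- homa_ir(cohort$fasting_glucose, cohort$fasting_insulin,
                              glucose_unit)
  if (all(c("vat_cm3", "sat_cm3") %in% names(cohort)))
    cohort$vat_sat_ratio <- ifelse(!is.na(cohort$sat_cm3) & cohort$sat_cm3 > 0,
                                   cohort$vat_cm3 / cohort$sat_cm3, NA_real_)
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate-adjusted rank-correlation screen with FDR control
#'
#' For each predictor, computes the partial Spearman correlation (with the
#' given covariates) against every outcome, then applies Benjamini-Hochberg
#' FDR control within that predictor's outcome family. This reproduces the
#' shape of a predictors-by-outcomes correlation table: one rho, raw p,
#' adjusted p and rejection flag per cell. Families for which multiplicity
#' correction is deliberately not applied (e.g. strongly interdependent
#' outcome regions) can set `adjust = FALSE`, in which case cells are
#' flagged by the raw p-value.
#'
#' Stratified runs are supported through `stratify_by`: the analysis is
#' repeated within each level of the named column, dropping that column
#' from the covariates (e.g. sex-stratified analyses with age as the
#' remaining covariate).
#'
#' An alternative `method = "linear"` replaces the partial Spearman cell
#' statistic with an ordinary least-squares slope test of outcome on
#' predictor plus covariates (for use when the normality assumption is
#' judged adequate; the choice is an explicit configuration, never an
#' automatic branch on the data). `shapiro` optionally reports the
#' Shapiro-Wilk statistic of each outcome alongside.
#'
#' @param cohort a cohort data.frame.
#' @param predictors,outcomes,covariates column names.
#' @param q FDR level.
#' @param adjust apply BH within each predictor family (default TRUE).
#' @param stratify_by optional column name to stratify on.
#' @param method `"spearman_partial"` (default) or `"linear"`.
#' @param shapiro also report Shapiro-Wilk W and p per outcome.
#' @return An object of class `adipose_screen`: a data.frame with one row
#'   per predictor x outcome (x stratum) cell.
#' @export
correlation_screen <- function(cohort, predictors, outcomes,
                               covariates = c("age", "sex"), q = 0.05,
                               adjust = TRUE, stratify_by = NULL,
                               method = c("spearman_partial", "linear"),
                               shapiro = FALSE) {
  method <- match.arg(method)
  if (length(outcomes) == 0L)
    stopf("correlation_screen: outcomes list is empty")
  missing_cols <- setdiff(c(predictors, outcomes, covariates, stratify_by),
                          names(cohort))
  if (length(missing_cols))
    stopf("correlation_screen: columns not in cohort: %s",
          paste(missing_cols, collapse = ", "))
  strata <- if (is.null(stratify_by)) {
    list(all = cohort)
  } else {
    covariates <- setdiff(covariates, stratify_by)
    split(cohort, cohort[[stratify_by]])
  }
  rows <- list()
  for (sname in names(strata)) {
    dat <- strata[[sname]]
    for (pred in predictors) {
      cell <- lapply(outcomes, function(outc) {
        if (method == "spearman_partial") {
          r <- spearman_partial(dat[[pred]], dat[[outc]],
                                if (length(covariates))
                                  dat[, covariates, drop = FALSE] else NULL)
          data.frame(rho = r$rho, raw_p = r$p_value, n_effective = r$n_effective)
        } else {
          keep <- stats::complete.cases(dat[, c(pred, outc, covariates), drop = FALSE])
          d2 <- dat[keep, , drop = FALSE]
          f <- stats::as.formula(paste(outc, "~",
                                       paste(c(pred, covariates), collapse = "+")))
          sm <- summary(stats::lm(f, data = d2))
          data.frame(rho = sm$coefficients[2, 1], raw_p = sm$coefficients[2, 4],
                     n_effective = nrow(d2))
        }
      })
      fam <- do.call(rbind, cell)
      fam$predictor <- pred
      fam$outcome <- outcomes
      fam$stratum <- sname
      if (adjust) {
        bh <- bh_adjust(fam$raw_p, q = q, labels = fam$outcome)
        fam$adjusted_p <- bh$adjusted_p
        fam$rejected <- bh$rejected
      } else {
        fam$adjusted_p <- NA_real_
        fam$rejected <- fam$raw_p <= q
      }
      if (shapiro) {
        sw <- t(vapply(outcomes, function(outc) {
          v <- dat[[outc]][!is.na(dat[[outc]])]
          if (length(v) >= 3 && length(v) <= 5000 && var(v) > 0) {
            s <- stats::shapiro.test(v); c(s$statistic, s$p.value)
          } else c(NA_real_, NA_real_)
        }, numeric(2)))
        fam$shapiro_w <- sw[, 1]
        fam$shapiro_p <- sw[, 2]
      }
      rows[[length(rows) + 1L]] <- fam
    }
  }
  out <- do.call(rbind, rows)
  front <- c("stratum", "predictor", "outcome", "rho", "raw_p",
             "adjusted_p", "rejected", "n_effective")
  out <- out[, c(front, setdiff(names(out), front))]
  rownames(out) <- NULL
  attr(out, "q") <- q
  attr(out, "covariates") <- covariates
  attr(out, "method") <- method
  class(out) <- c("adipose_screen", "data.frame")
  out
}

#' @export
print.adipose_screen <- function(x, digits = 3, ...) {
  cat(sprintf("Covariate-adjusted correlation screen (%s; covariates: %s; q = %g)\n",
              attr(x, "method"),
              if (length(attr(x, "covariates")))
                paste(attr(x, "covariates"), collapse = ", ") else "none",
              attr(x, "q")))
  df <- as.data.frame(x)
  df$rho <- round(df$rho, digits)
  df$raw_p <- signif(df$raw_p, digits)
  df$adjusted_p <- signif(df$adjusted_p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a correlation screen as delimited text
#'
#' @param screen an `adipose_screen`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_screen <- function(screen, path) {
  write.csv(as.data.frame(screen), path, row.names = FALSE, na = "")
  invisible(path)
}
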
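#' Read a pipeline run configuration
#'
#' A run configuration is a YAML file (or equivalent list) with fields:
#' `subjects` (list of `id` + `image` path + optional `edits` script path),
#' `out` (output directory), optional `params` (arguments to
#' [voxa_params()]), `window` (two integers, default 4-11), `cohort_extra`
#' (CSV of per-subject tabular variables keyed by `subject`), `stats`
#' (arguments to [correlation_screen()]: predictors, outcomes, covariates,
#' q, adjust, stratify_by), `fail_fast` (logical) and `seed` (recorded in
#' provenance).
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("read_run_config: no such file '%s'", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$subjects) || length(cfg$subjects) == 0L)
    stopf("run config: no subjects listed")
  if (is.null(cfg$out)) stopf("run config: no output directory ('out')")
  for (s in cfg$subjects) {
    if (is.null(s$id) || is.null(s$image))
      stopf("run config: every subject needs an id and an image path")
    if (!file.exists(s$image) && !dir.exists(s$image))
      stopf("run config: image path '%s' for subject '%s' does not exist",
            s$image, s$id)
    if (!is.null(s$edits) && !file.exists(s$edits))
      stopf("run config: edit script '%s' does not exist", s$edits)
  }
  if (!is.null(cfg$window)) {
    w <- as.integer(cfg$window)
    if (length(w) != 2L || w[1] > w[2] || w[1] < 1L)
      stopf("run config: invalid slice window")
  }
  if (!is.null(cfg$stats$q) && (cfg$stats$q <= 0 || cfg$stats$q >= 1))
    stopf("run config: stats q must lie in (0, 1)")
  cfg
}

#' Run the full segmentation-to-statistics pipeline
#'
#' Per subject: read image, normalize, extract torso, segment fat, split
#' SAT/VAT, apply any scripted edits, compute windowed volumes, and write
#' masks and a volume report. Results are assembled into a cohort table
#' (subject, sat_cm3, vat_cm3, vat_sat_ratio, merged with any extra tabular
#' variables), derived measures are appended, and an optional correlation
#' screen is run. A failing subject is quarantined (skipped with its error
#' recorded) unless `fail_fast` is set.
#'
#' @param config a configuration list or YAML path (see
#'   [read_run_config()]).
#' @return A list of class `adiposeg_run`: `cohort`, `screen` (or NULL),
#'   `succeeded`, `failed` (named error messages), `out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- config$out
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("run_pipeline: cannot create output directory '%s'", out_dir)
  params <- do.call(voxa_params, config$params %||% list())
  window <- if (!is.null(config$window)) as.integer(config$window) else NULL
  fail_fast <- isTRUE(config$fail_fast)

  reports <- list()
  failed <- character()
  for (s in config$subjects) {
    res <- tryCatch({
      stack <- read_image(s$image)
      edits <- if (!is.null(s$edits)) read_edit_script(s$edits)
      seg <- voxa(stack, params, edits)
      vol <- compute_volumes(seg, stack, window)
      sd <- file.path(out_dir, s$id)
      write_masks(seg, sd, stack, seed = config$seed)
      write.csv(vol$per_slice_breakdown,
                file.path(sd, "per_slice_areas.csv"), row.names = FALSE)
      vol
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("subject %s: %s", s$id, conditionMessage(res))
      if (fail_fast) stopf("run_pipeline: %s", msg)
      failed[s$id] <- conditionMessage(res)
      message("quarantined ", msg)
    } else {
      reports[[s$id]] <- res
    }
  }
  if (length(reports) == 0L) stopf("run_pipeline: every subject failed")

  cohort <- do.call(rbind, lapply(names(reports), function(id) {
    cbind(subject = id, as.data.frame(reports[[id]]))
  }))
  if (!is.null(config$cohort_extra)) {
    extra <- read_cohort(config$cohort_extra)
    if (!"subject" %in% names(extra))
      stopf("run_pipeline: cohort_extra table needs a 'subject' column")
    cohort <- merge(cohort, extra, by = "subject", all.x = TRUE, sort = TRUE)
    attr(cohort, "glucose_unit") <- attr(extra, "glucose_unit")
  }
  cohort <- cohort[order(cohort$subject), ]
  rownames(cohort) <- NULL
  cohort <- derive_measures(cohort)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  screen <- NULL
  if (!is.null(config$stats)) {
    st <- config$stats
    screen <- correlation_screen(
      cohort,
      predictors = st$predictors, outcomes = st$outcomes,
      covariates = st$covariates %||% c("age", "sex"),
      q = st$q %||% 0.05,
      adjust = st$adjust %||% TRUE,
      stratify_by = st$stratify_by,
      method = st$method %||% "spearman_partial")
    write_screen(screen, file.path(out_dir, "screen.csv"))
  }
  structure(list(cohort = cohort, screen = screen,
                 succeeded = names(reports), failed = failed,
                 out = out_dir),
            class = "adiposeg_run")
}

#' @export
print.adiposeg_run <- function(x, ...) {
  cat(sprintf("<adiposeg_run> %d succeeded / %d failed -> %s\n",
              length(x$succeeded), length(x$failed), x$out))
  if (length(x$failed)) {
    for (id in names(x$failed)) cat(sprintf("  FAILED %s: %s\n", id, x$failed[id]))
  }
  invisible(x)
}
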
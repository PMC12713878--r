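#' Run the full endotyping pipeline on a flow trace and annotations
#'
#' Chains the whole method: breath segmentation, per-breath ventilation,
#' normalization to the local eupneic baseline, context tagging, windowed
#' chemoreflex drive fitting, endogram construction, trait derivation with
#' bootstrap confidence intervals, optional classification against reference
#' tertiles, and the scored-study surrogate indices. Deterministic given
#' (inputs, config, seed). Analysis failures are captured in the returned
#' report with a machine-readable code rather than thrown, so a batch run
#' can keep going.
#'
#' @param flow A flow tibble (`time_s`, `flow`), e.g. [read_flow()] output.
#' @param annotations An `annotation_set` (or coercible data frame).
#' @param cohort Optional reference cohort (`"MrOS"`, `"MESA"`, `"CMUH"`, or
#'   a custom tertile table) for trait classification.
#' @param config Named list of parameter overrides; recognized keys are the
#'   arguments of [segment_breaths()] (`min_breath_s`, `max_breath_s`,
#'   `smooth_s`), `window_s` for [normalize_to_eupnea()], the
#'   [drivefit_control()] arguments under `drivefit`, and `min_arousals`,
#'   `vmin_decile`, `boot_B` for the trait stage.
#' @param seed Seed for the bootstrap confidence intervals.
#' @return An object of class `endotype_report`: `status` (`"ok"` or
#'   `"failed"` with `code`/`message`), `metadata` (package version, config
#'   echo, seed), `night` traits with CIs and labels, `windows`, `endogram`,
#'   `surrogates`, `fit` diagnostics, and `warnings`.
#' @export
run_endotyping <- function(flow, annotations, cohort = NULL, config = list(),
                           seed = 1) {
  annotations <- as_annotations(annotations)
  cfg <- utils::modifyList(default_run_config(), config)
  warnings <- character(0)
  result <- tryCatch(
    withCallingHandlers(
      {
        breaths <- segment_breaths(
          flow,
          min_breath_s = cfg$min_breath_s, max_breath_s = cfg$max_breath_s,
          smooth_s = cfg$smooth_s
        )
        breaths <- compute_ventilation(breaths)
        breaths <- normalize_to_eupnea(breaths, window_s = cfg$window_s)
        breaths <- assign_context(breaths, annotations)
        control <- do.call(drivefit_control, cfg$drivefit)
        fit <- fit_drive_model(breaths, annotations, control)
        endo <- derive_endotypes(
          fit, annotations,
          min_arousals = cfg$min_arousals, vmin_decile = cfg$vmin_decile,
          boot_B = cfg$boot_B, boot_seed = seed
        )
        night <- if (!is.null(cohort)) classify_traits(endo, cohort) else {
          dplyr::mutate(endo$night, label = NA_character_)
        }
        surro <- surrogate_indices(annotations)
        list(breaths = breaths, fit = fit, endo = endo, night = night,
             surrogates = surro)
      },
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    endotyper_input_error = function(e) e,
    endotyper_analysis_error = function(e) e
  )

  if (inherits(result, "condition")) {
    code <- if (inherits(result, "endotyper_input_error")) "input_error" else "analysis_failure"
    return(structure(
      list(
        status = "failed", code = code, message = conditionMessage(result),
        metadata = report_metadata(cfg, seed, cohort), warnings = warnings
      ),
      class = "endotype_report"
    ))
  }

  structure(
    list(
      status = "ok", code = "ok",
      metadata = report_metadata(cfg, seed, cohort),
      night = result$night,
      windows = result$endo$windows,
      endogram = result$endo$endogram,
      surrogates = result$surrogates,
      fit = list(
        night_params = unclass(result$fit$night_params),
        n_windows_valid = result$fit$n_windows_valid,
        n_windows_candidate = result$fit$n_windows_candidate,
        n_breaths = nrow(result$breaths)
      ),
      warnings = warnings
    ),
    class = "endotype_report"
  )
}

default_run_config <- function() {
  list(
    min_breath_s = 1.5, max_breath_s = 12, smooth_s = 2, window_s = 420,
    drivefit = list(), min_arousals = 5, vmin_decile = 0.1, boot_B = 1000
  )
}

report_metadata <- function(cfg, seed, cohort) {
  list(
    package = "endotyper",
    version = as.character(packageVersion("endotyper")),
    seed = seed,
    cohort = if (is.null(cohort)) NA_character_ else if (is.data.frame(cohort)) "custom" else cohort,
    config = cfg
  )
}

#' Run the pipeline from input files
#'
#' File-based front end to [run_endotyping()]: reads the flow trace and
#' annotations, records their MD5 hashes in the report metadata, and
#' optionally loads a YAML configuration file whose top-level keys are the
#' `config` entries of [run_endotyping()] (plus `flow_channel`,
#' `check_filters`, and `cohort`).
#'
#' @param flow_path Flow CSV or EDF path.
#' @param annotations_path Annotations CSV path.
#' @param cohort Reference cohort; overrides any `cohort` in the config file.
#' @param config_path Optional YAML config path.
#' @param seed Bootstrap seed.
#' @return An `endotype_report` (see [run_endotyping()]) with input hashes in
#'   the metadata.
#' @export
run_endotyping_files <- function(flow_path, annotations_path, cohort = NULL,
                                 config_path = NULL, seed = 1) {
  cfg <- list()
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) stop_input(sprintf("config not found: %s", config_path))
    cfg <- yaml::read_yaml(config_path) %||% list()
  }
  cohort <- cohort %||% cfg$cohort
  flow <- read_flow(flow_path, flow_channel = cfg$flow_channel,
                    check_filters = isTRUE(cfg$check_filters))
  ann <- read_annotations(annotations_path)
  cfg$flow_channel <- NULL
  cfg$check_filters <- NULL
  cfg$cohort <- NULL
  report <- run_endotyping(flow, ann, cohort = cohort, config = cfg, seed = seed)
  report$metadata$inputs <- list(
    flow = list(path = flow_path, md5 = unname(tools::md5sum(flow_path))),
    annotations = list(path = annotations_path,
                       md5 = unname(tools::md5sum(annotations_path)))
  )
  report
}

#' @export
print.endotype_report <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<endotype_report> FAILED (%s): %s\n", x$code, x$message))
    return(invisible(x))
  }
  cat(sprintf("<endotype_report> ok; %d valid windows, %d breaths\n",
              x$fit$n_windows_valid, x$fit$n_breaths))
  print(as.data.frame(x$night), row.names = FALSE, digits = 4)
  if (length(x$warnings) > 0) {
    cat("warnings:\n")
    for (w in unique(x$warnings)) cat("  -", w, "\n")
  }
  invisible(x)
}

round_pct <- function(x, digits = 1) {
  ifelse(is.na(x), NA_real_, round(x, digits))
}

#' Serialize an endotype report to JSON
#'
#' Writes the report as stable, human-readable JSON (%eupnea quantities to
#' one decimal, loop gains to three); the body carries no timestamps, so the
#' same inputs, config, and seed produce a byte-identical file. The shipped
#' schema (`system.file("schema", "endotype-report.schema.json", package =
#' "endotyper")`) documents the structure.
#'
#' @param report An `endotype_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "endotype_report"))
  body <- report_body(report)
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

report_body <- function(report) {
  if (report$status != "ok") {
    return(list(status = report$status, code = report$code,
                message = report$message, metadata = report$metadata,
                warnings = as.list(report$warnings)))
  }
  night <- report$night
  pct_traits <- c("vpassive", "vmin", "vactive", "compensation", "arousal_threshold")
  fmt <- function(tr, x) ifelse(tr %in% pct_traits, round_pct(x, 1), round_pct(x, 3))
  night_out <- purrr::pmap(
    list(night$trait, night$estimate, night$ci_lo, night$ci_hi,
         night$n_windows, night$flag,
         if ("label" %in% names(night)) night$label else NA_character_),
    function(tr, est, lo, hi, nw, fl, lab) {
      list(trait = tr, estimate = fmt(tr, est), ci_lo = fmt(tr, lo),
           ci_hi = fmt(tr, hi), n_windows = nw, flag = fl, label = lab)
    }
  )
  win <- dplyr::select(report$windows, -dplyr::any_of(c("breath_idx", "drive")))
  win <- dplyr::mutate(win, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
  list(
    status = report$status,
    code = report$code,
    metadata = report$metadata,
    night_traits = night_out,
    windows = win,
    endogram = dplyr::mutate(
      tibble::as_tibble(report$endogram),
      drive_median = round_pct(.data$drive_median, 1),
      vent_median = round_pct(.data$vent_median, 1)
    ),
    surrogate_indices = lapply(as.list(report$surrogates), function(v) round(v, 3)),
    fit = report$fit,
    warnings = as.list(report$warnings)
  )
}

#' Write an endogram as CSV
#'
#' Three columns: `drive_median,vent_median,n`, one row per drive bin.
#'
#' @param endogram An endogram tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_endogram_csv <- function(endogram, path) {
  out <- tibble::tibble(
    drive_median = round_pct(endogram$drive_median, 1),
    vent_median = round_pct(endogram$vent_median, 1),
    n = endogram$n_breaths
  )
  readr::write_csv(out, path)
  invisible(path)
}
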
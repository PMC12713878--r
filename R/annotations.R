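#' Validate and normalize an annotation table
#'
#' Annotations are a single tidy table with columns `onset_s`, `duration_s`,
#' `kind` (`resp_event`, `arousal`, or `stage`) and `label`: respiratory
#' events carry their type (`obstructive_apnea`, `central_apnea`,
#' `mixed_apnea`, `hypopnea`), arousals the label `arousal`, and sleep stages
#' one of `W`, `N1`, `N2`, `N3`, `R` on a strict 30-s epoch grid. Intervals
#' are half-open `[onset, onset + duration)`, seconds from recording start.
#' Rows are sorted stably by onset within kind and validated.
#'
#' @param x A data frame with the four annotation columns.
#' @return A validated, sorted tibble of class `annotation_set`.
#' @export
as_annotations <- function(x) {
  if (inherits(x, "annotation_set")) return(x)
  if (!is.data.frame(x)) stop_input("annotations must be a data frame")
  req <- c("onset_s", "duration_s", "kind", "label")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0) {
    stop_input(paste0("annotations missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- tibble::as_tibble(x[req])
  bad_kind <- !x$kind %in% c("resp_event", "arousal", "stage")
  if (any(bad_kind)) {
    stop_input(sprintf("unknown annotation kind in row(s): %s",
                       paste(which(bad_kind), collapse = ", ")))
  }
  bad_dur <- !is.finite(x$duration_s) | x$duration_s <= 0
  if (any(bad_dur)) {
    stop_input(sprintf("non-positive duration in row(s): %s",
                       paste(which(bad_dur), collapse = ", ")))
  }
  bad_ev <- x$kind == "resp_event" & !x$label %in% resp_event_types
  if (any(bad_ev)) {
    stop_input(sprintf("unknown respiratory event label in row(s): %s",
                       paste(which(bad_ev), collapse = ", ")))
  }
  bad_st <- x$kind == "stage" & !x$label %in% sleep_stages
  if (any(bad_st)) {
    stop_input(sprintf("unknown sleep stage label in row(s): %s",
                       paste(which(bad_st), collapse = ", ")))
  }
  x <- dplyr::arrange(x, .data$kind, .data$onset_s)
  st <- x[x$kind == "stage", ]
  if (nrow(st) > 1) {
    if (any(diff(st$onset_s) <= 0)) stop_input("overlapping or duplicated stage epochs")
    on_grid <- abs(st$onset_s / 30 - round(st$onset_s / 30)) < 1e-9
    if (!all(on_grid) || any(st$duration_s != 30)) {
      stop_input("stage epochs must lie on a 30-s grid with 30-s durations")
    }
  }
  class(x) <- c("annotation_set", class(x))
  x
}

ann_events <- function(ann) ann[ann$kind == "resp_event", , drop = FALSE]
ann_arousals <- function(ann) ann[ann$kind == "arousal", , drop = FALSE]
ann_stages <- function(ann) ann[ann$kind == "stage", , drop = FALSE]

#' Build an annotation table from separate event, arousal, and stage tables
#'
#' @param events Data frame `onset_s`, `duration_s`, `type`; may be empty.
#' @param arousals Data frame `onset_s`, `duration_s`; may be empty.
#' @param stages Data frame `onset_s`, `stage` (30-s epochs).
#' @return An `annotation_set` tibble.
#' @export
make_annotations <- function(events = NULL, arousals = NULL, stages = NULL) {
  parts <- list()
  if (!is.null(events) && nrow(events) > 0) {
    parts$ev <- tibble::tibble(onset_s = events$onset_s, duration_s = events$duration_s,
                               kind = "resp_event", label = events$type)
  }
  if (!is.null(arousals) && nrow(arousals) > 0) {
    parts$ar <- tibble::tibble(onset_s = arousals$onset_s, duration_s = arousals$duration_s,
                               kind = "arousal", label = "arousal")
  }
  if (!is.null(stages) && nrow(stages) > 0) {
    parts$st <- tibble::tibble(onset_s = stages$onset_s, duration_s = 30,
                               kind = "stage", label = stages$stage)
  }
  as_annotations(dplyr::bind_rows(parts))
}
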
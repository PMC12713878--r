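#' Build an endogram (ventilation-versus-drive curve)
#'
#' Partitions breaths into equal-count bins by total-drive percentile and
#' summarizes each bin by its median drive and median ventilation. The
#' resulting curve shows how much ventilation the pharynx actually delivers
#' at each level of ventilatory drive over the night: collapsibility,
#' compensation, and the active ventilation can be read straight off it.
#'
#' @param breaths A breath tibble with `ventilation_pct`, `total_drive`, and
#'   (when `scope` is not `"all"`) `stage`.
#' @param n_bins Number of drive bins. Default: 100 (centiles) when at least
#'   1000 breaths are in scope, otherwise `max(10, floor(n / 10))`. Bins with
#'   identical drive medians are merged.
#' @param scope `"NREM"` (default) restricts to stages N1-N3; `"all"` uses
#'   every breath.
#' @return A tibble of class `endogram` with columns `drive_median`,
#'   `vent_median`, `n_breaths`, ordered by increasing drive.
#' @export
build_endogram <- function(breaths, n_bins = NULL, scope = c("NREM", "all")) {
  scope <- match.arg(scope)
  check_breaths(breaths, c("ventilation_pct", "total_drive"))
  if (scope == "NREM") {
    check_breaths(breaths, "stage")
    breaths <- breaths[breaths$stage %in% nrem_stages, , drop = FALSE]
  }
  n <- nrow(breaths)
  if (n == 0) stop_analysis("empty endogram: no breaths in scope")
  if (is.null(n_bins)) {
    n_bins <- if (n >= 1000) 100L else max(10L, n %/% 10L)
  }
  n_bins <- min(as.integer(n_bins), n)
  # deterministic under permutation: order by drive, ties broken by ventilation
  ord <- order(breaths$total_drive, breaths$ventilation_pct)
  d <- breaths$total_drive[ord]
  v <- breaths$ventilation_pct[ord]
  bin <- ceiling(seq_len(n) * n_bins / n)
  bin_med <- tapply(d, bin, median)
  # merge bins whose drive medians coincide (heavy ties) by re-keying each
  # breath to its bin's drive median before summarizing
  key <- as.numeric(bin_med[as.character(bin)])
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(key = key, v = v), .data$key),
    vent_median = median(.data$v), n_breaths = dplyr::n(), .groups = "drop"
  )
  out$drive_median <- out$key
  out <- dplyr::arrange(out, .data$drive_median)
  structure(out[, c("drive_median", "vent_median", "n_breaths")],
            class = c("endogram", class(out)))
}

#' Read ventilation off an endogram at a given drive level
#'
#' Linear interpolation of median ventilation versus median drive. Outside
#' the observed drive range the value is clamped to the nearest edge bin and
#' flagged as extrapolated rather than linearly extended, which avoids
#' unphysical ventilation estimates beyond the data.
#'
#' @param endogram An [build_endogram()] result.
#' @param drive_level Drive level(s) in %eupnea at which to evaluate.
#' @return A tibble with `drive_level`, `ventilation`, `extrapolated`.
#' @export
ventilation_at_drive <- function(endogram, drive_level) {
  if (!inherits(endogram, "endogram") || nrow(endogram) == 0) {
    stop_input("`endogram` must be a non-empty endogram")
  }
  rng <- range(endogram$drive_median)
  if (nrow(endogram) == 1) {
    v <- rep(endogram$vent_median, length(drive_level))
  } else {
    v <- approx(endogram$drive_median, endogram$vent_median,
                xout = drive_level, rule = 2, ties = "ordered")$y
  }
  tibble::tibble(
    drive_level = drive_level,
    ventilation = pmax(v, 0),
    extrapolated = drive_level < rng[1] | drive_level > rng[2]
  )
}

#' Arousal threshold: chemical drive preceding scored arousals
#'
#' For each scored arousal, takes the chemical drive of the last breath
#' ending at or before the arousal onset (skipping arousals with no such
#' breath within `max_lookback_s`); the trait is the median across arousals.
#'
#' @param breaths A breath tibble with `t_end` and `chemical_drive`.
#' @param arousals A data frame of arousals with `onset_s` (e.g.
#'   `ann_arousals()` of an annotation set, or the full annotation set).
#' @param min_arousals Minimum usable arousals for the trait to be defined.
#' @param max_lookback_s Maximum gap between breath end and arousal onset.
#' @return A list with `value` (median pre-arousal drive, `NA` when
#'   undefined), `per_arousal` (tibble of per-arousal drives), `n_usable`,
#'   and `defined`.
#' @export
arousal_threshold <- function(breaths, arousals, min_arousals = 5,
                              max_lookback_s = 30) {
  check_breaths(breaths, c("t_end", "chemical_drive"))
  if (inherits(arousals, "annotation_set") ||
      (is.data.frame(arousals) && "kind" %in% names(arousals))) {
    arousals <- ann_arousals(as_annotations(arousals))
  }
  onsets <- arousals$onset_s
  per <- purrr::map_dbl(onsets, function(on) {
    i <- findInterval(on, breaths$t_end)
    # last breath with t_end <= onset; findInterval gives t_end[i] <= on
    if (i == 0) return(NA_real_)
    if (on - breaths$t_end[i] > max_lookback_s) return(NA_real_)
    breaths$chemical_drive[i]
  })
  usable <- which(!is.na(per))
  defined <- length(usable) >= min_arousals
  list(
    value = if (defined) median(per[usable]) else NA_real_,
    per_arousal = tibble::tibble(onset_s = onsets, chemical_drive = per),
    n_usable = length(usable),
    defined = defined
  )
}
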
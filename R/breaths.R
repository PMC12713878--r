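#' Segment breaths from an airflow trace
#'
#' Detects individual breaths in a single-channel airflow signal (inspiration
#' positive, linear units). The signal is smoothed with a centered moving
#' average before negative-to-positive zero crossings mark inspiratory
#' onsets; tidal volume is the trapezoidal integral of the positive flow over
#' each inspiratory phase. A crossing that would close a breath shorter than
#' `min_breath_s` is ignored (the breaths merge); an inter-onset gap longer
#' than `max_breath_s` is split into pseudo-breaths of nominal duration with
#' zero tidal volume, so apneic stretches still contribute near-zero
#' ventilation instead of silently vanishing from the breath series.
#'
#' @param flow A data frame with columns `time_s` (uniform grid) and `flow`,
#'   e.g. from [read_flow()].
#' @param sampling_rate Sampling rate in Hz; inferred from `time_s` if `NULL`.
#'   Must be at least 10 Hz.
#' @param min_breath_s,max_breath_s Breath duration limits, seconds.
#' @param smooth_s Moving-average smoothing width, seconds.
#' @param nominal_breath_s Duration used for pseudo-breaths inside long gaps;
#'   default is the median duration of directly detected breaths.
#' @return A tibble of breath records: `t_start`, `t_insp_end`, `t_end`
#'   (seconds), `tidal_volume` (flow-units x s), and `is_pseudo` marking
#'   zero-volume filler breaths inside apneic gaps.
#' @examples
#' t <- seq(0, 60, by = 1 / 25)
#' fl <- tibble::tibble(time_s = t, flow = 0.5 * sin(2 * pi * t / 4))
#' segment_breaths(fl)
#' @export
segment_breaths <- function(flow, sampling_rate = NULL,
                            min_breath_s = 1.5, max_breath_s = 12,
                            smooth_s = 2, nominal_breath_s = NULL) {
  if (!is.data.frame(flow) || !all(c("time_s", "flow") %in% names(flow))) {
    stop_input("`flow` must be a data frame with columns `time_s` and `flow`")
  }
  t <- flow$time_s
  x <- flow$flow
  if (any(!is.finite(x))) stop_input("flow contains NaN/NA samples")
  if (length(x) < 4) stop_input("flow trace too short")
  fs <- sampling_rate %||% (1 / median(diff(t)))
  if (!is.finite(fs) || fs < 10) {
    stop_input("sampling rate must be at least 10 Hz")
  }

  # centered moving average (odd width => zero phase), edges padded by
  # replication so crossings near the record boundary are still usable
  k <- max(1L, 2L * floor(smooth_s * fs / 2) + 1L)
  if (k > 1) {
    half <- (k - 1L) / 2L
    xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
    s <- as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))
    s <- s[(half + 1L):(half + length(x))]
  } else {
    s <- x
  }

  n <- length(s)
  up <- which(s[-n] <= 0 & s[-1] > 0)
  if (length(up) < 2) {
    if (all(x <= 0)) stop_analysis("no breaths detected: flow never positive")
    stop_analysis("no breaths detected: fewer than two inspiratory onsets")
  }
  cross_t <- function(i) {
    # linear interpolation of the smoothed signal's zero crossing
    ds <- s[i + 1] - s[i]
    if (ds == 0) t[i] else t[i] - s[i] * (t[i + 1] - t[i]) / ds
  }
  onsets <- vapply(up, cross_t, numeric(1))
  # a record opening mid-inspiration starts its first breath at the record edge
  if (s[1] > 0 && onsets[1] - t[1] >= min_breath_s) {
    onsets <- c(t[1], onsets)
  }
  dn <- which(s[-n] > 0 & s[-1] <= 0)
  downs <- vapply(dn, cross_t, numeric(1))

  # merge rule: drop any onset closing a breath shorter than min_breath_s
  kept <- onsets[1]
  for (o in onsets[-1]) {
    if (o - kept[length(kept)] >= min_breath_s) kept <- c(kept, o)
  }
  starts <- kept
  ends <- c(kept[-1], min(t[length(t)], kept[length(kept)] + max_breath_s))
  durs <- ends - starts
  if (is.null(nominal_breath_s)) {
    ok <- durs <= max_breath_s
    nominal_breath_s <- if (any(ok)) median(durs[ok]) else 4
    nominal_breath_s <- min(max(nominal_breath_s, min_breath_s), max_breath_s)
  }

  # split over-long inter-onset gaps: a real breath of nominal duration, then
  # zero-volume pseudo-breaths tiling the apneic remainder
  b_start <- numeric(0)
  b_end <- numeric(0)
  b_pseudo <- logical(0)
  for (i in seq_along(starts)) {
    if (durs[i] <= max_breath_s) {
      b_start <- c(b_start, starts[i])
      b_end <- c(b_end, ends[i])
      b_pseudo <- c(b_pseudo, FALSE)
    } else {
      first_end <- starts[i] + nominal_breath_s
      rem <- ends[i] - first_end
      m <- max(1L, as.integer(round(rem / nominal_breath_s)))
      cuts <- seq(first_end, ends[i], length.out = m + 1L)
      b_start <- c(b_start, starts[i], cuts[-(m + 1L)])
      b_end <- c(b_end, cuts)
      b_pseudo <- c(b_pseudo, FALSE, rep(TRUE, m))
    }
  }

  insp_end <- vapply(seq_along(b_start), function(i) {
    if (b_pseudo[i]) return((b_start[i] + b_end[i]) / 2)
    d <- downs[downs > b_start[i] & downs < b_end[i]]
    if (length(d) > 0) d[1] else (b_start[i] + b_end[i]) / 2
  }, numeric(1))

  ia <- findInterval(b_start, t)
  ib <- findInterval(insp_end, t)
  vt <- vapply(seq_along(b_start), function(i) {
    if (b_pseudo[i]) return(0)
    integrate_positive_flow(t, x, b_start[i], insp_end[i], ia[i], ib[i])
  }, numeric(1))

  tibble::tibble(
    t_start = b_start, t_insp_end = insp_end, t_end = b_end,
    tidal_volume = vt, is_pseudo = b_pseudo
  )
}

# trapezoidal integral of max(flow, 0) over [a, b], with linearly
# interpolated boundary samples so the result does not depend on where the
# sample grid falls relative to the crossing
integrate_positive_flow <- function(t, x, a, b, i0, i1) {
  idx <- if (i1 >= i0 + 1) seq(i0 + 1, i1) else integer(0)
  idx <- idx[t[idx] > a & t[idx] < b]
  interp_at <- function(q, i) {
    i <- min(max(i, 1), length(t) - 1)
    x[i] + (x[i + 1] - x[i]) * (q - t[i]) / (t[i + 1] - t[i])
  }
  tt <- c(a, t[idx], b)
  xx <- c(interp_at(a, i0), x[idx], interp_at(b, i1))
  xx <- pmax(xx, 0)
  sum(diff(tt) * (head(xx, -1) + tail(xx, -1)) / 2)
}

#' Per-breath ventilation from tidal volume
#'
#' Ventilation is tidal volume divided by breath duration, scaled to a
#' per-minute rate: `ventilation_abs = tidal_volume * 60 / (t_end - t_start)`.
#'
#' @param breaths A breath tibble from [segment_breaths()].
#' @return `breaths` with a `ventilation_abs` column (flow-units/min).
#' @export
compute_ventilation <- function(breaths) {
  check_breaths(breaths, c("t_start", "t_end", "tidal_volume"))
  dur <- breaths$t_end - breaths$t_start
  if (any(dur <= 0)) {
    abort("internal error: zero- or negative-duration breath violates the segmentation contract")
  }
  breaths$ventilation_abs <- breaths$tidal_volume * 60 / dur
  breaths
}

#' Normalize ventilation to a local eupneic baseline
#'
#' Expresses each breath's ventilation as a percentage of the time-weighted
#' mean ventilation over a centered window (default 7 min), truncated at the
#' record edges. 100% is eupneic breathing, 0% a complete apnea, and values
#' above 100% are hyperpnea. The baseline includes all breaths, scored-event
#' breaths included.
#'
#' @param breaths A breath tibble with `ventilation_abs`.
#' @param window_s Baseline window length, seconds (default 420 = 7 min).
#' @return `breaths` with a `ventilation_pct` column (%eupnea).
#' @export
normalize_to_eupnea <- function(breaths, window_s = 420) {
  check_breaths(breaths, c("t_start", "t_end", "ventilation_abs"))
  n <- nrow(breaths)
  rec_len <- breaths$t_end[n] - breaths$t_start[1]
  if (rec_len < window_s) {
    stop_input(sprintf("record (%.0f s) shorter than the %.0f s eupnea window", rec_len, window_s))
  }
  # cumulative time-weighted integral of ventilation over breath-covered time
  knots <- c(breaths$t_start[1], breaths$t_end)
  cum_v <- c(0, cumsum(breaths$ventilation_abs * (breaths$t_end - breaths$t_start)))
  cum_t <- c(0, cumsum(breaths$t_end - breaths$t_start))
  # gaps between breaths (t_end[i] < t_start[i+1]) hold the cumulative values
  int_at <- function(q, cum) {
    # piecewise-linear within breaths, flat across gaps
    i <- findInterval(q, breaths$t_start)
    i <- pmax(pmin(i, n), 1)
    base <- cum[i]
    frac <- pmin(pmax(q - breaths$t_start[i], 0), breaths$t_end[i] - breaths$t_start[i])
    if (identical(cum, cum_t)) base + frac
    else base + frac * breaths$ventilation_abs[i]
  }
  mid <- (breaths$t_start + breaths$t_end) / 2
  lo <- pmax(mid - window_s / 2, breaths$t_start[1])
  hi <- pmin(mid + window_s / 2, breaths$t_end[n])
  num <- int_at(hi, cum_v) - int_at(lo, cum_v)
  den <- int_at(hi, cum_t) - int_at(lo, cum_t)
  mean_v <- num / den
  if (any(!is.finite(mean_v)) || any(mean_v <= 0)) {
    stop_analysis("flat signal: local eupnea baseline is zero")
  }
  breaths$ventilation_pct <- 100 * breaths$ventilation_abs / mean_v
  breaths
}

#' Tag breaths with sleep stage, event, and arousal context
#'
#' A breath is `in_event` when its interval `[t_start, t_end)` overlaps any
#' scored respiratory event, `in_arousal` when its midpoint falls inside a
#' scored arousal, and its stage comes from the 30-s epoch containing the
#' midpoint. Breaths outside the staged period are assigned stage `W` with a
#' warning.
#'
#' @param breaths A breath tibble.
#' @param annotations An annotation tibble from [read_annotations()] or
#'   [as_annotations()].
#' @param min_event_overlap_s A breath counts as in-event only when it
#'   overlaps the event interval by more than this many seconds. Breath
#'   boundaries detected from the flow signal jitter by fractions of a
#'   second against scored event edges; without a small tolerance the first
#'   recovery breath after every event — the breath that best reveals peak
#'   ventilatory drive — is excluded by a sliver of overlap.
#' @return `breaths` with `stage`, `in_event`, and `in_arousal` columns.
#' @export
assign_context <- function(breaths, annotations, min_event_overlap_s = 0.5) {
  check_breaths(breaths, c("t_start", "t_end"))
  annotations <- as_annotations(annotations)
  ev <- ann_events(annotations)
  ar <- ann_arousals(annotations)
  st <- ann_stages(annotations)

  in_event <- rep(FALSE, nrow(breaths))
  for (i in seq_len(nrow(ev))) {
    ov <- pmin(breaths$t_end, ev$onset_s[i] + ev$duration_s[i]) -
      pmax(breaths$t_start, ev$onset_s[i])
    in_event <- in_event | (ov > min_event_overlap_s)
  }
  mid <- (breaths$t_start + breaths$t_end) / 2
  in_arousal <- rep(FALSE, nrow(breaths))
  for (i in seq_len(nrow(ar))) {
    in_arousal <- in_arousal |
      (mid >= ar$onset_s[i] & mid < ar$onset_s[i] + ar$duration_s[i])
  }
  if (nrow(st) > 0) {
    i <- findInterval(mid, st$onset_s)
    stage <- ifelse(i == 0, NA_character_, st$label[pmax(i, 1)])
    beyond <- mid >= st$onset_s[nrow(st)] + st$duration_s[nrow(st)]
    stage[beyond] <- NA_character_
  } else {
    stage <- rep(NA_character_, nrow(breaths))
  }
  if (anyNA(stage)) {
    warn(sprintf("%d breath(s) outside the staged period; assigned stage W", sum(is.na(stage))))
    stage[is.na(stage)] <- "W"
  }
  breaths$stage <- stage
  breaths$in_event <- in_event
  breaths$in_arousal <- in_arousal
  breaths
}
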
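#' Endotypic traits from an endogram, drive series, and fitted model
#'
#' Reads the four endotypic traits off one analysis scope (a window or a
#' whole night): `vpassive` is the ventilation at eupneic (100%) drive,
#' `vactive` the ventilation at the arousal-threshold drive, `compensation`
#' their difference (the ventilation recovered by dilator-muscle activation
#' as drive rises), `vmin` the median ventilation of the lowest-drive decile
#' (a collapsibility measure insensitive to systematic drive bias), and
#' `lg1`/`lgn` the loop-gain magnitudes implied by the fitted chemoreflex
#' parameters.
#'
#' @param endogram An [build_endogram()] result for the scope.
#' @param arth Arousal threshold in %eupnea (`NA` if undefined).
#' @param breaths Breaths of the scope with `total_drive` and
#'   `ventilation_pct` (for `vmin`).
#' @param params Fitted [chemoreflex_params()].
#' @param identifiable Whether the fit was identifiable; when `FALSE` the
#'   loop-gain values are still reported but flagged.
#' @param vmin_decile Fraction of lowest-drive breaths defining `vmin`.
#' @param f1_cpm LG1 frequency, cycles/min.
#' @return A one-row tibble with the traits plus flag columns
#'   `arth_defined`, `lg_identifiable`, `vpassive_extrapolated`,
#'   `vactive_extrapolated`.
#' @export
compute_traits <- function(endogram, arth, breaths, params,
                           identifiable = TRUE, vmin_decile = 0.1,
                           f1_cpm = 1) {
  vp <- ventilation_at_drive(endogram, 100)
  if (is.na(arth)) {
    va <- tibble::tibble(ventilation = NA_real_, extrapolated = FALSE)
  } else {
    va <- ventilation_at_drive(endogram, arth)
  }
  comp <- va$ventilation - vp$ventilation

  n <- nrow(breaths)
  n_low <- max(1L, floor(n * vmin_decile))
  low_idx <- order(breaths$total_drive)[seq_len(n_low)]
  vmin <- median(breaths$ventilation_pct[low_idx])

  lg <- if (params$delay_s > 0) lg1_lgn(params, f1_cpm) else
    list(lg1 = loop_gain_magnitude(params, f1_cpm / 60), lgn = NA_real_)

  tibble::tibble(
    vpassive = vp$ventilation,
    vmin = vmin,
    vactive = va$ventilation,
    compensation = comp,
    arousal_threshold = arth,
    lg1 = lg$lg1,
    lgn = lg$lgn,
    arth_defined = !is.na(arth),
    lg_identifiable = identifiable,
    vpassive_extrapolated = vp$extrapolated,
    vactive_extrapolated = isTRUE(va$extrapolated[1])
  )
}

trait_names <- c("vpassive", "vmin", "vactive", "compensation",
                 "arousal_threshold", "lg1", "lgn")

#' Aggregate per-window traits to night level
#'
#' The night value of each trait is the median across valid NREM windows
#' (undefined windows excluded per trait); 95% confidence intervals come from
#' a seeded bootstrap of the median over windows (resampling windows with
#' replacement), so within-night physiological variability is carried into
#' the interval. The identity `vactive = vpassive + compensation` is enforced
#' at night level by deriving `vactive` from the night `vpassive` and
#' `compensation` medians.
#'
#' @param window_traits A tibble of per-window traits from [compute_traits()]
#'   (one row per window).
#' @param boot_B Bootstrap replicates (default 1000).
#' @param boot_seed Seed for the bootstrap RNG (reproducible bit-exact).
#' @return A tibble with one row per trait: `trait`, `estimate`, `ci_lo`,
#'   `ci_hi`, `n_windows`, `flag` (`""`, `"undefined"`, `"single_window"`,
#'   or `"not_identifiable"`).
#' @export
aggregate_night <- function(window_traits, boot_B = 1000, boot_seed = 1) {
  if (!is.data.frame(window_traits) || nrow(window_traits) == 0) {
    stop_analysis("zero valid windows: no per-window traits to aggregate")
  }
  boot_ci <- function(x) {
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    meds <- vapply(seq_len(boot_B), function(b) {
      median(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    unname(quantile(meds, c(0.025, 0.975), type = 7))
  }
  rows <- withr::with_seed(boot_seed, {
    purrr::map(trait_names, function(tr) {
      x <- window_traits[[tr]]
      if (tr %in% c("lg1", "lgn")) {
        usable <- x[!is.na(x) & window_traits$lg_identifiable]
        flag_extra <- if (any(!window_traits$lg_identifiable)) "not_identifiable" else ""
      } else {
        usable <- x[!is.na(x)]
        flag_extra <- ""
      }
      if (length(usable) == 0) {
        return(tibble::tibble(trait = tr, estimate = NA_real_, ci_lo = NA_real_,
                              ci_hi = NA_real_, n_windows = 0L, flag = "undefined"))
      }
      ci <- boot_ci(usable)
      flag <- if (length(usable) == 1) "single_window" else flag_extra
      tibble::tibble(trait = tr, estimate = median(usable), ci_lo = ci[1],
                     ci_hi = ci[2], n_windows = length(usable), flag = flag)
    })
  })
  night <- dplyr::bind_rows(rows)
  # enforce the vactive = vpassive + compensation identity at night level
  vp <- night$estimate[night$trait == "vpassive"]
  cp <- night$estimate[night$trait == "compensation"]
  if (!is.na(vp) && !is.na(cp)) {
    night$estimate[night$trait == "vactive"] <- vp + cp
  }
  night
}

#' Derive endotypic traits from a fitted night
#'
#' Runs the full trait derivation on a [fit_drive_model()] result: for each
#' valid window, the window's own drive series feeds a window endogram, the
#' pre-arousal chemical drives give the window arousal threshold, and
#' [compute_traits()] reads off the traits; [aggregate_night()] then forms
#' night medians with bootstrap confidence intervals. A night-scope endogram
#' over all NREM breaths (night-median parameters) is attached for reporting
#' and plotting.
#'
#' @param fit A `drivefit_night` object.
#' @param annotations The `annotation_set` used for the fit.
#' @param min_arousals Minimum usable arousals for the night arousal
#'   threshold to be considered defined.
#' @param vmin_decile Lowest-drive fraction defining `vmin`.
#' @param arousal_blank_s Breaths whose midpoint falls inside a scored
#'   arousal or within this many seconds after it are excluded from the
#'   endogram and `vmin`: the arousal opens the airway, so those breaths
#'   describe open-airway breathing, not the sleeping pharynx the traits
#'   characterize. They would otherwise sit on the ventilation = drive
#'   identity line and bias `vpassive` and `vactive` toward the drive axis.
#' @param boot_B,boot_seed Bootstrap settings for [aggregate_night()].
#' @return An object of class `endotype_set`: `windows` (per-window trait
#'   table), `night` (trait, estimate, CI, flag), `endogram` (night-scope),
#'   `arousal` (per-arousal drives at night scope), and `params`.
#' @export
derive_endotypes <- function(fit, annotations, min_arousals = 5,
                             vmin_decile = 0.1, arousal_blank_s = 10,
                             boot_B = 1000, boot_seed = 1) {
  stopifnot(inherits(fit, "drivefit_night"))
  annotations <- as_annotations(annotations)
  ar <- ann_arousals(annotations)
  control <- fit$control

  # breaths opened up by an arousal (within its margins or the brief
  # post-arousal recovery) do not describe the sleeping airway
  mid <- (fit$breaths$t_start + fit$breaths$t_end) / 2
  open_by_arousal <- rep(FALSE, nrow(fit$breaths))
  for (i in seq_len(nrow(ar))) {
    open_by_arousal <- open_by_arousal |
      (mid >= ar$onset_s[i] &
         mid < ar$onset_s[i] + ar$duration_s[i] + arousal_blank_s)
  }

  win_rows <- purrr::map(seq_len(nrow(fit$windows)), function(w) {
    idx <- fit$windows$breath_idx[[w]]
    br <- fit$breaths[idx, ]
    # calibrate ventilation and drive to true-eupnea units using the
    # window fit's eupneic fixed point (see drivefit_control(scale_range))
    sc <- fit$windows$scale_c[w]
    br$ventilation_pct <- sc * br$ventilation_pct
    br$chemical_drive <- sc * fit$windows$drive[[w]]$chemical_drive
    br$total_drive <- sc * fit$windows$drive[[w]]$total_drive
    br_sleep <- br[!open_by_arousal[idx], , drop = FALSE]
    if (nrow(br_sleep) < 10) br_sleep <- br
    endo <- build_endogram(br_sleep, scope = "all")
    ar_w <- ar[ar$onset_s >= fit$windows$win_start[w] &
                 ar$onset_s < fit$windows$win_end[w], , drop = FALSE]
    th <- arousal_threshold(br, ar_w, min_arousals = 1)
    params <- chemoreflex_params(fit$windows$gain[w], fit$windows$tau_s[w],
                                 fit$windows$delay_s[w], fit$windows$gamma[w])
    tr <- compute_traits(endo, th$value, br_sleep, params,
                         identifiable = fit$windows$identifiable[w],
                         vmin_decile = vmin_decile, f1_cpm = control$f1_cpm)
    dplyr::bind_cols(
      tibble::tibble(win_start = fit$windows$win_start[w],
                     win_end = fit$windows$win_end[w],
                     n_arousals = nrow(ar_w)),
      tr
    )
  })
  window_traits <- dplyr::bind_rows(win_rows)
  night <- aggregate_night(window_traits, boot_B = boot_B, boot_seed = boot_seed)

  # night-scope context: endogram over all NREM breaths with night-median
  # parameters, and the night-scope arousal threshold diagnostics
  night_breaths <- fit$breaths
  night_breaths$ventilation_pct <- fit$night_scale * night_breaths$ventilation_pct
  night_breaths$chemical_drive <- fit$night_scale * night_breaths$chemical_drive
  night_breaths$total_drive <- fit$night_scale * night_breaths$total_drive
  night_sleep <- night_breaths[!open_by_arousal, , drop = FALSE]
  if (nrow(night_sleep) < 10) night_sleep <- night_breaths
  night_endo <- build_endogram(night_sleep, scope = "NREM")
  night_arth <- arousal_threshold(night_breaths, ar, min_arousals = min_arousals)
  if (!night_arth$defined) {
    for (tr in c("arousal_threshold", "vactive", "compensation")) {
      i <- night$trait == tr
      if (night$flag[i] == "") {
        night$flag[i] <- sprintf("few_arousals_night (%d usable)", night_arth$n_usable)
      }
    }
  }
  structure(
    list(
      windows = window_traits,
      night = night,
      endogram = night_endo,
      arousal = night_arth,
      params = fit$night_params
    ),
    class = "endotype_set"
  )
}

#' @export
print.endotype_set <- function(x, ...) {
  cat(sprintf("<endotype_set> night medians over %d window(s):\n",
              max(x$night$n_windows)))
  print(as.data.frame(x$night), row.names = FALSE, digits = 4)
  invisible(x)
}
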
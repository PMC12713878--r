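#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-span drive fit
#'
#' @param x A `drivefit` object.
#' @param ... Unused.
#' @return A one-row tibble of fitted parameters and fit diagnostics.
#' @method tidy drivefit
#' @export
tidy.drivefit <- function(x, ...) {
  tibble::tibble(
    gain = x$params$gain_G, tau_s = x$params$tau_s,
    delay_s = x$params$delay_s, gamma = x$params$arousal_gamma,
    sse = x$sse, n_fit_breaths = x$n_fit_breaths,
    identifiable = x$identifiable
  )
}

#' Tidy a night-level drive fit (one row per window)
#'
#' @param x A `drivefit_night` object.
#' @param ... Unused.
#' @return A tibble of per-window fitted parameters.
#' @method tidy drivefit_night
#' @export
tidy.drivefit_night <- function(x, ...) {
  dplyr::select(x$windows, -dplyr::any_of(c("breath_idx", "drive")))
}

#' Night-level summary of a drive fit
#'
#' @param x A `drivefit_night` object.
#' @param ... Unused.
#' @return A one-row tibble with the night-median parameters, implied loop
#'   gains, and window counts.
#' @method glance drivefit_night
#' @export
glance.drivefit_night <- function(x, ...) {
  lg <- if (x$night_params$delay_s > 0) lg1_lgn(x$night_params, x$control$f1_cpm)
        else list(lg1 = loop_gain_magnitude(x$night_params, x$control$f1_cpm / 60),
                  lgn = NA_real_, fn_cpm = NA_real_)
  tibble::tibble(
    gain = x$night_params$gain_G, tau_s = x$night_params$tau_s,
    delay_s = x$night_params$delay_s, gamma = x$night_params$arousal_gamma,
    lg1 = lg$lg1, lgn = lg$lgn, fn_cpm = lg$fn_cpm,
    n_windows_valid = x$n_windows_valid,
    n_windows_candidate = x$n_windows_candidate
  )
}

#' Tidy an endotype set (per-window trait values)
#'
#' @param x An `endotype_set`.
#' @param ... Unused.
#' @return The per-window trait tibble.
#' @method tidy endotype_set
#' @export
tidy.endotype_set <- function(x, ...) x$windows

#' One-row night summary of an endotype set
#'
#' @param x An `endotype_set`.
#' @param ... Unused.
#' @return A one-row wide tibble of night trait estimates.
#' @method glance endotype_set
#' @export
glance.endotype_set <- function(x, ...) {
  est <- setNames(x$night$estimate, x$night$trait)
  dplyr::bind_cols(
    tibble::as_tibble(as.list(est)),
    tibble::tibble(n_windows = max(x$night$n_windows))
  )
}
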
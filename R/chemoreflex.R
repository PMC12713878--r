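#' Chemoreflex model parameters
#'
#' Bundles the parameters of the delayed first-order chemoreflex model of
#' ventilatory control. Writing ventilation and chemical drive as percentages
#' of eupnea, the drive deviation `d(t) = drive(t) - 100` obeys
#' `tau_s * d'(t) + d(t) = gain_G * u(t)` with disturbance
#' `u(t) = 100 - ventilation(t - delay_s)`. During scored arousals an
#' additional wakefulness drive `arousal_gamma` is added on top of the
#' chemical drive.
#'
#' @param gain_G Steady-state chemoreflex gain (dimensionless, \eqn{\ge 0}):
#'   percent drive change per percent sustained ventilation change.
#' @param tau_s Time constant of the chemoreflex response, seconds (> 0).
#' @param delay_s Pure circulatory/neural delay, seconds (\eqn{\ge 0}).
#' @param arousal_gamma Ventilatory response to arousal, %eupnea (\eqn{\ge 0}).
#' @return An object of class `chemoreflex_params`.
#' @examples
#' chemoreflex_params(gain_G = 3, tau_s = 60, delay_s = 10)
#' @export
chemoreflex_params <- function(gain_G, tau_s, delay_s, arousal_gamma = 0) {
  if (!is.numeric(gain_G) || length(gain_G) != 1 || !is.finite(gain_G) || gain_G < 0) {
    stop_input("`gain_G` must be a single finite number >= 0")
  }
  if (!is.numeric(tau_s) || length(tau_s) != 1 || !is.finite(tau_s) || tau_s <= 0) {
    stop_input("`tau_s` must be a single finite number > 0")
  }
  if (!is.numeric(delay_s) || length(delay_s) != 1 || !is.finite(delay_s) || delay_s < 0) {
    stop_input("`delay_s` must be a single finite number >= 0")
  }
  if (!is.numeric(arousal_gamma) || length(arousal_gamma) != 1 ||
      !is.finite(arousal_gamma) || arousal_gamma < 0) {
    stop_input("`arousal_gamma` must be a single finite number >= 0")
  }
  structure(
    list(gain_G = gain_G, tau_s = tau_s, delay_s = delay_s,
         arousal_gamma = arousal_gamma),
    class = "chemoreflex_params"
  )
}

#' @export
print.chemoreflex_params <- function(x, ...) {
  cat(sprintf(
    "<chemoreflex_params> gain = %.3g, tau = %.3g s, delay = %.3g s, arousal response = %.3g %%eupnea\n",
    x$gain_G, x$tau_s, x$delay_s, x$arousal_gamma
  ))
  invisible(x)
}

# Unit-gain chemoreflex filter evaluated at breath starts, vectorized over a
# set of time constants for one delay.
#
# The disturbance u(t) = 100 - vent(t - delay) is piecewise constant, stepping
# at (breath start + delay); before the first delayed breath start u = 0
# (ventilation assumed eupneic before the record). Between step times the ODE
# tau d' + d = u has the exact solution d(t0 + h) = u + (d(t0) - u) e^{-h/tau},
# so the update is exact for the piecewise-constant input, whatever the grid.
# Returns a length(ts) x length(taus) matrix of unit-gain drive deviations
# evaluated at breath starts, starting from d = 0 at the first breath.
chemo_filter_bank <- function(ts, vent_pct, delay_s, taus) {
  n <- length(ts)
  u_step_t <- ts + delay_s
  u_step_v <- 100 - vent_pct
  knots <- sort(unique(c(ts, u_step_t)))
  knots <- knots[knots >= ts[1] & knots <= ts[n]]
  # constant u on [knots[j], knots[j+1]) taken from the step active at knots[j]
  iu <- findInterval(knots, u_step_t)
  u <- ifelse(iu == 0, 0, u_step_v[pmax(iu, 1)])
  h <- diff(knots)
  is_eval <- knots %in% ts
  eval_row <- match(ts, knots)

  ntau <- length(taus)
  out <- matrix(0, nrow = n, ncol = ntau)
  d <- numeric(ntau)
  decay <- exp(-outer(h, taus, "/")) # n_intervals x ntau
  row_at <- integer(length(knots))
  row_at[eval_row] <- seq_len(n)
  if (row_at[1] > 0) out[row_at[1], ] <- d
  for (j in seq_along(h)) {
    d <- u[j] + (d - u[j]) * decay[j, ]
    r <- row_at[j + 1]
    if (r > 0) out[r, ] <- d
  }
  out
}

#' Chemical drive from ventilation via the chemoreflex model
#'
#' Runs the delayed first-order chemoreflex model over a breath series,
#' producing the chemical component of ventilatory drive for each breath.
#' Ventilation is treated as constant over each breath (stepping at
#' inspiratory onsets), the delayed first-order dynamics are integrated
#' exactly between step times, and drive is evaluated at each breath's
#' inspiratory onset. Output is clamped at 0 unless `clamp = FALSE`.
#'
#' @param breaths A breath tibble with `t_start` and `ventilation_pct`.
#' @param params A [chemoreflex_params()] object.
#' @param clamp Clamp chemical drive at 0 (default `TRUE`). `FALSE` gives the
#'   raw linear-model output used inside the least-squares fit.
#' @return `breaths` with a `chemical_drive` column (%eupnea).
#' @examples
#' br <- tibble::tibble(t_start = seq(0, 396, 4), ventilation_pct = 100)
#' br <- chemoreflex_response(br, chemoreflex_params(3, 60, 10))
#' all(br$chemical_drive == 100)
#' @export
chemoreflex_response <- function(breaths, params, clamp = TRUE) {
  check_breaths(breaths, c("t_start", "ventilation_pct"))
  stopifnot(inherits(params, "chemoreflex_params"))
  ts <- breaths$t_start
  if (any(!is.finite(ts)) || is.unsorted(ts, strictly = TRUE)) {
    stop_input("breath start times must be finite and strictly increasing")
  }
  if (any(!is.finite(breaths$ventilation_pct))) {
    stop_input("`ventilation_pct` contains non-finite values")
  }
  uhat <- chemo_filter_bank(ts, breaths$ventilation_pct, params$delay_s, params$tau_s)[, 1]
  drive <- 100 + params$gain_G * uhat
  if (clamp) drive <- pmax(drive, 0)
  breaths$chemical_drive <- drive
  breaths
}

#' Loop-gain magnitude at a given frequency
#'
#' Amplitude ratio of the fitted chemoreflex transfer function
#' \eqn{|H(f)| = G / \sqrt{1 + (2\pi f \tau)^2}}: the size of the drive
#' response elicited by a sinusoidal ventilation disturbance at frequency `f`.
#' The pure delay shifts phase only and does not change the magnitude.
#'
#' @param params A [chemoreflex_params()] object.
#' @param f Frequency in cycles per second (Hz), > 0 (vectorized).
#' @return Dimensionless loop-gain magnitude(s).
#' @examples
#' loop_gain_magnitude(chemoreflex_params(3, 60, 10), f = 1 / 60)
#' @export
loop_gain_magnitude <- function(params, f) {
  stopifnot(inherits(params, "chemoreflex_params"))
  if (any(!is.finite(f)) || any(f <= 0)) stop_input("`f` must be > 0")
  params$gain_G / sqrt(1 + (2 * pi * f * params$tau_s)^2)
}

# phase lag (positive radians) of the chemoreflex transfer function
chemo_phase_lag <- function(f, tau_s, delay_s) {
  atan(2 * pi * f * tau_s) + 2 * pi * f * delay_s
}

#' Natural frequency of the ventilatory control loop
#'
#' The frequency at which the chemoreflex feedback phase lag
#' \eqn{\arctan(2\pi f \tau) + 2\pi f \delta} reaches 180 degrees, i.e. where
#' a disturbance is fed back in phase and periodic breathing can
#' self-sustain. Unique because the phase lag is strictly increasing in `f`;
#' found by bracketed root finding polished with Newton steps.
#'
#' @param params A [chemoreflex_params()] object with `delay_s > 0`.
#' @return Natural frequency in cycles per minute.
#' @examples
#' natural_frequency(chemoreflex_params(3, 60, 10))
#' @export
natural_frequency <- function(params) {
  stopifnot(inherits(params, "chemoreflex_params"))
  tau <- params$tau_s
  delta <- params$delay_s
  if (delta <= 0) {
    stop_analysis("no phase crossing: the phase lag never reaches 180 degrees when delay_s = 0")
  }
  g <- function(f) chemo_phase_lag(f, tau, delta) - pi
  hi <- 1 / (2 * delta) # 2*pi*f*delta = pi there, so g(hi) > 0
  f <- uniroot(g, lower = 1e-12, upper = hi, tol = 1e-14)$root
  # Newton polish to drive the phase residual to machine precision
  for (i in 1:8) {
    gp <- 2 * pi * tau / (1 + (2 * pi * f * tau)^2) + 2 * pi * delta
    step <- g(f) / gp
    f <- f - step
    if (abs(step) < 1e-16 * f) break
  }
  60 * f
}

#' Loop gain at one cycle per minute and at the natural frequency
#'
#' `LG1` is the loop-gain magnitude at 1 cycle/min (close to the cycling rate
#' of typical obstructive event sequences); `LGn` is the magnitude at the
#' loop's natural (180-degree phase) frequency, where instability actually
#' develops. Frequency conventions follow the established polysomnographic
#' endotyping literature and `f1_cpm` is overridable.
#'
#' @param params A [chemoreflex_params()] object.
#' @param f1_cpm Frequency for LG1 in cycles per minute (default 1).
#' @return A named list with `lg1`, `lgn`, and `fn_cpm` (natural frequency).
#' @examples
#' lg1_lgn(chemoreflex_params(3, 60, 10))
#' @export
lg1_lgn <- function(params, f1_cpm = 1) {
  stopifnot(inherits(params, "chemoreflex_params"))
  lg1 <- loop_gain_magnitude(params, f1_cpm / 60)
  fn <- natural_frequency(params)
  lgn <- loop_gain_magnitude(params, fn / 60)
  list(lg1 = lg1, lgn = lgn, fn_cpm = fn)
}
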
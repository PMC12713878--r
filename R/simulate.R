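#' Configuration for the closed-loop ventilatory-control simulator
#'
#' Defines one simulated sleep study: a chemoreflex feedback loop (gain, time
#' constant, circulatory delay, and a wakefulness drive added during
#' arousal), an airway that converts intended ventilation (drive) into
#' achieved ventilation (`vpassive_true` at eupneic drive, rising with slope
#' `comp_slope` above it, floored at 0), arousals triggered when chemical
#' drive reaches `threshold_true`, breath-level multiplicative lognormal
#' noise, and automatic event scoring of the noiseless achieved ventilation.
#' All drives and ventilations are in %eupnea of the programmed eupneic
#' level.
#'
#' @param duration_s Recording length, seconds.
#' @param breath_period_s Breath duration, seconds.
#' @param gain_G,tau_s,delay_s Chemoreflex parameters (see
#'   [chemoreflex_params()]); `delay_s` must be positive so the loop has a
#'   natural frequency.
#' @param arousal_gamma Wakefulness drive added during arousal, %eupnea.
#' @param vpassive_true Achieved ventilation at eupneic drive through the
#'   obstructed airway, %eupnea.
#' @param comp_slope Increase in achieved ventilation per unit drive above
#'   eupnea (dimensionless, in \[-1, 1\]).
#' @param threshold_true Chemical drive triggering arousal, %eupnea
#'   (\eqn{\ge} 100).
#' @param arousal_duration_s Arousal length, seconds.
#' @param post_arousal_airway_open_s Extra time the airway stays open after
#'   an arousal ends (recovery hyperpnea).
#' @param noise_sd Standard deviation of the multiplicative lognormal breath
#'   noise (on the log scale, mean-one correction applied).
#' @param eupneic_ventilation_abs Eupneic ventilation in absolute flow
#'   units/min, used to scale the synthesized flow signal.
#' @param sampling_rate Flow sampling rate, Hz.
#' @param stage_schedule Data frame `onset_s`, `stage` of 30-s epochs;
#'   default is all N2 for the whole recording.
#' @param hypopnea_frac,apnea_frac,min_event_s Auto-scoring rule: maximal
#'   runs with ventilation below `hypopnea_frac * 100` lasting at least
#'   `min_event_s` become events; an event whose minimum ventilation falls
#'   below `apnea_frac * 100` is an apnea, otherwise a hypopnea.
#' @param seed Default RNG seed used by [simulate_night()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 7200, breath_period_s = 4,
                       gain_G = 4, tau_s = 45, delay_s = 8,
                       arousal_gamma = 20,
                       vpassive_true = 50, comp_slope = 0.1,
                       threshold_true = 150, arousal_duration_s = 10,
                       post_arousal_airway_open_s = 5,
                       noise_sd = 0.05, eupneic_ventilation_abs = 7.5,
                       sampling_rate = 25, stage_schedule = NULL,
                       hypopnea_frac = 0.7, apnea_frac = 0.1,
                       min_event_s = 10, seed = 1) {
  cfg <- list(
    duration_s = duration_s, breath_period_s = breath_period_s,
    gain_G = gain_G, tau_s = tau_s, delay_s = delay_s,
    arousal_gamma = arousal_gamma, vpassive_true = vpassive_true,
    comp_slope = comp_slope, threshold_true = threshold_true,
    arousal_duration_s = arousal_duration_s,
    post_arousal_airway_open_s = post_arousal_airway_open_s,
    noise_sd = noise_sd, eupneic_ventilation_abs = eupneic_ventilation_abs,
    sampling_rate = sampling_rate, stage_schedule = stage_schedule,
    hypopnea_frac = hypopnea_frac, apnea_frac = apnea_frac,
    min_event_s = min_event_s, seed = seed
  )
  stopifnot(duration_s > 0, breath_period_s > 0, gain_G >= 0, tau_s > 0,
            delay_s > 0, arousal_gamma >= 0, vpassive_true >= 0,
            threshold_true >= 100, arousal_duration_s > 0,
            post_arousal_airway_open_s >= 0, noise_sd >= 0,
            eupneic_ventilation_abs > 0, sampling_rate >= 10)
  if (abs(comp_slope) > 1) stop_input("`comp_slope` must lie in [-1, 1]")
  if (1 + gain_G * comp_slope <= 0) {
    stop_input(paste0(
      "unstable configuration: comp_slope <= -1/gain_G makes the obstructed ",
      "airway a runaway positive-feedback loop (drive diverges)"
    ))
  }
  structure(cfg, class = "sim_config")
}

#' Ground-truth traits implied by a simulator configuration
#'
#' @param cfg A [sim_config()].
#' @return A list with the programmed `vpassive`, `compensation`, `vactive`,
#'   `arousal_threshold`, `lg1`, `lgn`, and `fn_cpm`.
#' @export
sim_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  comp <- cfg$comp_slope * (cfg$threshold_true - 100)
  lg <- lg1_lgn(chemoreflex_params(cfg$gain_G, cfg$tau_s, cfg$delay_s,
                                   cfg$arousal_gamma))
  list(
    vpassive = cfg$vpassive_true,
    compensation = comp,
    vactive = cfg$vpassive_true + comp,
    arousal_threshold = cfg$threshold_true,
    lg1 = lg$lg1,
    lgn = lg$lgn,
    fn_cpm = lg$fn_cpm
  )
}

#' Simulate one night of closed-loop breathing
#'
#' Iterates breath by breath: chemical drive follows the same delayed
#' first-order chemoreflex dynamics as [chemoreflex_response()], driven by
#' the achieved (noisy) ventilation it produced; the airway turns total drive
#' into achieved ventilation (open during wake, arousal, and a short
#' post-arousal interval; otherwise `vpassive_true + comp_slope * (D - 100)`
#' above eupneic drive and `min(D, vpassive_true)` below it); an arousal
#' starts when chemical drive reaches `threshold_true`, lasts
#' `arousal_duration_s`, and adds `arousal_gamma` to the drive. The achieved
#' ventilation gets multiplicative lognormal noise, a half-sine flow signal
#' is synthesized per breath, respiratory events are auto-scored from the
#' noiseless ventilation, and arousals/stages become annotations. The whole
#' run is reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return A list of class `psg_simulation`: `flow` (tibble `time_s`,
#'   `flow`), `annotations` (`annotation_set`), `truth` (ground-truth traits
#'   plus scored counts), `breaths` (per-breath truth table with chemical and
#'   total drive, achieved clean/noisy ventilation, arousal and airway
#'   state), and `config`.
#' @export
simulate_night <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  T_b <- cfg$breath_period_s
  n <- floor(cfg$duration_s / T_b)
  if (n < 10) stop_input("duration too short for a simulated night")
  ts <- (seq_len(n) - 1) * T_b
  tshift <- ts + cfg$delay_s

  st <- cfg$stage_schedule
  if (is.null(st)) {
    st <- tibble::tibble(onset_s = seq(0, cfg$duration_s - 30, by = 30), stage = "N2")
  }
  stage_at <- function(t) {
    i <- findInterval(t, st$onset_s)
    st$stage[pmax(i, 1)]
  }

  z <- withr::with_seed(seed, rnorm(n))
  noise_fac <- exp(cfg$noise_sd * z - cfg$noise_sd^2 / 2)

  d <- 0 # chemical drive deviation at current breath start
  arousal_until <- -Inf
  open_until <- -Inf
  arousal_onsets <- numeric(0)
  D_chem <- numeric(n)
  D_tot <- numeric(n)
  V_clean <- numeric(n)
  V_noisy <- numeric(n)
  aroused <- logical(n)
  airway_open <- logical(n)
  stage_b <- stage_at(ts)

  G <- cfg$gain_G
  tau <- cfg$tau_s
  p <- 1L # pointer into tshift for the delayed-input breakpoints
  for (k in seq_len(n)) {
    t0 <- ts[k]
    t1 <- t0 + T_b
    D_chem[k] <- 100 + d
    if (!is.finite(d) || abs(d) > 1e7) {
      stop_analysis("simulated drive diverged; configuration is unstable")
    }
    asleep <- stage_b[k] != "W"
    if (asleep && t0 >= arousal_until && D_chem[k] >= cfg$threshold_true) {
      arousal_onsets <- c(arousal_onsets, t0)
      arousal_until <- t0 + cfg$arousal_duration_s
      open_until <- arousal_until + cfg$post_arousal_airway_open_s
    }
    aroused[k] <- t0 < arousal_until
    D_tot[k] <- D_chem[k] + cfg$arousal_gamma * aroused[k]
    airway_open[k] <- aroused[k] || !asleep || t0 < open_until
    V_clean[k] <- if (airway_open[k]) {
      max(D_tot[k], 0)
    } else if (D_tot[k] >= 100) {
      max(0, cfg$vpassive_true + cfg$comp_slope * (D_tot[k] - 100))
    } else {
      min(max(D_tot[k], 0), cfg$vpassive_true)
    }
    V_noisy[k] <- V_clean[k] * noise_fac[k]

    # advance the chemoreflex state over [t0, t1], splitting at the delayed
    # breath-onset times so the piecewise-constant input is integrated exactly
    while (p <= n && tshift[p] <= t0) p <- p + 1L
    seg_start <- t0
    pp <- p
    while (pp <= n && tshift[pp] <= t1) {
      if (tshift[pp] > seg_start) {
        i_u <- pp - 1L
        u <- if (i_u < 1) 0 else 100 - V_noisy[i_u]
        h <- tshift[pp] - seg_start
        d <- G * u + (d - G * u) * exp(-h / tau)
        seg_start <- tshift[pp]
      }
      pp <- pp + 1L
    }
    if (t1 > seg_start) {
      i_u <- pp - 1L
      u <- if (i_u < 1) 0 else 100 - V_noisy[i_u]
      h <- t1 - seg_start
      d <- G * u + (d - G * u) * exp(-h / tau)
    }
  }

  breaths <- tibble::tibble(
    t_start = ts, t_end = ts + T_b,
    stage = stage_b,
    chemical_drive = D_chem, total_drive = D_tot,
    aroused = aroused, airway_open = airway_open,
    ventilation_clean = V_clean, ventilation_pct = V_noisy
  )

  events <- score_events(
    tibble::tibble(t_start = ts, t_end = ts + T_b, ventilation_pct = V_clean),
    hypopnea_frac = cfg$hypopnea_frac, apnea_frac = cfg$apnea_frac,
    min_event_s = cfg$min_event_s
  )
  # score each arousal through the end of the last breath it affected, so a
  # breath is inside the scored margins exactly when it received the
  # wakefulness drive
  arousal_ends <- vapply(arousal_onsets, function(on) {
    until <- on + cfg$arousal_duration_s
    last <- max(which(ts < until))
    max(until, ts[last] + T_b)
  }, numeric(1))
  arousals <- tibble::tibble(
    onset_s = arousal_onsets,
    duration_s = arousal_ends - arousal_onsets
  )
  annotations <- make_annotations(
    events = if (nrow(events) > 0) {
      tibble::tibble(onset_s = events$onset_s, duration_s = events$duration_s,
                     type = events$type)
    } else NULL,
    arousals = if (nrow(arousals) > 0) arousals else NULL,
    stages = tibble::tibble(onset_s = st$onset_s, stage = st$stage)
  )

  flow <- synthesize_flow(ts, T_b, V_noisy, cfg$eupneic_ventilation_abs,
                          cfg$sampling_rate, cfg$duration_s)

  truth <- sim_ground_truth(cfg)
  truth$n_events_scored <- nrow(events)
  truth$n_arousals <- length(arousal_onsets)

  structure(
    list(flow = flow, annotations = annotations, truth = truth,
         breaths = breaths, config = cfg),
    class = "psg_simulation"
  )
}

#' @export
print.psg_simulation <- function(x, ...) {
  cat(sprintf(
    "<psg_simulation> %.1f h, %d breaths, %d scored events, %d arousals\n",
    x$config$duration_s / 3600, nrow(x$breaths), x$truth$n_events_scored,
    x$truth$n_arousals
  ))
  invisible(x)
}

# half-sine inspiration/expiration flow, tidal volume matched to the
# achieved ventilation of each breath
synthesize_flow <- function(ts, T_b, vent_pct, eupneic_abs, fs, duration_s) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  k <- pmin(findInterval(t, ts), length(ts))
  vt <- vent_pct / 100 * eupneic_abs * T_b / 60 # flow-units * s per breath
  amp <- vt * pi / T_b
  phase <- t - ts[k]
  half <- T_b / 2
  fl <- ifelse(phase < half,
               amp[k] * sin(pi * phase / half),
               -amp[k] * sin(pi * (phase - half) / half))
  tibble::tibble(time_s = t, flow = fl)
}

#' Auto-score respiratory events from per-breath ventilation
#'
#' Emulates human event scoring on a known ventilation series: maximal runs
#' of consecutive breaths with ventilation below `hypopnea_frac * 100`
#' lasting at least `min_event_s` become events; an event is an obstructive
#' apnea when its minimum ventilation drops below `apnea_frac * 100`,
#' otherwise a hypopnea.
#'
#' @param breaths A breath tibble with `t_start`, `t_end`,
#'   `ventilation_pct` (%eupnea of the programmed eupneic level).
#' @param hypopnea_frac,apnea_frac,min_event_s Scoring rule parameters.
#' @return A tibble of events: `onset_s`, `duration_s`, `type`.
#' @export
score_events <- function(breaths, hypopnea_frac = 0.7, apnea_frac = 0.1,
                         min_event_s = 10) {
  check_breaths(breaths, c("t_start", "t_end", "ventilation_pct"))
  low <- breaths$ventilation_pct < hypopnea_frac * 100
  if (!any(low)) {
    return(tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                          type = character(0)))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  rows <- purrr::map(keep, function(j) {
    i0 <- starts[j]
    i1 <- ends[j]
    onset <- breaths$t_start[i0]
    dur <- breaths$t_end[i1] - onset
    if (dur < min_event_s) return(NULL)
    vmin <- min(breaths$ventilation_pct[i0:i1])
    tibble::tibble(
      onset_s = onset, duration_s = dur,
      type = if (vmin < apnea_frac * 100) "obstructive_apnea" else "hypopnea"
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    tibble::tibble(onset_s = numeric(0), duration_s = numeric(0), type = character(0))
  } else {
    out
  }
}
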
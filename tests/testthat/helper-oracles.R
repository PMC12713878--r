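# Shared generators and independent oracles.

# Fine-step RK4 integration of the chemoreflex ODE
#   tau d'(t) + d(t) = G (100 - vent(t - delay))
# with vent piecewise constant on breath intervals (steps at breath starts,
# vent = 100 before the record). Returns drive (100 + d) evaluated at each
# breath start. Independent of the package's knot-based exponential updates.
ode_drive_oracle <- function(t_start, vent_pct, gain_G, tau_s, delay_s,
                             dt = 0.01) {
  u_at <- function(t) {
    i <- findInterval(t - delay_s, t_start)
    if (i < 1) 0 else 100 - vent_pct[i]
  }
  t0 <- t_start[1]
  t_end <- t_start[length(t_start)]
  # march RK4 inside intervals where the (piecewise-constant) input cannot
  # change, so no step straddles a discontinuity
  knots <- sort(unique(c(t_start, t_start + delay_s)))
  knots <- c(knots[knots > t0 & knots < t_end], t_end)
  d <- 0
  out <- numeric(length(t_start))
  out[1] <- 100
  nxt <- 2
  t <- t0
  for (kn in knots) {
    u <- u_at(t + 1e-9)
    m <- max(1L, ceiling((kn - t) / dt))
    h <- (kn - t) / m
    for (s in seq_len(m)) {
      k1 <- (gain_G * u - d) / tau_s
      k2 <- (gain_G * u - (d + h * k1 / 2)) / tau_s
      k3 <- (gain_G * u - (d + h * k2 / 2)) / tau_s
      k4 <- (gain_G * u - (d + h * k3)) / tau_s
      d <- d + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    t <- kn
    while (nxt <= length(t_start) && t >= t_start[nxt] - 1e-9) {
      out[nxt] <- 100 + d
      nxt <- nxt + 1
    }
  }
  out
}

# Self-consistent night: ventilation on non-event breaths is exactly the
# model's own total drive (sequentially constructed, so the filtered
# disturbance at breath k only involves earlier breaths). Used for exact
# parameter-recovery checks.
make_selfconsistent_breaths <- function(n = 400, breath_s = 4, gain_G = 3,
                                        tau_s = 60, delay_s = 10,
                                        gamma = 20, event_vent = 30) {
  ts <- (seq_len(n) - 1) * breath_s
  in_event <- rep(FALSE, n)
  in_arousal <- rep(FALSE, n)
  if (n >= 40) {
    for (s in seq(20, n - 20, by = 50)) in_event[s:(s + 5)] <- TRUE
    for (s in seq(27, n - 20, by = 50)) in_arousal[s:(s + 2)] <- TRUE
  } else {
    in_event[5:8] <- TRUE
    in_arousal[9:10] <- TRUE
  }
  vent <- numeric(n)
  for (k in seq_len(n)) {
    uh <- endotyper:::chemo_filter_bank(ts[1:k], c(vent[seq_len(k - 1)], 0)[1:k],
                                        delay_s, tau_s)[k, 1]
    vent[k] <- if (in_event[k]) event_vent else {
      100 + gain_G * uh + gamma * in_arousal[k]
    }
  }
  tibble::tibble(
    t_start = ts, t_end = ts + breath_s, ventilation_pct = vent,
    in_event = in_event, in_arousal = in_arousal
  )
}

# draw one acceptance-style night configuration (traits spread over the
# ranges the recovery study covers), deterministically from its seed
draw_recovery_config <- function(s, duration_s = 7200) {
  set.seed(s)
  lg1_true <- runif(1, 0.4, 0.8)
  tau <- runif(1, 30, 90)
  delta <- runif(1, 5, 15)
  gain <- lg1_true * sqrt(1 + (2 * pi * tau / 60)^2)
  sim_config(
    duration_s = duration_s,
    vpassive_true = runif(1, 40, 90),
    threshold_true = runif(1, 120, 180),
    comp_slope = runif(1, -0.1, 0.4),
    gain_G = gain, tau_s = tau, delay_s = delta,
    noise_sd = 0.05, seed = s
  )
}

run_recovery_night <- function(cfg, boot_B = 100) {
  sim <- simulate_night(cfg)
  out <- try({
    br <- segment_breaths(sim$flow)
    br <- compute_ventilation(br)
    br <- normalize_to_eupnea(br)
    br <- assign_context(br, sim$annotations)
    fit <- fit_drive_model(br, sim$annotations)
    endo <- derive_endotypes(fit, sim$annotations, boot_B = boot_B,
                             boot_seed = cfg$seed)
    setNames(endo$night$estimate, endo$night$trait)
  }, silent = TRUE)
  tr <- sim$truth
  est <- if (inherits(out, "try-error")) {
    setNames(rep(NA_real_, 7), c("vpassive", "vmin", "vactive", "compensation",
                                 "arousal_threshold", "lg1", "lgn"))
  } else out
  tibble::tibble(
    seed = cfg$seed,
    vpassive_true = tr$vpassive, vpassive_est = est[["vpassive"]],
    arth_true = tr$arousal_threshold, arth_est = est[["arousal_threshold"]],
    lg1_true = tr$lg1, lg1_est = est[["lg1"]],
    comp_true = tr$compensation, comp_est = est[["compensation"]]
  )
}
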
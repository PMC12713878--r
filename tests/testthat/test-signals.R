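half_sine_flow <- function(duration_s = 600, period_s = 4, amp = 0.5, fs = 25) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  tibble::tibble(time_s = t, flow = amp * sin(2 * pi * t / period_s))
}

test_that("half-sine breathing is segmented into the right breaths and tidal volumes", {
  fl <- half_sine_flow()
  br <- segment_breaths(fl)
  expect_equal(nrow(br), 150)
  # closed form: integral of 0.5 sin(pi t / 2) over the 2-s inspiration
  vt_expected <- 2 / pi
  expect_true(all(abs(br$tidal_volume - vt_expected) / vt_expected < 0.01))
  expect_true(all(abs((br$t_end - br$t_start) - 4) < 0.2))
  br <- compute_ventilation(br)
  expect_true(all(abs(br$ventilation_abs - vt_expected * 60 / 4) / 9.549 < 0.02))
})

test_that("degenerate flow inputs are rejected", {
  t <- seq(0, 60, by = 1 / 25)
  expect_error(segment_breaths(tibble::tibble(time_s = t, flow = 0)),
               "no breaths detected")
  expect_error(segment_breaths(tibble::tibble(time_s = t, flow = -abs(sin(t)))),
               "no breaths detected")
  x <- sin(2 * pi * t / 4)
  x[100] <- NA
  expect_error(segment_breaths(tibble::tibble(time_s = t, flow = x)), "NaN|NA")
  expect_error(segment_breaths(half_sine_flow(), sampling_rate = 5), "10 Hz")
})

test_that("breaths are time-ordered, non-overlapping, and fit in the record", {
  cfg <- sim_config(duration_s = 1200, vpassive_true = 40, seed = 7)
  sim <- simulate_night(cfg)
  br <- segment_breaths(sim$flow)
  expect_true(all(diff(br$t_start) > 0))
  expect_true(all(br$t_end[-nrow(br)] <= br$t_start[-1] + 1e-9))
  expect_true(all(br$t_start < br$t_insp_end & br$t_insp_end <= br$t_end + 1e-9))
  expect_lte(sum(br$t_end - br$t_start),
             max(sim$flow$time_s) - min(sim$flow$time_s) + 1e-6)
  expect_true(all(br$tidal_volume >= 0))
})

test_that("tidal volumes agree with brute-force quadrature on each inspiration", {
  cfg <- sim_config(duration_s = 900, vpassive_true = 60, noise_sd = 0.05, seed = 3)
  sim <- simulate_night(cfg)
  br <- segment_breaths(sim$flow)
  br <- br[!br$is_pseudo & br$tidal_volume > 1e-3, ]
  fine_vt <- vapply(seq_len(nrow(br)), function(i) {
    tt <- seq(br$t_start[i], br$t_insp_end[i], length.out = 2000)
    xx <- pmax(approx(sim$flow$time_s, sim$flow$flow, xout = tt, rule = 2)$y, 0)
    sum(diff(tt) * (head(xx, -1) + tail(xx, -1)) / 2)
  }, numeric(1))
  expect_true(all(abs(br$tidal_volume - fine_vt) / fine_vt < 0.005))
})

test_that("per-breath ventilation follows tidal volume over duration", {
  br <- tibble::tibble(t_start = c(0, 4), t_insp_end = c(2, 6), t_end = c(4, 8),
                       tidal_volume = c(0.5, 0))
  v <- compute_ventilation(br)
  expect_equal(v$ventilation_abs, c(7.5, 0))
  br$t_end[1] <- 0
  expect_error(compute_ventilation(br), "segmentation contract")
})

make_even_breaths <- function(vent, breath_s = 4) {
  n <- length(vent)
  tibble::tibble(
    t_start = (seq_len(n) - 1) * breath_s,
    t_insp_end = (seq_len(n) - 1) * breath_s + breath_s / 2,
    t_end = seq_len(n) * breath_s,
    tidal_volume = vent * breath_s / 60,
    ventilation_abs = vent
  )
}

test_that("eupnea normalization gives 100% for steady breathing and the right split for alternating breathing", {
  br <- make_even_breaths(rep(8, 300))
  expect_true(all(abs(normalize_to_eupnea(br)$ventilation_pct - 100) < 1e-9))

  br2 <- make_even_breaths(rep(c(5, 10), 150))
  pct <- normalize_to_eupnea(br2)$ventilation_pct
  interior <- 60:240
  expect_true(all(abs(pct[interior][br2$ventilation_abs[interior] == 5] - 200 / 3) < 1))
  expect_true(all(abs(pct[interior][br2$ventilation_abs[interior] == 10] - 400 / 3) < 1))
})

test_that("eupnea normalization is scale-invariant and locally self-normalizing", {
  set.seed(11)
  br <- make_even_breaths(pmax(rnorm(400, 8, 2), 0))
  p1 <- normalize_to_eupnea(br)$ventilation_pct
  br_scaled <- br
  br_scaled$ventilation_abs <- br$ventilation_abs * 3.7
  br_scaled$tidal_volume <- br$tidal_volume * 3.7
  expect_equal(p1, normalize_to_eupnea(br_scaled)$ventilation_pct,
               tolerance = 1e-12)

  # a fully interior window of the normalized signal averages to ~100%
  out <- normalize_to_eupnea(br)
  mid <- (out$t_start + out$t_end) / 2
  win <- which(mid >= 800 - 210 & mid < 800 + 210)
  w <- out$t_end[win] - out$t_start[win]
  expect_lt(abs(sum(out$ventilation_pct[win] * w) / sum(w) - 100), 2)
})

test_that("an apneic breath normalizes toward 0% and lifts its neighbors", {
  vent <- rep(8, 300)
  vent[150] <- 0
  pct <- normalize_to_eupnea(make_even_breaths(vent))$ventilation_pct
  expect_lt(pct[150], 1)
  expect_gt(pct[149], 100)
  expect_gt(pct[151], 100)
})

test_that("normalization rejects too-short records and flat signals", {
  expect_error(normalize_to_eupnea(make_even_breaths(rep(8, 10))), "shorter")
  expect_error(normalize_to_eupnea(make_even_breaths(rep(0, 300))), "flat signal")
})

test_that("context tagging follows the overlap, midpoint, and epoch rules", {
  ann <- make_annotations(
    events = tibble::tibble(onset_s = 103, duration_s = 17, type = "hypopnea"),
    arousals = tibble::tibble(onset_s = 102, duration_s = 10),
    stages = tibble::tibble(onset_s = seq(0, 150, 30), stage = c("W", "N2", "N2", "N2", "N2", "N2"))
  )
  br <- tibble::tibble(
    t_start = c(28.1, 96, 100, 104),
    t_insp_end = c(30.1, 98, 102, 106),
    t_end = c(32.1, 100, 104, 108),
    tidal_volume = 1
  )
  out <- assign_context(br, ann)
  # breath [100,104) overlaps event [103,120) by 1 s -> in event
  expect_true(out$in_event[3])
  expect_false(out$in_event[2])
  # breath midpoint 102 >= arousal onset 102 -> inside; midpoint 98 -> not
  expect_false(out$in_arousal[2])
  expect_true(out$in_arousal[3])
  # stage from the epoch containing the midpoint (30.1 s -> N2)
  expect_equal(out$stage[1], "N2")

  # sliver overlaps below the tolerance do not flag the breath
  br_sliver <- tibble::tibble(t_start = 99.4, t_insp_end = 101, t_end = 103.4,
                              tidal_volume = 1)
  expect_false(assign_context(br_sliver, ann)$in_event[1])
  br_sliver2 <- tibble::tibble(t_start = 99.4, t_insp_end = 101, t_end = 104,
                               tidal_volume = 1)
  expect_true(assign_context(br_sliver2, ann)$in_event[1])
})

test_that("breaths outside the staged period get stage W with a warning", {
  ann <- make_annotations(
    stages = tibble::tibble(onset_s = 0, stage = "N2")
  )
  br <- tibble::tibble(t_start = c(10, 50), t_insp_end = c(12, 52),
                       t_end = c(14, 54), tidal_volume = 1)
  expect_warning(out <- assign_context(br, ann), "outside the staged period")
  expect_equal(out$stage, c("N2", "W"))
})
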
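test_that("a stable open-airway loop produces no scored events", {
  cfg <- sim_config(duration_s = 3600, vpassive_true = 100, comp_slope = 0,
                    gain_G = 3, tau_s = 60, delay_s = 10, noise_sd = 0, seed = 1)
  expect_lt(sim_ground_truth(cfg)$lgn, 1)
  sim <- simulate_night(cfg)
  expect_equal(sim$truth$n_events_scored, 0)
})

test_that("a collapsible airway with a reachable arousal threshold cycles", {
  cfg <- sim_config(duration_s = 3600, vpassive_true = 30, threshold_true = 150,
                    gain_G = 4, tau_s = 45, delay_s = 8, seed = 2)
  sim <- simulate_night(cfg)
  expect_gt(sim$truth$n_events_scored, 5)
  expect_gt(sim$truth$n_arousals, 5)
  ev <- ann_events <- sim$annotations[sim$annotations$kind == "resp_event", ]
  expect_true(all(ev$duration_s >= cfg$min_event_s))
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(duration_s = 1200, vpassive_true = 50, seed = 9)
  s1 <- simulate_night(cfg)
  s2 <- simulate_night(cfg)
  expect_identical(s1$flow, s2$flow)
  expect_identical(s1$breaths, s2$breaths)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- simulate_night(cfg, seed = 10)
  expect_false(identical(s1$breaths$ventilation_pct, s3$breaths$ventilation_pct))
})

test_that("achieved ventilation never exceeds intended drive beyond noise", {
  cfg <- sim_config(duration_s = 2400, vpassive_true = 45, threshold_true = 140,
                    noise_sd = 0.05, seed = 4)
  sim <- simulate_night(cfg)
  expect_true(all(sim$breaths$ventilation_clean <= sim$breaths$total_drive + 1e-9))
  # noisy achieved ventilation only deviates by the lognormal factor
  ratio <- sim$breaths$ventilation_pct / pmax(sim$breaths$ventilation_clean, 1e-12)
  expect_true(all(ratio[sim$breaths$ventilation_clean > 0] < exp(5 * 0.05)))
})

test_that("simulator drive dynamics match the analysis filter on the same input", {
  cfg <- sim_config(duration_s = 2400, vpassive_true = 40, threshold_true = 150,
                    gain_G = 4, tau_s = 45, delay_s = 8, noise_sd = 0.05, seed = 6)
  sim <- simulate_night(cfg)
  br <- tibble::tibble(t_start = sim$breaths$t_start,
                       ventilation_pct = sim$breaths$ventilation_pct)
  got <- chemoreflex_response(br, chemoreflex_params(4, 45, 8), clamp = FALSE)
  expect_lt(max(abs(got$chemical_drive - sim$breaths$chemical_drive) /
                  pmax(abs(sim$breaths$chemical_drive), 1)), 0.001)
})

test_that("ground truth satisfies the active = passive + compensation identity", {
  for (s in 1:5) {
    set.seed(s)
    cfg <- sim_config(duration_s = 600, vpassive_true = runif(1, 30, 90),
                      comp_slope = runif(1, -0.2, 0.5),
                      threshold_true = runif(1, 110, 200), seed = s)
    tr <- sim_ground_truth(cfg)
    expect_equal(tr$vactive, tr$vpassive + tr$compensation)
    expect_gte(tr$lg1, 0)
    expect_gte(tr$lgn, 0)
  }
})

test_that("event auto-scoring applies the depth and duration rules", {
  mk <- function(vent) {
    n <- length(vent)
    tibble::tibble(t_start = (seq_len(n) - 1) * 4, t_end = seq_len(n) * 4,
                   ventilation_pct = vent)
  }
  # 20-s dip to 50% -> one hypopnea
  ev <- score_events(mk(c(rep(100, 10), rep(50, 5), rep(100, 10))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "hypopnea")
  expect_equal(ev$duration_s, 20)
  # 8-s dip -> no event
  ev2 <- score_events(mk(c(rep(100, 10), rep(50, 2), rep(100, 10))))
  expect_equal(nrow(ev2), 0)
  # 16-s dip reaching 5% -> apnea
  ev3 <- score_events(mk(c(rep(100, 10), rep(5, 4), rep(100, 10))))
  expect_equal(ev3$type, "obstructive_apnea")
})

test_that("runaway positive-feedback configurations are rejected", {
  expect_error(sim_config(gain_G = 4, comp_slope = -0.3),
               "unstable configuration")
  expect_error(sim_config(comp_slope = 1.5), "comp_slope")
})

test_that("scored arousal margins cover exactly the breaths given the wakefulness drive", {
  cfg <- sim_config(duration_s = 2400, vpassive_true = 40, threshold_true = 140,
                    noise_sd = 0, seed = 8)
  sim <- simulate_night(cfg)
  br <- tibble::tibble(t_start = sim$breaths$t_start, t_end = sim$breaths$t_end,
                       tidal_volume = 1)
  tagged <- assign_context(br, sim$annotations)
  expect_equal(tagged$in_arousal, sim$breaths$aroused)
})
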
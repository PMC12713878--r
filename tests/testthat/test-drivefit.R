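test_that("the fit recovers its own model exactly on self-consistent data", {
  br <- make_selfconsistent_breaths(gain_G = 3, tau_s = 60, delay_s = 10, gamma = 20)
  fit <- fit_drive_segment(br)
  expect_lt(abs(fit$params$gain_G - 3), 1e-6)
  expect_lt(abs(fit$params$arousal_gamma - 20), 1e-6)
  expect_lt(abs(fit$baseline - 100), 1e-6)
  expect_lt(fit$sse, 1e-8)
  expect_true(fit$identifiable)
  # SSE at the generating dynamics is minimal over the whole grid
  truth_row <- fit$grid$tau_s == 60 & fit$grid$delay_s == 10
  expect_true(any(truth_row))
  expect_lte(min(fit$grid$sse[truth_row]), min(fit$grid$sse) + 1e-9)
})

test_that("a flat, disturbance-free night is flagged unidentifiable", {
  n <- 200
  br <- tibble::tibble(
    t_start = (seq_len(n) - 1) * 4, t_end = seq_len(n) * 4,
    ventilation_pct = 100, in_event = FALSE, in_arousal = FALSE
  )
  fit <- fit_drive_segment(br)
  expect_false(fit$identifiable)
})

test_that("fitting fails cleanly without enough unobstructed breaths", {
  br <- make_selfconsistent_breaths()
  br$in_event <- TRUE
  expect_error(fit_drive_segment(br), "insufficient unobstructed breaths")
  br2 <- make_selfconsistent_breaths(n = 30)
  br2$in_event[1:25] <- TRUE
  expect_error(fit_drive_segment(br2), "insufficient unobstructed breaths")
})

test_that("only non-event breaths are scored, and event flags shrink the fit domain exactly", {
  br <- make_selfconsistent_breaths()
  fit <- fit_drive_segment(br)
  expect_true(all(!br$in_event[fit$fit_idx]))
  # flagging one more breath as in-event removes (at most) that breath from
  # the scored set and nothing else
  k <- fit$fit_idx[10]
  br2 <- br
  br2$in_event[k] <- TRUE
  fit2 <- fit_drive_segment(br2)
  expect_false(k %in% fit2$fit_idx)
  expect_setequal(fit2$fit_idx, setdiff(fit$fit_idx, k))
  expect_equal(fit2$n_fit_breaths, fit$n_fit_breaths - 1)
})

test_that("drive clamping preserves the total >= chemical ordering", {
  br <- make_selfconsistent_breaths(gain_G = 5, gamma = 30, event_vent = 0)
  fit <- fit_drive_segment(br)
  expect_true(all(fit$drive$total_drive >= fit$drive$chemical_drive - 1e-9))
  expect_true(all(fit$drive$chemical_drive >= 0))
})

test_that("whole-night fitting tiles NREM segments and aggregates medians", {
  cfg <- sim_config(duration_s = 3600, vpassive_true = 45, threshold_true = 150,
                    gain_G = 4, tau_s = 45, delay_s = 8, seed = 5)
  sim <- simulate_night(cfg)
  br <- segment_breaths(sim$flow)
  br <- compute_ventilation(br)
  br <- normalize_to_eupnea(br)
  br <- assign_context(br, sim$annotations)
  fit <- fit_drive_model(br, sim$annotations)
  w <- tidy(fit)
  expect_gt(nrow(w), 3)
  expect_true(all(w$win_end - w$win_start == 420))
  expect_true(all(diff(w$win_start) == 210))
  expect_equal(fit$night_params$tau_s, median(w$tau_s))
  expect_true(all(c("chemical_drive", "total_drive") %in% names(fit$breaths)))
  g <- glance(fit)
  expect_equal(g$n_windows_valid, nrow(w))
  expect_true(g$lgn < g$lg1)
})

test_that("whole-night fitting reports a diagnosable failure when no window is valid", {
  # no scored events at all -> every candidate window is invalid
  cfg <- sim_config(duration_s = 3600, vpassive_true = 100, comp_slope = 0,
                    gain_G = 2, tau_s = 60, delay_s = 10, noise_sd = 0, seed = 2)
  sim <- simulate_night(cfg)
  br <- segment_breaths(sim$flow)
  br <- compute_ventilation(br)
  br <- normalize_to_eupnea(br)
  br <- assign_context(br, sim$annotations)
  expect_error(fit_drive_model(br, sim$annotations), "no valid analysis windows")
})
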
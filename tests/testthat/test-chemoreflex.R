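even_breaths <- function(vent, breath_s = 4) {
  tibble::tibble(
    t_start = (seq_along(vent) - 1) * breath_s,
    ventilation_pct = vent
  )
}

test_that("sustained apnea drives the chemoreflex to its steady state", {
  p <- chemoreflex_params(gain_G = 0.5, tau_s = 30, delay_s = 5)
  br <- chemoreflex_response(even_breaths(rep(0, 200)), p)
  expect_lt(abs(tail(br$chemical_drive, 1) - 150), 1e-3)

  br100 <- chemoreflex_response(even_breaths(rep(100, 100)), p)
  expect_true(all(br100$chemical_drive == 100))
})

test_that("drive response is linear in the ventilation deviation", {
  p <- chemoreflex_params(gain_G = 2, tau_s = 45, delay_s = 8)
  set.seed(4)
  dev <- rnorm(200, 0, 10)
  d1 <- chemoreflex_response(even_breaths(100 + dev), p, clamp = FALSE)$chemical_drive - 100
  d2 <- chemoreflex_response(even_breaths(100 + 2 * dev), p, clamp = FALSE)$chemical_drive - 100
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("breath-domain updates match fine-step ODE integration on random traces", {
  set.seed(9)
  for (i in 1:5) {
    vent <- 100 + cumsum(rnorm(120, 0, 8))
    vent <- pmax(pmin(vent, 180), 10)
    p <- chemoreflex_params(gain_G = runif(1, 1, 5), tau_s = runif(1, 20, 90),
                            delay_s = runif(1, 3, 15))
    got <- chemoreflex_response(even_breaths(vent), p, clamp = FALSE)$chemical_drive
    want <- ode_drive_oracle(even_breaths(vent)$t_start, vent,
                             p$gain_G, p$tau_s, p$delay_s)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 0.001)
  }
})

test_that("sinusoidal ventilation is attenuated and lagged per the transfer function", {
  p <- chemoreflex_params(gain_G = 3, tau_s = 60, delay_s = 10)
  for (f in c(1 / 120, 1 / 60, 1 / 30)) {
    tb <- 0.25
    t <- seq(0, 1200 - tb, by = tb)
    amp <- 10
    vent <- 100 + amp * sin(2 * pi * f * t)
    br <- chemoreflex_response(tibble::tibble(t_start = t, ventilation_pct = vent),
                               p, clamp = FALSE)
    keep <- t > 600 # steady state
    fit <- lm(br$chemical_drive[keep] ~ sin(2 * pi * f * t[keep]) + cos(2 * pi * f * t[keep]))
    amp_got <- sqrt(sum(coef(fit)[2:3]^2))
    amp_want <- amp * p$gain_G / sqrt(1 + (2 * pi * f * p$tau_s)^2)
    expect_lt(abs(amp_got - amp_want) / amp_want, 0.01)
    # drive opposes ventilation (sign flip = pi) and lags by the transfer
    # function's arctan + delay phase; the breath-held input adds half a
    # breath of effective delay
    phase_got <- atan2(coef(fit)[3], coef(fit)[2]) %% (2 * pi)
    phase_want <- (pi - atan(2 * pi * f * p$tau_s) - 2 * pi * f * p$delay_s -
                     2 * pi * f * tb / 2) %% (2 * pi)
    err <- abs(phase_got - phase_want) %% (2 * pi)
    expect_lt(min(err, 2 * pi - err), 0.02)
  }
})

test_that("loop-gain magnitude follows the first-order closed form", {
  p <- chemoreflex_params(gain_G = 3, tau_s = 60, delay_s = 10)
  expect_lt(abs(loop_gain_magnitude(p, 1e-9) - 3), 1e-6)
  expect_equal(loop_gain_magnitude(p, 1 / 60), 3 / sqrt(1 + 4 * pi^2))
  f <- c(0.005, 0.01, 0.02, 0.05)
  expect_true(all(diff(loop_gain_magnitude(p, f)) < 0))
  expect_error(loop_gain_magnitude(p, 0), "f")
})

test_that("the natural frequency solves the 180-degree phase equation", {
  p <- chemoreflex_params(gain_G = 3, tau_s = 60, delay_s = 10)
  fn <- natural_frequency(p) / 60
  phase <- atan(2 * pi * fn * 60) + 2 * pi * fn * 10
  expect_lt(abs(phase - pi), 1e-9)

  p2 <- chemoreflex_params(3, 60, 20)
  expect_lt(natural_frequency(p2), natural_frequency(p))
  expect_error(natural_frequency(chemoreflex_params(3, 60, 0)), "no phase crossing")
})

test_that("LG1 and LGn follow their frequency conventions", {
  p <- chemoreflex_params(gain_G = 3, tau_s = 60, delay_s = 10)
  lg <- lg1_lgn(p)
  expect_equal(lg$lg1, 3 / sqrt(1 + 4 * pi^2), tolerance = 1e-12)
  expect_gt(lg$fn_cpm, 1)
  expect_lt(lg$lgn, lg$lg1)
  expect_equal(lg$lgn, loop_gain_magnitude(p, lg$fn_cpm / 60), tolerance = 1e-12)
  # with a vanishing lag, LG1 approaches the DC gain
  p_fast <- chemoreflex_params(gain_G = 3, tau_s = 1e-4, delay_s = 10)
  expect_lt(abs(lg1_lgn(p_fast)$lg1 - 3), 1e-4)
})

test_that("invalid inputs to the drive filter are rejected", {
  p <- chemoreflex_params(1, 10, 2)
  br <- even_breaths(rep(100, 10))
  br$t_start[5] <- br$t_start[4]
  expect_error(chemoreflex_response(br, p), "strictly increasing")
  expect_error(chemoreflex_params(-1, 10, 2), "gain_G")
  expect_error(chemoreflex_params(1, 0, 2), "tau_s")
})
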
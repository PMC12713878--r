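breaths_with_drive <- function(drive, vent, stage = "N2") {
  n <- length(drive)
  tibble::tibble(
    t_start = (seq_len(n) - 1) * 4, t_end = seq_len(n) * 4,
    ventilation_pct = vent, total_drive = drive,
    chemical_drive = drive, stage = stage
  )
}

test_that("an identity ventilation-drive relation yields an identity endogram", {
  set.seed(21)
  drive <- runif(2000, 60, 140)
  endo <- build_endogram(breaths_with_drive(drive, drive))
  expect_equal(endo$vent_median, endo$drive_median, tolerance = 1e-12)
  expect_true(all(diff(endo$drive_median) > 0))
  expect_equal(sum(endo$n_breaths), 2000)
})

test_that("a piecewise-linear airway curve is recovered within bin tolerance", {
  set.seed(22)
  drive <- runif(3000, 80, 180)
  vent <- ifelse(drive <= 100, 50, 50 + 0.2 * (drive - 100))
  endo <- build_endogram(breaths_with_drive(drive, vent))
  want <- ifelse(endo$drive_median <= 100, 50, 50 + 0.2 * (endo$drive_median - 100))
  expect_lt(max(abs(endo$vent_median - want)), 0.5)
})

test_that("the endogram is invariant under breath permutation", {
  set.seed(23)
  drive <- runif(500, 60, 160)
  vent <- pmax(drive + rnorm(500, 0, 15), 0)
  br <- breaths_with_drive(drive, vent)
  e1 <- build_endogram(br)
  perm <- sample(nrow(br))
  br2 <- br[perm, ]
  br2$t_start <- br$t_start
  br2$t_end <- br$t_end
  e2 <- build_endogram(br2)
  expect_identical(e1$drive_median, e2$drive_median)
  expect_identical(e1$vent_median, e2$vent_median)
})

test_that("endogram scope and bin-count rules behave", {
  drive <- runif(400, 60, 160)
  br <- breaths_with_drive(drive, drive, stage = rep(c("N2", "R"), 200))
  endo <- build_endogram(br, scope = "NREM")
  expect_equal(sum(endo$n_breaths), 200)
  expect_lte(nrow(endo), max(10, 200 %/% 10))
  br_w <- breaths_with_drive(drive, drive, stage = "W")
  expect_error(build_endogram(br_w, scope = "NREM"), "empty endogram")
})

test_that("ventilation is read off the endogram by interpolation with edge clamping", {
  endo <- structure(
    tibble::tibble(drive_median = c(90, 100, 110), vent_median = c(40, 50, 55),
                   n_breaths = c(10L, 10L, 10L)),
    class = c("endogram", class(tibble::tibble()))
  )
  out <- ventilation_at_drive(endo, c(100, 105, 130, 80))
  expect_equal(out$ventilation, c(50, 52.5, 55, 40))
  expect_equal(out$extrapolated, c(FALSE, FALSE, TRUE, TRUE))
  # monotone input -> monotone interpolation
  grid <- ventilation_at_drive(endo, seq(85, 125, 1))
  expect_true(all(diff(grid$ventilation) >= 0))
})

test_that("arousal threshold is the median pre-arousal chemical drive", {
  br <- breaths_with_drive(drive = c(100, 110, 100, 130, 100, 150, 100),
                           vent = rep(50, 7))
  arous <- tibble::tibble(onset_s = c(8.5, 16.5, 24.5), duration_s = 10)
  th <- arousal_threshold(br, arous, min_arousals = 3)
  # last breath ending before each onset carries drives 110, 130, 150
  expect_equal(th$value, 130)
  expect_true(th$defined)

  th2 <- arousal_threshold(br, arous[0, ], min_arousals = 5)
  expect_false(th2$defined)
  expect_true(is.na(th2$value))
  # arousals with no breath within the lookback window are skipped
  th3 <- arousal_threshold(br, tibble::tibble(onset_s = 500, duration_s = 10),
                           min_arousals = 1)
  expect_equal(th3$n_usable, 0)
})

test_that("traits follow their definitions and identities", {
  set.seed(24)
  drive <- runif(2000, 60, 170)
  br <- breaths_with_drive(drive, drive)
  endo <- build_endogram(br)
  params <- chemoreflex_params(3, 60, 10, 20)
  tr <- compute_traits(endo, arth = 150, br, params)
  expect_equal(tr$vpassive, 100, tolerance = 1)
  expect_equal(tr$vactive, 150, tolerance = 1)
  expect_equal(tr$compensation, tr$vactive - tr$vpassive)
  expect_equal(tr$lg1, loop_gain_magnitude(params, 1 / 60))
  # vmin: median ventilation of the lowest drive decile
  low <- sort(drive)[1:200]
  expect_equal(tr$vmin, median(low), tolerance = 1e-9)

  tr_na <- compute_traits(endo, arth = NA_real_, br, params)
  expect_true(is.na(tr_na$vactive) && is.na(tr_na$compensation))
  expect_false(tr_na$arth_defined)
})

test_that("a ventilation rise above eupnea yields positive compensation, a flat curve does not", {
  set.seed(25)
  drive <- runif(3000, 70, 170)
  vent_up <- ifelse(drive <= 100, 60, 60 + 0.3 * (drive - 100))
  tr_up <- compute_traits(build_endogram(breaths_with_drive(drive, vent_up)),
                          arth = 160, breaths_with_drive(drive, vent_up),
                          chemoreflex_params(3, 60, 10))
  expect_gt(tr_up$compensation, 0)
  vent_flat <- rep(60, 3000)
  tr_flat <- compute_traits(build_endogram(breaths_with_drive(drive, vent_flat)),
                            arth = 160, breaths_with_drive(drive, vent_flat),
                            chemoreflex_params(3, 60, 10))
  expect_lte(tr_flat$compensation, 0 + 1e-9)
})

test_that("night aggregation takes medians with a reproducible bootstrap", {
  win <- tibble::tibble(
    vpassive = c(50, 60, 70), vmin = c(40, 45, 50), vactive = c(60, 75, 90),
    compensation = c(10, 15, 20), arousal_threshold = c(140, 150, 160),
    lg1 = c(0.4, 0.6, 0.8), lgn = c(0.3, 0.4, 0.5),
    arth_defined = TRUE, lg_identifiable = TRUE,
    vpassive_extrapolated = FALSE, vactive_extrapolated = FALSE
  )
  n1 <- aggregate_night(win, boot_B = 200, boot_seed = 42)
  expect_equal(n1$estimate[n1$trait == "lg1"], 0.6)
  expect_equal(n1$estimate[n1$trait == "vactive"],
               n1$estimate[n1$trait == "vpassive"] +
                 n1$estimate[n1$trait == "compensation"])
  expect_true(all(n1$ci_lo <= n1$estimate & n1$estimate <= n1$ci_hi, na.rm = TRUE))
  n2 <- aggregate_night(win, boot_B = 200, boot_seed = 42)
  expect_identical(n1, n2)

  single <- aggregate_night(win[2, ], boot_B = 50, boot_seed = 1)
  expect_equal(single$estimate[single$trait == "lg1"], 0.6)
  expect_true(all(single$flag %in% c("single_window", "undefined")))
  expect_error(aggregate_night(win[0, ]), "zero valid windows")
})

test_that("trait classification against cohort tertiles partitions the line", {
  tert <- reference_tertiles("CMUH")
  expect_equal(tert$p33[tert$trait == "vpassive"], 58.7)
  night <- tibble::tibble(
    trait = c("vpassive", "lg1", "vmin", "compensation"),
    estimate = c(62.0, 0.62, 30, NA)
  )
  out <- classify_traits(night, "CMUH")
  expect_equal(out$label, c("moderate", "high", "low", "n/a"))
  out_mros <- classify_traits(tibble::tibble(trait = "lg1", estimate = 0.62), "MrOS")
  expect_equal(out_mros$label, "moderate")

  # exactly one label for any finite value, ties at boundaries are moderate
  for (v in c(-10, 58.7, 60, 75.5, 75.6, 200)) {
    lab <- classify_traits(tibble::tibble(trait = "vpassive", estimate = v), "CMUH")$label
    expect_true(lab %in% c("low", "moderate", "high"))
  }
  expect_equal(classify_traits(tibble::tibble(trait = "vpassive", estimate = 58.7), "CMUH")$label, "moderate")
  expect_equal(classify_traits(tibble::tibble(trait = "vpassive", estimate = 75.5), "CMUH")$label, "moderate")
})

test_that("surrogate indices summarize the scored study", {
  st <- tibble::tibble(onset_s = seq(0, 8 * 3600 - 30, 30), stage = "N2")
  ev <- tibble::tibble(
    onset_s = seq(100, by = 600, length.out = 40),
    duration_s = 20,
    type = c(rep("obstructive_apnea", 10), rep("hypopnea", 30))
  )
  ann <- make_annotations(events = ev, stages = st)
  s <- surrogate_indices(ann)
  expect_equal(s$ahi, 5)
  expect_equal(s$f_hypopnea, 0.75)
  expect_equal(s$mean_oa_duration_s, 20)
  expect_equal(s$nrem_oai_over_nrem_ahi, 0.25)
  expect_true(is.na(s$rem_ahi_over_nrem_ahi)) # no REM scored

  ann0 <- make_annotations(stages = st)
  s0 <- surrogate_indices(ann0)
  expect_true(is.na(s0$f_hypopnea))
  expect_equal(s0$ahi, 0)
})
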
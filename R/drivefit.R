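#' Control parameters for the chemoreflex drive fit
#'
#' @param tau_grid,delay_grid Grid of time constants and delays (seconds)
#'   searched exhaustively; at each grid point the gain and arousal response
#'   are obtained by non-negative linear least squares, turning the
#'   four-parameter nonlinear fit into a robust 2-D grid search over a convex
#'   subproblem.
#' @param window_s,step_s Analysis window length and advance, seconds. Each
#'   contiguous NREM segment is tiled with `window_s` windows advanced by
#'   `step_s`; fitting is per-window and night-level parameters are medians
#'   over valid windows.
#' @param min_fit_breaths Minimum unobstructed (non-event) breaths a window
#'   must contain to be fitted.
#' @param max_wake_frac Maximum tolerated fraction of wake-staged breaths in
#'   a window.
#' @param tol_flat Relative flatness threshold on the SSE surface below which
#'   the fit is flagged unidentifiable.
#' @param var_min Minimum variance (%eupnea^2) of the filtered disturbance
#'   over fit breaths for identifiability.
#' @param f1_cpm Frequency (cycles/min) at which LG1 is evaluated.
#' @param baseline_range Allowed range for the fitted eupneic intercept of
#'   each window (a wide sanity box). The intercept is free because in
#'   obstructed sleep the local mean ventilation — the normalization's 100%
#'   — sits below true eupnea, and a fixed intercept of 100 would force that
#'   offset into the gain.
#' @param scale_range The fitted intercept and gain imply the ratio of the
#'   local normalization baseline to true eupnea,
#'   `c = 100 (1 + G) / (b0 + 100 G)` (the fitted model's own eupneic fixed
#'   point): ventilation and drive are multiplied by this calibration before
#'   traits are read, so traits are expressed relative to true eupnea rather
#'   than the event-depressed local mean. The estimate is clamped to this
#'   range.
#' @param gamma_max Upper bound (%eupnea) on the fitted ventilatory response
#'   to arousal. Reported arousal responses are a few tens of %eupnea; an
#'   unbounded response lets the regression explain obstructed-versus-aroused
#'   ventilation as a pure arousal effect instead of chemoreflex dynamics.
#' @param robust_trim After each pass, breaths whose ventilation falls more
#'   than `trim_k` robust residual scales (MAD) *below* the fitted drive are
#'   treated as unscored flow-limited breaths (the airway was obstructed even
#'   though no event was scored, so ventilation does not reveal drive there)
#'   and the fit is repeated without them. One-sided by design: obstruction
#'   can only lower ventilation.
#' @param trim_k Robust-scale multiple for the flow-limitation trim.
#' @param trim_iter Maximum number of trim-and-refit iterations.
#' @param post_arousal_s Breaths starting within this many seconds after a
#'   scored arousal are treated, together with breaths inside arousal
#'   margins, as securely open-airway anchor breaths for the first trim pass
#'   (the arousal has just opened the airway).
#' @param min_anchor_breaths Minimum anchor breaths required before the
#'   anchored first pass is used instead of the all-breath first pass.
#' @param gamma_prior Ventilatory response to arousal (%eupnea) assumed when
#'   the arousal indicator is too collinear with the intercept to estimate
#'   the response (nearly every fit breath aroused), as in severely
#'   obstructed sleep where only arousal breaths escape event scoring.
#' @param fix_gamma,fix_baseline When non-`NULL`, hold the arousal response
#'   and/or eupneic intercept at the given value instead of estimating them.
#'   [fit_drive_model()] estimates both once per night and fixes them across
#'   windows, so each window fits only its gain and dynamics.
#' @param polish After the grid search, refine (tau, delay) continuously by
#'   local optimization from the chosen grid point (Nelder-Mead on the
#'   profiled SSE); the delay in particular matters at sub-grid resolution
#'   because the first recovery breath after an event moves against the
#'   delayed disturbance by fractions of a breath.
#' @param ridge_tol,tau_ref,delay_ref The SSE surface over (tau, delay) is
#'   often nearly flat along a ridge on which the implied drive series is
#'   essentially unchanged but the (gain, tau) decomposition — and hence the
#'   loop-gain extrapolation away from the data's cycling frequency — varies
#'   widely. Among grid points within `ridge_tol` relative SSE of the
#'   minimum, the fit therefore prefers the point closest (in log-tau, then
#'   delay) to the canonical chemoreflex time constant `tau_ref` and
#'   circulatory delay `delay_ref`.
#' @return A list of class `drivefit_control`.
#' @export
drivefit_control <- function(tau_grid = seq(10, 180, by = 5),
                             delay_grid = seq(2, 30, by = 2),
                             window_s = 420, step_s = 210,
                             min_fit_breaths = 20, max_wake_frac = 0.5,
                             tol_flat = 0.01, var_min = 1.0, f1_cpm = 1,
                             baseline_range = c(60, 200),
                             scale_range = c(0.7, 1.15),
                             gamma_max = 60,
                             robust_trim = TRUE, trim_k = 1.5,
                             trim_iter = 2, post_arousal_s = 5,
                             min_anchor_breaths = 12,
                             ridge_tol = 0.05, tau_ref = 60, delay_ref = 10,
                             gamma_prior = 20,
                             fix_gamma = NULL, fix_baseline = NULL,
                             polish = TRUE) {
  stopifnot(all(tau_grid > 0), all(delay_grid >= 0), window_s > 0, step_s > 0,
            min_fit_breaths >= 2, length(baseline_range) == 2,
            baseline_range[1] <= 100, baseline_range[2] >= 100)
  structure(
    list(tau_grid = tau_grid, delay_grid = delay_grid, window_s = window_s,
         step_s = step_s, min_fit_breaths = min_fit_breaths,
         max_wake_frac = max_wake_frac, tol_flat = tol_flat,
         var_min = var_min, f1_cpm = f1_cpm, baseline_range = baseline_range,
         scale_range = scale_range, gamma_max = gamma_max, robust_trim = robust_trim, trim_k = trim_k,
         trim_iter = trim_iter, post_arousal_s = post_arousal_s,
         min_anchor_breaths = min_anchor_breaths,
         ridge_tol = ridge_tol, tau_ref = tau_ref, delay_ref = delay_ref,
         gamma_prior = gamma_prior, fix_gamma = fix_gamma,
         fix_baseline = fix_baseline, polish = polish),
    class = "drivefit_control"
  )
}

# closed-form non-negative least squares for y ~ G*u + g*a with G >= 0 and
# 0 <= g <= gmax, vectorized over columns of U. Returns list(gain, gamma,
# sse) vectors.
nnls2 <- function(U, a, y, gmax = Inf) {
  Suu <- colSums(U * U)
  Sua <- as.numeric(crossprod(U, a))
  Suy <- as.numeric(crossprod(U, y))
  Saa <- sum(a * a)
  Say <- sum(a * y)
  Syy <- sum(y * y)
  ntau <- ncol(U)

  sse_of <- function(G, g) {
    Syy - 2 * G * Suy - 2 * g * Say + G^2 * Suu + 2 * G * g * Sua + g^2 * Saa
  }
  # boundary candidates: g = 0, g = gmax, G = 0, plus the interior solution
  G_u <- ifelse(Suu > 0, pmax(Suy / Suu, 0), 0)
  G <- G_u
  g <- rep(0, ntau)
  sse <- sse_of(G_u, 0)

  consider <- function(Gc, gc) {
    sse_c <- sse_of(Gc, gc)
    take <- sse_c < sse
    G[take] <<- if (length(Gc) == 1) Gc else Gc[take]
    g[take] <<- if (length(gc) == 1) gc else gc[take]
    sse[take] <<- sse_c[take]
  }
  if (Saa > 0) {
    g_a <- min(max(Say / Saa, 0), gmax)
    consider(0, g_a)
    if (is.finite(gmax)) {
      G_gmax <- ifelse(Suu > 0, pmax((Suy - gmax * Sua) / Suu, 0), 0)
      consider(G_gmax, gmax)
    }
    det <- Suu * Saa - Sua^2
    ok <- det > 1e-12 * pmax(Suu * Saa, 1e-300)
    G0 <- ifelse(ok, (Saa * Suy - Sua * Say) / det, -1)
    g0 <- ifelse(ok, (Suu * Say - Sua * Suy) / det, -1)
    interior <- ok & G0 >= 0 & g0 >= 0 & g0 <= gmax
    sse0 <- sse_of(G0, g0)
    take <- interior & sse0 < sse
    G[take] <- G0[take]
    g[take] <- g0[take]
    sse[take] <- sse0[take]
  }
  list(gain = G, gamma = g, sse = pmax(sse, 0))
}

#' Fit the chemoreflex drive model to one span of breaths
#'
#' Searches a grid of (time constant, delay) pairs; at each grid point the
#' unit-gain filtered disturbance is computed with [chemoreflex_response()]
#' dynamics (gain 1, no clamp) and the ventilation of unobstructed breaths is
#' regressed on it together with the arousal indicator,
#' `ventilation_pct ~ b0 + G * uhat + gamma * A`, under `G >= 0`,
#' `0 <= gamma <= gamma_max`, and an eupneic intercept `b0` (free within
#' `baseline_range`, or fixed via the control). The residual sum of squares
#' is evaluated only on breaths outside scored respiratory events, where the
#' airway is expected open and ventilation reveals drive; an optional robust
#' screen drops unscored flow-limited breaths (see [drivefit_control()]).
#' Grid selection uses a mildly regularized score and is refined by a
#' continuous local search; the chosen point is returned along with the
#' implied per-breath chemical and total drive (clamped at 0).
#'
#' @param breaths A breath tibble with `t_start`, `ventilation_pct`,
#'   `in_event`, and `in_arousal`.
#' @param control A [drivefit_control()] object.
#' @param .bank Optional precomputed filter bank (internal; one matrix per
#'   delay, rows aligned with `breaths`), used to carry burn-in from before
#'   the span when fitting windows inside a night.
#' @return An object of class `drivefit`: fitted [chemoreflex_params()],
#'   `sse`, `n_fit_breaths`, `identifiable`, the SSE `grid` trace, and a
#'   `drive` tibble with `chemical_drive` and `total_drive` per breath.
#' @export
fit_drive_segment <- function(breaths, control = drivefit_control(), .bank = NULL) {
  check_breaths(breaths, c("t_start", "ventilation_pct", "in_event", "in_arousal"))
  fit_idx <- which(!breaths$in_event)
  if (length(fit_idx) < control$min_fit_breaths) {
    stop_analysis(sprintf(
      "insufficient unobstructed breaths: %d available, %d required",
      length(fit_idx), control$min_fit_breaths
    ))
  }
  ts <- breaths$t_start
  if (is.unsorted(ts, strictly = TRUE)) {
    stop_input("breath start times must be strictly increasing")
  }
  taus <- control$tau_grid
  deltas <- control$delay_grid
  bank_local <- is.null(.bank)
  if (bank_local) {
    .bank <- lapply(deltas, function(d) {
      chemo_filter_bank(ts, breaths$ventilation_pct, d, taus)
    })
  }
  b_lo <- control$baseline_range[1]
  b_hi <- control$baseline_range[2]
  a_all <- as.numeric(breaths$in_arousal)

  # One grid pass over a given fit-breath set. The eupneic baseline of each
  # window is a free intercept boxed inside control$baseline_range: the free
  # solution comes from mean-centered regressors (profiling out the
  # intercept); when it leaves the box the intercept is clamped to the
  # violated bound and the non-negative gain / arousal-response subproblem is
  # re-solved, which is exact for this convex box-constrained problem.
  # closed-form solve for (gain, gamma, baseline) given filtered
  # disturbances U (one column per candidate tau), honouring fixed
  # gamma/baseline; returns equal-length vectors
  solve_cols <- function(U, a, y) {
    fg <- control$fix_gamma
    fb <- control$fix_baseline
    n_tau <- ncol(U)
    {
      if (!is.null(fg) && !is.null(fb)) {
        # only the gain is free
        y2 <- y - fg * a - (fb - 100)
        Suu <- colSums(U * U)
        Suy <- as.numeric(crossprod(U, y2))
        gain <- ifelse(Suu > 0, pmax(Suy / Suu, 0), 0)
        sse <- pmax(sum(y2 * y2) - 2 * gain * Suy + gain^2 * Suu, 0)
        gamma <- rep(fg, n_tau)
        b0 <- rep(fb, n_tau)
      } else if (!is.null(fg)) {
        # gain + free (boxed) baseline, arousal response fixed
        y2 <- y - fg * a
        um <- colMeans(U)
        Uc <- sweep(U, 2, um)
        y2c <- y2 - mean(y2)
        Suu <- colSums(Uc * Uc)
        Suy <- as.numeric(crossprod(Uc, y2c))
        gain <- ifelse(Suu > 0, pmax(Suy / Suu, 0), 0)
        b0 <- 100 + mean(y2) - gain * um
        sse <- pmax(sum(y2c * y2c) - 2 * gain * Suy + gain^2 * Suu, 0)
        viol <- b0 < b_lo | b0 > b_hi
        if (any(viol)) {
          b0v <- pmin(pmax(b0[viol], b_lo), b_hi)
          Uv <- U[, viol, drop = FALSE]
          Suuv <- colSums(Uv * Uv)
          Suyv <- as.numeric(crossprod(Uv, y2)) - b0v * colSums(Uv) +
            100 * colSums(Uv)
          gv <- ifelse(Suuv > 0, pmax(Suyv / Suuv, 0), 0)
          ss0 <- sum((y2)^2) - 2 * (b0v - 100) * sum(y2) +
            length(y2) * (b0v - 100)^2
          ssev <- pmax(ss0 - 2 * gv * Suyv + gv^2 * Suuv, 0)
          gain[viol] <- gv
          b0[viol] <- b0v
          sse[viol] <- ssev
        }
        gamma <- rep(fg, ncol(U))
      } else {
        um <- colMeans(U)
        Uc <- sweep(U, 2, um)
        ac <- a - mean(a)
        yc <- y - mean(y)
        free <- nnls2(Uc, ac, yc, gmax = control$gamma_max)
        b0 <- 100 + mean(y) - free$gain * um - free$gamma * mean(a)
        gain <- free$gain
        gamma <- free$gamma
        sse <- free$sse
        viol_lo <- b0 < b_lo
        viol_hi <- b0 > b_hi
        if (any(viol_lo)) {
          clamped <- nnls2(U[, viol_lo, drop = FALSE], a, y - (b_lo - 100),
                           gmax = control$gamma_max)
          gain[viol_lo] <- clamped$gain
          gamma[viol_lo] <- clamped$gamma
          sse[viol_lo] <- clamped$sse
          b0[viol_lo] <- b_lo
        }
        if (any(viol_hi)) {
          clamped <- nnls2(U[, viol_hi, drop = FALSE], a, y - (b_hi - 100),
                           gmax = control$gamma_max)
          gain[viol_hi] <- clamped$gain
          gamma[viol_hi] <- clamped$gamma
          sse[viol_hi] <- clamped$sse
          b0[viol_hi] <- b_hi
        }
      }
    }
    list(gain = gain, gamma = gamma, baseline = b0, sse = sse)
  }

  grid_pass <- function(idx) {
    a <- a_all[idx]
    y <- breaths$ventilation_pct[idx] - 100
    grids <- vector("list", length(deltas))
    for (j in seq_along(deltas)) {
      sol <- solve_cols(.bank[[j]][idx, , drop = FALSE], a, y)
      grids[[j]] <- tibble::tibble(
        tau_s = taus, delay_s = deltas[j],
        gain = sol$gain, gamma = sol$gamma, sse = sol$sse,
        baseline = sol$baseline
      )
    }
    grid <- dplyr::bind_rows(grids)
    best <- which.min(ridge_score(grid))
    uhat <- .bank[[match(grid$delay_s[best], deltas)]][, match(grid$tau_s[best], taus)]
    list(grid = grid, best = best, uhat = uhat)
  }

  # Regularized model-selection score: the SSE surface over (tau, delay) is
  # often nearly flat along a ridge on which the implied drive series barely
  # changes but the (gain, tau) decomposition varies widely; a mild penalty
  # toward the canonical chemoreflex time constant, circulatory delay, and
  # physiological arousal response picks a stable point on that ridge
  # (trading about ridge_tol relative SSE per unit of preference).
  ridge_score <- function(grid) {
    pref <- abs(log(grid$tau_s / control$tau_ref)) +
      0.02 * abs(grid$gamma - control$gamma_prior) +
      0.01 * abs(grid$delay_s - control$delay_ref) +
      0.004 * abs(grid$baseline - 100)
    grid$sse * (1 + control$ridge_tol * pref)
  }

  # local continuous refinement of (tau, delay) from the chosen grid point:
  # the grid is a coarse global search and the true optimum usually lies
  # between grid lines (the delay in particular is finer than the 2-s grid)
  polish_pass <- function(pass, idx) {
    a <- a_all[idx]
    y <- breaths$ventilation_pct[idx] - 100
    g0 <- pass$grid[pass$best, ]
    eval_at <- function(tau, delta) {
      u <- chemo_filter_bank(ts, breaths$ventilation_pct, delta, tau)
      sol <- solve_cols(u[idx, , drop = FALSE], a, y)
      list(sol = sol, uhat = u[, 1])
    }
    row_at <- function(tau, delta, sol) {
      tibble::tibble(tau_s = tau, delay_s = delta, gain = sol$gain,
                     gamma = sol$gamma, sse = sol$sse, baseline = sol$baseline)
    }
    obj <- function(p) {
      tau <- min(max(exp(p[1]), min(taus)), max(taus))
      delta <- min(max(p[2], min(deltas)), max(deltas))
      ridge_score(row_at(tau, delta, eval_at(tau, delta)$sol))
    }
    opt <- stats::optim(c(log(g0$tau_s), g0$delay_s), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 60, reltol = 1e-6))
    tau <- min(max(exp(opt$par[1]), min(taus)), max(taus))
    delta <- min(max(opt$par[2], min(deltas)), max(deltas))
    if (opt$value <= ridge_score(pass$grid[pass$best, ])) {
      ev <- eval_at(tau, delta)
      grid <- dplyr::bind_rows(pass$grid, row_at(tau, delta, ev$sol))
      list(grid = grid, best = nrow(grid), uhat = ev$uhat)
    } else {
      pass
    }
  }

  # Breaths inside scored arousal margins, or just after them, have a
  # securely open airway (the arousal opened it): when enough of them exist
  # they anchor a first pass whose predictions flag unscored flow-limited
  # breaths — non-event breaths ventilating far below the drive the open
  # breaths imply. Without enough anchors, the first pass uses all non-event
  # breaths and the same one-sided residual trim is iterated.
  resid_of <- function(pass, idx) {
    g <- pass$grid[pass$best, ]
    pred <- g$baseline - 100 + g$gain * pass$uhat[idx] + g$gamma * a_all[idx]
    (breaths$ventilation_pct[idx] - 100) - pred
  }
  anchored <- FALSE
  if (isTRUE(control$robust_trim) && "t_end" %in% names(breaths)) {
    post <- rep(FALSE, nrow(breaths))
    last_ar_end <- -Inf
    for (k in seq_len(nrow(breaths))) {
      if (breaths$in_arousal[k]) {
        last_ar_end <- breaths$t_end[k]
      } else if (breaths$t_start[k] - last_ar_end < control$post_arousal_s) {
        post[k] <- TRUE
      }
    }
    anchor_idx <- which((breaths$in_arousal | post) & !breaths$in_event)
    anchored <- length(anchor_idx) >= control$min_anchor_breaths &&
      sum(a_all[anchor_idx] > 0) >= 4 && sum(a_all[anchor_idx] == 0) >= 4
  }

  n_trimmed <- 0L
  if (anchored) {
    p1 <- grid_pass(anchor_idx)
    s_r <- stats::mad(resid_of(p1, anchor_idx))
    r_all <- resid_of(p1, fit_idx)
    keep <- r_all >= -control$trim_k * max(s_r, 5) | fit_idx %in% anchor_idx
    if (sum(keep) >= control$min_fit_breaths) {
      n_trimmed <- sum(!keep)
      fit_idx <- fit_idx[keep]
    }
    pass <- grid_pass(fit_idx)
  } else {
    pass <- grid_pass(fit_idx)
    if (isTRUE(control$robust_trim)) {
      for (it in seq_len(control$trim_iter)) {
        r <- resid_of(pass, fit_idx)
        s_r <- stats::mad(r)
        # one-sided: breaths ventilating far below the fitted drive are
        # treated as unscored flow-limited breaths and removed from the fit
        keep <- r >= -control$trim_k * s_r
        if (s_r <= 0 || all(keep) || sum(keep) < control$min_fit_breaths) break
        n_trimmed <- n_trimmed + sum(!keep)
        fit_idx <- fit_idx[keep]
        pass <- grid_pass(fit_idx)
      }
    }
  }
  # continuous (tau, delay) refinement needs the filter state to start at
  # this span's first breath, so it only runs when the bank was computed
  # locally (whole-record fits), not for windows carrying night burn-in
  if (isTRUE(control$polish) && bank_local) {
    pass <- polish_pass(pass, fit_idx)
  }
  grid <- pass$grid
  best <- pass$best
  uhat <- pass$uhat

  sse_min <- grid$sse[best]
  sse_max <- max(grid$sse)
  flat <- (sse_max - sse_min) < control$tol_flat * sse_min
  low_var <- var(uhat[fit_idx]) < control$var_min
  params <- chemoreflex_params(
    gain_G = grid$gain[best], tau_s = grid$tau_s[best],
    delay_s = grid$delay_s[best], arousal_gamma = grid$gamma[best]
  )
  baseline <- grid$baseline[best]
  # calibration from the fitted model's eupneic fixed point: ratio of the
  # local normalization baseline to true eupnea
  scale_c <- 100 * (1 + params$gain_G) / (baseline + 100 * params$gain_G)
  scale_c <- min(max(scale_c, control$scale_range[1]), control$scale_range[2])
  chem_raw <- baseline + params$gain_G * uhat
  total_raw <- chem_raw + params$arousal_gamma * a_all
  structure(
    list(
      params = params,
      baseline = baseline,
      scale_c = scale_c,
      sse = sse_min,
      n_fit_breaths = length(fit_idx),
      fit_idx = fit_idx,
      n_trimmed = n_trimmed,
      identifiable = !(flat || low_var),
      grid = grid,
      drive = tibble::tibble(
        chemical_drive = pmax(chem_raw, 0),
        total_drive = pmax(total_raw, 0)
      )
    ),
    class = "drivefit"
  )
}

#' @export
print.drivefit <- function(x, ...) {
  cat(sprintf(
    "<drivefit> G = %.3f, tau = %.0f s, delay = %.0f s, gamma = %.1f; SSE = %.4g over %d breaths%s\n",
    x$params$gain_G, x$params$tau_s, x$params$delay_s, x$params$arousal_gamma,
    x$sse, x$n_fit_breaths, if (x$identifiable) "" else " [NOT identifiable]"
  ))
  invisible(x)
}

# contiguous NREM segments [start, end) from an annotation set
nrem_segments <- function(annotations) {
  st <- ann_stages(annotations)
  st <- st[st$label %in% nrem_stages, , drop = FALSE]
  if (nrow(st) == 0) return(tibble::tibble(seg_start = numeric(0), seg_end = numeric(0)))
  brk <- c(TRUE, diff(st$onset_s) > 30 + 1e-9)
  seg_id <- cumsum(brk)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(onset = st$onset_s, dur = st$duration_s, seg = seg_id), .data$seg),
    seg_start = min(.data$onset), seg_end = max(.data$onset + .data$dur),
    .groups = "drop"
  )[, c("seg_start", "seg_end")]
}

#' Fit the chemoreflex drive model over a night
#'
#' Tiles every contiguous NREM segment with overlapping analysis windows
#' (default 7 min advanced by 3.5 min), fits the drive model independently in
#' each valid window, and takes night-level parameters as medians over valid
#' windows. A window is valid when it contains at least one scored
#' respiratory event (so the disturbance has something to recover from), at
#' least `min_fit_breaths` unobstructed breaths, and less than
#' `max_wake_frac` wake. The filtered disturbance is always computed over the
#' whole night so each window's filter state carries realistic burn-in.
#'
#' @param breaths A breath tibble with ventilation and context columns (see
#'   [normalize_to_eupnea()] and [assign_context()]).
#' @param annotations An `annotation_set`.
#' @param control A [drivefit_control()].
#' @return An object of class `drivefit_night`: `windows` (one row per valid
#'   window with fitted parameters, a `drive` list-column, and breath-row
#'   indices), `night_params` ([chemoreflex_params()] of the medians),
#'   `breaths` augmented with night-parameter `chemical_drive` and
#'   `total_drive`, and window diagnostics.
#' @export
fit_drive_model <- function(breaths, annotations, control = drivefit_control()) {
  check_breaths(breaths, c("t_start", "t_end", "ventilation_pct", "stage",
                           "in_event", "in_arousal"))
  annotations <- as_annotations(annotations)
  ts <- breaths$t_start

  # Night-level fit: estimates the arousal response and the eupneic
  # intercept once for the whole night (the normalization sag and the
  # wakefulness response are night-level properties), with the internal
  # anchored flow-limitation screen and continuous (tau, delay) polish.
  # Windows then refit only the gain and dynamics with these held fixed.
  ctl_g <- control
  a_fit <- breaths$in_arousal[!breaths$in_event]
  if (is.null(ctl_g$fix_gamma) && (mean(a_fit) > 0.8 || mean(a_fit) < 0.02)) {
    # arousal indicator nearly constant across fit breaths: the response is
    # not identifiable and is pinned at the physiological prior
    ctl_g$fix_gamma <- if (mean(a_fit) > 0.5) control$gamma_prior else 0
  }
  g1 <- fit_drive_segment(breaths, ctl_g)
  gamma_night <- g1$params$arousal_gamma
  b0_night <- g1$baseline
  night_scale <- g1$scale_c
  fit_excluded <- rep(TRUE, nrow(breaths))
  fit_excluded[g1$fit_idx] <- FALSE
  fit_excluded <- fit_excluded & !breaths$in_event
  n_flowlim <- sum(fit_excluded)
  breaths_fit <- breaths
  breaths_fit$in_event <- breaths$in_event | fit_excluded

  # windows may also select the night fit's refined (tau, delay)
  taus <- sort(unique(c(control$tau_grid, g1$params$tau_s)))
  deltas <- sort(unique(c(control$delay_grid, g1$params$delay_s)))
  control$tau_grid <- taus
  control$delay_grid <- deltas
  bank <- lapply(deltas, function(d) chemo_filter_bank(ts, breaths$ventilation_pct, d, taus))

  segs <- nrem_segments(annotations)
  ev <- ann_events(annotations)
  mid <- (breaths$t_start + breaths$t_end) / 2

  win_start <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    if (segs$seg_end[i] - segs$seg_start[i] >= control$window_s) {
      win_start <- c(win_start, seq(segs$seg_start[i],
                                    segs$seg_end[i] - control$window_s,
                                    by = control$step_s))
    }
  }
  n_win <- length(win_start)
  drop_reason <- character(0)
  rows <- list()
  for (w in seq_len(n_win)) {
    w0 <- win_start[w]
    w1 <- w0 + control$window_s
    idx <- which(mid >= w0 & mid < w1)
    has_event <- any(ev$onset_s < w1 & ev$onset_s + ev$duration_s > w0)
    n_fit <- sum(!breaths_fit$in_event[idx])
    n_fit_raw <- sum(!breaths$in_event[idx])
    wake_frac <- if (length(idx) > 0) mean(breaths$stage[idx] == "W") else 1
    if (!has_event) { drop_reason <- c(drop_reason, "no_event"); next }
    if (n_fit_raw < control$min_fit_breaths) { drop_reason <- c(drop_reason, "too_few_fit_breaths"); next }
    if (wake_frac >= control$max_wake_frac) { drop_reason <- c(drop_reason, "too_much_wake"); next }
    sub_bank <- lapply(bank, function(m) m[idx, , drop = FALSE])
    ctl_w <- control
    ctl_w$robust_trim <- FALSE # flow limitation already screened night-wide
    ctl_w$fix_gamma <- gamma_night
    ctl_w$fix_baseline <- b0_night
    ctl_w$min_fit_breaths <- min(control$min_fit_breaths, 10)
    # use the screened fit domain when enough clean breaths remain,
    # otherwise fall back to all non-event breaths
    wb <- if (n_fit >= 10) breaths_fit[idx, ] else breaths[idx, ]
    fit <- fit_drive_segment(wb, ctl_w, .bank = sub_bank)
    rows[[length(rows) + 1]] <- tibble::tibble(
      win_start = w0, win_end = w1,
      gain = fit$params$gain_G, tau_s = fit$params$tau_s,
      delay_s = fit$params$delay_s, gamma = fit$params$arousal_gamma,
      baseline = fit$baseline, scale_c = night_scale,
      sse = fit$sse, n_fit_breaths = fit$n_fit_breaths,
      n_trimmed = fit$n_trimmed,
      identifiable = fit$identifiable,
      breath_idx = list(idx), drive = list(fit$drive)
    )
  }
  if (length(rows) == 0) {
    stop_analysis(sprintf(
      "no valid analysis windows (of %d candidate windows: %s)",
      n_win,
      if (n_win == 0) "no NREM segment long enough"
      else paste(names(table(drop_reason)), table(drop_reason), sep = "=", collapse = ", ")
    ))
  }
  windows <- dplyr::bind_rows(rows)
  night_params <- chemoreflex_params(
    gain_G = median(windows$gain), tau_s = median(windows$tau_s),
    delay_s = median(windows$delay_s), arousal_gamma = gamma_night
  )
  night_baseline <- b0_night
  uhat <- chemo_filter_bank(ts, breaths$ventilation_pct, night_params$delay_s,
                            night_params$tau_s)[, 1]
  chem_raw <- night_baseline + night_params$gain_G * uhat
  total_raw <- chem_raw + night_params$arousal_gamma * as.numeric(breaths$in_arousal)
  breaths$chemical_drive <- pmax(chem_raw, 0)
  breaths$total_drive <- pmax(total_raw, 0)
  structure(
    list(
      windows = windows,
      night_params = night_params,
      night_baseline = night_baseline,
      night_scale = night_scale,
      breaths = breaths,
      control = control,
      n_windows_candidate = n_win,
      n_windows_valid = nrow(windows),
      n_flowlim_excluded = n_flowlim,
      dropped = drop_reason
    ),
    class = "drivefit_night"
  )
}

#' @export
print.drivefit_night <- function(x, ...) {
  cat(sprintf(
    "<drivefit_night> %d/%d valid windows; night medians: G = %.3f, tau = %.0f s, delay = %.0f s, gamma = %.1f\n",
    x$n_windows_valid, x$n_windows_candidate, x$night_params$gain_G,
    x$night_params$tau_s, x$night_params$delay_s, x$night_params$arousal_gamma
  ))
  invisible(x)
}
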
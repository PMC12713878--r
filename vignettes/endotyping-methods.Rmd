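---
title: "How endotyper estimates obstructive sleep apnea endotypes from airflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How endotyper estimates obstructive sleep apnea endotypes from airflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotyper)
```

## The problem

Obstructive sleep apnea (OSA) is not one disease. The same apnea–hypopnea
index can arise from a highly collapsible pharynx, from over-responsive
ventilatory control (high loop gain), from a low arousal threshold that
fragments sleep before the airway can be rescued, or from upper-airway
muscles that fail to compensate as drive rises. These four *endotypes* —
collapsibility, compensation, arousal threshold, and loop gain — predict who
responds to which therapy, but measuring them classically requires overnight
CPAP manipulation or invasive drive sensors.

`endotyper` implements the polysomnography-only alternative: all four traits
are estimated from a routine airflow signal plus the scored respiratory
events, arousals, and sleep stages that every clinical study already has.
A closed-loop simulator with known ground-truth traits makes the entire
pipeline testable without any real recording.

## From airflow to ventilation

Breaths are segmented at negative-to-positive zero crossings of the smoothed
flow signal (2-s centered moving average by default). Tidal volume is the
trapezoidal integral of positive flow over the inspiratory phase, and
per-breath ventilation is tidal volume over breath duration, by minute.
Two guard rules matter for pathological breathing:

* a crossing that would close a breath shorter than `min_breath_s` (1.5 s)
  is ignored, merging spurious micro-breaths;
* a gap longer than `max_breath_s` (12 s) is tiled with zero-volume
  pseudo-breaths, so apneas appear as 0% ventilation instead of silently
  disappearing from the breath series.

Ventilation is then expressed in **%eupnea**: percent of the time-weighted
mean ventilation in a centered 7-min window (truncated at record edges, all
breaths included). 0% is a complete apnea, 100% eupneic breathing, more
hyperpnea. Normalization is scale-invariant, so the flow channel's units
never matter.

## The chemoreflex drive model

Ventilatory drive — the ventilation the controller *intends* — equals
achieved ventilation only when the airway is open. The package models the
chemical component of drive with a delayed first-order chemoreflex: writing
$d(t)$ for the drive deviation from eupnea and
$u(t) = 100 - \mathrm{vent}(t - \delta)$ for the delayed ventilation
deficit,

$$\tau \, d'(t) + d(t) = G\, u(t),$$

with gain $G$, time constant $\tau$ (s), and circulatory delay $\delta$ (s).
During scored arousals a wakefulness drive $\gamma$ is added on top. The
dynamics are integrated exactly between the breakpoints of the
breath-held input, and drive is evaluated at each inspiratory onset — the
same convention the simulator uses, so the two agree to rounding on
identical inputs.

Loop gain is read off the fitted transfer function:
$|H(f)| = G / \sqrt{1 + (2\pi f \tau)^2}$, reported at 1 cycle/min (LG1) and
at the natural frequency where the loop's phase lag reaches 180° (LGn), the
frequency at which periodic breathing can self-sustain.

## Fitting drive to ventilation

Only breaths outside scored respiratory events are scored in the fit — when
the airway is believed open, ventilation reveals drive. Over a grid of
$(\tau, \delta)$ (default $\tau \in \{10,\dots,180\}$ s by 5,
$\delta \in \{2,\dots,30\}$ s by 2, then refined continuously from the best
grid point), the unit-gain filtered disturbance $\hat u$ is computed and

$$\mathrm{vent} \approx b_0 + G\,\hat u + \gamma A$$

is solved in closed form with $G \ge 0$ and $0 \le \gamma \le$ 60 %eupnea.
Several choices here were genuinely open and deserve their rationale:

* **A free eupneic intercept $b_0$.** In obstructed sleep the 7-min local
  mean — the normalization's "100%" — sits below true eupnea, because the
  proportional chemoreflex tolerates a sustained ventilation deficit. With
  the intercept pinned at 100 that offset is forced into $G$ and inflates
  loop gain severalfold. $b_0$ and $G$ together imply the ratio of the local
  baseline to true eupnea, $c = 100(1+G)/(b_0 + 100G)$ (the fitted model's
  own eupneic fixed point), and ventilation and drive are multiplied by $c$
  before traits are read, so traits are expressed relative to true eupnea.
* **Night-level $\gamma$ and $b_0$.** Both describe slow physiology (the
  arousal response; the normalization offset). They are estimated once per
  night and held fixed across windows; each 7-min window then refits only
  its gain and dynamics. Estimating all four per window lets severe nights
  collapse into a degenerate "obstructed level versus aroused level"
  two-parameter description. When nearly every fit breath is aroused the
  arousal indicator is collinear with the intercept, and $\gamma$ is pinned
  at its physiological prior of 20 %eupnea.
* **A flow-limitation screen.** Some obstructed breaths are never scored
  (ventilation above the scoring threshold but below drive). Breaths inside
  scored arousal margins — plus the few seconds after, while the airway is
  still open — are securely open; a fit anchored on them predicts what every
  open breath should ventilate, and non-event breaths falling far below that
  prediction (1.5 robust SDs) are excluded from the fit domain as unscored
  flow limitation.
* **Ridge regularization of $(\tau, G)$.** The SSE surface is nearly flat
  along a ridge on which the drive *series* barely changes but its
  decomposition into gain and time constant varies widely. Among
  statistically indistinguishable fits the package prefers the canonical
  chemoreflex values ($\tau$ = 60 s, $\delta$ = 10 s, $\gamma$ = 20,
  $b_0$ = 100), trading about 5% relative SSE per unit of preference.
* **Event overlap.** A breath counts as in-event only when it overlaps the
  event by more than 0.5 s: detected breath edges jitter by fractions of a
  second against scored event edges, and without the tolerance the first
  recovery breath of every event — the breath that best reveals peak drive —
  is lost to a sliver of overlap.

Windows are 7 min advanced by 3.5 min inside contiguous NREM segments; a
window is valid if it holds at least one scored event, at least 20
unobstructed breaths, and under 50% wake. Flat SSE surfaces and
near-constant disturbances set `identifiable = FALSE`, which flags the
loop-gain traits downstream rather than silently reporting them.

## The endogram and the traits

Breaths are binned into equal-count total-drive bins (centiles when at least
1000 breaths are in scope) and each bin is summarized by its median drive
and median ventilation: the **endogram**, the ventilation-versus-drive
signature of the night. Traits are read off it:

* **Vpassive** — ventilation at 100% (eupneic) drive: collapsibility.
* **Vactive** — ventilation at the arousal-threshold drive.
* **Compensation** — Vactive − Vpassive, the ventilation recovered by
  dilator-muscle activation as drive rises.
* **Vmin** — median ventilation of the lowest-drive decile, a collapsibility
  measure insensitive to systematic drive bias.
* **Arousal threshold** — median chemical drive of the last breath ending
  before each scored arousal (arousals with no such breath within 30 s are
  skipped).
* **LG1 / LGn** — from the fitted chemoreflex parameters.

Breaths inside arousal margins (plus 10 s after) are excluded from the
endogram and Vmin: the arousal has opened the airway, so those breaths
describe open-airway breathing, not the sleeping pharynx the traits
characterize; left in, they sit on the ventilation = drive identity line and
drag Vpassive and Vactive toward the drive axis. Interpolation beyond the
observed drive range clamps to the edge bin and sets an extrapolation flag
rather than extending linearly.

Night values are medians across valid windows (`vactive` is rebuilt from the
night `vpassive + compensation` so the identity holds exactly), with 95%
intervals from a seeded bootstrap over windows (B = 1000). Classification
against shipped reference tertiles (two community cohorts and one clinical
cohort) labels each trait low / moderate / high; values exactly on a
boundary are moderate, and no cohort is a default.

## The simulator

`simulate_night()` closes the loop the analysis assumes: chemical drive
follows the same delayed first-order dynamics, driven by the achieved (noisy)
ventilation; the airway delivers `vpassive_true + comp_slope * (drive - 100)`
above eupneic drive and `min(drive, vpassive_true)` below it (a convention —
the behavior of a collapsed airway below eupneic drive has to be fixed for a
closed loop, and the passive capacity is the natural ceiling); an arousal
triggers when chemical drive reaches `threshold_true`, lasts 10 s, adds
`arousal_gamma`, and holds the airway open 5 s beyond its end (recovery
hyperpnea). Multiplicative lognormal noise (`noise_sd`, mean-one corrected)
perturbs each breath's achieved ventilation; flow is synthesized as half-sine
inspiration/expiration; events are auto-scored from the noiseless
ventilation (runs below 70% of eupnea lasting 10 s or more; apnea when the
minimum falls below 10%), so ground-truth event boundaries stay crisp.
Scored arousal annotations extend to the end of the last breath that
received the wakefulness drive, so the margin rule tags exactly the aroused
breaths. Configurations with `comp_slope <= -1/gain_G` are rejected: a
steeper negative slope makes the obstructed branch a runaway positive
feedback loop.

What the simulator does *not* emulate: flow-shape changes under partial
obstruction (its flow is always half-sine), REM physiology, position
effects, SpO2, scorer variability, and — importantly — integral (CO2-store)
control, so sustained mean ventilation can sit below eupnea in severe
configurations, which real chemostatic physiology would partly correct.
Passing recovery tests on simulated nights therefore demonstrates internal
consistency of the method under its own model class, not clinical accuracy.

## Numerical and design notes

* Drive is evaluated at inspiratory onsets; with a positive circulatory
  delay this avoids any algebraic loop between a breath's drive and its own
  ventilation.
* The 2-D grid plus closed-form non-negative solve makes the fit convex at
  every grid point; the continuous polish is a local refinement from the
  selected grid point and respects the same regularized objective.
* Bootstrap confidence intervals and all simulator draws are seeded;
  identical inputs, configuration, and seed give byte-identical reports.
* Windowed analyses use 2-h simulated nights in the package's recovery
  studies; the estimator itself has no record-length assumptions beyond one
  valid 7-min window.

## Known limitations

* With no scored events (mild or stable nights) there is no valid analysis
  window and the night fails with a diagnostic — by design, as the method
  needs obstruction to reveal the airway's behavior.
* In severely flow-limited nights only arousal-burst breaths inform the fit;
  the gain/time-constant decomposition of loop gain is then weakly
  identified even though the drive series itself (and with it Vpassive,
  compensation, and the arousal threshold) remains accurate. Loop-gain
  values carry the `identifiable` flag for this reason.
* All traits are expressed relative to estimated eupnea; the calibration
  recovers the local-baseline offset only through the fitted model, and
  residual unit error of a few percent is expected in heavily obstructed
  sleep.
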
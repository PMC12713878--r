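#' Surrogate endotype indices from the scored study alone
#'
#' Simple polysomnography-report quantities that track the endotypes without
#' any signal modelling: the apnea-hypopnea index (AHI), the hypopnea
#' fraction `F_hypopnea` (lower values reflect greater collapsibility), the
#' mean obstructive apnea duration (shorter events suggest a lower arousal
#' threshold), the NREM obstructive-apnea-index to NREM-AHI ratio, and the
#' REM-AHI to NREM-AHI ratio (high NREM-relative event rates suggest higher
#' loop gain). Total sleep time comes from the staged epochs; each event is
#' attributed to the stage it overlaps most.
#'
#' @param annotations An `annotation_set` with staged epochs.
#' @param total_sleep_time_h Override for total sleep time in hours;
#'   computed from non-wake epochs when `NULL`.
#' @return A one-row tibble: `tst_h`, `ahi`, `f_hypopnea`,
#'   `mean_oa_duration_s`, `nrem_oai_over_nrem_ahi`, `rem_ahi_over_nrem_ahi`.
#'   Undefined ratios are `NA`.
#' @export
surrogate_indices <- function(annotations, total_sleep_time_h = NULL) {
  annotations <- as_annotations(annotations)
  ev <- ann_events(annotations)
  st <- ann_stages(annotations)
  if (nrow(st) == 0) stop_input("surrogate indices need staged epochs")

  sleep <- st[st$label != "W", , drop = FALSE]
  tst_h <- total_sleep_time_h %||% (sum(sleep$duration_s) / 3600)
  if (!is.finite(tst_h) || tst_h <= 0) stop_input("total sleep time must be > 0")

  n_ev <- nrow(ev)
  is_apnea <- ev$label %in% c("obstructive_apnea", "central_apnea", "mixed_apnea")
  is_hyp <- ev$label == "hypopnea"
  ahi <- n_ev / tst_h
  f_hyp <- if (n_ev > 0) sum(is_hyp) / n_ev else NA_real_
  oa_dur <- ev$duration_s[ev$label == "obstructive_apnea"]
  mean_oa <- if (length(oa_dur) > 0) mean(oa_dur) else NA_real_

  # attribute each event to the stage class it overlaps most
  stage_of_event <- vapply(seq_len(n_ev), function(i) {
    a <- ev$onset_s[i]
    b <- a + ev$duration_s[i]
    ov <- pmin(b, st$onset_s + st$duration_s) - pmax(a, st$onset_s)
    ov[ov < 0] <- 0
    if (sum(ov) == 0) return(NA_character_)
    cls <- ifelse(st$label == "R", "REM", ifelse(st$label == "W", "W", "NREM"))
    by_cls <- tapply(ov, cls, sum)
    names(by_cls)[which.max(by_cls)]
  }, character(1))

  nrem_h <- sum(st$duration_s[st$label %in% nrem_stages]) / 3600
  rem_h <- sum(st$duration_s[st$label == "R"]) / 3600
  nrem_ev <- sum(stage_of_event == "NREM", na.rm = TRUE)
  nrem_oa <- sum(stage_of_event == "NREM" & ev$label == "obstructive_apnea", na.rm = TRUE)
  rem_ev <- sum(stage_of_event == "REM", na.rm = TRUE)

  nrem_ahi <- if (nrem_h > 0) nrem_ev / nrem_h else NA_real_
  nrem_oai <- if (nrem_h > 0) nrem_oa / nrem_h else NA_real_
  rem_ahi <- if (rem_h > 0) rem_ev / rem_h else NA_real_

  tibble::tibble(
    tst_h = tst_h,
    ahi = ahi,
    f_hypopnea = f_hyp,
    mean_oa_duration_s = mean_oa,
    nrem_oai_over_nrem_ahi = if (!is.na(nrem_ahi) && nrem_ahi > 0) nrem_oai / nrem_ahi else NA_real_,
    rem_ahi_over_nrem_ahi = if (!is.na(rem_ahi) && !is.na(nrem_ahi) && nrem_ahi > 0) rem_ahi / nrem_ahi else NA_real_
  )
}
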
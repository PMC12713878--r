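#' Published reference tertiles for the endotypic traits
#'
#' Tertile boundaries (33rd and 66th percentiles) of the NREM endotypic
#' traits in three previously characterized cohorts analyzed with the same
#' polysomnographic endotyping approach: MrOS (Osteoporotic Fractures in Men
#' Study, community, older men), MESA (Multi-Ethnic Study of Atherosclerosis,
#' community), and CMUH (China Medical University Hospital, clinical sleep
#' cohort). They give each trait a low / moderate / high context; no cohort
#' is a default, because the appropriate reference depends on the population
#' the patient comes from.
#'
#' @param cohort One of `"MrOS"`, `"MESA"`, `"CMUH"`, or a data frame with
#'   columns `trait`, `p33`, `p66` supplying custom boundaries.
#' @return A tibble with columns `trait`, `p33`, `p66`.
#' @export
reference_tertiles <- function(cohort) {
  if (is.data.frame(cohort)) {
    req <- c("trait", "p33", "p66")
    if (!all(req %in% names(cohort))) {
      stop_input("custom tertiles need columns trait, p33, p66")
    }
    out <- tibble::as_tibble(cohort[req])
    if (any(out$p33 > out$p66)) stop_input("tertiles must satisfy p33 <= p66")
    return(out)
  }
  cohort <- match.arg(cohort, c("MrOS", "MESA", "CMUH"))
  tab <- tibble::tribble(
    ~trait,              ~MrOS_33, ~MESA_33, ~CMUH_33, ~MrOS_66, ~MESA_66, ~CMUH_66,
    "vpassive",              70.3,     76.8,     58.7,     78.7,     83.7,     75.5,
    "vmin",                  46.1,     63.2,     45.7,     64.9,     74.8,     59.4,
    "compensation",           4.1,      4.3,     -7.4,     11.1,      8.2,      6.2,
    "lg1",                   0.54,     0.49,     0.46,     0.68,     0.62,     0.60,
    "lgn",                   0.45,     0.38,     0.34,     0.55,     0.47,     0.42,
    "arousal_threshold",    134.9,    127.7,    142.4,    156.0,    144.4,    165.3
  )
  tibble::tibble(
    trait = tab$trait,
    p33 = tab[[paste0(cohort, "_33")]],
    p66 = tab[[paste0(cohort, "_66")]]
  )
}

#' Classify night traits against reference tertiles
#'
#' Labels each trait `low` (below the 33rd percentile), `moderate` (up to and
#' including the 66th percentile; values exactly on either boundary are
#' moderate), or `high` (above the 66th percentile) relative to a reference
#' cohort. Undefined traits are labelled `"n/a"`.
#'
#' @param night A night trait tibble (columns `trait`, `estimate`), e.g. the
#'   `night` element of [derive_endotypes()], or an `endotype_set`.
#' @param ref A cohort name or custom tertile table for
#'   [reference_tertiles()].
#' @return `night` with `p33`, `p66`, and `label` columns (traits without
#'   reference boundaries keep `label = "n/a"`).
#' @export
classify_traits <- function(night, ref) {
  if (inherits(night, "endotype_set")) night <- night$night
  if (!is.data.frame(night) || !all(c("trait", "estimate") %in% names(night))) {
    stop_input("`night` must have columns `trait` and `estimate`")
  }
  tert <- reference_tertiles(ref)
  out <- dplyr::left_join(tibble::as_tibble(night), tert, by = "trait")
  out$label <- dplyr::case_when(
    is.na(out$estimate) | is.na(out$p33) ~ "n/a",
    out$estimate < out$p33 ~ "low",
    out$estimate <= out$p66 ~ "moderate",
    TRUE ~ "high"
  )
  out
}
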
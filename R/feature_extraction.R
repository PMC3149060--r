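# Episode-level predictor derivation. For each predictor the value
# "most indicative of infection" observed during the surveillance
# episode is taken: the maximum for markers that rise with infection
# (CRP, leukocytes, thrombocytes, CSF cell counts, CSF protein) and the
# minimum for markers that fall (hemoglobin, CSF glucose).

WORST_DIRECTION <- c(
  crp = "max", blood_leukocytes = "max", hemoglobin = "min",
  thrombocytes = "max", csf_leukocytes = "max", csf_erythrocytes = "max",
  csf_neutrophils = "max", csf_neutrophil_pct = "max",
  csf_glucose = "min", csf_protein = "max"
)

#' Worst value of a laboratory series within an episode
#'
#' @param values Numeric measurements taken within the episode.
#' @param direction `"max"` for markers that rise with infection,
#'   `"min"` for markers that fall.
#' @return The extremum, or `NA` for an empty series.
#' @export
#' @examples
#' worst_value(c(10, 200, 50), "max") # 200
#' worst_value(c(3.4, 1.1, 2.0), "min") # 1.1
worst_value <- function(values, direction = c("max", "min")) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  if (direction == "max") max(values) else min(values)
}

#' Reclassify probable skin-flora contaminant cultures as negative
#'
#' A culture growing coagulase-negative staphylococci (CoNS) is
#' considered a contaminant — and its positive flag cleared — unless
#' antibiotic therapy was initiated between one day before and three
#' days after the culture. Non-CoNS results are never altered, and no
#' negative result is ever flipped positive.
#'
#' @param cultures Tibble with `patient_id`, `day`, `cons_flag`,
#'   `positive_flag`.
#' @param antibiotics Tibble with `patient_id`, `start_day`.
#' @return `cultures` with a `corrected_positive` column.
#' @export
correct_contamination <- function(cultures, antibiotics) {
  starts <- split(antibiotics$start_day, antibiotics$patient_id)
  corrected <- cultures$positive_flag
  needs_check <- which(cultures$positive_flag & cultures$cons_flag)
  for (i in needs_check) {
    s <- starts[[cultures$patient_id[i]]] %||% integer(0)
    d <- cultures$day[i]
    if (!any(s >= d - 1 & s <= d + 3)) corrected[i] <- FALSE
  }
  cultures$corrected_positive <- corrected
  cultures
}

#' Episode-level culture result (CSF and/or drain)
#'
#' @param cultures Contamination-corrected culture rows of one episode,
#'   already restricted to CSF and drain(-tip) sites within the episode
#'   window.
#' @param no_culture Value when no culture was taken: `NA` (default;
#'   imputed downstream, mirroring the treatment of never-sampled
#'   episodes) or `0` for a strict negative interpretation.
#' @return 1, 0 or `NA`.
#' @export
any_positive_culture <- function(cultures, no_culture = NA_real_) {
  if (nrow(cultures) == 0) return(no_culture)
  as.numeric(any(cultures$corrected_positive))
}

EMPIRIC_LATE_PAIR <- c("vancomycin", "ceftazidime")
EMPIRIC_EARLY_PAIR <- c("ceftriaxone", "flucloxacillin")

#' Detect protocolized empiric antibiotic therapy
#'
#' Empiric therapy for drain-related meningitis is the simultaneous use
#' of vancomycin and ceftazidime started four or more days after
#' admission, or of ceftriaxone and flucloxacillin initiated within the
#' first four days. "Simultaneous" is operationalized as first start
#' days within one day of each other.
#'
#' @param antibiotics Antibiotic-start rows of one episode with `agent`
#'   (lowercase canonical names) and `start_day`.
#' @return 1 if either protocol pair is detected, else 0.
#' @export
detect_empiric_therapy <- function(antibiotics) {
  first_start <- function(agent) {
    d <- antibiotics$start_day[antibiotics$agent == agent]
    if (length(d)) min(d) else NA_integer_
  }
  late <- vapply(EMPIRIC_LATE_PAIR, first_start, numeric(1))
  early <- vapply(EMPIRIC_EARLY_PAIR, first_start, numeric(1))
  late_hit <- !any(is.na(late)) && all(late >= 4) &&
    abs(late[1] - late[2]) <= 1
  early_hit <- !any(is.na(early)) && all(early <= 4) &&
    abs(early[1] - early[2]) <= 1
  as.numeric(late_hit || early_hit)
}

#' Number of distinct systemic antibiotics started in an episode
#'
#' Surrogate marker for concomitant infections: counts distinct
#' systemic agents whose first start falls inside the surveillance
#' episode.
#'
#' @param antibiotics Antibiotic-start rows of one episode with
#'   `agent` and `systemic` columns.
#' @return Non-negative integer count.
#' @export
count_antibiotics_started <- function(antibiotics) {
  length(unique(antibiotics$agent[antibiotics$systemic]))
}

#' Polynomial C-reactive protein terms
#'
#' Returns the linear, squared and cubic CRP terms on the scales used in
#' the prediction model: `crp` (mg/L), `(crp/10)^2` and `(crp/100)^3`.
#'
#' @param crp CRP in mg/L (non-negative).
#' @return Named numeric vector `c(crp, crp_sq, crp_cu)`.
#' @export
#' @examples
#' crp_terms(100) # c(crp = 100, crp_sq = 100, crp_cu = 1)
crp_terms <- function(crp) {
  if (any(crp < 0, na.rm = TRUE)) abort("CRP must be non-negative.")
  c(crp = crp, crp_sq = (crp / 10)^2, crp_cu = (crp / 100)^3)
}

CSF_LOG_OFFSET <- 1

#' Derive the episode-level feature matrix
#'
#' Assembles one predictor row per included episode: worst-in-episode
#' laboratory values (direction per the fixed direction table),
#' contamination-corrected culture result, empiric-therapy flag,
#' distinct systemic antibiotic count, CRP polynomial terms and the
#' natural-log-transformed CSF leukocyte count (`log(count + offset)`,
#' counts in hundreds per microlitre). Events from every surveillance
#' window of the episode (including merged readmissions) contribute.
#' Missing stays missing: absent analytes and untaken cultures are
#' passed through as `NA` for the imputation stage.
#'
#' @param episodes A `drm_episodes` tibble (typically the `included`
#'   element of [apply_exclusions()]).
#' @param tables The raw `drm_tables` the episodes were built from.
#' @param csf_log_offset Offset added before log-transforming CSF
#'   leukocytes (default 1; zero counts occur).
#' @param csf_leuko_binary_threshold Threshold (in 100/uL) above which
#'   the screening-only binary CSF leukocyte indicator is 1.
#' @param no_culture Passed to [any_positive_culture()].
#' @return A tibble of class `drm_features`, one row per episode, with
#'   the outcome attached when `tables$outcomes` is present.
#' @export
extract_features <- function(episodes, tables,
                             csf_log_offset = CSF_LOG_OFFSET,
                             csf_leuko_binary_threshold = 5,
                             no_culture = NA_real_) {
  # one row per (episode, surveillance window); events join on patient
  win <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(episodes), "episode_id", "windows"),
    "windows") |>
    dplyr::rename(win_start = "start_day", win_end = "end_day")

  # laboratory worst values (direction per the fixed direction table)
  lab <- dplyr::inner_join(tables$labs, win, by = "patient_id",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$day >= .data$win_start,
                  .data$day <= .data$win_end) |>
    dplyr::group_by(.data$episode_id, .data$analyte) |>
    dplyr::summarise(worst = worst_value(
      .data$value, WORST_DIRECTION[[.data$analyte[1]]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "worst")
  for (a in names(WORST_DIRECTION)) {
    if (!a %in% names(lab)) lab[[a]] <- NA_real_
  }

  # contamination-corrected episode culture result
  cultures <- correct_contamination(tables$cultures, tables$antibiotics)
  cultures <- cultures[cultures$site %in% c("CSF", "drain"), ]
  cult <- dplyr::inner_join(cultures, win, by = "patient_id",
                            relationship = "many-to-many") |>
    dplyr::filter(.data$day >= .data$win_start,
                  .data$day <= .data$win_end) |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::summarise(
      culture_positive = as.numeric(any(.data$corrected_positive)),
      .groups = "drop")

  # antibiotic exposure
  abx <- dplyr::inner_join(tables$antibiotics, win, by = "patient_id",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$start_day >= .data$win_start,
                  .data$start_day <= .data$win_end)
  abx_summary <- abx |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::summarise(
      n_abx_started = length(unique(.data$agent[.data$systemic])),
      abx_after_day4 = as.numeric(any(.data$systemic &
                                        .data$start_day > 4)),
      empiric_abx = detect_empiric_therapy(
        dplyr::pick("agent", "start_day")),
      .groups = "drop")

  feats <- tibble::tibble(episode_id = episodes$episode_id) |>
    dplyr::left_join(lab, by = "episode_id") |>
    dplyr::left_join(cult, by = "episode_id") |>
    dplyr::left_join(abx_summary, by = "episode_id") |>
    dplyr::mutate(
      crp_sq = (.data$crp / 10)^2,
      crp_cu = (.data$crp / 100)^3,
      csf_leukocytes_log = log(.data$csf_leukocytes + csf_log_offset),
      csf_leuko_binary = as.numeric(
        .data$csf_leukocytes > csf_leuko_binary_threshold),
      n_abx_started = dplyr::coalesce(.data$n_abx_started, 0L),
      abx_after_day4 = dplyr::coalesce(.data$abx_after_day4, 0),
      empiric_abx = dplyr::coalesce(.data$empiric_abx, 0)
    )
  # "no culture taken" stays NA under the default policy (imputed
  # downstream); strict mode maps it to `no_culture`
  if (!is.na(no_culture)) {
    feats$culture_positive <- dplyr::coalesce(feats$culture_positive,
                                              no_culture)
  }
  meta <- tibble::tibble(
    episode_id = episodes$episode_id,
    drain_type_evd = as.numeric(episodes$drain_type == "EVD"),
    n_drains = as.numeric(episodes$n_drains),
    total_drain_days = as.numeric(episodes$total_drain_days),
    days_at_risk = as.numeric(episodes$days_at_risk),
    admission_days = as.numeric(episodes$discharge_day),
    icu_days = as.numeric(episodes$icu_days),
    age = episodes$age,
    year = episodes$year
  )
  out <- dplyr::left_join(meta, feats, by = "episode_id")
  if (!is.null(tables$outcomes)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(tables$outcomes, episode_id = "patient_id", "drm_flag"),
      by = "episode_id")
  }
  class(out) <- c("drm_features", class(out))
  out
}

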
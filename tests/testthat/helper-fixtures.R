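# Shared fixtures, built in code.

# A hand-checkable three-patient event set:
#   A: adult, EVD day 3 -> 10, discharge 30; CRP 10/200/50, CSF sampled,
#      CoNS culture day 8 with vancomycin started day 9 (stays positive)
#   B: adult, ELD day 0 -> 5, discharge 12; CoNS culture day 2 with no
#      antibiotics nearby (corrected to negative); no CSF labs
#   C: 17-year-old (excluded downstream)
tiny_tables <- function() {
  patients <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    person_id = c("A", "B", "C"),
    admission_seq = 1L,
    days_since_prior_discharge = NA_real_,
    age = c(60, 45, 17),
    sex = c("F", "M", "F"),
    admission_day = 0L,
    discharge_day = c(30L, 12L, 20L),
    icu_admitted = c(TRUE, FALSE, FALSE),
    icu_days = c(4, 0, 0),
    death_day = NA_integer_,
    year = c(2005L, 2006L, 2007L),
    preexisting_cns_infection = FALSE,
    drain_other_centre = FALSE,
    external_site = FALSE
  )
  drains <- tibble::tibble(
    patient_id = c("A", "A", "B", "C"),
    drain_id = c("A-D1", "A-D2", "B-D1", "C-D1"),
    drain_type = c("EVD", "ELD", "ELD", "EVD"),
    insertion_day = c(3L, 12L, 0L, 1L),
    removal_day = c(10L, 20L, 5L, 4L),
    indication = "SAH/IVH"
  )
  labs <- tibble::tibble(
    patient_id = c("A", "A", "A", "A", "A", "B"),
    day = c(4L, 6L, 9L, 5L, 7L, 1L),
    analyte = c("crp", "crp", "crp", "csf_leukocytes", "csf_glucose",
                "crp"),
    value = c(10, 200, 50, 12, 1.8, 40),
    unit = c("mg/L", "mg/L", "mg/L", "1e2/uL", "mmol/L", "mg/L")
  )
  cultures <- tibble::tibble(
    patient_id = c("A", "B"),
    day = c(8L, 2L),
    site = c("CSF", "drain"),
    organism = "coagulase-negative staphylococcus",
    cons_flag = TRUE,
    positive_flag = TRUE
  )
  antibiotics <- tibble::tibble(
    patient_id = c("A", "A", "A"),
    agent = c("vancomycin", "ceftazidime", "vancomycin"),
    start_day = c(9L, 9L, 15L),
    systemic = TRUE
  )
  outcomes <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    drm_flag = c(1L, 0L, 0L),
    infection_day = c(8L, NA_integer_, NA_integer_)
  )
  structure(list(patients = patients, drains = drains, labs = labs,
                 cultures = cultures, antibiotics = antibiotics,
                 outcomes = outcomes),
            class = "drm_tables")
}

# Minimal single-patient tables for episode-boundary cases.
one_patient_tables <- function(insertions, removals, discharge,
                               age = 50, death_day = NA_integer_,
                               drain_type = NULL, seq = 1L,
                               gap = NA_real_, person = "P1",
                               id = "P1") {
  k <- length(insertions)
  if (is.null(drain_type)) drain_type <- rep("EVD", k)
  structure(list(
    patients = tibble::tibble(
      patient_id = id, person_id = person, admission_seq = seq,
      days_since_prior_discharge = gap, age = age, sex = "F",
      admission_day = 0L, discharge_day = as.integer(discharge),
      icu_admitted = FALSE, icu_days = 0,
      death_day = as.integer(death_day), year = 2005L,
      preexisting_cns_infection = FALSE, drain_other_centre = FALSE,
      external_site = FALSE),
    drains = tibble::tibble(
      patient_id = id, drain_id = paste0(id, "-D", seq_len(k)),
      drain_type = drain_type,
      insertion_day = as.integer(insertions),
      removal_day = as.integer(removals), indication = "Other"),
    labs = tibble::tibble(patient_id = character(0), day = integer(0),
                          analyte = character(0), value = numeric(0),
                          unit = character(0)),
    cultures = tibble::tibble(patient_id = character(0), day = integer(0),
                              site = character(0), organism = character(0),
                              cons_flag = logical(0),
                              positive_flag = logical(0)),
    antibiotics = tibble::tibble(patient_id = character(0),
                                 agent = character(0),
                                 start_day = integer(0),
                                 systemic = logical(0)),
    outcomes = tibble::tibble(patient_id = id, drm_flag = 0L,
                              infection_day = NA_integer_)
  ), class = "drm_tables")
}

bind_tables <- function(a, b) {
  structure(purrr::map2(unclass(a), unclass(b), dplyr::bind_rows),
            class = "drm_tables")
}

# A large complete cohort, generated once per test run and reused.
big_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_patients = 20000, seed = 20)
      tb <- generate_cohort(cfg)
      ep <- apply_exclusions(merge_readmissions(build_episodes(tb)))
      cache <<- list(config = cfg, tables = tb,
                     episodes = ep$included,
                     features = extract_features(ep$included, tb))
    }
    cache
  }
})

# Shared generator config for rule-based simulation (marginals only).
sim_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generator_config(n_patients = 10, seed = 1)
    cache
  }
})
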
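# Surveillance episodes: from raw event tables to analyzable episodes.
# An episode runs from the day of first drain placement up to seven days
# after removal of the last drain, or up to discharge, whichever comes
# first. All day fields are integer offsets from admission (day 0).

FOLLOWUP_DAYS <- 7L
READMISSION_WINDOW <- 30L

#' Build surveillance episodes from raw event tables
#'
#' Creates one surveillance episode per admission with drains. The
#' episode starts the day the first drain is placed and ends at
#' `min(last removal + 7, discharge)`. Drain records are ordered by
#' insertion; the episode drain type is `"EVD"` if any drain is an
#' external ventricular drain (EVD priority over lumbar drains).
#'
#' @param tables A `drm_tables` object (or any list with `patients` and
#'   `drains` tibbles following the documented schema).
#' @return A tibble of class `drm_episodes`, one row per admission, with
#'   a `windows` list-column of per-admission surveillance windows
#'   (used after readmission merging).
#' @export
build_episodes <- function(tables) {
  drains <- tables$drains
  patients <- tables$patients
  if (nrow(drains) == 0) abort("no drain records: nothing to build.")
  if (any(drains$removal_day < drains$insertion_day)) {
    abort("drain removal before insertion in input tables.")
  }
  drains <- dplyr::arrange(drains, .data$patient_id, .data$insertion_day)

  per <- drains |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      start_day = min(.data$insertion_day),
      last_removal = max(.data$removal_day),
      n_drains = dplyr::n(),
      drain_type = if (any(.data$drain_type == "EVD")) "EVD" else "ELD",
      total_drain_days = sum(.data$removal_day - .data$insertion_day),
      simultaneous_drains = has_overlapping_drains(
        .data$insertion_day, .data$removal_day),
      .groups = "drop"
    )

  ep <- dplyr::inner_join(per, patients, by = "patient_id") |>
    dplyr::mutate(
      end_day = pmin(.data$last_removal + FOLLOWUP_DAYS, .data$discharge_day),
      days_at_risk = .data$total_drain_days
    )
  ep$episode_id <- ep$patient_id
  ep$merged_admissions <- 1L
  ep$windows <- purrr::pmap(
    list(ep$patient_id, ep$start_day, ep$end_day),
    function(pid, s, e) tibble::tibble(patient_id = pid,
                                       start_day = s, end_day = e))
  ep <- dplyr::select(
    ep, "episode_id", "patient_id", "person_id", "admission_seq",
    "days_since_prior_discharge", "start_day", "end_day", "n_drains",
    "drain_type", "total_drain_days", "days_at_risk",
    "simultaneous_drains", "age", "sex", "discharge_day", "icu_admitted",
    "icu_days", "death_day", "year", "preexisting_cns_infection",
    "drain_other_centre", "external_site", "merged_admissions", "windows")
  class(ep) <- c("drm_episodes", class(ep))
  ep
}

# Half-open intervals [insertion, removal): a drain exchanged on the day
# of removal does not count as simultaneous.
has_overlapping_drains <- function(ins, rem) {
  k <- length(ins)
  if (k < 2) return(FALSE)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (ins[i] < rem[j] && ins[j] < rem[i]) return(TRUE)
    }
  }
  FALSE
}

#' Fold early readmissions into their parent surveillance episode
#'
#' A readmission starting within `window_days` of the prior discharge is
#' folded into the prior episode's surveillance record: drain counts,
#' drainage days and days at risk accumulate, and the readmission's
#' surveillance window is appended to the `windows` list-column so
#' events from both admissions contribute to feature extraction. A
#' readmission beyond the window remains a separate record and is
#' flagged for exclusion downstream.
#'
#' @param episodes A `drm_episodes` tibble (sorted per person by
#'   `admission_seq`).
#' @param window_days Merge window in days after discharge (default 30).
#' @return A `drm_episodes` tibble with merged records.
#' @export
merge_readmissions <- function(episodes, window_days = READMISSION_WINDOW) {
  episodes <- dplyr::arrange(episodes, .data$person_id, .data$admission_seq)
  out <- vector("list", nrow(episodes))
  n_out <- 0
  last_idx_for <- character(0)
  for (i in seq_len(nrow(episodes))) {
    row <- episodes[i, ]
    gap <- row$days_since_prior_discharge
    pid <- row$person_id
    if (!is.na(gap) && gap <= window_days && pid %in% names(last_idx_for)) {
      j <- as.integer(last_idx_for[[pid]])
      parent <- out[[j]]
      parent$n_drains <- parent$n_drains + row$n_drains
      parent$total_drain_days <- parent$total_drain_days + row$total_drain_days
      parent$days_at_risk <- parent$days_at_risk + row$days_at_risk
      parent$drain_type <- if ("EVD" %in% c(parent$drain_type, row$drain_type))
        "EVD" else "ELD"
      parent$merged_admissions <- parent$merged_admissions + 1L
      parent$simultaneous_drains <- parent$simultaneous_drains ||
        row$simultaneous_drains
      parent$windows[[1]] <- dplyr::bind_rows(parent$windows[[1]],
                                              row$windows[[1]])
      out[[j]] <- parent
    } else {
      n_out <- n_out + 1
      out[[n_out]] <- row
      last_idx_for[[pid]] <- n_out
    }
  }
  res <- dplyr::bind_rows(out[seq_len(n_out)])
  class(res) <- c("drm_episodes", setdiff(class(res), "drm_episodes"))
  res
}

exclusion_rules <- function() {
  list(
    death_within_1day = function(e)
      !is.na(e$death_day) & (e$death_day - e$start_day) <= 1,
    age_under_18 = function(e) e$age < 18,
    preexisting_cns_infection = function(e) e$preexisting_cns_infection,
    simultaneous_drains = function(e) e$simultaneous_drains,
    drain_other_centre = function(e) e$drain_other_centre,
    admission_under_1day = function(e) e$discharge_day < 1,
    readmission_over_30days = function(e)
      !is.na(e$days_since_prior_discharge) &
        e$days_since_prior_discharge > READMISSION_WINDOW,
    external_site = function(e) e$external_site
  )
}

#' Apply the surveillance inclusion/exclusion criteria
#'
#' Evaluates every episode against all eight exclusion criteria (death
#' within one day of drain placement, age under 18, pre-existing CNS
#' infection, more than one simultaneous drain, drain placed at another
#' centre, admission shorter than one day, readmission more than 30
#' days after a prior in-study drainage episode, external/referring
#' site). All triggered reasons are recorded; the filter is idempotent.
#'
#' @param episodes A `drm_episodes` tibble (after
#'   [merge_readmissions()] if readmissions are present).
#' @return A list with `included` (episodes passing all criteria, with
#'   an empty `exclusion_reasons` entry) and `log`, a tibble of
#'   `(episode_id, reason)` rows, one per triggered criterion.
#' @export
apply_exclusions <- function(episodes) {
  rules <- exclusion_rules()
  if (nrow(episodes) == 0) {
    episodes$exclusion_reasons <- list()
    return(list(included = episodes,
                log = tibble::tibble(episode_id = character(0),
                                     reason = character(0))))
  }
  hit <- vapply(rules, function(f) as.logical(f(episodes)),
                logical(nrow(episodes)))
  if (nrow(episodes) == 1) hit <- matrix(hit, nrow = 1,
                                         dimnames = list(NULL, names(rules)))
  reasons <- apply(hit, 1, function(r) names(rules)[which(r)],
                   simplify = FALSE)
  episodes$exclusion_reasons <- reasons
  excluded <- lengths(reasons) > 0
  log <- tibble::tibble(
    episode_id = rep(episodes$episode_id, lengths(reasons)),
    reason = unlist(reasons) %||% character(0)
  )
  list(included = episodes[!excluded, , drop = FALSE], log = log)
}
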
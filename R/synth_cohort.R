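# Synthetic multi-source hospital event data for external-CSF-drainage
# surveillance. Patients, drains, time-stamped laboratory results,
# microbiology cultures and antibiotic-start events are generated so
# that the *episode-level worst values* recovered downstream follow the
# configured per-group distributions. Correlation between predictors is
# induced through the latent infection flag, except that length of stay
# and total drainage time share a latent severity quantile (longer
# drainage implies longer stay).

# Uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample()).
sample_days <- function(lo, hi, n = 1L) {
  if (hi < lo) hi <- lo
  lo + floor(runif(n) * (hi - lo + 1))
}

draw_group_value <- function(kind, params, n) {
  if (n == 0) return(numeric(0))
  switch(kind,
    lognormal   = rlnorm(n, params$meanlog, params$sdlog),
    logitnormal = 100 * plogis(rnorm(n, params$mu, params$sigma)),
    normal      = rnorm(n, params$mean, params$sd),
    negbin      = rnbinom(n, mu = params$mu, size = params$size),
    pois1       = 1L + rpois(n, params$lambda)
  )
}

# Draw one value per patient from the group-specific distribution.
draw_by_group <- function(drm, kind, p_nodrm, p_drm) {
  out <- numeric(length(drm))
  out[!drm] <- draw_group_value(kind, p_nodrm, sum(!drm))
  out[drm] <- draw_group_value(kind, p_drm, sum(drm))
  out
}

draw_binary <- function(drm, p0, p1) {
  rbinom(length(drm), 1L, ifelse(drm, p1, p0)) == 1L
}

# Quantile-coupled log-normal draws: the same standard-normal severity
# quantile drives both variables within a patient.
draw_coupled_lognormal <- function(z, params) exp(params$meanlog + params$sdlog * z)

target_params <- function(config, variable, drmgroup) {
  row <- config$targets[config$targets$variable == variable, ]
  if (drmgroup) row$params_drm[[1]] else row$params_nodrm[[1]]
}

proportion_of <- function(config, variable) {
  row <- config$proportions[config$proportions$variable == variable, ]
  c(row$p_nodrm, row$p_drm)
}

#' Generate a complete synthetic surveillance cohort
#'
#' Simulates raw event tables (patients/admissions, drain placements,
#' laboratory time series, microbiology cultures, antibiotic starts and
#' the latent infection outcome) for `config$n_patients` admissions.
#' Tables are complete: use [inject_missingness()] to emulate
#' never-measured analytes. The per-episode extremum of each laboratory
#' series is drawn from the configured group distribution and the
#' remaining measurements are scattered on the non-infectious side of
#' it, so downstream worst-value extraction recovers the configured
#' distribution exactly.
#'
#' @param config A [generator_config()] object.
#' @return An object of class `drm_tables`: a list of tibbles
#'   `patients`, `drains`, `labs`, `cultures`, `antibiotics`,
#'   `outcomes`. All day fields are integer offsets from admission
#'   (day 0).
#' @export
#' @examples
#' tables <- generate_cohort(generator_config(n_patients = 50, seed = 7))
#' names(tables)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "drm_config"))
  set.seed(config$seed)
  n <- config$n_patients

  drm <- rbinom(n, 1L, config$prevalence) == 1L
  patient_id <- sprintf("P%05d", seq_len(n))

  # --- patient-level characteristics ----------------------------------
  age <- pmax(18, draw_by_group(drm, "normal",
    target_params(config, "age", FALSE), target_params(config, "age", TRUE)))
  p <- proportion_of(config, "sex_female")
  sex_female <- draw_binary(drm, p[1], p[2])
  p <- proportion_of(config, "death")
  died <- draw_binary(drm, p[1], p[2])
  p <- proportion_of(config, "icu_admitted")
  icu_admitted <- draw_binary(drm, p[1], p[2])

  # shared severity quantile couples stay length and drainage time
  z <- rnorm(n)
  adm_par0 <- target_params(config, "admission_days", FALSE)
  adm_par1 <- target_params(config, "admission_days", TRUE)
  drn_par0 <- target_params(config, "total_drain_days", FALSE)
  drn_par1 <- target_params(config, "total_drain_days", TRUE)
  admission_days <- ifelse(drm, draw_coupled_lognormal(z, adm_par1),
                                draw_coupled_lognormal(z, adm_par0))
  total_drain_days <- ifelse(drm, draw_coupled_lognormal(z, drn_par1),
                                  draw_coupled_lognormal(z, drn_par0))

  icu_days <- icu_stay_days(drm, icu_admitted, admission_days)

  n_drains <- as.integer(draw_by_group(drm, "pois1",
    target_params(config, "n_drains", FALSE),
    target_params(config, "n_drains", TRUE)))
  p <- proportion_of(config, "drain_type_evd")
  has_evd <- draw_binary(drm, p[1], p[2])

  discharge_day <- pmax(2L, as.integer(round(admission_days)))
  year <- sample(config$study_years, n, replace = TRUE,
                 prob = config$year_weights)
  indication <- sample(names(DRAIN_INDICATIONS), n, replace = TRUE,
                       prob = DRAIN_INDICATIONS)

  # --- drains ----------------------------------------------------------
  drains <- build_drain_rows(patient_id, n_drains, has_evd,
                             total_drain_days, discharge_day, indication)
  # discharge can never precede the last removal
  last_removal <- vapply(split(drains$removal_day, drains$patient_id),
                         max, numeric(1))
  discharge_day <- pmax(discharge_day,
                        as.integer(last_removal[patient_id]))

  ep_start <- vapply(split(drains$insertion_day, drains$patient_id),
                     min, numeric(1))[patient_id]
  ep_end <- pmin(last_removal[patient_id] + 7L, discharge_day)

  death_day <- ifelse(died, discharge_day, NA_integer_)

  patients <- tibble::tibble(
    patient_id = patient_id,
    person_id = patient_id,
    admission_seq = 1L,
    days_since_prior_discharge = NA_real_,
    age = age,
    sex = ifelse(sex_female, "F", "M"),
    admission_day = 0L,
    discharge_day = discharge_day,
    icu_admitted = icu_admitted,
    icu_days = icu_days,
    death_day = as.integer(death_day),
    year = year,
    preexisting_cns_infection = FALSE,
    drain_other_centre = FALSE,
    external_site = FALSE
  )

  # --- laboratory time series -----------------------------------------
  labs <- build_lab_rows(config, patient_id, drm, ep_start, ep_end)

  # --- antibiotics -----------------------------------------------------
  p4 <- proportion_of(config, "abx_after_day4")
  abx_after_day4 <- draw_binary(drm, p4[1], p4[2])
  pe <- proportion_of(config, "empiric_abx")
  empiric <- draw_binary(drm, pe[1], pe[2])
  n_abx <- as.integer(draw_by_group(drm, "negbin",
    target_params(config, "n_abx_started", FALSE),
    target_params(config, "n_abx_started", TRUE)))
  antibiotics <- build_antibiotic_rows(patient_id, n_abx, empiric,
                                       abx_after_day4, ep_start, ep_end)

  # --- cultures --------------------------------------------------------
  pc <- proportion_of(config, "culture_positive")
  culture_pos <- draw_binary(drm, pc[1], pc[2])
  cultures <- build_culture_rows(config, patient_id, culture_pos,
                                 ep_start, ep_end, antibiotics)

  # --- outcomes --------------------------------------------------------
  infection_day <- ifelse(
    drm,
    pmin(ep_end, ep_start + 2L +
           floor(runif(n) * pmax(1, ep_end - ep_start - 1))),
    NA_real_)
  outcomes <- tibble::tibble(
    patient_id = patient_id,
    drm_flag = as.integer(drm),
    infection_day = as.integer(infection_day)
  )

  structure(
    list(patients = patients, drains = drains, labs = labs,
         cultures = cultures, antibiotics = antibiotics,
         outcomes = outcomes),
    class = "drm_tables"
  )
}

# ICU stay: zero unless admitted; conditional log-normal solved so that
# the marginal medians/IQRs approximate the published group summaries.
icu_stay_days <- function(drm, icu_admitted, admission_days) {
  n <- length(drm)
  out <- numeric(n)
  par <- list(
    nodrm = lognormal_from_two_quantiles(0.101, 2, 0.550, 5),
    drm   = lognormal_from_two_quantiles(0.306, 4.5, 0.653, 12.3)
  )
  for (g in c(TRUE, FALSE)) {
    idx <- which(drm == g & icu_admitted)
    prm <- if (g) par$drm else par$nodrm
    out[idx] <- rlnorm(length(idx), prm$meanlog, prm$sdlog)
  }
  pmin(out, admission_days)
}

build_drain_rows <- function(patient_id, n_drains, has_evd,
                             total_drain_days, discharge_day, indication) {
  n <- length(patient_id)
  first_insert <- sample(0:2, n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_drains[i]
    # split total drainage time across drains (each at least 1 day)
    w <- runif(k) + 0.25
    dur <- pmax(1, round(total_drain_days[i] * w / sum(w)))
    gaps <- if (k > 1) sample(1:2, k - 1, replace = TRUE) else integer(0)
    ins <- first_insert[i] + cumsum(c(0, dur[-k] + gaps))
    rem <- ins + dur
    # keep the drain chain inside the admission where possible
    overshoot <- max(rem) - discharge_day[i]
    if (overshoot > 0) {
      shift <- min(first_insert[i], overshoot)
      ins <- ins - shift; rem <- rem - shift
      rem <- pmin(rem, discharge_day[i])
      rem <- pmax(rem, ins + 1L)
    }
    type <- rep("ELD", k)
    if (has_evd[i]) {
      type[sample.int(k, 1)] <- "EVD"
      if (k > 1 && runif(1) < 0.3) type[] <- "EVD"
    }
    rows[[i]] <- tibble::tibble(
      patient_id = patient_id[i],
      drain_id = sprintf("%s-D%d", patient_id[i], seq_len(k)),
      drain_type = type,
      insertion_day = as.integer(ins),
      removal_day = as.integer(rem),
      indication = indication[i]
    )
  }
  dplyr::bind_rows(rows)
}

build_lab_rows <- function(config, patient_id, drm, ep_start, ep_end) {
  n <- length(patient_id)
  kmin <- config$measurements_range[1]
  kmax <- config$measurements_range[2]
  unit_of <- setNames(config$targets$unit, config$targets$variable)
  out <- vector("list", length(LAB_ANALYTES))
  for (j in seq_along(LAB_ANALYTES)) {
    analyte <- LAB_ANALYTES[j]
    row <- config$targets[config$targets$variable == analyte, ]
    extremum <- draw_by_group(drm, row$kind,
                              row$params_nodrm[[1]], row$params_drm[[1]])
    direction <- row$direction
    k <- sample(kmin:kmax, n, replace = TRUE)
    idx <- rep(seq_len(n), k)
    total <- length(idx)
    day <- ep_start[idx] +
      floor(runif(total) * (ep_end[idx] - ep_start[idx] + 1))
    # first measurement of each patient carries the extremum
    first <- !duplicated(idx)
    value <- if (identical(direction, "max")) {
      extremum[idx] * runif(total, 0.3, 1)
    } else {
      extremum[idx] * runif(total, 1, 1.6)
    }
    value[first] <- extremum[idx][first]
    if (analyte == "csf_neutrophil_pct") value <- pmin(value, 100)
    out[[j]] <- tibble::tibble(
      patient_id = patient_id[idx],
      day = as.integer(day),
      analyte = analyte,
      value = value,
      unit = unname(unit_of[analyte])
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$patient_id, .data$analyte,
                 .data$day)
}

# Antibiotic-start events. Constraints honoured jointly:
#  - the empiric-therapy flag materialises as the protocol pair
#    (vancomycin + ceftazidime from day >= 4, or ceftriaxone +
#    flucloxacillin within the first four days);
#  - the "any start after day 4" flag controls whether any systemic
#    start falls after day 4.
build_antibiotic_rows <- function(patient_id, n_abx, empiric,
                                  abx_after_day4, ep_start, ep_end) {
  n <- length(patient_id)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    agents <- character(0); days <- integer(0)
    lo <- ep_start[i]; hi <- ep_end[i]
    if (empiric[i]) {
      if (abx_after_day4[i]) {
        d <- sample_days(max(5, lo), max(hi, 5))
        agents <- c("vancomycin", "ceftazidime")
      } else {
        d <- sample_days(lo, max(lo, min(3, hi)))
        agents <- c("ceftriaxone", "flucloxacillin")
      }
      days <- c(d, d + sample(0:1, 1))
    }
    extra <- max(n_abx[i] - length(agents),
                 if (abx_after_day4[i] && !empiric[i]) 1L else 0L)
    if (extra > 0) {
      pool <- setdiff(SYSTEMIC_AGENTS, agents)
      add <- sample(pool, min(extra, length(pool)))
      dlo <- lo; dhi <- hi
      if (!abx_after_day4[i]) dhi <- min(hi, 4L)
      add_days <- sample_days(dlo, dhi, length(add))
      if (abx_after_day4[i] && !empiric[i] && all(add_days <= 4)) {
        add_days[1] <- sample_days(max(5, lo), max(hi, 5))
      }
      agents <- c(agents, add); days <- c(days, add_days)
    }
    if (!abx_after_day4[i]) days <- pmin(days, 4L)
    if (length(agents) == 0) next
    rows[[i]] <- tibble::tibble(
      patient_id = patient_id[i],
      agent = agents,
      start_day = as.integer(pmax(0L, days)),
      systemic = TRUE
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(patient_id = character(0), agent = character(0),
                          start_day = integer(0), systemic = logical(0))
  }
  out
}

# Culture rows. True positives grow CoNS only when an antibiotic start
# covers the contamination-correction window (otherwise the rule would
# reclassify a genuine infection); planted contaminants are CoNS with no
# antibiotic start nearby, so the correction removes them.
build_culture_rows <- function(config, patient_id, culture_pos,
                               ep_start, ep_end, antibiotics) {
  n <- length(patient_id)
  abx_days <- split(antibiotics$start_day, antibiotics$patient_id)
  rows <- vector("list", n)
  organisms <- c("coagulase-negative staphylococcus", "Staphylococcus aureus",
                 "Enterobacteriaceae", "other")
  org_prob <- c(0.338, 0.146, 0.134, 0.382)
  for (i in seq_len(n)) {
    lo <- ep_start[i]; hi <- ep_end[i]
    starts <- abx_days[[patient_id[i]]] %||% integer(0)
    n_cult <- sample(1:2, 1)
    day <- sample_days(lo, hi, n_cult)
    site <- sample(c("CSF", "drain"), n_cult, replace = TRUE,
                   prob = c(0.7, 0.3))
    org <- rep("no growth", n_cult)
    pos <- rep(FALSE, n_cult)
    cons <- rep(FALSE, n_cult)
    if (culture_pos[i]) {
      pos[1] <- TRUE
      org[1] <- sample(organisms, 1, prob = org_prob)
      if (org[1] == organisms[1]) {
        covered <- covered_days(starts, lo, hi)
        if (length(covered)) {
          day[1] <- sample(rep(covered, 2), 1)
          cons[1] <- TRUE
        } else {
          org[1] <- organisms[2]
        }
      }
    } else if (runif(1) < config$contaminant_rate) {
      uncovered <- setdiff(lo:hi, covered_days(starts, lo, hi))
      if (length(uncovered)) {
        day[1] <- sample(rep(uncovered, 2), 1)
        org[1] <- organisms[1]
        pos[1] <- TRUE
        cons[1] <- TRUE
      }
    }
    rows[[i]] <- tibble::tibble(
      patient_id = patient_id[i],
      day = as.integer(day),
      site = site,
      organism = org,
      cons_flag = cons,
      positive_flag = pos
    )
  }
  dplyr::bind_rows(rows)
}

# Days d in [lo, hi] such that some antibiotic start falls in [d-1, d+3].
covered_days <- function(starts, lo, hi) {
  if (!length(starts)) return(integer(0))
  days <- lo:hi
  days[vapply(days, function(d) any(starts >= d - 1 & starts <= d + 3),
              logical(1))]
}

#' Delete never-measured analytes from a complete cohort
#'
#' Emulates pre-imputation missingness: for each configured variable the
#' *entire* per-episode measurement set is removed with the configured
#' probability (an analyte that was never ordered), leaving observed
#' values untouched. Under the `"MAR"` mechanism the deletion odds for
#' DRM episodes are scaled by `config$mar_odds_ratio` while preserving
#' the configured marginal rate; `"MCAR"` deletes uniformly. The
#' variable `"culture"` removes all culture rows of the episode.
#'
#' @param tables A `drm_tables` object from [generate_cohort()].
#' @param config The [generator_config()] used to create it.
#' @param seed Optional integer; when supplied the deletion draws are
#'   seeded independently of the generator stream.
#' @return A `drm_tables` object with rows removed.
#' @export
inject_missingness <- function(tables, config, seed = NULL) {
  stopifnot(inherits(tables, "drm_tables"), inherits(config, "drm_config"))
  if (!is.null(seed)) set.seed(seed)
  miss <- config$missingness
  if (any(miss$rate < 0 | miss$rate > 1)) {
    abort("missingness rates must lie in [0, 1].")
  }
  drm <- setNames(tables$outcomes$drm_flag == 1L, tables$outcomes$patient_id)
  prev <- mean(drm)
  ids <- tables$patients$patient_id
  for (k in seq_len(nrow(miss))) {
    rate <- miss$rate[k]
    if (rate == 0) next
    if (miss$mechanism[k] == "MAR" && rate < 1) {
      pg <- mar_group_rates(rate, prev, config$mar_odds_ratio)
      p_del <- ifelse(drm[ids], pg[2], pg[1])
    } else {
      p_del <- rep(rate, length(ids))
    }
    drop <- ids[runif(length(ids)) < p_del]
    if (miss$variable[k] == "culture") {
      tables$cultures <- tables$cultures[
        !(tables$cultures$patient_id %in% drop), ]
    } else {
      keep <- !(tables$labs$patient_id %in% drop &
                  tables$labs$analyte == miss$variable[k])
      tables$labs <- tables$labs[keep, ]
    }
  }
  tables
}

# Solve per-group deletion probabilities (no-DRM, DRM) whose
# prevalence-weighted mean equals the marginal rate and whose odds
# ratio (DRM vs no-DRM) equals `or`.
mar_group_rates <- function(marginal, prevalence, or) {
  f <- function(p0) {
    odds1 <- or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    (1 - prevalence) * p0 + prevalence * p1 - marginal
  }
  upper <- min(1 - 1e-9, marginal / (1 - prevalence) + 1e-9)
  p0 <- uniroot(f, c(1e-12, max(upper, marginal)), tol = 1e-12)$root
  odds1 <- or * p0 / (1 - p0)
  c(p0, odds1 / (1 + odds1))
}

#' @export
print.drm_tables <- function(x, ...) {
  cat("<drm_tables>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
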
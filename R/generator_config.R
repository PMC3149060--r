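# Configuration for the synthetic cohort generator.
#
# The generator reproduces the episode-level statistical structure of an
# external-CSF-drainage surveillance cohort: per-group (DRM vs no-DRM)
# distributions of worst-in-episode laboratory values, culture positivity,
# antibiotic exposure and drainage characteristics, plus realistic
# "never measured" missingness. Distribution parameters are solved once,
# at configuration time, from published group medians and interquartile
# ranges; they are not free knobs of the simulation functions.

LOGNORMAL_Z75 <- qnorm(0.75)

# Solve log-normal (meanlog, sdlog) from a median and IQR. When the lower
# quartile is at (or below) zero the scale is solved from the median and
# upper quartile alone, since a strictly positive family cannot place
# 25% of its mass at zero.
lognormal_from_quartiles <- function(q50, q25, q75) {
  stopifnot(q50 > 0, q75 > q50)
  meanlog <- log(q50)
  sdlog <- if (q25 > 0) {
    (log(q75) - log(q25)) / (2 * LOGNORMAL_Z75)
  } else {
    (log(q75) - log(q50)) / LOGNORMAL_Z75
  }
  list(meanlog = meanlog, sdlog = sdlog)
}

# Solve log-normal parameters from two arbitrary quantiles.
lognormal_from_two_quantiles <- function(p1, x1, p2, x2) {
  z1 <- qnorm(p1); z2 <- qnorm(p2)
  sdlog <- (log(x2) - log(x1)) / (z2 - z1)
  list(meanlog = log(x1) - z1 * sdlog, sdlog = sdlog)
}

# Logit-normal for percentage-type variables bounded in (0, 100).
logitnormal_from_quartiles <- function(q50, q25, q75) {
  lg <- function(x) qlogis(x / 100)
  list(mu = lg(q50), sigma = (lg(q75) - lg(q25)) / (2 * LOGNORMAL_Z75))
}

normal_from_quartiles <- function(q50, q25, q75) {
  list(mean = q50, sd = (q75 - q25) / (2 * LOGNORMAL_Z75))
}

# Match a negative-binomial to target quartiles by deterministic grid
# search (medians/IQRs are the only published summaries for counts).
# Among parameter settings attaining the minimal quartile loss, the
# central one is taken, so the fitted distribution does not sit on a
# quantile boundary where the sample median could flip.
negbin_from_quartiles <- function(q50, q25, q75) {
  mus <- seq(0.2, 8, by = 0.05)
  sizes <- c(0.5, 0.75, 1, 1.5, 2, 3, 5, 8, 12, 20)
  grid <- expand.grid(mu = mus, size = sizes)
  loss <- mapply(function(mu, size) {
    q <- qnbinom(c(0.25, 0.5, 0.75), mu = mu, size = size)
    sum(abs(q - c(q25, q50, q75)))
  }, grid$mu, grid$size)
  best <- grid[loss == min(loss), ]
  best <- best[order(best$size, best$mu), ]
  mid <- best[ceiling(nrow(best) / 2), ]
  list(mu = mid$mu, size = mid$size)
}

# Shifted Poisson (1 + Poisson(lambda)) for the number of drains placed.
pois1_from_quartiles <- function(q50, q25, q75) {
  lambdas <- seq(0.01, 4, by = 0.01)
  loss <- vapply(lambdas, function(l) {
    q <- 1 + qpois(c(0.25, 0.5, 0.75), lambda = l)
    sum(abs(q - c(q25, q50, q75)))
  }, numeric(1))
  feasible <- lambdas[loss == min(loss)]
  list(lambda = feasible[ceiling(length(feasible) / 2)])
}

# Per-variable, per-group calibration targets: worst-in-episode group
# medians (IQR) and group proportions for an external-drainage cohort
# (DRM prevalence 15.3%). `direction` is the worst-value direction used
# downstream; `min`-type variables fall with infection.
cohort_targets <- function() {
  tibble::tribble(
    ~variable,             ~kind,         ~direction, ~unit,
      ~q_nodrm,             ~q_drm,
    "age",                 "normal",      NA,         "years",
      c(59.3, 46.8, 69.4),  c(56.0, 47.5, 65.6),
    "admission_days",      "lognormal",   NA,         "days",
      c(19, 11, 30),        c(40, 28.5, 59.3),
    "total_drain_days",    "lognormal",   NA,         "days",
      c(8, 5, 13),          c(20, 15, 29.8),
    "n_drains",            "pois1",       NA,         "count",
      c(1, 1, 1),           c(2, 1, 2),
    "n_abx_started",       "negbin",      NA,         "count",
      c(1, 0, 2),           c(4, 3, 6),
    "crp",                 "lognormal",   "max",      "mg/L",
      c(85, 32, 165),       c(141, 95, 190),
    "blood_leukocytes",    "lognormal",   "max",      "1e9/L",
      c(14.8, 11.3, 19.0),  c(20.1, 16.3, 23.6),
    "hemoglobin",          "lognormal",   "min",      "mmol/L",
      c(6.8, 5.8, 7.6),     c(6.0, 5.2, 6.8),
    "thrombocytes",        "lognormal",   "max",      "1e9/L",
      c(329, 252, 452),     c(540, 381, 714),
    "csf_leukocytes",      "lognormal",   "max",      "1e2/uL",
      c(1.4, 0.2, 4.3),     c(10.4, 2.5, 53.1),
    "csf_erythrocytes",    "lognormal",   "max",      "1e4/uL",
      c(1.2, 0.2, 6.9),     c(2.4, 0.8, 10.6),
    "csf_neutrophils",     "lognormal",   "max",      "1e2/uL",
      c(0.4, 0, 2.3),       c(6.3, 0.6, 38.0),
    "csf_neutrophil_pct",  "logitnormal", "max",      "%",
      c(47.8, 31.3, 66.0),  c(85.0, 70.0, 91.5),
    "csf_glucose",         "lognormal",   "min",      "mmol/L",
      c(3.5, 2.9, 4.2),     c(2.3, 1.1, 3.3),
    "csf_protein",         "lognormal",   "max",      "g/L",
      c(1.7, 0.8, 2.7),     c(1.8, 1.1, 3.3)
  )
}

# Binary variables: per-group proportions.
cohort_proportions <- function() {
  tibble::tribble(
    ~variable,          ~p_nodrm,  ~p_drm,
    "sex_female",       0.543,     0.524,
    "death",            0.174,     0.134,
    "icu_admitted",     0.556,     0.720,
    "drain_type_evd",   0.585,     0.866,
    "culture_positive", 45 / 455,  61 / 82,
    "empiric_abx",      0.134,     0.756,
    "abx_after_day4",   0.424,     0.951
  )
}

# Pre-imputation fractions of episodes in which a measurement set was
# never obtained. CSF analytes and cultures are collected only on
# clinical suspicion of infection, so their absence depends on outcome
# (MAR); blood panels are part of routine monitoring (MCAR).
default_missingness <- function() {
  tibble::tribble(
    ~variable,           ~rate,  ~mechanism,
    "crp",               0.112,  "MCAR",
    "blood_leukocytes",  0.084,  "MCAR",
    "hemoglobin",        0.061,  "MCAR",
    "thrombocytes",      0.112,  "MCAR",
    "csf_leukocytes",    0.292,  "MAR",
    "csf_erythrocytes",  0.291,  "MAR",
    "csf_glucose",       0.307,  "MAR",
    "csf_protein",       0.292,  "MAR",
    "culture",           0.199,  "MAR"
  )
}

LAB_ANALYTES <- c(
  "crp", "blood_leukocytes", "hemoglobin", "thrombocytes",
  "csf_leukocytes", "csf_erythrocytes", "csf_neutrophils",
  "csf_neutrophil_pct", "csf_glucose", "csf_protein"
)

CSF_ANALYTES <- grep("^csf_", LAB_ANALYTES, value = TRUE)

SYSTEMIC_AGENTS <- c(
  "vancomycin", "ceftazidime", "ceftriaxone", "flucloxacillin",
  "meropenem", "cefotaxime", "amoxicillin", "ciprofloxacin",
  "metronidazole", "gentamicin", "rifampicin", "cotrimoxazole"
)

DRAIN_INDICATIONS <- c(
  "SAH/IVH" = 0.464, "Infarction" = 0.026, "CSF leakage" = 0.158,
  "Perioperative" = 0.160, "Trauma" = 0.026, "Tumor" = 0.069,
  "Other" = 0.097
)

#' Configure the synthetic cohort generator
#'
#' Builds a validated generator configuration whose per-group
#' distributions are solved from published group medians/IQRs and
#' proportions of a drain-related meningitis (DRM) surveillance cohort:
#' log-normal for skewed worst-in-episode laboratory values, logit-normal
#' for CSF neutrophil percentage, Bernoulli for binary characteristics,
#' negative binomial for antibiotic-start counts and shifted Poisson for
#' the number of drains.
#'
#' @param n_patients Number of admissions to simulate.
#' @param prevalence Probability that an episode develops DRM
#'   (default 0.153, the development cohort rate of 82/537).
#' @param seed Integer seed; identical configurations produce
#'   byte-identical cohorts.
#' @param study_years Calendar years to assign episodes to.
#' @param year_weights Optional per-year weights (or expected episode
#'   counts); default uniform.
#' @param missingness Tibble with columns `variable`, `rate`,
#'   `mechanism` (`"MCAR"` or `"MAR"`); defaults to the development
#'   cohort's pre-imputation rates (e.g. CRP 11.2%, CSF leukocytes
#'   29.2%, cultures 19.9%).
#' @param mar_odds_ratio Odds ratio of deletion for DRM vs no-DRM
#'   episodes under the MAR mechanism (default 0.15: infected patients
#'   almost always have CSF sampled).
#' @param contaminant_rate Fraction of truly culture-negative episodes
#'   in which a skin-flora (coagulase-negative staphylococcus)
#'   contaminant culture is planted; the contamination-correction rule
#'   reclassifies these as negative downstream.
#' @param measurements_range Integer range (min, max) of measurements
#'   per analyte per episode.
#'
#' @return An object of class `drm_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 200, seed = 42)
#' cfg$prevalence
generator_config <- function(n_patients,
                             prevalence = 0.153,
                             seed = 1L,
                             study_years = 2004:2009,
                             year_weights = NULL,
                             missingness = default_missingness(),
                             mar_odds_ratio = 0.15,
                             contaminant_rate = 0.08,
                             measurements_range = c(1L, 5L)) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 1) {
    abort("`n_patients` must be a positive integer.")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie strictly between 0 and 1.")
  }
  if (any(missingness$rate < 0 | missingness$rate > 1)) {
    abort("missingness rates must lie in [0, 1].")
  }
  known <- c(LAB_ANALYTES, "culture")
  bad <- setdiff(missingness$variable, known)
  if (length(bad)) {
    abort(paste0("unknown variable(s) in missingness config: ",
                 paste(bad, collapse = ", ")))
  }
  if (mar_odds_ratio <= 0) abort("`mar_odds_ratio` must be positive.")

  targets <- cohort_targets()
  targets$params_nodrm <- purrr::map2(targets$kind, targets$q_nodrm, solve_params)
  targets$params_drm <- purrr::map2(targets$kind, targets$q_drm, solve_params)

  if (is.null(year_weights)) year_weights <- rep(1, length(study_years))
  stopifnot(length(year_weights) == length(study_years), all(year_weights >= 0))

  structure(
    list(
      n_patients = as.integer(n_patients),
      prevalence = prevalence,
      seed = as.integer(seed),
      study_years = as.integer(study_years),
      year_weights = year_weights / sum(year_weights),
      targets = targets,
      proportions = cohort_proportions(),
      missingness = missingness,
      mar_odds_ratio = mar_odds_ratio,
      contaminant_rate = contaminant_rate,
      measurements_range = as.integer(measurements_range)
    ),
    class = "drm_config"
  )
}

solve_params <- function(kind, q) {
  switch(kind,
    lognormal   = lognormal_from_quartiles(q[1], q[2], q[3]),
    logitnormal = logitnormalize(q),
    normal      = normal_from_quartiles(q[1], q[2], q[3]),
    negbin      = negbin_from_quartiles(q[1], q[2], q[3]),
    pois1       = pois1_from_quartiles(q[1], q[2], q[3]),
    abort(paste0("unknown distribution kind: ", kind))
  )
}

logitnormalize <- function(q) logitnormal_from_quartiles(q[1], q[2], q[3])

#' @export
print.drm_config <- function(x, ...) {
  cat("<drm_config>\n")
  cat("  admissions:", x$n_patients, " prevalence:", x$prevalence,
      " seed:", x$seed, "\n")
  cat("  years:", paste(range(x$study_years), collapse = "-"), "\n")
  cat("  variables:", nrow(x$targets), "continuous/count,",
      nrow(x$proportions), "binary\n")
  invisible(x)
}
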
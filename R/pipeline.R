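# End-to-end orchestration: simulate (or read) raw event tables, build
# and filter episodes, extract features, impute, develop the model,
# evaluate at the configured cut-offs and summarise per-year
# surveillance. Deterministic under a fixed seed; the run report
# carries a manifest with content hashes of every input table.

TABLE_SCHEMAS <- list(
  patients = list(
    required = c("patient_id", "age", "sex", "discharge_day", "year"),
    defaults = list(person_id = NULL, admission_seq = 1L,
                    days_since_prior_discharge = NA_real_,
                    admission_day = 0L, icu_admitted = FALSE, icu_days = 0,
                    death_day = NA_integer_,
                    preexisting_cns_infection = FALSE,
                    drain_other_centre = FALSE, external_site = FALSE)
  ),
  drains = list(
    required = c("patient_id", "drain_type", "insertion_day",
                 "removal_day"),
    defaults = list(drain_id = NULL, indication = "unknown")
  ),
  labs = list(
    required = c("patient_id", "day", "analyte", "value"),
    defaults = list(unit = NA_character_)
  ),
  cultures = list(
    required = c("patient_id", "day", "site", "cons_flag",
                 "positive_flag"),
    defaults = list(organism = NA_character_)
  ),
  antibiotics = list(
    required = c("patient_id", "agent", "start_day"),
    defaults = list(systemic = TRUE)
  ),
  outcomes = list(
    required = c("patient_id", "drm_flag"),
    defaults = list(infection_day = NA_integer_)
  )
)

#' Read raw event tables from a directory of CSV files
#'
#' Expects `patients.csv`, `drains.csv`, `labs.csv`, `cultures.csv`,
#' `antibiotics.csv` and `outcomes.csv` with the documented headers
#' (UTF-8, comma-separated, day fields as integer offsets from
#' admission day 0). A missing required column is an error naming the
#' column; unknown extra columns are preserved with a warning; optional
#' columns are filled with documented defaults.
#'
#' @param dir Directory containing the six CSV files.
#' @return A `drm_tables` object.
#' @export
read_event_tables <- function(dir) {
  out <- list()
  for (nm in names(TABLE_SCHEMAS)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) abort(paste0("missing input file: ", path))
    tb <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
    schema <- TABLE_SCHEMAS[[nm]]
    absent <- setdiff(schema$required, names(tb))
    if (length(absent)) {
      abort(paste0("table '", nm, "' lacks required column(s): ",
                   paste(absent, collapse = ", ")))
    }
    extra <- setdiff(names(tb),
                     c(schema$required, names(schema$defaults)))
    if (length(extra)) {
      warn(paste0("table '", nm, "': unknown column(s) preserved: ",
                  paste(extra, collapse = ", ")))
    }
    for (d in names(schema$defaults)) {
      val <- schema$defaults[[d]]
      if (is.null(val)) next
      if (!d %in% names(tb)) {
        tb[[d]] <- val
      } else if (all(is.na(tb[[d]]))) {
        # all-NA columns come back from CSV as logical; restore the
        # documented type
        storage.mode(tb[[d]]) <- storage.mode(val)
      }
    }
    if (nm == "patients" && !"person_id" %in% names(tb)) {
      tb$person_id <- tb$patient_id
    }
    out[[nm]] <- tb
  }
  structure(out, class = "drm_tables")
}

#' Write raw event tables as CSV files
#'
#' Inverse of [read_event_tables()]: one CSV per table, UTF-8,
#' comma-delimited, dot decimal separator. List-columns are not part of
#' the schema and are rejected.
#'
#' @param tables A `drm_tables` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_event_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Assemble a pipeline run configuration
#'
#' @param mode One of `"simulate-and-fit"`, `"fit-only"`.
#' @param n_patients Cohort size for simulate mode.
#' @param input_dir Directory of event CSVs for fit-only mode.
#' @param prevalence Generator prevalence.
#' @param m Number of imputations.
#' @param bootstrap_B Bootstrap resamples per imputation set.
#' @param alpha Backward-selection threshold.
#' @param cutoffs Probability cut-offs for confusion reports.
#' @param seed Master seed for the whole run.
#' @param inject_missing Whether to delete never-measured analytes in
#'   simulate mode (default TRUE).
#' @return A list of class `drm_run_config`.
#' @export
run_config <- function(mode = c("simulate-and-fit", "fit-only"),
                       n_patients = 537, input_dir = NULL,
                       prevalence = 0.153, m = 10, bootstrap_B = 100,
                       alpha = 0.05, cutoffs = c(0.107, 0.175),
                       seed = 1L, inject_missing = TRUE) {
  mode <- match.arg(mode)
  if (any(cutoffs <= 0 | cutoffs >= 1)) {
    abort("cutoffs must lie strictly in (0, 1).")
  }
  if (mode == "fit-only") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      abort("fit-only mode requires an existing `input_dir`.")
    }
  }
  structure(list(mode = mode, n_patients = n_patients,
                 input_dir = input_dir, prevalence = prevalence, m = m,
                 bootstrap_B = bootstrap_B, alpha = alpha,
                 cutoffs = cutoffs, seed = as.integer(seed),
                 inject_missing = inject_missing),
            class = "drm_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `drm_run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the surveillance pipeline end to end
#'
#' Executes the stages in order: simulate (or read) raw event tables,
#' build episodes, merge readmissions, apply exclusions, extract
#' features, impute, develop the prediction model (screening, backward
#' selection, Rubin pooling, bootstrap shrinkage), evaluate at the
#' configured cut-offs and summarise per-year surveillance. Identical
#' configuration and seed give identical reports (verifiable through
#' the manifest hashes).
#'
#' @param config A `drm_run_config` (or path to a YAML file for
#'   [read_run_config()]).
#' @return A list of class `drm_report` with elements `manifest`,
#'   `exclusions`, `model`, `confusion` (one per cut-off),
#'   `calibration`, `roc`, `surveillance`, and the fitted `drm_model`
#'   object under `fit`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "drm_run_config"))
  seed <- config$seed

  tables <- with_stage("input", {
    if (config$mode == "simulate-and-fit") {
      gen <- generator_config(n_patients = config$n_patients,
                              prevalence = config$prevalence,
                              seed = seed)
      tb <- generate_cohort(gen)
      if (config$inject_missing) {
        tb <- inject_missingness(tb, gen, seed = seed + 1L)
      }
      tb
    } else {
      read_event_tables(config$input_dir)
    }
  })

  episodes <- with_stage("episodes", {
    ep <- build_episodes(tables)
    ep <- merge_readmissions(ep)
    apply_exclusions(ep)
  })

  features <- with_stage("features", {
    extract_features(episodes$included, tables)
  })

  imp <- with_stage("impute", {
    impute_features(features, m = config$m, seed = seed + 2L)
  })

  fit <- with_stage("fit", {
    develop_model(imp, alpha = config$alpha, B = config$bootstrap_B,
                  seed = seed + 3L)
  })

  evaluation <- with_stage("evaluate", {
    mean_dat <- mean_dataset(imp)
    p <- predict_probability(fit$rule, mean_dat)
    y <- mean_dat$drm_flag
    list(
      probabilities = p,
      confusion = purrr::map(config$cutoffs, function(ct)
        confusion_metrics(p, y, ct)),
      roc = roc_auc(p, y),
      calibration = calibration_table(p, y,
                                      bins = min(10, length(p) %/% 5)),
      surveillance = surveillance_summary(
        dplyr::mutate(
          dplyr::select(mean_dat, "year", "days_at_risk", "drm_flag"),
          probability = p),
        truth = "drm_flag")
    )
  })

  manifest <- list(
    package = "drmdetect",
    version = as.character(utils::packageVersion("drmdetect")),
    mode = config$mode,
    seed = seed,
    n_input_admissions = nrow(tables$patients),
    n_included_episodes = nrow(episodes$included),
    table_hashes = purrr::map(
      unclass(tables)[names(TABLE_SCHEMAS)],
      function(tb) rlang::hash(as.data.frame(tb)))
  )

  structure(list(
    manifest = manifest,
    exclusions = episodes$log,
    model = list(
      intercept = fit$rule$intercept,
      coefficients = as.list(fit$rule$coefficients),
      odds_ratios = as.list(exp(fit$rule$coefficients)),
      shrinkage = fit$rule$shrinkage,
      apparent_auc = fit$optimism$apparent_auc,
      corrected_auc = fit$optimism$corrected_auc,
      n = fit$n, events = fit$events, m = fit$m
    ),
    confusion = evaluation$confusion,
    roc = evaluation$roc,
    calibration = evaluation$calibration,
    surveillance = evaluation$surveillance,
    probabilities = evaluation$probabilities,
    fit = fit
  ), class = "drm_report")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}

#' Write a run report as JSON
#'
#' Serialises the JSON-representable parts of a pipeline report
#' (manifest, model, confusion tables, calibration, surveillance) to
#' `path`.
#'
#' @param report A `drm_report` from [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "drm_report"))
  payload <- list(
    manifest = report$manifest,
    model = report$model,
    confusion = purrr::map(report$confusion, function(cm) {
      list(cutoff = attr(cm, "cutoff"),
           counts = as.list(attr(cm, "counts")),
           flagged_fraction = attr(cm, "flagged_fraction"),
           metrics = as.data.frame(cm))
    }),
    roc = list(auc = report$roc$auc, conf.low = report$roc$conf.low,
               conf.high = report$roc$conf.high),
    calibration = as.data.frame(report$calibration),
    surveillance = as.data.frame(report$surveillance)
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.drm_report <- function(x, ...) {
  cat("<drm_report>", x$manifest$mode, "seed", x$manifest$seed, "\n")
  cat("  episodes:", x$manifest$n_included_episodes, "of",
      x$manifest$n_input_admissions, "admissions included\n")
  cat(sprintf("  corrected AUC: %.3f (apparent %.3f, shrinkage %.3f)\n",
              x$model$corrected_auc, x$model$apparent_auc,
              x$model$shrinkage))
  invisible(x)
}
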
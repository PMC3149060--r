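# Worst-value extraction, contamination correction, empiric-therapy
# detection, antibiotic counting and the assembled feature vector.

test_that("worst_value returns the direction-appropriate extremum", {
  expect_equal(worst_value(c(10, 200, 50), "max"), 200)
  expect_equal(worst_value(c(3.4, 1.1, 2.0), "min"), 1.1)
  expect_true(is.na(worst_value(numeric(0), "max")))
  expect_true(is.na(worst_value(c(NA, NA), "min")))
  expect_error(worst_value(1:3, "extreme"))
})

test_that("worst_value is an attained bound of its series", {
  set.seed(41)
  for (i in 1:50) {
    x <- rlnorm(sample(1:20, 1), 2, 1)
    w <- worst_value(x, "max")
    expect_true(all(w >= x))
    expect_true(w %in% x)
  }
})

test_that("CoNS cultures flip negative without nearby antibiotic starts", {
  abx <- tibble::tibble(patient_id = "A", agent = "vancomycin",
                        start_day = 11L, systemic = TRUE)
  no_abx <- abx[0, ]
  cons <- tibble::tibble(patient_id = "A", day = 10L, site = "CSF",
                         organism = "cons", cons_flag = TRUE,
                         positive_flag = TRUE)
  # start on day 11 lies inside [9, 13]: stays positive
  expect_true(correct_contamination(cons, abx)$corrected_positive)
  # no starts at all: contaminant
  expect_false(correct_contamination(cons, no_abx)$corrected_positive)
  # start outside the window (day 14): contaminant
  late <- dplyr::mutate(abx, start_day = 14L)
  expect_false(correct_contamination(cons, late)$corrected_positive)
  # boundary days -1 and +3 are inside
  for (d in c(9L, 13L)) {
    at <- dplyr::mutate(abx, start_day = d)
    expect_true(correct_contamination(cons, at)$corrected_positive)
  }
  # non-CoNS positives are never altered
  aureus <- dplyr::mutate(cons, cons_flag = FALSE)
  expect_true(correct_contamination(aureus, no_abx)$corrected_positive)
})

test_that("contamination correction never flips negative to positive", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    cult <- tibble::tibble(
      patient_id = sample(c("A", "B"), n, TRUE),
      day = sample(0:20, n, TRUE),
      site = "CSF", organism = "x",
      cons_flag = runif(n) < 0.5,
      positive_flag = runif(n) < 0.5)
    abx <- tibble::tibble(patient_id = "A", agent = "vancomycin",
                          start_day = sample(0:20, 1), systemic = TRUE)
    out <- correct_contamination(cult, abx)
    expect_true(all(out$corrected_positive <= cult$positive_flag))
    flipped <- cult$positive_flag & !out$corrected_positive
    expect_true(all(cult$cons_flag[flipped]))
  }
})

test_that("episode culture policy distinguishes untaken from negative", {
  taken <- tibble::tibble(corrected_positive = c(FALSE, TRUE, FALSE))
  expect_equal(any_positive_culture(taken), 1)
  expect_equal(any_positive_culture(taken[c(1, 3), ]), 0)
  none <- taken[0, ]
  expect_true(is.na(any_positive_culture(none)))
  expect_equal(any_positive_culture(none, no_culture = 0), 0)
})

test_that("empiric therapy detection follows the two protocol pairs", {
  mk <- function(agents, days) {
    tibble::tibble(patient_id = "A", agent = agents,
                   start_day = as.integer(days), systemic = TRUE)
  }
  expect_equal(detect_empiric_therapy(
    mk(c("vancomycin", "ceftazidime"), c(6, 6))), 1)
  expect_equal(detect_empiric_therapy(
    mk(c("ceftriaxone", "flucloxacillin"), c(2, 3))), 1)
  expect_equal(detect_empiric_therapy(mk("vancomycin", 6)), 0)
  # late pair too early
  expect_equal(detect_empiric_therapy(
    mk(c("vancomycin", "ceftazidime"), c(2, 2))), 0)
  # day 4 counts for the late pair
  expect_equal(detect_empiric_therapy(
    mk(c("vancomycin", "ceftazidime"), c(4, 4))), 1)
  # not simultaneous (starts 3 days apart)
  expect_equal(detect_empiric_therapy(
    mk(c("vancomycin", "ceftazidime"), c(5, 8))), 0)
  # early pair started late
  expect_equal(detect_empiric_therapy(
    mk(c("ceftriaxone", "flucloxacillin"), c(6, 6))), 0)
})

test_that("antibiotic count is over distinct systemic agents", {
  abx <- tibble::tibble(
    patient_id = "A",
    agent = c("vancomycin", "ceftazidime", "vancomycin", "nystatin"),
    start_day = c(5L, 5L, 9L, 2L),
    systemic = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(count_antibiotics_started(abx), 2L)
  expect_equal(count_antibiotics_started(abx[0, ]), 0L)
})

test_that("CRP polynomial terms use the model scalings", {
  expect_equal(unname(crp_terms(100)), c(100, 100, 1))
  expect_equal(unname(crp_terms(150)), c(150, 225, 3.375))
  expect_equal(unname(crp_terms(0)), c(0, 0, 0))
  expect_error(crp_terms(-1), "non-negative")
  # scale consistency: crp_sq(10x) = x^2, crp_cu(100x) = x^3
  for (x in c(0.5, 2, 7)) {
    expect_equal(crp_terms(10 * x)[["crp_sq"]], x^2)
    expect_equal(crp_terms(100 * x)[["crp_cu"]], x^3)
  }
})

test_that("the assembled feature vector matches hand computation", {
  tb <- tiny_tables()
  res <- apply_exclusions(merge_readmissions(build_episodes(tb)))
  # C excluded for age
  expect_setequal(res$included$episode_id, c("A", "B"))
  ft <- extract_features(res$included, tb)
  a <- ft[ft$episode_id == "A", ]
  b <- ft[ft$episode_id == "B", ]

  # A: EVD + ELD -> EVD priority; windows [3, 27] (removal 20 + 7)
  expect_equal(a$drain_type_evd, 1)
  expect_equal(a$n_drains, 2)
  expect_equal(a$total_drain_days, 15)
  # worst CRP of 10/200/50 = 200 with its polynomial terms
  expect_equal(a$crp, 200)
  expect_equal(a$crp_sq, 400)
  expect_equal(a$crp_cu, 8)
  expect_equal(a$csf_leukocytes, 12)
  expect_equal(a$csf_leukocytes_log, log(13))
  expect_equal(a$csf_glucose, 1.8)
  # CoNS culture day 8 covered by vancomycin day 9 -> positive
  expect_equal(a$culture_positive, 1)
  # vanco + ceftazidime day 9 (>= 4): empiric protocol
  expect_equal(a$empiric_abx, 1)
  expect_equal(a$n_abx_started, 2L)
  expect_equal(a$abx_after_day4, 1)

  # B: CoNS contaminant corrected to negative; no CSF sample -> NA
  expect_equal(b$culture_positive, 0)
  expect_true(is.na(b$csf_leukocytes))
  expect_true(is.na(b$csf_leukocytes_log))
  expect_equal(b$crp, 40)
  expect_equal(b$n_abx_started, 0L)
  expect_equal(b$empiric_abx, 0)

  # purity: identical inputs give identical output
  expect_identical(ft, extract_features(res$included, tb))
})
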
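# Cohort measures: eligibility, modified-HEDIS engagement, cause-of-death
# classification, matched controls, covariate assembly.

test_that("eligibility applies age, diagnosis-prefix and window rules", {
  adm <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    admit_date = c(10L, 10L, 10L, 2000L),
    discharge_date = c(15L, 15L, 15L, 2005L),
    diagnosis_codes = c("F1120", "F119", "I10", "F1120"),
    admission_number = 1L, stringsAsFactors = FALSE)
  pat <- data.frame(patient_id = c("A", "B", "C", "D"),
                    age = c(17, 40, 40, 40), stringsAsFactors = FALSE)
  el <- select_eligible(adm, pat, eligibility_window(0, 1248, 1006))
  # A: under 18; C: no OUD code; D: outside window
  expect_equal(el$patient_id, "B")
  expect_true(el$mortality_cohort)
})

test_that("malformed diagnosis codes warn and are excluded from matching", {
  adm <- data.frame(patient_id = "A", admit_date = 10L, discharge_date = 15L,
                    diagnosis_codes = "F11!20", admission_number = 1L,
                    stringsAsFactors = FALSE)
  pat <- data.frame(patient_id = "A", age = 30, stringsAsFactors = FALSE)
  expect_warning(el <- select_eligible(adm, pat), "malformed")
  expect_equal(nrow(el), 0)
})

test_that("engagement rule: both clauses, the day-window convention", {
  # clause (a): two MOUD fills inside days 1..30
  expect_true(classify_engagement(100, fills_of(
    list("buprenorphine", 105, 14), list("buprenorphine", 120, 14))))
  # clause (b): a single 30-day supply from day 1
  expect_true(classify_engagement(100, fills_of(
    list("buprenorphine", 101, 30))))
  # a single methadone visit meets neither clause
  expect_false(classify_engagement(100, fills_of(
    list("methadone_otp", 103, 1))))
  # one short fill fails both
  expect_false(classify_engagement(100, fills_of(
    list("buprenorphine", 110, 7))))
  # discharge day itself (day 0) is outside the window
  expect_false(classify_engagement(100, fills_of(
    list("buprenorphine", 100, 1), list("buprenorphine", 131, 1))))
  # methadone never counts toward the coverage clause
  expect_false(classify_engagement(100, fills_of(
    list("methadone_otp", 101, 30))))
  # 28 covered days is exactly enough
  expect_true(classify_engagement(100, fills_of(
    list("xr_naltrexone", 103, 28))))
  expect_false(classify_engagement(100, no_fills))
  expect_error(classify_engagement(100, fills_of(
    list("buprenorphine", 105, -1))), "negative")
})

test_that("engagement is monotone in qualifying fills", {
  classes <- c("buprenorphine", "xr_naltrexone", "methadone_otp")
  set.seed(5)
  for (i in 1:50) {
    k <- sample(0:3, 1)
    f <- if (k == 0) no_fills else do.call(fills_of, lapply(seq_len(k),
      function(j) list(sample(classes, 1),
                       100 + sample(1:30, 1), sample(c(7, 14, 30), 1))))
    before <- classify_engagement(100, f)
    extra <- fills_of(list("buprenorphine", 100 + sample(1:30, 1), 14))
    after <- classify_engagement(100, rbind(f, extra))
    if (before) expect_true(after)
  }
})

test_that("death classification partitions by window, code set, override", {
  map <- cause_map()
  rec <- function(day, code) data.frame(patient_id = "P1", death_date = day,
                                        underlying_cause_code = code,
                                        stringsAsFactors = FALSE)
  expect_equal(classify_death(NULL, 100, map), "none")
  expect_equal(classify_death(rec(500, "X42"), 100, map), "none")   # day 400
  expect_equal(classify_death(rec(130, "X42"), 100, map), "drug")
  expect_equal(classify_death(rec(200, "C34"), 100, map), "non_drug")
  expect_equal(classify_death(rec(200, "Y12"), 100, map), "drug")
  expect_error(classify_death(rec(200, ""), 100, map), "P1")
  ov <- cause_map(overrides = data.frame(patient_id = "P1",
                                         category = "drug",
                                         stringsAsFactors = FALSE))
  expect_equal(classify_death(rec(200, "C34"), 100, ov), "drug")
})

test_that("cause map round-trips through JSON and expands ranges", {
  m <- cause_map()
  expect_true(all(c("X40", "X44", "X60", "X64", "X85", "Y10", "Y14") %in%
                    m$drug_related_codes))
  f <- file.path(tempdir(), "causes.json")
  jsonlite::write_json(list(drug_related_codes = c("X40-X44", "X85")), f,
                       auto_unbox = TRUE)
  m2 <- read_cause_map(f)
  expect_equal(m2$drug_related_codes, c("X40", "X41", "X42", "X43", "X44",
                                        "X85"))
})

test_that("matching caps at the ratio, flags shortages, never reuses", {
  mk <- function(ids, q = 1L, an = 1L, dates = seq_along(ids)) {
    data.frame(patient_id = ids, admit_date = dates, admission_quarter = q,
               admission_number = an, stringsAsFactors = FALSE)
  }
  # ample stratum: 3 of 5 taken
  m <- match_controls(mk("case1"), mk(paste0("c", 1:5)), ratio = 3)
  expect_equal(nrow(m$matches), 3)
  expect_length(m$under_matched, 0)
  # shortage: both taken, case flagged
  m2 <- match_controls(mk("case1"), mk(paste0("c", 1:2)), ratio = 3)
  expect_equal(nrow(m2$matches), 2)
  expect_equal(m2$under_matched, "case1")
  empty_pool <- data.frame(patient_id = character(), admit_date = integer(),
                           admission_quarter = integer(),
                           admission_number = integer(),
                           stringsAsFactors = FALSE)
  expect_error(match_controls(mk("case1"), empty_pool), "empty")
})

test_that("matching on a simulated cohort is stratum-exact with no reuse", {
  set.seed(31)
  n_cases <- 100
  cases <- data.frame(patient_id = sprintf("case%03d", 1:n_cases),
                      admit_date = sample(1000, n_cases),
                      admission_quarter = sample(1:8, n_cases, TRUE),
                      admission_number = sample(1:2, n_cases, TRUE),
                      stringsAsFactors = FALSE)
  pool <- data.frame(patient_id = sprintf("ctrl%04d", 1:5000),
                     admit_date = sample(1000, 5000, TRUE),
                     admission_quarter = sample(1:8, 5000, TRUE),
                     admission_number = sample(1:2, 5000, TRUE),
                     stringsAsFactors = FALSE)
  m <- match_controls(cases, pool, ratio = 3)
  expect_equal(nrow(m$matches), 3 * n_cases)
  expect_length(m$under_matched, 0)
  # no reused control
  expect_false(any(duplicated(m$matches$control_id)))
  # brute-force stratum agreement for every pair
  key <- function(d, id) {
    i <- match(id, d$patient_id)
    paste(d$admission_quarter[i], d$admission_number[i])
  }
  expect_equal(key(cases, m$matches$case_id), key(pool, m$matches$control_id))
  # without-replacement property: removing matched controls and re-running
  # yields a disjoint selection
  pool2 <- pool[!pool$patient_id %in% m$matches$control_id, ]
  m2 <- match_controls(cases, pool2, ratio = 3)
  expect_length(intersect(m$matches$control_id, m2$matches$control_id), 0)
})

test_that("analysis table recovers latent truth exactly on synthetic data", {
  co <- generate_cohort(sim_config(1500, seed = 17))
  el <- select_eligible(co$admissions, co$patients)
  at <- build_covariates(el, co$patients, co$fills, co$deaths,
                         co$truth$patient_id[co$truth$referral == 1])
  expect_equal(nrow(at), 1500)
  tr <- co$truth[match(at$patient_id, co$truth$patient_id), ]
  expect_equal(at$engagement, tr$engagement)
  expect_equal(at$death_category, tr$death_category)
  expect_equal(at$referral, tr$referral)
  expect_equal(at$moud_at_admission, tr$moud_at_admission)
  expect_equal(at$naloxone_fill_30d, tr$naloxone_fill_30d)
  expect_equal(at$prior_admission, tr$prior_admission)
  # rule-forced single rows
  expect_true(all(at$prior_admission[at$admission_number == 1] == 0))
  # one row per patient; death categories partition
  expect_false(any(duplicated(at$patient_id)))
  expect_true(all(at$death_category %in% c("none", "drug", "non_drug")))
  # analysis table round-trips as TSV
  f <- file.path(tempdir(), "at.tsv")
  write_analysis_table(at, f)
  back <- read_analysis_table(f)
  expect_equal(back$engagement, at$engagement)
  expect_equal(back$death_category, at$death_category)
})

test_that("missing covariate source columns raise a schema error", {
  co <- generate_cohort(sim_config(50, seed = 2))
  el <- select_eligible(co$admissions, co$patients)
  broken <- co$patients[, setdiff(names(co$patients), "cdps")]
  expect_error(build_covariates(el, broken, co$fills, co$deaths, character(0)),
               "cdps")
})

test_that("eligibility counts scale to the study cohort split", {
  set.seed(404)
  n <- 8450; n_before <- 6654
  admit <- c(sample(0:1006, n_before, TRUE),
             sample(1007:1248, n - n_before, TRUE))
  adm <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                    admit_date = admit, discharge_date = admit + 3L,
                    diagnosis_codes = "F1120", admission_number = 1L,
                    stringsAsFactors = FALSE)
  pat <- data.frame(patient_id = adm$patient_id, age = 40,
                    stringsAsFactors = FALSE)
  el <- select_eligible(adm, pat)
  expect_equal(nrow(el), 8450)
  expect_equal(sum(el$mortality_cohort), 6654)
})
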
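# Claims-style cohort measures: eligibility, modified-HEDIS engagement,
# cause-of-death classification, matched controls, covariate assembly.

#' Study eligibility window
#'
#' Day offsets from the study origin (day 0 = 2015-04-01).  Defaults cover
#' admissions from April 2015 (day 0) through August 2018 (day 1248), with
#' the 12-month-mortality cohort restricted to admissions on or before
#' 2018-01-01 (day 1006) so every member has a full year of follow-up.
#'
#' @param start_date,end_date admission window bounds (integer days).
#' @param mortality_cutoff_date latest admission allowed into the mortality
#'   cohort.
#' @return an `eligibility_window` list.
#' @export
eligibility_window <- function(start_date = 0L, end_date = 1248L,
                               mortality_cutoff_date = 1006L) {
  if (!(start_date < mortality_cutoff_date &&
        mortality_cutoff_date <= end_date)) {
    stop("need start_date < mortality_cutoff_date <= end_date", call. = FALSE)
  }
  structure(list(start_date = as.integer(start_date),
                 end_date = as.integer(end_date),
                 mortality_cutoff_date = as.integer(mortality_cutoff_date)),
            class = "eligibility_window")
}

# does a semicolon-separated diagnosis string carry an OUD code?
# (ICD-9 304.* or ICD-10 F11*, codes stored without dots)
has_oud_code <- function(diagnosis_codes) {
  vapply(strsplit(as.character(diagnosis_codes), ";", fixed = TRUE),
         function(codes) {
           codes <- trimws(codes)
           ok <- grepl("^(304|F11)", codes)
           malformed <- nzchar(codes) & !grepl("^[A-Za-z0-9.]+$", codes)
           if (any(malformed)) {
             warning("malformed diagnosis code(s) ignored: ",
                     paste(codes[malformed], collapse = ", "), call. = FALSE)
             ok[malformed] <- FALSE
           }
           any(ok)
         }, logical(1))
}

#' Select eligible index admissions
#'
#' Retains patients at least 18 years old with an opioid-use-disorder
#' diagnosis (ICD-9 prefix 304 or ICD-10 prefix F11) on an admission inside
#' the study window, keeps the first such admission per patient as the index
#' admission, and flags the subset admitted on or before the mortality
#' cutoff as the 12-month-mortality cohort.
#'
#' @param admissions data frame: `patient_id`, `admit_date`,
#'   `discharge_date`, `diagnosis_codes` (semicolon-separated),
#'   `admission_number`.
#' @param patients data frame with `patient_id` and `age`.
#' @param window an [eligibility_window()].
#' @return the index-admission rows joined with `age`, plus
#'   `admission_quarter` (calendar quarter index of the admission date) and
#'   logical `mortality_cohort`.
#' @export
select_eligible <- function(admissions, patients, window = eligibility_window()) {
  stopifnot(inherits(window, "eligibility_window"))
  a <- merge(admissions, patients[, c("patient_id", "age")], by = "patient_id")
  keep <- a$age >= 18 &
    a$admit_date >= window$start_date & a$admit_date <= window$end_date &
    has_oud_code(a$diagnosis_codes)
  a <- a[keep, ]
  a <- a[order(a$patient_id, a$admit_date, a$admission_number), ]
  idx <- a[!duplicated(a$patient_id), ]
  idx$admission_quarter <- (idx$admit_date - window$start_date) %/% 91L
  idx$mortality_cohort <- idx$admit_date <= window$mortality_cutoff_date
  rownames(idx) <- NULL
  idx
}

MOUD_CLASSES <- c("buprenorphine", "xr_naltrexone", "methadone_otp")

#' Modified HEDIS engagement classifier
#'
#' A patient engages in post-discharge OUD treatment when, in the 30 days
#' after hospital discharge (days 1..30, discharge day itself excluded),
#' either (a) at least two fills of buprenorphine, extended-release
#' naltrexone or methadone from an opioid treatment program occur, or
#' (b) buprenorphine / XR-naltrexone supply covers at least 28 of those 30
#' days (per-fill overlap with the window, summed and capped at 30).
#'
#' @param discharge_day integer day offset of hospital discharge.
#' @param fills the patient's fill rows: `drug_class`, `fill_date`,
#'   `days_supply`.
#' @return logical.
#' @export
classify_engagement <- function(discharge_day, fills) {
  if (nrow(fills) == 0L) return(FALSE)
  if (any(fills$days_supply < 0)) {
    stop("data error: negative days_supply", call. = FALSE)
  }
  lo <- discharge_day + 1L
  hi <- discharge_day + 30L
  in_window <- fills$fill_date >= lo & fills$fill_date <= hi
  moud <- fills$drug_class %in% MOUD_CLASSES
  if (sum(in_window & moud) >= 2L) return(TRUE)           # clause (a)
  cover <- fills[fills$drug_class %in% c("buprenorphine", "xr_naltrexone"), ,
                 drop = FALSE]
  if (nrow(cover) == 0L) return(FALSE)
  overlap <- pmax(0, pmin(cover$fill_date + cover$days_supply - 1, hi) -
                     pmax(cover$fill_date, lo) + 1)
  min(sum(overlap), 30) >= 28                              # clause (b)
}

# expand a range prefix like "X40-X44" into c("X40", ..., "X44")
expand_code_range <- function(x) {
  unlist(lapply(x, function(s) {
    if (!grepl("-", s, fixed = TRUE)) return(s)
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    letter <- sub("[0-9]+$", "", parts[1])
    lo <- as.integer(sub("^[A-Za-z]+", "", parts[1]))
    hi <- as.integer(sub("^[A-Za-z]+", "", parts[2]))
    sprintf("%s%02d", letter, lo:hi)
  }))
}

#' Map from underlying-cause codes to drug-related / non-drug-related
#'
#' The default drug-related set is the ICD-10 underlying-cause poisoning
#' prefixes X40-X44 (accidental), X60-X64 (intentional self-harm), X85
#' (assault) and Y10-Y14 (undetermined intent).  Manual reclassification of
#' individual deaths is expressed through the `overrides` table, which takes
#' precedence over the code mapping.
#'
#' @param drug_related_codes character vector of code prefixes; ranges like
#'   `"X40-X44"` are expanded.
#' @param overrides data frame `patient_id`, `category` ("drug"/"non_drug"),
#'   or NULL.
#' @return a `cause_map` list.
#' @export
cause_map <- function(drug_related_codes = c("X40-X44", "X60-X64", "X85",
                                             "Y10-Y14"),
                      overrides = NULL) {
  if (!is.null(overrides)) {
    stopifnot(all(c("patient_id", "category") %in% names(overrides)),
              all(overrides$category %in% c("drug", "non_drug")))
  }
  structure(list(drug_related_codes = expand_code_range(drug_related_codes),
                 overrides = overrides),
            class = "cause_map")
}

#' Read a cause map from JSON or YAML
#' @param path file with fields `drug_related_codes` and optional `overrides`.
#' @return a [cause_map()].
#' @export
read_cause_map <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  ov <- x$overrides
  if (!is.null(ov) && !is.data.frame(ov)) ov <- as.data.frame(ov)
  if (!is.null(ov) && nrow(ov) == 0L) ov <- NULL
  cause_map(drug_related_codes = x$drug_related_codes, overrides = ov)
}

#' Classify a 12-month death outcome
#'
#' `"none"` when the patient has no death record within 365 days of the
#' index discharge; otherwise `"drug"` when the underlying cause matches the
#' drug-related code set (or an override says so), else `"non_drug"`.
#'
#' @param death one death-record row (`death_date`,
#'   `underlying_cause_code`, `patient_id`) or NULL.
#' @param index_discharge_day discharge day of the index admission.
#' @param map a [cause_map()].
#' @return one of `"none"`, `"drug"`, `"non_drug"`.
#' @export
classify_death <- function(death, index_discharge_day, map = cause_map()) {
  stopifnot(inherits(map, "cause_map"))
  if (is.null(death) || nrow(death) == 0L) return("none")
  if (death$death_date[1] > index_discharge_day + 365L) return("none")
  pid <- as.character(death$patient_id[1])
  ov <- map$overrides
  if (!is.null(ov) && pid %in% ov$patient_id) {
    return(ov$category[match(pid, ov$patient_id)])
  }
  code <- toupper(trimws(as.character(death$underlying_cause_code[1])))
  if (is.na(code) || !nzchar(code)) {
    stop("classification error: death with empty cause and no override for ",
         "patient ", pid, call. = FALSE)
  }
  hit <- any(startsWith(code, map$drug_related_codes))
  if (hit) "drug" else "non_drug"
}

#' Match referred cases to non-referred controls without replacement
#'
#' Each case receives up to `ratio` controls with identical
#' (admission_quarter, admission_number); no control is used twice.  Cases
#' are processed in ascending admission date; within a stratum, controls are
#' taken in ascending admission date then patient id (a deterministic,
#' audit-friendly tie-break).  Cases with fewer than `ratio` available
#' controls keep what exists and are flagged under-matched.
#'
#' @param cases,pool data frames with `patient_id`, `admit_date`,
#'   `admission_quarter`, `admission_number`; one row per patient.
#' @param ratio controls per case (default 3).
#' @return a `matched_cohort` list: `matches` (case_id, control_id rows),
#'   `under_matched` (case ids), and the input tables.
#' @export
match_controls <- function(cases, pool, ratio = 3L) {
  stopifnot(ratio >= 1)
  req <- c("patient_id", "admit_date", "admission_quarter", "admission_number")
  stopifnot(all(req %in% names(cases)), all(req %in% names(pool)))
  if (nrow(pool) == 0L) stop("matching error: empty control pool",
                             call. = FALSE)
  pool <- pool[order(pool$admit_date, pool$patient_id), ]
  used <- character(0)
  cases <- cases[order(cases$admit_date, cases$patient_id), ]
  matches <- vector("list", nrow(cases))
  under <- character(0)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    avail <- pool[pool$admission_quarter == cs$admission_quarter &
                  pool$admission_number == cs$admission_number &
                  !(pool$patient_id %in% used), , drop = FALSE]
    take <- utils::head(avail$patient_id, ratio)
    used <- c(used, take)
    if (length(take) < ratio) under <- c(under, cs$patient_id)
    if (length(take)) {
      matches[[i]] <- data.frame(case_id = cs$patient_id, control_id = take,
                                 stringsAsFactors = FALSE)
    }
  }
  matches <- if (any(!vapply(matches, is.null, logical(1)))) {
    do.call(rbind, matches)
  } else {
    data.frame(case_id = character(), control_id = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(matches = matches, under_matched = under,
                 cases = cases, pool = pool, ratio = as.integer(ratio)),
            class = "matched_cohort")
}

#' Assemble the patient-level analysis table
#'
#' One row per eligible index admission, carrying every model covariate
#' (age, gender, 3-level race, ethnicity, concurrent alcohol and stimulant
#' use disorder, length of stay, rural residence, MOUD fill in the 30 days
#' before admission, prior hospital admission, CDPS score, naloxone fill in
#' the 30 days after discharge), the ACS referral flag, the modified-HEDIS
#' engagement flag and the 12-month death category.
#'
#' @param eligible output of [select_eligible()].
#' @param patients,fills,deaths the raw event tables.
#' @param referred_ids character vector of patient ids referred to the ACS
#'   (the referral registry).
#' @param map a [cause_map()].
#' @return an `analysis_table` data frame.
#' @export
build_covariates <- function(eligible, patients, fills, deaths, referred_ids,
                             map = cause_map()) {
  req <- c("patient_id", "age", "male", "race", "hispanic", "aud", "stud",
           "rural", "cdps")
  miss <- setdiff(req, names(patients))
  if (length(miss)) stop("schema error: patients table lacks column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab <- merge(eligible[, c("patient_id", "admit_date", "discharge_date",
                            "admission_number", "admission_quarter",
                            "mortality_cohort")],
               patients, by = "patient_id")
  tab$length_of_stay <- tab$discharge_date - tab$admit_date
  tab$race_not_white <- as.integer(tab$race == "not_white")
  tab$race_unknown <- as.integer(tab$race == "unknown")
  tab$prior_admission <- as.integer(tab$admission_number > 1L)
  tab$referral <- as.integer(tab$patient_id %in% referred_ids)

  fills_by <- split(fills, fills$patient_id)
  per_patient <- function(pid) fills_by[[pid]]
  n <- nrow(tab)
  moud_pre <- integer(n); engaged <- integer(n); nalox <- integer(n)
  for (i in seq_len(n)) {
    f <- per_patient(tab$patient_id[i])
    if (is.null(f)) f <- fills[0, , drop = FALSE]
    moud_pre[i] <- as.integer(any(
      f$drug_class %in% MOUD_CLASSES &
        f$fill_date >= tab$admit_date[i] - 30L &
        f$fill_date <= tab$admit_date[i] - 1L))
    engaged[i] <- as.integer(classify_engagement(tab$discharge_date[i], f))
    nalox[i] <- as.integer(any(
      f$drug_class == "naloxone" &
        f$fill_date >= tab$discharge_date[i] + 1L &
        f$fill_date <= tab$discharge_date[i] + 30L))
  }
  tab$moud_at_admission <- moud_pre
  tab$engagement <- engaged
  tab$naloxone_fill_30d <- nalox

  deaths_by <- split(deaths, deaths$patient_id)
  tab$death_category <- vapply(seq_len(n), function(i) {
    classify_death(deaths_by[[tab$patient_id[i]]], tab$discharge_date[i], map)
  }, character(1))

  cols <- c("patient_id", "admit_date", "discharge_date", "admission_number",
            "admission_quarter", "mortality_cohort", COVARIATE_NAMES,
            "naloxone_fill_30d", "referral", "engagement", "death_category")
  out <- tab[, c(cols, "race")]
  class(out) <- c("analysis_table", "data.frame")
  out
}

#' Write / read an analysis table as tab-separated text
#' @param table an `analysis_table`.
#' @param path output file.
#' @export
write_analysis_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_analysis_table
#' @export
read_analysis_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(patient_id = "character"))
  class(out) <- c("analysis_table", "data.frame")
  out
}
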
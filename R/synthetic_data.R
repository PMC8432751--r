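# Synthetic claims-like cohorts with known ground truth.
#
# All dates are integer day offsets from a fixed study origin (day 0 =
# 2015-04-01); the admissions window runs to day 1248 (2018-08-31) with the
# 12-month-mortality cutoff at day 1006 (2018-01-01).

# covariates every model may use, in canonical column order
COVARIATE_NAMES <- c("age", "male", "race_not_white", "race_unknown",
                     "hispanic", "aud", "stud", "length_of_stay", "rural",
                     "moud_at_admission", "prior_admission", "cdps")

DRUG_CLASSES <- c("buprenorphine", "xr_naltrexone", "methadone_otp",
                  "naloxone", "other")

default_covariate_params <- function() {
  list(
    age_mean = 44.5, age_sd = 15.4,          # years, truncated at 18
    p_male = 0.430,
    p_white = 0.701, p_not_white = 0.064,    # remainder: unknown race
    p_hispanic = 0.035,
    p_aud = 0.036, p_stud = 0.082,
    los_mean = 6.6, los_sd = 11.2,           # days; log-normal
    p_rural = 0.264,
    p_moud_at_admission = 0.178,
    p_prior_admission = 0.224,
    cdps_mean = 2.5, cdps_sd = 1.6,          # gamma
    p_naloxone = 0.05                        # post-discharge naloxone fill
  )
}

# Exact marginal event probability of a logistic model whose nonzero
# covariate effects are all on independent Bernoulli covariates: enumerate
# the 2^k covariate combinations.
marginal_logistic <- function(intercept, coefs, probs) {
  if (length(coefs) == 0L) return(stats::plogis(intercept))
  k <- length(coefs)
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  w <- apply(combos, 1, function(z) prod(ifelse(z == 1, probs, 1 - probs)))
  sum(w * stats::plogis(intercept + combos %*% coefs))
}

# Intercept giving a target marginal event rate, by root finding.
calibrate_intercept <- function(target, coefs, probs) {
  stats::uniroot(function(b0) marginal_logistic(b0, coefs, probs) - target,
                 c(-30, 30), tol = 1e-12)$root
}

default_true_coefficients <- function(cp) {
  # binary-covariate effects only, so the implied marginals are exact;
  # intercepts calibrated so the model-implied rates match the published
  # Oregon estimates: 4% referred, 20% engaged if not referred (47% if
  # referred), 15% twelve-month death if not engaged (10% if engaged).
  ref_cf  <- c(prior_admission = 0.9, stud = 0.6, rural = -0.8)
  ref_pr  <- c(cp$p_prior_admission, cp$p_stud, cp$p_rural)
  eng_cf  <- c(moud_at_admission = 0.8, rural = -0.4)
  eng_pr  <- c(cp$p_moud_at_admission, cp$p_rural)
  mor_cf  <- c(prior_admission = 0.5, naloxone_fill_30d = -0.2)
  mor_pr  <- c(cp$p_prior_admission, cp$p_naloxone)
  list(
    referral = c("(Intercept)" = calibrate_intercept(0.04, ref_cf, ref_pr),
                 ref_cf),
    engagement = c("(Intercept)" = calibrate_intercept(0.20, eng_cf, eng_pr),
                   eng_cf,
                   referral = stats::qlogis(0.47) - stats::qlogis(0.20)),
    mortality = c("(Intercept)" = calibrate_intercept(0.15, mor_cf, mor_pr),
                  mor_cf,
                  engagement = stats::qlogis(0.10) - stats::qlogis(0.15))
  )
}

# ICD-10 underlying-cause codes used when generating death records
DRUG_CAUSE_CODES    <- c("X42", "X44", "X62", "Y12")
NONDRUG_CAUSE_CODES <- c("I251", "C349", "A419", "K703", "J189", "E119")

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer seed; same config + seed gives byte-identical output.
#' @param covariate_params named list of distribution parameters for the
#'   patient-level covariates (age mean/sd, binary-covariate proportions,
#'   length-of-stay mean/sd, CDPS mean/sd, naloxone fill rate); defaults are
#'   the published cohort's demographics.
#' @param true_coefficients list with elements `referral`, `engagement`,
#'   `mortality`: named log-odds coefficient vectors (names drawn from the
#'   model covariate vocabulary plus `"(Intercept)"`); defaults are
#'   calibrated so the implied marginal rates match the published transition
#'   estimates.
#' @param mortality_split probability a 12-month death is drug-related,
#'   given death, by engagement status:
#'   `c(engaged = 0.30, not_engaged = 0.40)` by default (so the implied
#'   drug/non-drug splits are 3%/7% engaged and 6%/9% not engaged).
#' @param window an [eligibility_window()]; admission days are uniform on it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients, seed,
                       covariate_params = list(),
                       true_coefficients = NULL,
                       mortality_split = c(engaged = 0.30, not_engaged = 0.40),
                       window = eligibility_window()) {
  if (!(is.numeric(n_patients) && length(n_patients) == 1L && n_patients >= 1)) {
    stop("configuration error: n_patients must be a positive integer",
         call. = FALSE)
  }
  cp <- utils::modifyList(default_covariate_params(), covariate_params)
  extra <- setdiff(names(covariate_params), names(default_covariate_params()))
  if (length(extra)) {
    stop("configuration error: unknown covariate_params ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nm in grep("^p_", names(cp), value = TRUE)) {
    if (!is.finite(cp[[nm]]) || cp[[nm]] < 0 || cp[[nm]] > 1) {
      stop("configuration error: ", nm, " must be a proportion in [0, 1]",
           call. = FALSE)
    }
  }
  if (cp$p_white + cp$p_not_white > 1) {
    stop("configuration error: p_white + p_not_white exceeds 1", call. = FALSE)
  }
  for (nm in c("age_sd", "los_mean", "los_sd", "cdps_mean", "cdps_sd")) {
    if (!is.finite(cp[[nm]]) || cp[[nm]] <= 0) {
      stop("configuration error: ", nm, " must be positive", call. = FALSE)
    }
  }
  if (is.null(true_coefficients)) {
    true_coefficients <- default_true_coefficients(cp)
  }
  stopifnot(all(c("referral", "engagement", "mortality") %in%
                  names(true_coefficients)))
  vocab <- c("(Intercept)", COVARIATE_NAMES, "referral", "engagement",
             "naloxone_fill_30d")
  for (m in c("referral", "engagement", "mortality")) {
    bad <- setdiff(names(true_coefficients[[m]]), vocab)
    if (length(bad)) {
      stop("configuration error: ", m, " coefficients name unknown ",
           "covariates: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  ms <- mortality_split
  if (!all(c("engaged", "not_engaged") %in% names(ms)) ||
      any(ms < 0) || any(ms > 1)) {
    stop("configuration error: mortality_split needs 'engaged' and ",
         "'not_engaged' probabilities in [0, 1]", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 covariate_params = cp, true_coefficients = true_coefficients,
                 mortality_split = ms, window = window),
            class = "sim_config")
}

# linear predictor for a named coefficient vector over a covariate frame
linpred <- function(coefs, data) {
  eta <- rep(if ("(Intercept)" %in% names(coefs)) coefs[["(Intercept)"]] else 0,
             nrow(data))
  for (nm in setdiff(names(coefs), "(Intercept)")) {
    if (!nm %in% names(data)) stop("covariate '", nm, "' not in data",
                                   call. = FALSE)
    eta <- eta + coefs[[nm]] * data[[nm]]
  }
  eta
}

#' Generate a synthetic claims-like cohort
#'
#' Draws patient covariates from the configured marginal distributions,
#' samples latent referral, engagement and 12-month death from logistic
#' models with the configured true coefficients, and constructs admissions,
#' pharmacy-fill and death-record tables that are exactly consistent with
#' the latent truth: engaged patients receive fills satisfying the modified
#' HEDIS engagement rule (either two MOUD fills at days 5 and 20
#' post-discharge, or one 30-day buprenorphine supply from day 1); not-
#' engaged patients receive at most one short fill; drug-related deaths get
#' an underlying-cause code from the drug-related set.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_cohort` list of data frames: `patients`,
#'   `admissions`, `fills`, `deaths`, `truth`, plus the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  cp <- config$covariate_params
  w <- config$window

  age <- stats::rnorm(n, cp$age_mean, cp$age_sd)
  while (any(age < 18)) {                      # truncate at adulthood
    i <- age < 18
    age[i] <- stats::rnorm(sum(i), cp$age_mean, cp$age_sd)
  }
  race <- sample(c("white", "not_white", "unknown"), n, replace = TRUE,
                 prob = c(cp$p_white, cp$p_not_white,
                          1 - cp$p_white - cp$p_not_white))
  sdlog <- sqrt(log(1 + (cp$los_sd / cp$los_mean)^2))
  los <- pmax(1, round(stats::rlnorm(n, log(cp$los_mean) - sdlog^2 / 2, sdlog)))
  shape <- (cp$cdps_mean / cp$cdps_sd)^2
  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = round(age, 1),
    male = stats::rbinom(n, 1, cp$p_male),
    race = race,
    hispanic = stats::rbinom(n, 1, cp$p_hispanic),
    aud = stats::rbinom(n, 1, cp$p_aud),
    stud = stats::rbinom(n, 1, cp$p_stud),
    rural = stats::rbinom(n, 1, cp$p_rural),
    cdps = round(stats::rgamma(n, shape = shape,
                               scale = cp$cdps_sd^2 / cp$cdps_mean), 2),
    stringsAsFactors = FALSE
  )

  moud_at_admission <- stats::rbinom(n, 1, cp$p_moud_at_admission)
  prior_admission <- stats::rbinom(n, 1, cp$p_prior_admission)
  naloxone <- stats::rbinom(n, 1, cp$p_naloxone)

  admit <- sample(seq(w$start_date, w$end_date), n, replace = TRUE)
  discharge <- admit + los

  # covariate frame on which the latent outcome models operate
  X <- data.frame(
    age = patients$age, male = patients$male,
    race_not_white = as.integer(race == "not_white"),
    race_unknown = as.integer(race == "unknown"),
    hispanic = patients$hispanic, aud = patients$aud, stud = patients$stud,
    length_of_stay = los, rural = patients$rural,
    moud_at_admission = moud_at_admission, prior_admission = prior_admission,
    naloxone_fill_30d = naloxone
  )
  tc <- config$true_coefficients
  referral <- stats::rbinom(n, 1, stats::plogis(linpred(tc$referral, X)))
  X$referral <- referral
  engagement <- stats::rbinom(n, 1, stats::plogis(linpred(tc$engagement, X)))
  X$engagement <- engagement
  death <- stats::rbinom(n, 1, stats::plogis(linpred(tc$mortality, X)))
  p_drug <- ifelse(engagement == 1, config$mortality_split[["engaged"]],
                   config$mortality_split[["not_engaged"]])
  drug_death <- death == 1 & stats::runif(n) < p_drug
  death_category <- ifelse(death == 0, "none",
                           ifelse(drug_death, "drug", "non_drug"))

  # admissions: index admission carries the OUD diagnosis; patients with a
  # prior admission get an earlier non-OUD admission so the index stays the
  # first OUD-coded admission
  idx_adm <- data.frame(
    patient_id = patients$patient_id, admit_date = admit,
    discharge_date = discharge,
    diagnosis_codes = paste0("F1120;", sample(NONDRUG_CAUSE_CODES, n,
                                              replace = TRUE)),
    admission_number = 1L + prior_admission, stringsAsFactors = FALSE
  )
  prev <- which(prior_admission == 1L)
  adm <- idx_adm
  if (length(prev)) {
    gap <- sample(60:400, length(prev), replace = TRUE)
    prev_adm <- data.frame(
      patient_id = patients$patient_id[prev],
      admit_date = admit[prev] - gap,
      discharge_date = admit[prev] - gap +
        sample(1:10, length(prev), replace = TRUE),
      diagnosis_codes = sample(NONDRUG_CAUSE_CODES, length(prev),
                               replace = TRUE),
      admission_number = 1L, stringsAsFactors = FALSE
    )
    adm <- rbind(prev_adm, idx_adm)
  }
  adm <- adm[order(adm$patient_id, adm$admission_number), ]
  rownames(adm) <- NULL

  # pharmacy fills
  fills <- list()
  pre <- which(moud_at_admission == 1L)
  if (length(pre)) {
    fills$pre <- data.frame(
      patient_id = patients$patient_id[pre], drug_class = "buprenorphine",
      fill_date = admit[pre] - sample(1:30, length(pre), replace = TRUE),
      days_supply = 14L, stringsAsFactors = FALSE
    )
  }
  eng <- which(engagement == 1L)
  if (length(eng)) {
    two_fill <- stats::runif(length(eng)) < 0.5
    a <- eng[two_fill]; b <- eng[!two_fill]
    if (length(a)) {
      cls <- sample(c("buprenorphine", "xr_naltrexone", "methadone_otp"),
                    length(a), replace = TRUE)
      fills$eng2 <- data.frame(
        patient_id = rep(patients$patient_id[a], 2L),
        drug_class = rep(cls, 2L),
        fill_date = c(discharge[a] + 5L, discharge[a] + 20L),
        days_supply = 14L, stringsAsFactors = FALSE
      )
    }
    if (length(b)) {
      fills$eng1 <- data.frame(
        patient_id = patients$patient_id[b], drug_class = "buprenorphine",
        fill_date = discharge[b] + 1L, days_supply = 30L,
        stringsAsFactors = FALSE
      )
    }
  }
  noneng <- which(engagement == 0L)
  if (length(noneng)) {
    one_short <- noneng[stats::runif(length(noneng)) < 0.3]
    if (length(one_short)) {
      fills$short <- data.frame(
        patient_id = patients$patient_id[one_short],
        drug_class = "buprenorphine",
        fill_date = discharge[one_short] +
          sample(1:20, length(one_short), replace = TRUE),
        days_supply = 7L, stringsAsFactors = FALSE
      )
    }
  }
  nx <- which(naloxone == 1L)
  if (length(nx)) {
    fills$nx <- data.frame(
      patient_id = patients$patient_id[nx], drug_class = "naloxone",
      fill_date = discharge[nx] + sample(1:30, length(nx), replace = TRUE),
      days_supply = 1L, stringsAsFactors = FALSE
    )
  }
  fills <- if (length(fills)) do.call(rbind, fills) else
    data.frame(patient_id = character(), drug_class = character(),
               fill_date = integer(), days_supply = integer(),
               stringsAsFactors = FALSE)
  fills <- fills[order(fills$patient_id, fills$fill_date), ]
  rownames(fills) <- NULL

  dead <- which(death_category != "none")
  deaths <- data.frame(
    patient_id = patients$patient_id[dead],
    death_date = discharge[dead] + sample(1:365, length(dead), replace = TRUE),
    underlying_cause_code = ifelse(
      death_category[dead] == "drug",
      sample(DRUG_CAUSE_CODES, length(dead), replace = TRUE),
      sample(NONDRUG_CAUSE_CODES, length(dead), replace = TRUE)),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    patient_id = patients$patient_id,
    referral = referral, engagement = engagement,
    death_category = death_category,
    naloxone_fill_30d = naloxone,
    moud_at_admission = moud_at_admission,
    prior_admission = prior_admission, stringsAsFactors = FALSE
  )

  structure(list(patients = patients, admissions = adm, fills = fills,
                 deaths = deaths, truth = truth, config = config),
            class = "synthetic_cohort")
}

COHORT_TABLES <- c("patients", "admissions", "fills", "deaths", "truth")

#' Write / read a synthetic cohort as delimited text
#'
#' One tab-separated file per table (`patients.tsv`, `admissions.tsv`,
#' `fills.tsv`, `deaths.tsv`, `truth.tsv`) plus a `config.json` sidecar
#' recording the generator configuration including the seed.  The readers
#' round-trip the tables field-for-field.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if absent).
#' @return `write_cohort()` invisibly returns the directory;
#'   `read_cohort()` returns the list of tables.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create directory '", directory, "'", call. = FALSE)
  }
  for (tb in COHORT_TABLES) {
    utils::write.table(cohort[[tb]], file.path(directory, paste0(tb, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cfg <- cohort$config
  cfg$window <- unclass(cfg$window)
  cfg$true_coefficients <- lapply(cfg$true_coefficients, as.list)
  jsonlite::write_json(unclass(cfg), file.path(directory, "config.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  out <- lapply(COHORT_TABLES, function(tb) {
    path <- file.path(directory, paste0(tb, ".tsv"))
    if (!file.exists(path)) stop("missing table file '", path, "'",
                                 call. = FALSE)
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(patient_id = "character"))
  })
  names(out) <- COHORT_TABLES
  out
}
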
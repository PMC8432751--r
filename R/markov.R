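#' Transition probabilities for the single-cycle Markov model
#'
#' Bundles the five branch probabilities of the care-trajectory model --
#' referral to an addiction consult service (ACS), post-discharge treatment
#' engagement in each referral stratum, and 12-month drug-related and
#' non-drug-related death in each engagement stratum -- each as a
#' (point, lower, upper) triple on the probability scale.
#'
#' @param referral,engage_referred,engage_not_referred,drug_death_engaged,drug_death_not_engaged,nondrug_death_engaged,nondrug_death_not_engaged
#'   numeric length-3 vectors `c(point, lower, upper)`, all in `[0, 1]`.
#' @return an object of class `transition_probabilities`: a named list of
#'   triples, validated so that `lower <= point <= upper` and, within each
#'   engagement stratum, the point death probabilities sum to at most 1.
#' @seealso [oregon_transitions()] for the published Oregon estimates,
#'   [project_cohort()] for expected-count projections.
#' @export
transition_probabilities <- function(referral,
                                     engage_referred,
                                     engage_not_referred,
                                     drug_death_engaged,
                                     drug_death_not_engaged,
                                     nondrug_death_engaged,
                                     nondrug_death_not_engaged) {
  tp <- list(
    referral                  = referral,
    engage_referred           = engage_referred,
    engage_not_referred       = engage_not_referred,
    drug_death_engaged        = drug_death_engaged,
    drug_death_not_engaged    = drug_death_not_engaged,
    nondrug_death_engaged     = nondrug_death_engaged,
    nondrug_death_not_engaged = nondrug_death_not_engaged
  )
  for (nm in names(tp)) {
    x <- tp[[nm]]
    if (!is.numeric(x) || length(x) != 3L || anyNA(x)) {
      stop("'", nm, "' must be a numeric (point, lower, upper) triple",
           call. = FALSE)
    }
    if (any(x < 0) || any(x > 1)) {
      stop("'", nm, "' has values outside [0, 1]", call. = FALSE)
    }
    if (!(x[2] <= x[1] && x[1] <= x[3])) {
      stop("'", nm, "' violates lower <= point <= upper", call. = FALSE)
    }
    tp[[nm]] <- stats::setNames(as.numeric(x), c("point", "lower", "upper"))
  }
  if (tp$drug_death_engaged["point"] + tp$nondrug_death_engaged["point"] > 1 ||
      tp$drug_death_not_engaged["point"] + tp$nondrug_death_not_engaged["point"] > 1) {
    stop("point death probabilities within an engagement stratum exceed 1",
         call. = FALSE)
  }
  structure(tp, class = "transition_probabilities")
}

#' Published Oregon transition probabilities
#'
#' The point estimates and 95% intervals for hospital-based addiction care in
#' Oregon, 2015--2018: 4% (2, 6) referred to an ACS; engagement 47% (37, 57)
#' if referred versus 20% (16, 24) if not; 12-month drug-related death 3%
#' (0, 7) engaged versus 6% (2, 10) not engaged; non-drug-related death 7%
#' (1, 13) versus 9% (5, 13).
#'
#' @return a [transition_probabilities()] object.
#' @export
oregon_transitions <- function() {
  transition_probabilities(
    referral                  = c(0.04, 0.02, 0.06),
    engage_referred           = c(0.47, 0.37, 0.57),
    engage_not_referred       = c(0.20, 0.16, 0.24),
    drug_death_engaged        = c(0.03, 0.00, 0.07),
    drug_death_not_engaged    = c(0.06, 0.02, 0.10),
    nondrug_death_engaged     = c(0.07, 0.01, 0.13),
    nondrug_death_not_engaged = c(0.09, 0.05, 0.13)
  )
}

#' Read / write transition probabilities as JSON or YAML
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_transitions()` returns a [transition_probabilities()] object.
#' @export
read_transitions <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(transition_probabilities, lapply(x, as.numeric))
}

#' @rdname read_transitions
#' @param probs a [transition_probabilities()] object.
#' @export
write_transitions <- function(probs, path) {
  stopifnot(inherits(probs, "transition_probabilities"))
  x <- lapply(unclass(probs), unname)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# Pick the (referral, engagement) bound combination for a scenario.
# The deterministic bound scenarios combine interval endpoints across all
# transitions: the "high death" scenario takes the referral and engagement
# intervals at their lower bounds (fewest patients protected by engagement)
# and, downstream, mortality at its upper bounds; "low death" is the mirror.
scenario_levels <- function(bound) {
  switch(bound,
    point              = list(ref = "point", eng = "point"),
    high_death_scenario = list(ref = "lower", eng = "lower"),
    low_death_scenario  = list(ref = "upper", eng = "upper"),
    stop("unknown bound scenario '", bound, "'", call. = FALSE)
  )
}

#' Fraction of the cohort engaging in post-discharge OUD care
#'
#' Two conventions coexist because the published projections use both: the
#' `combined` two-branch fraction
#' \eqn{p_{ref} p_{eng|ref} + (1 - p_{ref}) p_{eng|\neg ref}} feeds the death
#' projections, while the engaged-count projection uses the not-referred
#' engagement probability alone (`not_referred_only`).
#'
#' @param probs a [transition_probabilities()] object.
#' @param convention `"combined"` or `"not_referred_only"`.
#' @param bound `"point"`, `"low_death_scenario"` (upper referral/engagement
#'   bounds) or `"high_death_scenario"` (lower bounds).
#' @return a single probability.
#' @export
engaged_fraction <- function(probs,
                             convention = c("combined", "not_referred_only"),
                             bound = "point") {
  stopifnot(inherits(probs, "transition_probabilities"))
  convention <- match.arg(convention)
  lv <- scenario_levels(bound)
  p_ref <- probs$referral[[lv$ref]]
  p_er  <- probs$engage_referred[[lv$eng]]
  p_en  <- probs$engage_not_referred[[lv$eng]]
  if (convention == "not_referred_only") {
    return(unname(p_en))
  }
  unname(p_ref * p_er + (1 - p_ref) * p_en)
}

# Expected deaths per cohort member for one cause under a scenario.
# Point: engaged fraction at point values, point mortality.
# High death: high_death_scenario engaged fraction, upper mortality bounds.
# Low death: low_death_scenario engaged fraction, lower mortality bounds.
death_risk <- function(probs, cause = c("drug", "nondrug"),
                       bound = c("point", "low_death_scenario",
                                 "high_death_scenario")) {
  cause <- match.arg(cause)
  bound <- match.arg(bound)
  f <- engaged_fraction(probs, "combined", bound)
  mort_level <- switch(bound, point = "point",
                       low_death_scenario = "lower",
                       high_death_scenario = "upper")
  p_e  <- probs[[paste0(cause, "_death_engaged")]][[mort_level]]
  p_ne <- probs[[paste0(cause, "_death_not_engaged")]][[mort_level]]
  unname(f * p_e + (1 - f) * p_ne)
}

round1 <- function(x) round(x, 1)

#' Project expected 12-month counts for a cohort
#'
#' Pushes a cohort of `cohort_n` hospitalized patients with OUD through the
#' single-cycle model and reports expected counts with deterministic Low/High
#' bounds.  The expected engaged count uses the not-referred engagement
#' probability with its interval; expected deaths use the combined two-branch
#' engaged fraction, with bounds from the scenario combinations (High death:
#' lower referral and engagement bounds with upper mortality bounds; Low
#' death: the mirror).  Expected counts are reported to one decimal.
#'
#' @param cohort_n cohort size (positive integer).
#' @param probs a [transition_probabilities()] object.
#' @return a `cohort_projection` list: `cohort_n`, and for engaged, drug
#'   deaths, non-drug deaths, total deaths and death percent a
#'   `c(point, low, high)` vector; plus point `survivors`.
#' @export
project_cohort <- function(cohort_n, probs) {
  stopifnot(cohort_n >= 1, inherits(probs, "transition_probabilities"))
  eng <- cohort_n * c(
    point = probs$engage_not_referred[["point"]],
    low   = probs$engage_not_referred[["lower"]],
    high  = probs$engage_not_referred[["upper"]]
  )
  risk <- function(cause) c(
    point = death_risk(probs, cause, "point"),
    low   = death_risk(probs, cause, "low_death_scenario"),
    high  = death_risk(probs, cause, "high_death_scenario")
  )
  drug    <- cohort_n * risk("drug")
  nondrug <- cohort_n * risk("nondrug")
  total   <- drug + nondrug
  pct     <- 100 * total / cohort_n
  structure(list(
    cohort_n                = cohort_n,
    expected_engaged        = round1(eng),
    expected_drug_deaths    = round1(drug),
    expected_nondrug_deaths = round1(nondrug),
    expected_total_deaths   = round1(total),
    death_percent           = round1(pct),
    survivors               = round1(cohort_n - total[["point"]])
  ), class = "cohort_projection")
}

#' @export
print.cohort_projection <- function(x, ...) {
  fmt <- function(v) sprintf("%.1f (Low, High = (%.1f, %.1f))",
                             v[["point"]], v[["low"]], v[["high"]])
  cat("12-month cohort projection, n = ", x$cohort_n, "\n",
      "  engaged in post-discharge OUD care: ", fmt(x$expected_engaged), "\n",
      "  drug-related deaths:                ", fmt(x$expected_drug_deaths), "\n",
      "  non-drug-related deaths:            ", fmt(x$expected_nondrug_deaths), "\n",
      "  total deaths:                       ", fmt(x$expected_total_deaths), "\n",
      "  deaths as % of cohort:              ", fmt(x$death_percent), "\n",
      "  expected survivors:                 ", x$survivors, "\n", sep = "")
  invisible(x)
}

trunc0 <- function(x) trunc(x)

#' Project the model onto an external cohort
#'
#' Applies the fitted transition structure to an externally reported cohort
#' size and returns one published-comparison quantity.  Twelve-month risks
#' are treated as rates per 100 person-years (each member contributes one
#' person-year).  Point counts are rounded per `rounding`; count bounds are
#' truncated toward zero; rates and their bounds are reported to one decimal.
#'
#' @param cohort_n external cohort size.
#' @param probs a [transition_probabilities()] object.
#' @param output one of `"count_engaged"`, `"count_all_deaths"`,
#'   `"rate_drug_per100py"`, `"rate_nondrug_per100py"`.
#' @param rounding `"one_decimal"`, `"truncate_integer"` or
#'   `"one_decimal_rate"`; defaults to the convention used for each published
#'   quantity.
#' @return named vector `c(point, low, high)`.
#' @export
project_external <- function(cohort_n, probs,
                             output = c("count_engaged", "count_all_deaths",
                                        "rate_drug_per100py",
                                        "rate_nondrug_per100py"),
                             rounding = NULL) {
  stopifnot(cohort_n >= 1, inherits(probs, "transition_probabilities"))
  output <- match.arg(output)
  is_rate <- grepl("^rate_", output)
  if (is.null(rounding)) {
    rounding <- if (is_rate) "one_decimal_rate"
                else if (output == "count_engaged") "one_decimal"
                else "truncate_integer"
  }
  rounding <- match.arg(rounding,
                        c("one_decimal", "truncate_integer", "one_decimal_rate"))
  raw <- switch(output,
    count_engaged = cohort_n * c(
      point = probs$engage_not_referred[["point"]],
      low   = probs$engage_not_referred[["lower"]],
      high  = probs$engage_not_referred[["upper"]]),
    count_all_deaths = {
      tot <- function(b) death_risk(probs, "drug", b) +
                         death_risk(probs, "nondrug", b)
      cohort_n * c(point = tot("point"),
                   low = tot("low_death_scenario"),
                   high = tot("high_death_scenario"))
    },
    rate_drug_per100py = 100 * c(
      point = death_risk(probs, "drug", "point"),
      low   = death_risk(probs, "drug", "low_death_scenario"),
      high  = death_risk(probs, "drug", "high_death_scenario")),
    rate_nondrug_per100py = 100 * c(
      point = death_risk(probs, "nondrug", "point"),
      low   = death_risk(probs, "nondrug", "low_death_scenario"),
      high  = death_risk(probs, "nondrug", "high_death_scenario"))
  )
  if (rounding == "one_decimal_rate") {
    round1(raw)
  } else if (rounding == "truncate_integer") {
    trunc0(raw)
  } else {
    # published convention: one-decimal point estimate, truncated bounds
    c(point = round1(raw[["point"]]),
      low = trunc0(raw[["low"]]), high = trunc0(raw[["high"]]))
  }
}

#' Individual-level microsimulation oracle
#'
#' Samples each of `cohort_n` individuals through the referral -> engagement
#' -> death-category branches at the point probabilities and returns state
#' counts.  Used as a stochastic cross-check of the closed-form expected
#' counts in [project_cohort()].
#'
#' @param cohort_n number of individuals.
#' @param probs a [transition_probabilities()] object.
#' @param seed integer seed.
#' @return named integer vector: referred, engaged, drug_deaths,
#'   nondrug_deaths, survivors.
#' @export
microsim_oracle <- function(cohort_n, probs, seed) {
  stopifnot(cohort_n >= 1, inherits(probs, "transition_probabilities"))
  set.seed(as.integer(seed))
  referred <- stats::rbinom(cohort_n, 1L,
                            probs$referral[["point"]]) == 1L
  p_eng <- ifelse(referred, probs$engage_referred[["point"]],
                  probs$engage_not_referred[["point"]])
  engaged <- stats::rbinom(cohort_n, 1L, p_eng) == 1L
  p_drug <- ifelse(engaged, probs$drug_death_engaged[["point"]],
                   probs$drug_death_not_engaged[["point"]])
  p_nondrug <- ifelse(engaged, probs$nondrug_death_engaged[["point"]],
                      probs$nondrug_death_not_engaged[["point"]])
  u <- stats::runif(cohort_n)
  state <- ifelse(u < p_drug, "drug",
                  ifelse(u < p_drug + p_nondrug, "nondrug", "alive"))
  c(referred       = sum(referred),
    engaged        = sum(engaged),
    drug_deaths    = sum(state == "drug"),
    nondrug_deaths = sum(state == "nondrug"),
    survivors      = sum(state == "alive"))
}
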
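#' Summarize expert vignette responses
#'
#' Clinical experts rated, for each vignette (a covariate profile), the
#' probability of a transition event.  Per vignette we keep the mean and the
#' minimum/maximum rating; these are the quantities the beta priors are
#' fitted to.
#'
#' @param responses data frame with columns `expert_id`, `transition`,
#'   `vignette_id`, `probability` (all probabilities in `[0, 1]`).
#' @return data frame, one row per (transition, vignette): `n_experts`,
#'   `mean`, `min`, `max`, and `degenerate` (TRUE when min == max, e.g. a
#'   single respondent, so the interval method cannot be used).
#' @export
summarize_responses <- function(responses) {
  req <- c("expert_id", "transition", "vignette_id", "probability")
  if (!all(req %in% names(responses))) {
    stop("responses must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad <- responses$probability < 0 | responses$probability > 1 |
    is.na(responses$probability)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("probability outside [0, 1] for expert '", responses$expert_id[i],
         "', vignette '", responses$vignette_id[i], "'", call. = FALSE)
  }
  key <- interaction(responses$transition, responses$vignette_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(responses, key), function(d) {
    data.frame(
      transition  = d$transition[1],
      vignette_id = d$vignette_id[1],
      n_experts   = nrow(d),
      mean        = mean(d$probability),
      min         = min(d$probability),
      max         = max(d$probability),
      stringsAsFactors = FALSE
    )
  }))
  out$degenerate <- out$min == out$max
  rownames(out) <- NULL
  out[order(out$transition, out$vignette_id), ]
}

new_beta_prior <- function(alpha, beta, source) {
  if (!(is.finite(alpha) && is.finite(beta) && alpha > 0 && beta > 0)) {
    stop("beta prior requires alpha > 0 and beta > 0", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, source = source),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%.4g, %.4g) prior  [mean %.3f, ESS %.3f]  (%s)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta),
              x$alpha + x$beta, x$source))
  invisible(x)
}

#' Fit a beta prior by the sample-size method
#'
#' The prior is given the weight of a fixed fraction of the study cohort:
#' `alpha = mean * f * cohort_n`, `beta = (1 - mean) * f * cohort_n`, so the
#' effective prior sample size `alpha + beta` equals `f * cohort_n` exactly
#' and the prior mean equals the expert mean exactly.
#'
#' @param summary one row of [summarize_responses()] output (or any list with
#'   a `mean` element in (0, 1)).
#' @param sample_size_fraction prior weight as a fraction of `cohort_n`;
#'   the strengths examined are 0.001, 0.01, 0.05 and 0.10.
#' @param cohort_n study cohort size the fraction refers to.
#' @return a `beta_prior`.
#' @export
fit_beta_samplesize <- function(summary, sample_size_fraction, cohort_n) {
  m <- summary$mean
  stopifnot(is.numeric(m), length(m) == 1L, cohort_n > 0)
  ess <- sample_size_fraction * cohort_n
  if (!is.finite(ess) || ess * min(m, 1 - m) <= 0) {
    stop("degenerate prior: fraction ", sample_size_fraction, " x cohort ",
         cohort_n, " with mean ", m, " gives a zero-strength or one-sided ",
         "beta prior", call. = FALSE)
  }
  new_beta_prior(m * ess, (1 - m) * ess,
                 sprintf("sample_size f=%g n=%d", sample_size_fraction,
                         as.integer(cohort_n)))
}

#' Fit a beta prior by the confidence-interval method
#'
#' Treats the expert minimum and maximum as the endpoints of the central
#' `level` interval of a beta distribution whose mean is constrained to the
#' expert mean, and finds the (alpha, beta) pair by one-dimensional search
#' over alpha (beta = alpha (1 - mean) / mean).  The objective is the sum of
#' squared discrepancies between the fitted central-interval endpoints and
#' (min, max).
#'
#' @param summary one row of [summarize_responses()] output: needs `mean`,
#'   `min`, `max` with `min < max`.
#' @param level central interval mass; the strengths examined are 0.80,
#'   0.85, 0.90 and 0.95.
#' @param tol convergence tolerance on alpha for the scalar search.
#' @return a `beta_prior` with attributes `achieved` (fitted endpoints) and
#'   `feasible` (TRUE when both endpoints are within 1e-3 of their targets).
#' @export
fit_beta_interval <- function(summary, level, tol = 1e-8) {
  m <- summary$mean; lo <- summary$min; hi <- summary$max
  stopifnot(level > 0, level < 1)
  if (!(m > 0 && m < 1)) stop("mean must be in (0, 1)", call. = FALSE)
  if (!(lo < hi)) {
    stop("degenerate summary (min == max): the interval method needs ",
         "spread across experts; use the sample_size method instead",
         call. = FALSE)
  }
  if (!(lo <= m && m <= hi)) stop("need min <= mean <= max", call. = FALSE)
  tail <- (1 - level) / 2
  obj <- function(log_alpha) {
    a <- exp(log_alpha)
    b <- a * (1 - m) / m
    # qbeta warns about precision at the grid's extreme shapes; those points
    # never win the search
    suppressWarnings(
      (stats::qbeta(tail, a, b) - lo)^2 + (stats::qbeta(1 - tail, a, b) - hi)^2
    )
  }
  # Coarse log-grid bracket, then scalar minimization; ties broken toward
  # smaller alpha (a weaker prior) by scanning the grid in ascending order.
  grid <- seq(log(1e-4), log(1e6), length.out = 241)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)  # which.min returns the first (smallest-alpha) minimum
  lo_b <- grid[max(1, i - 1)]; hi_b <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, c(lo_b, hi_b), tol = tol)
  a <- exp(opt$minimum)
  b <- a * (1 - m) / m
  achieved <- stats::qbeta(c(tail, 1 - tail), a, b)
  prior <- new_beta_prior(a, b, sprintf("confidence_interval level=%g", level))
  attr(prior, "achieved") <- achieved
  attr(prior, "feasible") <- all(abs(achieved - c(lo, hi)) <= 1e-3)
  prior
}

#' Express vignette-level beta priors as pseudo-data
#'
#' Bridges the elicited probability-scale priors into the logistic
#' regressions: each vignette contributes one weighted pseudo-observation
#' pair at its covariate profile, with `alpha - offset` successes and
#' `beta - offset` failures, so the total prior weight is the sum of the
#' priors' effective sample sizes.
#'
#' @param priors list of `beta_prior` objects.
#' @param profiles list (same length) of named covariate profiles, each a
#'   named list/vector of covariate values matching the model design.
#' @param offset subtracted from both counts (default 0).
#' @return a `pseudo_data` object: data frame `profiles` (one row per
#'   vignette) plus numeric `successes` and `failures`.
#' @export
priors_to_pseudodata <- function(priors, profiles, offset = 0) {
  stopifnot(length(priors) == length(profiles))
  if (length(priors) == 0L) {
    return(structure(list(profiles = NULL, successes = numeric(0),
                          failures = numeric(0)), class = "pseudo_data"))
  }
  nm <- names(profiles[[1]])
  if (is.null(nm)) stop("profiles must be named covariate settings",
                        call. = FALSE)
  rows <- lapply(profiles, function(p) {
    if (!identical(sort(names(p)), sort(nm))) {
      stop("profiles name inconsistent covariates", call. = FALSE)
    }
    as.data.frame(as.list(p))[, nm, drop = FALSE]
  })
  succ <- vapply(priors, function(p) p$alpha - offset, numeric(1))
  fail <- vapply(priors, function(p) p$beta - offset, numeric(1))
  if (any(succ < 0) || any(fail < 0)) {
    stop("offset drives a pseudo-count below zero", call. = FALSE)
  }
  structure(list(profiles = do.call(rbind, rows),
                 successes = succ, failures = fail),
            class = "pseudo_data")
}

#' Total prior weight carried by a pseudo-data object
#' @param pd a `pseudo_data` object.
#' @return sum of pseudo successes and failures.
#' @export
pseudo_weight <- function(pd) {
  stopifnot(inherits(pd, "pseudo_data"))
  sum(pd$successes) + sum(pd$failures)
}

#' Simulate expert survey responses
#'
#' Generates an expert-by-vignette table of probability ratings: the true
#' per-vignette probabilities perturbed on the log-odds scale by centered
#' Gaussian noise, mapped back through the inverse logit (hence inside
#' (0, 1)).
#'
#' @param true_probs named vector of per-vignette true probabilities in (0,1).
#' @param n_experts number of simulated respondents.
#' @param noise_scale standard deviation of the logit-scale perturbation.
#' @param seed integer seed.
#' @param transition label recorded in the `transition` column.
#' @return data frame with columns `expert_id`, `transition`, `vignette_id`,
#'   `probability`.
#' @export
generate_expert_responses <- function(true_probs, n_experts, noise_scale,
                                      seed, transition = "transition") {
  if (any(true_probs <= 0) || any(true_probs >= 1)) {
    stop("true_probs must lie strictly in (0, 1)", call. = FALSE)
  }
  stopifnot(n_experts >= 1, noise_scale >= 0)
  set.seed(as.integer(seed))
  ids <- names(true_probs)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_along(true_probs))
  grid <- expand.grid(expert_id = sprintf("expert%02d", seq_len(n_experts)),
                      vignette_id = ids, stringsAsFactors = FALSE)
  eta <- stats::qlogis(true_probs[grid$vignette_id]) +
    stats::rnorm(nrow(grid), 0, noise_scale)
  data.frame(expert_id = grid$expert_id,
             transition = transition,
             vignette_id = grid$vignette_id,
             probability = unname(stats::plogis(eta)),
             stringsAsFactors = FALSE)
}
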
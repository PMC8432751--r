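# Bayesian logistic regression for the transition probabilities.
#
# The prior enters the likelihood as weighted pseudo-observations (a
# power-prior-style bridge from the elicited vignette-level beta priors),
# so the posterior is proportional to
#   prod_i p_i^{y_i} (1-p_i)^{1-y_i} * prod_s p_s^{a_s} (1-p_s)^{b_s}
# with (a_s, b_s) the pseudo-counts at the vignette covariate profiles.
# Sampling is adaptive random-walk Metropolis: the proposal covariance is
# the inverse Hessian at the weighted-likelihood mode, with Robbins-Monro
# scale adaptation during burn-in only (frozen afterwards, preserving
# detailed balance).

#' Specification of one transition model
#'
#' @param outcome `"referral"`, `"engagement"`, `"drug_death"` or
#'   `"nondrug_death"`.  The engagement model adds the referral flag to the
#'   shared covariate list; the mortality models add the engagement flag and
#'   the 30-day post-discharge naloxone fill.
#' @param covariates covariate names (defaults to the per-outcome list).
#' @param prior `"flat"`, `"kerman"` (a Beta(1/3, 1/3) pseudo-observation at
#'   the covariate-mean row -- Kerman's neutral prior on a probability), or
#'   a `pseudo_data` object from [priors_to_pseudodata()].
#' @return a `transition_model_spec`.
#' @export
transition_model_spec <- function(outcome = c("referral", "engagement",
                                              "drug_death", "nondrug_death"),
                                  covariates = NULL,
                                  prior = "flat") {
  outcome <- match.arg(outcome)
  if (is.null(covariates)) {
    covariates <- switch(outcome,
      referral = COVARIATE_NAMES,
      engagement = c(COVARIATE_NAMES, "referral"),
      c(COVARIATE_NAMES, "engagement", "naloxone_fill_30d"))
  }
  if (!(identical(prior, "flat") || identical(prior, "kerman") ||
        inherits(prior, "pseudo_data"))) {
    stop("prior must be 'flat', 'kerman' or a pseudo_data object",
         call. = FALSE)
  }
  structure(list(outcome = outcome, covariates = covariates, prior = prior),
            class = "transition_model_spec")
}

# outcome column (0/1) from an analysis table
outcome_vector <- function(table, outcome) {
  y <- switch(outcome,
    referral = table$referral,
    engagement = table$engagement,
    drug_death = as.integer(table$death_category == "drug"),
    nondrug_death = as.integer(table$death_category == "non_drug"))
  if (is.null(y)) stop("schema error: table lacks the '", outcome,
                       "' outcome source column", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("schema error: outcome is not binary",
                                   call. = FALSE)
  y
}

# intercept + named covariate columns -> design matrix
build_design <- function(table, covariates) {
  miss <- setdiff(covariates, names(table))
  if (length(miss)) stop("schema error: missing covariate column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind("(Intercept)" = 1,
             as.matrix(as.data.frame(table)[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

# pseudo-data design rows and weights for a model spec
prior_rows <- function(spec, X) {
  p <- spec$prior
  if (identical(p, "flat")) {
    return(list(X = X[0, , drop = FALSE], a = numeric(0), b = numeric(0)))
  }
  if (identical(p, "kerman")) {
    xm <- matrix(colMeans(X), nrow = 1,
                 dimnames = list(NULL, colnames(X)))
    return(list(X = xm, a = 1 / 3, b = 1 / 3))
  }
  if (length(p$successes) == 0L) {
    return(list(X = X[0, , drop = FALSE], a = numeric(0), b = numeric(0)))
  }
  miss <- setdiff(colnames(X)[-1], names(p$profiles))
  if (length(miss)) {
    stop("schema error: pseudo-data profiles lack covariate(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  Xs <- cbind("(Intercept)" = 1,
              as.matrix(p$profiles[, colnames(X)[-1], drop = FALSE]))
  storage.mode(Xs) <- "double"
  list(X = Xs, a = p$successes, b = p$failures)
}

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Classical (maximum-likelihood) logistic regression
#'
#' The frequentist analogue of each transition model, used as an
#' internal-validity oracle for the flat-prior Bayesian fits.
#'
#' @param table an analysis table (or any data frame with the needed
#'   columns).
#' @param spec a [transition_model_spec()] (its prior is ignored).
#' @return list with `coefficients`, `se`, `vcov`, `converged`, `n`.
#' @export
fit_classical_logistic <- function(table, spec) {
  y <- outcome_vector(table, spec$outcome)
  X <- build_design(table, spec$covariates)
  cc <- stats::complete.cases(X)
  fit <- suppressWarnings(
    stats::glm.fit(X[cc, , drop = FALSE], y[cc],
                   family = stats::binomial()))
  if (!fit$converged) warning("classical logistic fit did not converge ",
                              "(possible separation)", call. = FALSE)
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  H <- crossprod(X[cc, , drop = FALSE] * sqrt(W))
  V <- tryCatch(solve(H), error = function(e) matrix(NA, ncol(X), ncol(X)))
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       se = stats::setNames(sqrt(diag(V)), colnames(X)),
       vcov = V, converged = fit$converged, n = sum(cc))
}

#' MCMC settings
#'
#' @param n_draws total retained posterior draws across chains (default
#'   10,000, split evenly).
#' @param n_burnin burn-in iterations discarded per chain (default 2,000).
#' @param n_chains number of chains (default 4).
#' @param seed integer seed.
#' @return an `mcmc_config`.
#' @export
mcmc_config <- function(n_draws = 10000L, n_burnin = 2000L, n_chains = 4L,
                        seed = 1L) {
  stopifnot(n_draws > 0, n_burnin >= 0, n_chains >= 1)
  structure(list(n_draws = as.integer(n_draws),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit a Bayesian logistic regression for one transition
#'
#' Runs adaptive random-walk Metropolis on the pseudo-data-weighted
#' log-likelihood.  Rows with missing covariates are dropped with a message
#' recording the count.  With a flat prior and complete separation the mode
#' finder's non-convergence is surfaced as a warning and flagged in the
#' diagnostics.
#'
#' @param table analysis table with the outcome source and covariates.
#' @param spec a [transition_model_spec()].
#' @param mcmc an [mcmc_config()].
#' @param pointwise_loglik keep the draws-by-observations log-likelihood
#'   matrix needed for PSIS-LOO (default TRUE; disable for large runs).
#' @return a `posterior_fit`: `draws` (matrix, retained draws by
#'   parameters), `chain` (chain index per draw), `draws_array`
#'   (iterations x chains x parameters), `mode`, `accept_rate`, `loglik`
#'   (pointwise matrix or NULL), `spec`, `mcmc`, `n`, `n_dropped`,
#'   `separation_flag`.
#' @export
fit_bayes_logistic <- function(table, spec, mcmc = mcmc_config(),
                               pointwise_loglik = TRUE) {
  stopifnot(inherits(spec, "transition_model_spec"),
            inherits(mcmc, "mcmc_config"))
  y <- outcome_vector(table, spec$outcome)
  X <- build_design(table, spec$covariates)
  cc <- stats::complete.cases(X) & !is.na(y)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing covariates dropped")
  }
  X <- X[cc, , drop = FALSE]; y <- y[cc]
  pr <- prior_rows(spec, X)
  p <- ncol(X)

  # weighted-likelihood mode and Hessian via IRLS
  Xw <- rbind(X, pr$X, pr$X)
  yw <- c(y, rep(1, length(pr$a)), rep(0, length(pr$b)))
  ww <- c(rep(1, length(y)), pr$a, pr$b)
  keep <- ww > 0
  mode_fit <- suppressWarnings(
    stats::glm.fit(Xw[keep, , drop = FALSE], yw[keep],
                   weights = ww[keep], family = stats::binomial()))
  separation <- !mode_fit$converged ||
    any(abs(mode_fit$coefficients) > 15)
  if (separation && identical(spec$prior, "flat")) {
    warning("possible complete separation under a flat prior; posterior ",
            "may be improper", call. = FALSE)
  }
  mode <- mode_fit$coefficients
  mode[is.na(mode)] <- 0
  eta_m <- drop(Xw %*% mode)
  Wm <- ww * stats::plogis(eta_m) * (1 - stats::plogis(eta_m))
  H <- crossprod(Xw * sqrt(pmax(Wm, 1e-10)))
  Sigma <- tryCatch(solve(H), error = function(e) diag(1e-2, p))
  L <- tryCatch(t(chol(Sigma)), error = function(e) diag(sqrt(diag(Sigma))))

  log_post <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1pexp(eta))
    if (length(pr$a)) {
      eta_s <- drop(pr$X %*% beta)
      ll <- ll + sum(pr$a * eta_s - (pr$a + pr$b) * log1pexp(eta_s))
    }
    ll
  }

  n_chains <- mcmc$n_chains
  keep_per <- ceiling(mcmc$n_draws / n_chains)
  set.seed(mcmc$seed)
  draws_array <- array(NA_real_, c(keep_per, n_chains, p),
                       dimnames = list(NULL, NULL, colnames(X)))
  acc_total <- 0L
  for (ch in seq_len(n_chains)) {
    beta <- mode + drop(L %*% stats::rnorm(p)) * 2   # overdispersed start
    lp <- log_post(beta)
    log_scale <- log(2.38 / sqrt(p))
    n_iter <- mcmc$n_burnin + keep_per
    for (it in seq_len(n_iter)) {
      prop <- beta + exp(log_scale) * drop(L %*% stats::rnorm(p))
      lp_prop <- log_post(prop)
      acc <- log(stats::runif(1)) < lp_prop - lp
      if (acc) { beta <- prop; lp <- lp_prop }
      if (it <= mcmc$n_burnin) {
        log_scale <- log_scale +
          (as.numeric(acc) - 0.234) / sqrt(it)       # Robbins-Monro
      } else {
        draws_array[it - mcmc$n_burnin, ch, ] <- beta
        acc_total <- acc_total + as.integer(acc)
      }
    }
  }
  chain <- rep(seq_len(n_chains), each = keep_per)
  draws <- do.call(rbind, lapply(seq_len(n_chains), function(ch) {
    matrix(draws_array[, ch, ], ncol = p,
           dimnames = list(NULL, colnames(X)))
  }))

  ll_mat <- NULL
  if (pointwise_loglik) {
    ll_mat <- matrix(NA_real_, nrow(draws), nrow(X))
    block <- 500L
    for (s0 in seq(1L, nrow(draws), by = block)) {
      s1 <- min(s0 + block - 1L, nrow(draws))
      eta <- draws[s0:s1, , drop = FALSE] %*% t(X)
      ll_mat[s0:s1, ] <- sweep(eta, 2, y, "*") - log1pexp(eta)
    }
  }

  structure(list(draws = draws, chain = chain, draws_array = draws_array,
                 mode = stats::setNames(mode, colnames(X)),
                 accept_rate = acc_total / (keep_per * n_chains),
                 loglik = ll_mat, spec = spec, mcmc = mcmc,
                 n = length(y), n_dropped = n_dropped,
                 separation_flag = separation),
            class = "posterior_fit")
}

#' Marginal transition probability over observed cases
#'
#' For each posterior draw, averages the inverse-logit linear predictor over
#' the observed covariate rows (optionally with one covariate set to a fixed
#' value for every row -- the observed-case analogue of a stratum-specific
#' probability), then summarizes the draws by their mean and central 95%
#' interval.
#'
#' @param fit a `posterior_fit`.
#' @param table the analysis table whose rows define the observed cases.
#' @param covariate optional covariate name to pin.
#' @param value value the pinned covariate takes (for binary covariates must
#'   be 0 or 1).
#' @return list `point`, `lower`, `upper`, plus the per-draw means as
#'   `draws`.
#' @export
marginal_prob_observed <- function(fit, table, covariate = NULL,
                                   value = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  X <- build_design(table, fit$spec$covariates)
  if (!is.null(covariate)) {
    if (!covariate %in% fit$spec$covariates) {
      stop("covariate '", covariate, "' is not in the model", call. = FALSE)
    }
    col <- X[, covariate]
    if (all(col %in% c(0, 1)) && !value %in% c(0, 1)) {
      stop("domain error: '", covariate, "' is binary; value must be 0 or 1",
           call. = FALSE)
    }
    X[, covariate] <- value
  }
  S <- nrow(fit$draws)
  means <- numeric(S)
  block <- 500L
  for (s0 in seq(1L, S, by = block)) {
    s1 <- min(s0 + block - 1L, S)
    eta <- fit$draws[s0:s1, , drop = FALSE] %*% t(X)
    means[s0:s1] <- rowMeans(stats::plogis(eta))
  }
  q <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  list(point = mean(means), lower = q[1], upper = q[2], draws = means)
}

#' Marginal probabilities as a (point, lower, upper) triple
#'
#' Convenience wrapper turning [marginal_prob_observed()] output into the
#' `c(point, lower, upper)` triple format used by
#' [transition_probabilities()].
#'
#' @inheritParams marginal_prob_observed
#' @return numeric length-3 vector.
#' @export
marginal_triple <- function(fit, table, covariate = NULL, value = NULL) {
  m <- marginal_prob_observed(fit, table, covariate, value)
  c(point = m$point, lower = m$lower, upper = m$upper)
}
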
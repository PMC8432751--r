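# Bayesian logistic transitions: classical oracle, sampler behavior,
# priors, diagnostics, marginal probabilities.

test_that("classical fit matches closed forms", {
  # intercept-only: prevalence 0.25
  d <- data.frame(referral = rep(c(1, 0), c(25, 75)))
  cl <- fit_classical_logistic(d, transition_model_spec("referral",
                                                        covariates = character(0)))
  expect_equal(unname(cl$coefficients[1]), qlogis(0.25), tolerance = 1e-6)
  # single binary covariate from a 2x2 table: slope = log odds ratio
  d2 <- data.frame(
    x1 = rep(c(0, 1), each = 100),
    referral = c(rep(c(1, 0), c(20, 80)), rep(c(1, 0), c(40, 60))))
  cl2 <- fit_classical_logistic(d2, transition_model_spec("referral",
                                                          covariates = "x1"))
  expect_equal(unname(cl2$coefficients["x1"]),
               log((40 / 60) / (20 / 80)), tolerance = 1e-6)
  # balanced null covariate: slope within 3 SE of zero
  set.seed(2)
  d3 <- data.frame(x1 = rep(0:1, 500), referral = rbinom(1000, 1, 0.3))
  cl3 <- fit_classical_logistic(d3, transition_model_spec("referral",
                                                          covariates = "x1"))
  expect_lt(abs(cl3$coefficients["x1"]), 3 * cl3$se["x1"])
})

test_that("flat-prior posterior agrees with maximum likelihood", {
  d <- make_logistic_table(3000, seed = 10)
  spec <- transition_model_spec("referral", covariates = c("x1", "x2"))
  fit <- fit_bayes_logistic(d, spec, quick_mcmc(seed = 3, n_draws = 4000),
                            pointwise_loglik = FALSE)
  cl <- fit_classical_logistic(d, spec)
  dg <- diagnose(fit, ess_min = 100)
  for (j in seq_along(cl$coefficients)) {
    mcse <- sd(fit$draws[, j]) / sqrt(dg$ess[j])
    expect_lt(abs(mean(fit$draws[, j]) - cl$coefficients[j]), 3 * mcse + 1e-3)
  }
})

test_that("zero-weight pseudo-data prior equals the flat-prior fit", {
  d <- make_logistic_table(800, seed = 11)
  pd0 <- priors_to_pseudodata(list(), list())
  spec_f <- transition_model_spec("referral", covariates = c("x1", "x2"))
  spec_0 <- transition_model_spec("referral", covariates = c("x1", "x2"),
                                  prior = pd0)
  f1 <- fit_bayes_logistic(d, spec_f, quick_mcmc(seed = 5),
                           pointwise_loglik = FALSE)
  f2 <- fit_bayes_logistic(d, spec_0, quick_mcmc(seed = 5),
                           pointwise_loglik = FALSE)
  expect_identical(f1$draws, f2$draws)   # same seed, same likelihood
})

test_that("same data, spec and seed give identical draws", {
  d <- make_logistic_table(400, seed = 12)
  spec <- transition_model_spec("referral", covariates = c("x1", "x2"))
  f1 <- fit_bayes_logistic(d, spec, quick_mcmc(seed = 9))
  f2 <- fit_bayes_logistic(d, spec, quick_mcmc(seed = 9))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("kerman prior behaves near-flat on moderate data", {
  d <- make_logistic_table(2000, seed = 13)
  spec_k <- transition_model_spec("referral", covariates = c("x1", "x2"),
                                  prior = "kerman")
  fit <- fit_bayes_logistic(d, spec_k, quick_mcmc(seed = 6, n_draws = 3000),
                            pointwise_loglik = FALSE)
  cl <- fit_classical_logistic(d, spec_k)
  dg <- diagnose(fit, ess_min = 100)
  for (j in seq_along(cl$coefficients)) {
    mcse <- sd(fit$draws[, j]) / sqrt(dg$ess[j])
    expect_lt(abs(mean(fit$draws[, j]) - cl$coefficients[j]),
              3 * mcse + 0.05)
  }
})

test_that("informative pseudo-data pulls the marginal toward the prior mean", {
  # data marginal ~0.2, prior mean 0.8: posterior marginal increases
  # monotonically through the sample-size strength grid
  set.seed(21)
  n <- 5000
  d <- data.frame(x1 = rbinom(n, 1, 0.5))
  d$referral <- rbinom(n, 1, plogis(qlogis(0.2) + 0 * d$x1))
  marg <- vapply(c(0.001, 0.01, 0.05, 0.10), function(f) {
    bp <- fit_beta_samplesize(list(mean = 0.8), f, n)
    pd <- priors_to_pseudodata(list(bp), list(c(x1 = 0.5)))
    spec <- transition_model_spec("referral", covariates = "x1", prior = pd)
    fit <- fit_bayes_logistic(d, spec,
                              quick_mcmc(seed = 7, n_draws = 6000,
                                         n_chains = 4),
                              pointwise_loglik = FALSE)
    marginal_prob_observed(fit, d)$point
  }, numeric(1))
  expect_true(all(diff(marg) > 0))
  expect_true(all(marg > 0.19 & marg < 0.8))
})

test_that("non-binary outcomes raise a schema error", {
  d <- data.frame(x1 = 1:5, referral = c(0, 1, 2, 0, 1))
  expect_error(fit_bayes_logistic(d, transition_model_spec("referral",
                                                           covariates = "x1")),
               "binary")
})

test_that("default covariate lists follow the per-model definitions", {
  expect_false("referral" %in% transition_model_spec("referral")$covariates)
  expect_true("referral" %in% transition_model_spec("engagement")$covariates)
  mort <- transition_model_spec("drug_death")$covariates
  expect_true(all(c("engagement", "naloxone_fill_30d") %in% mort))
})

test_that("split R-hat and ESS behave on constructed chains", {
  set.seed(8)
  S <- 2000; k <- 4
  # i.i.d. normal chains: R-hat ~ 1, ESS ~ total draws
  arr <- array(rnorm(S * k), c(S, k, 1), dimnames = list(NULL, NULL, "b"))
  dg <- diagnose(arr, ess_min = 100)
  expect_lt(abs(dg$rhat - 1), 0.01)
  expect_gt(dg$ess, 0.5 * S * k)
  expect_lt(dg$ess, 1.5 * S * k)
  expect_lt(abs(dg$acf_lag1), 0.05)
  # chains centered at different means: R-hat well above 1.1
  arr2 <- array(c(rnorm(S, 0), rnorm(S, 3)), c(S, 2, 1),
                dimnames = list(NULL, NULL, "b"))
  dg2 <- diagnose(arr2)
  expect_gt(dg2$rhat, 1.1)
  expect_false(dg2$pass)
  # single chain allowed, with a note
  expect_message(diagnose(array(rnorm(S), c(S, 1, 1))), "single chain")
})

test_that("marginal probabilities match an enumeration oracle", {
  # 2-row table, 2 hand-specified draws: average the four inverse logits
  d <- data.frame(x1 = c(0, 1), referral = c(0, 1))  # separable by design
  spec <- transition_model_spec("referral", covariates = "x1")
  fit <- suppressWarnings(
    fit_bayes_logistic(d, spec, quick_mcmc(seed = 1, n_draws = 10,
                                           n_burnin = 10)))
  expect_true(fit$separation_flag)
  fit$draws <- matrix(c(0.0, 1.0,
                        0.5, -1.0), nrow = 2, byrow = TRUE,
                      dimnames = list(NULL, c("(Intercept)", "x1")))
  m <- marginal_prob_observed(fit, d)
  by_hand <- c(mean(plogis(c(0 + 0, 0 + 1))),
               mean(plogis(c(0.5 + 0, 0.5 - 1))))
  expect_equal(m$draws, by_hand)
  expect_equal(m$point, mean(by_hand))
  # all draws at intercept 0, slope 0: point 0.5, degenerate interval
  fit$draws <- matrix(0, 2, 2,
                      dimnames = list(NULL, c("(Intercept)", "x1")))
  m0 <- marginal_prob_observed(fit, d)
  expect_equal(c(m0$point, m0$lower, m0$upper), c(0.5, 0.5, 0.5))
  # null-effect invariance: zero slope draws make the pinned value moot
  expect_equal(marginal_prob_observed(fit, d, "x1", 0)$point,
               marginal_prob_observed(fit, d, "x1", 1)$point)
  # binary covariate domain is enforced
  expect_error(marginal_prob_observed(fit, d, "x1", 2), "domain")
  expect_error(marginal_prob_observed(fit, d, "nope", 1), "not in the model")
})
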
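# Shared fixtures: small simulated regression tables and MCMC settings
# sized for test runtimes.

# simple two-covariate logistic table with known truth
make_logistic_table <- function(n, beta = c(`(Intercept)` = -1, x1 = 0.8,
                                            x2 = -0.5),
                                outcome = "referral", seed = 1) {
  set.seed(seed)
  d <- data.frame(x1 = stats::rbinom(n, 1, 0.4), x2 = stats::rnorm(n))
  eta <- beta[["(Intercept)"]] + beta[["x1"]] * d$x1 + beta[["x2"]] * d$x2
  d[[outcome]] <- stats::rbinom(n, 1, stats::plogis(eta))
  d
}

quick_mcmc <- function(seed = 1, n_draws = 2000L, n_burnin = 400L,
                       n_chains = 2L) {
  mcmc_config(n_draws = n_draws, n_burnin = n_burnin, n_chains = n_chains,
              seed = seed)
}

# one-patient fill table
fills_of <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = "P1", drug_class = r[[1]],
               fill_date = as.integer(r[[2]]),
               days_supply = as.integer(r[[3]]), stringsAsFactors = FALSE)
  }))
}

no_fills <- data.frame(patient_id = character(), drug_class = character(),
                       fill_date = integer(), days_supply = integer(),
                       stringsAsFactors = FALSE)

# Random transition-probability set from the model's clinical domain:
# referral raises engagement (componentwise across point/lower/upper) and
# engagement is protective against both death causes.  The deterministic
# Low/High scenario algebra bounds the projections only on this domain.
random_transitions <- function() {
  sorted3 <- function(lo = 0, hi = 1) {
    x <- sort(stats::runif(3, lo, hi))
    c(x[2], x[1], x[3])                       # (point, lower, upper)
  }
  en <- sorted3(0, 0.6)
  er <- pmin(en + sorted3(0, 0.3), 1)
  de <- sorted3(0, 0.2)
  dne <- pmin(de + sorted3(0, 0.2), 0.45)
  nde <- sorted3(0, 0.2)
  ndne <- pmin(nde + sorted3(0, 0.2), 0.45)
  transition_probabilities(
    referral = sorted3(0, 0.5),
    engage_referred = er, engage_not_referred = en,
    drug_death_engaged = de, drug_death_not_engaged = dne,
    nondrug_death_engaged = nde, nondrug_death_not_engaged = ndne
  )
}

# direct beta-prior constructor for pseudo-data tests
new_beta_prior_test <- function(a, b) {
  acsmarkov:::new_beta_prior(a, b, "test")
}
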
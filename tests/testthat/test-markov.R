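# Single-cycle Markov algebra: engaged fractions, cohort projections,
# external projections, microsimulation oracle.

test_that("transition probability triples are validated", {
  expect_error(transition_probabilities(
    referral = c(0.5, 0.6, 0.7), engage_referred = c(0.5, 0.4, 0.6),
    engage_not_referred = c(0.2, 0.1, 0.3),
    drug_death_engaged = c(0.1, 0, 0.2),
    drug_death_not_engaged = c(0.1, 0, 0.2),
    nondrug_death_engaged = c(0.1, 0, 0.2),
    nondrug_death_not_engaged = c(0.1, 0, 0.2)),
    "lower <= point <= upper")
  expect_error(transition_probabilities(
    referral = c(0.5, 0.4, 0.6), engage_referred = c(0.5, 0.4, 0.6),
    engage_not_referred = c(0.2, 0.1, 0.3),
    drug_death_engaged = c(0.6, 0, 0.7),
    drug_death_not_engaged = c(0.1, 0, 0.2),
    nondrug_death_engaged = c(0.6, 0, 0.7),
    nondrug_death_not_engaged = c(0.1, 0, 0.2)),
    "exceed 1")
})

test_that("engaged fraction follows the two-branch algebra", {
  p <- oregon_transitions()
  expect_equal(engaged_fraction(p, "combined"),
               0.04 * 0.47 + 0.96 * 0.20)  # 0.2108
  expect_equal(engaged_fraction(p, "not_referred_only"), 0.20)
  # degenerate referral branch: p_ref = 0 collapses to the not-referred arm
  p0 <- transition_probabilities(
    referral = c(0, 0, 0), engage_referred = c(0.9, 0.8, 1),
    engage_not_referred = c(0.2, 0.1, 0.3),
    drug_death_engaged = c(0.1, 0, 0.2),
    drug_death_not_engaged = c(0.1, 0, 0.2),
    nondrug_death_engaged = c(0.1, 0, 0.2),
    nondrug_death_not_engaged = c(0.1, 0, 0.2))
  expect_equal(engaged_fraction(p0, "combined"), 0.2)
})

test_that("cohort projection reproduces published internal-validity counts", {
  pr <- project_cohort(6654, oregon_transitions())
  expect_equal(unname(pr$expected_engaged),        c(1330.8, 1064.6, 1597.0))
  expect_equal(unname(pr$expected_drug_deaths),    c(357.2, 98.5, 632.6))
  expect_equal(unname(pr$expected_nondrug_deaths), c(570.8, 263.6, 865.0))
  expect_equal(pr$expected_total_deaths[["point"]], 928.0)
  expect_equal(unname(pr$death_percent),           c(13.9, 5.4, 22.5))
})

test_that("zero mortality conserves the cohort", {
  p <- transition_probabilities(
    referral = c(0.04, 0.02, 0.06), engage_referred = c(0.47, 0.37, 0.57),
    engage_not_referred = c(0.20, 0.16, 0.24),
    drug_death_engaged = c(0, 0, 0), drug_death_not_engaged = c(0, 0, 0),
    nondrug_death_engaged = c(0, 0, 0),
    nondrug_death_not_engaged = c(0, 0, 0))
  pr <- project_cohort(1000, p)
  expect_equal(pr$expected_total_deaths[["point"]], 0)
  expect_equal(pr$survivors, 1000)
})

test_that("external projections reproduce published comparisons", {
  p <- oregon_transitions()
  expect_equal(project_external(36719, p, "count_engaged"),
               c(point = 7343.8, low = 5875, high = 8812))
  expect_equal(project_external(24340, p, "count_all_deaths"),
               c(point = 3394, low = 1324, high = 5478))
  expect_equal(project_external(6654, p, "rate_nondrug_per100py")[["point"]],
               8.6)
  expect_equal(project_external(6654, p, "rate_drug_per100py")[["point"]],
               5.4)
  expect_error(project_external(100, p, "count_engaged",
                                rounding = "nonsense"))
})

test_that("projection invariants hold over random probability sets", {
  set.seed(20250921)
  for (i in 1:250) {
    p <- random_transitions()
    pr <- project_cohort(5000, p)
    # bound ordering for every reported quantity
    for (q in list(pr$expected_engaged, pr$expected_drug_deaths,
                   pr$expected_nondrug_deaths, pr$expected_total_deaths,
                   pr$death_percent)) {
      expect_lte(q[["low"]], q[["point"]] + 1e-9)
      expect_lte(q[["point"]], q[["high"]] + 1e-9)
    }
    # additivity at the point estimate (up to the one-decimal reporting)
    expect_equal(pr$expected_total_deaths[["point"]],
                 round(pr$expected_drug_deaths[["point"]] +
                         pr$expected_nondrug_deaths[["point"]], 1),
                 tolerance = 0.11)
    expect_equal(pr$survivors + pr$expected_total_deaths[["point"]], 5000,
                 tolerance = 0.11)
  }
})

test_that("death-probability monotonicity: larger risk, more expected deaths", {
  base <- oregon_transitions()
  bumped <- unclass(base)
  bumped$drug_death_not_engaged <- c(0.08, 0.02, 0.10)
  bumped <- do.call(transition_probabilities,
                    lapply(bumped, function(x) unname(x)))
  expect_gt(project_cohort(6654, bumped)$expected_drug_deaths[["point"]],
            project_cohort(6654, base)$expected_drug_deaths[["point"]])
})

test_that("microsimulation is seeded and matches closed form", {
  p <- oregon_transitions()
  expect_identical(microsim_oracle(500, p, seed = 11),
                   microsim_oracle(500, p, seed = 11))
  # degenerate chain: everyone referred, engaged, survives
  pd <- transition_probabilities(
    referral = c(1, 1, 1), engage_referred = c(1, 1, 1),
    engage_not_referred = c(0, 0, 0),
    drug_death_engaged = c(0, 0, 0), drug_death_not_engaged = c(0, 0, 0),
    nondrug_death_engaged = c(0, 0, 0),
    nondrug_death_not_engaged = c(0, 0, 0))
  cnt <- microsim_oracle(123, pd, seed = 1)
  expect_equal(unname(cnt[c("referred", "engaged", "survivors")]),
               c(123, 123, 123))
  expect_equal(unname(cnt[c("drug_deaths", "nondrug_deaths")]), c(0, 0))
})

test_that("transition probabilities round-trip through JSON and YAML", {
  p <- oregon_transitions()
  for (ext in c("json", "yaml")) {
    f <- file.path(tempdir(), paste0("tp.", ext))
    write_transitions(p, f)
    q <- read_transitions(f)
    expect_equal(q, p)
  }
})
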
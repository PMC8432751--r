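#!/usr/bin/env Rscript
# Step 5: cohort projections and validation simulations.
#
# Internal validity: projects the 6,654-patient mortality cohort through
# the published transition probabilities, reporting expected engagement and
# 12-month deaths with deterministic Low/High scenario bounds, and
# cross-checks the closed-form expectations against an individual-level
# microsimulation.  External validity: applies the model to the published
# external cohort sizes.  Finally projects the synthetic cohort with the
# transition probabilities fitted in step 4 and compares against the
# cohort's observed outcome counts.

suppressPackageStartupMessages({
  library(acsmarkov)
  library(jsonlite)
})

published <- oregon_transitions()

cat("=== Internal validity: published transition probabilities ===\n")
proj <- project_cohort(6654, published)
print(proj)

cat("\nMicrosimulation cross-check (n = 100,000, point probabilities):\n")
ms <- microsim_oracle(100000, published, seed = 31415)
f <- engaged_fraction(published, "combined")
cat(sprintf("  engaged:  %d sampled vs %.0f expected\n", ms[["engaged"]],
            1e5 * f))
cat(sprintf("  drug deaths: %d vs %.0f;  non-drug: %d vs %.0f\n",
            ms[["drug_deaths"]], 1e5 * (f * 0.03 + (1 - f) * 0.06),
            ms[["nondrug_deaths"]], 1e5 * (f * 0.07 + (1 - f) * 0.09)))

cat("\n=== External validity: published comparison cohorts ===\n")
ext <- list(
  engaged_36719 = project_external(36719, published, "count_engaged"),
  all_deaths_24340 = project_external(24340, published, "count_all_deaths"),
  drug_rate_6654 = project_external(6654, published, "rate_drug_per100py"),
  nondrug_rate_6654 = project_external(6654, published,
                                       "rate_nondrug_per100py")
)
cat(sprintf("  engaged of 36,719:        %.1f (%d, %d)\n",
            ext$engaged_36719[["point"]], ext$engaged_36719[["low"]],
            ext$engaged_36719[["high"]]))
cat(sprintf("  all-cause deaths of 24,340: %d (%d, %d)\n",
            ext$all_deaths_24340[["point"]], ext$all_deaths_24340[["low"]],
            ext$all_deaths_24340[["high"]]))
cat(sprintf("  per 100 person-years (n=6,654): drug %.1f (%.1f, %.1f), ",
            ext$drug_rate_6654[["point"]], ext$drug_rate_6654[["low"]],
            ext$drug_rate_6654[["high"]]))
cat(sprintf("non-drug %.1f (%.1f, %.1f)\n",
            ext$nondrug_rate_6654[["point"]], ext$nondrug_rate_6654[["low"]],
            ext$nondrug_rate_6654[["high"]]))

cat("\n=== Synthetic cohort: fitted transition probabilities ===\n")
fitted <- read_transitions("results/transitions_fitted.json")
at <- read_analysis_table("results/analysis_table.tsv")
mort_n <- sum(at$mortality_cohort)
proj_fit <- project_cohort(mort_n, fitted)
print(proj_fit)
obs <- at[at$mortality_cohort, ]
cat(sprintf("Observed in the synthetic mortality cohort: %d engaged, %d drug deaths, %d non-drug deaths\n",
            sum(obs$engagement), sum(obs$death_category == "drug"),
            sum(obs$death_category == "non_drug")))

results <- list(
  internal_published = unclass(proj)[c("expected_engaged",
                                       "expected_drug_deaths",
                                       "expected_nondrug_deaths",
                                       "expected_total_deaths",
                                       "death_percent")],
  external_published = ext,
  microsim_100k = as.list(ms),
  synthetic_fitted = unclass(proj_fit)[c("cohort_n", "expected_engaged",
                                         "expected_drug_deaths",
                                         "expected_nondrug_deaths")],
  synthetic_observed = list(engaged = sum(obs$engagement),
                            drug = sum(obs$death_category == "drug"),
                            non_drug = sum(obs$death_category == "non_drug"))
)
write_json(results, "results/projections.json", digits = NA, pretty = TRUE)
cat("\nWrote results/projections.json\n")
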
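---
title: "Methods: a Markov model of addiction consult service care and 12-month mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov model of addiction consult service care and 12-month mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsmarkov)
```

## The model

Hospitalization is a high-risk moment for people with opioid use disorder
(OUD).  Addiction consult services (ACS) — interprofessional hospital teams
that start medications for OUD (MOUD) and link patients to outpatient care —
plausibly reduce post-discharge mortality, but drug-related death is too
rare and too distal for hospital-level trials to measure directly.
`acsmarkov` implements a single-cycle Markov (decision-tree) model of the
care trajectory: a hospitalized patient with OUD is referred to an ACS or
not, then engages in post-discharge OUD treatment or not, and over the
following 12 months dies of a drug-related cause, dies of a non-drug-related
cause, or survives.  All states at 12 months are absorbing and no transition
recurs, so the chain needs exactly one cycle; no time-step iteration is
implemented.

Five branch probabilities parameterize the chain: `referral`;
`engage_referred` / `engage_not_referred`; and cause-specific 12-month death
probabilities in each engagement stratum.  Each is carried as a
`(point, lower, upper)` triple; `oregon_transitions()` bundles the published
Oregon Medicaid estimates (referral 4% [2, 6]; engagement 47% [37, 57]
referred vs 20% [16, 24] not; drug-related death 3% [0, 7] engaged vs 6%
[2, 10]; non-drug death 7% [1, 13] vs 9% [5, 13]).

### Projection algebra and its two engagement conventions

The expected engaged count for a cohort of size $N$ uses the not-referred
engagement probability alone ($N \times p_{eng|\neg ref}$), while expected
deaths mix the strata through the combined two-branch engaged fraction

$$f = p_{ref}\,p_{eng|ref} + (1-p_{ref})\,p_{eng|\neg ref},$$

giving $N [f\,p_{death|eng} + (1-f)\,p_{death|\neg eng}]$ per cause.  These
two conventions coexist deliberately: the published internal-validity counts
(1,330.8 engaged of 6,654, but 357.2 drug and 570.8 non-drug deaths) are
reproducible only with the engaged count on the not-referred convention and
the death counts on the combined convention ($f = 0.2108$ at the point
estimates).  Both are exposed through `engaged_fraction()`'s `convention`
argument rather than silently resolved.

### Low/High bound scenarios

Uncertainty is propagated by deterministic bound combinations, not by
probabilistic sensitivity analysis: the **High-death** scenario takes
referral and engagement at their lower interval bounds and mortality at its
upper bounds; **Low-death** is the mirror image.  The engaged-count bounds
come directly from the engagement interval.  This algebra bounds the
projection *provided* referral raises engagement and engagement is
protective (componentwise across the point/lower/upper levels):
writing risk $= p_{\neg eng} - f\,(p_{\neg eng} - p_{eng})$, the High
scenario lowers $f$ and raises both stratum risks, hence raises the
mixture, and symmetrically for Low.  Outside that clinically-motivated
domain (e.g. an intervention that *reduces* engagement) the combination is
not a bound, so the package's property tests draw probability sets from the
protective domain; `project_cohort()` itself does not restrict its inputs.

### Rounding conventions

Oregon-cohort expected counts are reported to one decimal.  External-cohort
integer counts are truncated toward zero (5875.04 → 5875, 8812.56 → 8812,
3394.46 → 3394, 1324.4 → 1324, 5478.3 → 5478 — truncation is the only rule
that reproduces every published external bound simultaneously); external
point counts keep one decimal where published that way (7,343.8).
Twelve-month risks are converted to rates per 100 person-years by treating
each cohort member as one person-year, reported to one decimal.
Probabilities always enter the algebra at full precision; nothing is rounded
upstream of the final report.  One published pair of rate bounds (1.5 and
4.0 per 100 person-years for non-drug vs opioid deaths) appears transposed
relative to this algebra; the package reports the model-consistent bounds
(non-drug 4.0–13.0, drug 1.5–9.5) and does not force the transposition.

## Claims-style measures

* **Eligibility** (`select_eligible()`): adults (≥18) with an ICD-9 `304*`
  or ICD-10 `F11*` diagnosis on an admission inside the study window
  (day offsets from 2015-04-01, window through day 1248 = 2018-08-31).  The
  index admission is the first eligible one per patient; patients admitted
  on or before day 1006 (2018-01-01) form the 12-month-mortality cohort.
* **Engagement** (`classify_engagement()`): a modified HEDIS rule over days
  1..30 after discharge (the discharge day itself is day 0 and excluded,
  a convention the source text leaves open): (a) ≥2 fills of buprenorphine,
  XR-naltrexone, or methadone from an opioid treatment program; or (b)
  buprenorphine/XR-naltrexone supply covering ≥28 of the 30 days, computed
  as the per-fill overlap with the window summed across fills and capped at
  30.  Methadone counts only toward clause (a).
* **Death classification** (`classify_death()`): `none` unless death occurs
  within 365 days of index discharge; otherwise `drug` when the
  underlying-cause code starts with one of the configured prefixes
  (default X40–X44, X60–X64, X85, Y10–Y14 — accidental, intentional,
  assault and undetermined poisoning), else `non_drug`.  The published
  analysis manually reviewed uncaptured deaths; that step is expressed here
  as a per-patient override table in the `cause_map()`, which takes
  precedence over the code mapping.
* **Matching** (`match_controls()`): each referred case receives up to 3
  non-referred controls with identical admission quarter and admission
  number, without replacement.  Tie-breaks are deterministic (cases in
  ascending admission date; controls in ascending admission date then
  patient id) so a matched cohort is exactly reproducible from the same
  tables.

## Expert-elicitation priors

Experts rated event probabilities for clinical vignettes (16 referral, 17
engagement, 18 mortality vignettes; 6, 4 and 3 respondents respectively).
Per vignette the mean, minimum and maximum rating are kept, and a beta
distribution is fitted at a configurable strength:

* **Sample-size method** (`fit_beta_samplesize()`):
  $\alpha = \bar p f N$, $\beta = (1-\bar p) f N$ for
  $f \in \{0.001, 0.01, 0.05, 0.10\}$, so the prior's effective sample size
  is exactly $fN$ and its mean is exactly the expert mean.
* **Confidence-interval method** (`fit_beta_interval()`): `[min, max]` is
  read as the central interval at level 80/85/90/95%, with equal tail mass.
  The mean is a hard constraint ($\beta = \alpha(1-\bar p)/\bar p$) and a
  bracketed 1-D search over $\alpha$ (log-grid then `optimize()`, tolerance
  1e-8, ties toward smaller $\alpha$, i.e. the weaker prior) minimizes the
  squared endpoint discrepancy.  A mean-constrained beta cannot match an
  arbitrary (min, mean, max) triple exactly — one parameter, two targets —
  so the fit carries `achieved` endpoints and a `feasible` flag (within
  1e-3 of both targets).  Raising the level with fixed endpoints requires a
  more concentrated beta, so the prior strength $\alpha+\beta$ increases
  monotonically in the level (asserted numerically in the tests).

### The pseudo-data bridge

How vignette-level beta priors should enter a *regression* is genuinely
open; this package makes the choice explicit.  Each vignette contributes a
weighted pseudo-observation pair at its covariate profile — $\alpha$
successes and $\beta$ failures (`priors_to_pseudodata()`) — a power-prior
style construction that stays on the elicitation's probability scale and
keeps the prior's total weight interpretable as pseudo-patients.  A
zero-weight pseudo-data prior is exactly the flat prior.  The neutral
"Kerman" prior is realized in the same machinery: one Beta(1/3, 1/3)
pseudo-observation attached at the covariate-mean row (the attachment row is
an artifact decision; the covariate mean makes it a statement about the
average case), and is verified to behave near-flat against maximum
likelihood, mirroring the published internal-validity check.

## Bayesian transition models

Each transition is a Bayesian logistic regression: outcome = the
transition event, covariates = age, gender, 3-level race, ethnicity,
alcohol and stimulant use disorder, length of stay, rural residence, MOUD
fill in the 30 days before admission, prior admission, and CDPS score, with
the referral flag added to the engagement model and the engagement flag plus
post-discharge naloxone fill added to the mortality models.

The sampler is adaptive random-walk Metropolis: the proposal covariance is
the inverse Hessian at the weighted-likelihood mode (obtained by IRLS with
the pseudo-rows as fractional-weight observations), scaled from
$2.38/\sqrt{d}$ with Robbins–Monro adaptation toward 23.4% acceptance during
burn-in only, frozen afterwards so the retained chain is a valid Markov
chain.  Defaults are 4 chains, 2,000 burn-in iterations per chain, and
10,000 retained draws total (configurable); runs are exactly reproducible
from the seed.  The sampler contract is deliberately algorithm-agnostic:
anything producing the same diagnostics would do, and a random-walk chain's
effective sample size per draw is lower than a gradient-based sampler's —
the diagnostics report it honestly rather than hiding it.

**Diagnostics** (`diagnose()`): split-chain potential scale reduction factor
(values near 1.0 suggest convergence; threshold 1.01), effective sample size
from chain-averaged autocorrelations with Geyer's initial monotone positive
sequence, lag-1/lag-10 autocorrelations, and a divergence count (always 0
here; the random-walk kernel defines none).  **Model selection**: PSIS-LOO
implemented in-package — per-observation importance ratios $1/p(y_i|\theta)$,
generalized-Pareto tail fit by the Zhang–Stephens posterior-mean estimator
(with the usual weak prior nudging $\hat k$ toward 0.5), tail quantile
smoothing capped at the raw maximum, elpd with SE, and per-observation
Pareto-$\hat k$; `loo_compare()` ranks by *higher* elpd (the standard
convention) and flags any model with $\hat k \ge 0.7$.  Exact leave-one-out
refitting at small $n$ is the test oracle.  **Marginals**
(`marginal_prob_observed()`): per draw, the inverse-logit linear predictor
averaged over the observed covariate rows — optionally with one covariate
pinned (e.g. referral = 1) for stratum-specific probabilities — then
summarized by the posterior mean and central 95% percentile interval,
reported as "95% CI" to match the published labels.

## The synthetic-data generator

No source data are deposited (Medicaid claims, an ACS referral registry and
vital statistics), so the package ships a seeded generator whose defaults
*are* the study conditions: covariate marginals at the published cohort
demographics (age ~ normal(44.5, 15.4) truncated at 18; length of stay ~
log-normal moment-matched to mean 6.6, SD 11.2 days; CDPS ~ gamma matched
to mean 2.5, SD 1.6; binary covariates Bernoulli at the published
proportions), and outcomes drawn from logistic models whose default
coefficients place modest effects on a few binary covariates with
intercepts calibrated (exactly, by enumeration over the binary covariate
combinations) so the implied marginal rates match the published transition
estimates: 4% referred, 20% engaged if not referred (47% if referred via a
log-odds shift), 15% twelve-month death if not engaged (10% if engaged),
split drug/non-drug 30/70 engaged and 40/60 not engaged.  Admission dates
are uniform over the study window; all dates are integer day offsets from
2015-04-01, avoiding calendar-library dialects.

Event tables are constructed to be *exactly* consistent with the latent
truth, so the measures layer can be validated against a known answer:
engaged patients get either two MOUD fills at days 5 and 20 or one 30-day
buprenorphine supply from day 1 (exercising both HEDIS clauses); not-engaged
patients get at most one short fill; drug-related deaths draw their
underlying-cause code from the drug-related set.  This makes classification
invertible by design — the tests assert 100% recovery of latent engagement
and death category.

What the generator does **not** emulate: covariate correlations (the
published joint distribution is unknown; marginals only), realistic ICD
code frequencies beyond the cause split, enrollment gaps, multiple eligible
index admissions, in-hospital deaths, or fills interrupted by death.
Passing tests therefore demonstrate that the pipeline's logic is correct
and self-consistent, not that the generator reproduces real claims data.

## Problem sizes and numerical choices

The analysis drivers simulate 8,450 patients (the published eligibility
count) and fit with 4 chains × 2,500 retained draws.  The test suite uses
smaller cohorts (50–10,000) and shorter chains (2 × 1,000 is typical), with
tolerances stated per test: binomial checks use 3 standard errors,
Bayesian-vs-classical comparisons use 3 ESS-based Monte Carlo standard
errors, the parameter-recovery experiment requires ≥90/100 coverage of 95%
intervals at n = 5,000, and the beta-interval fits are checked to 1e-3
against `qbeta` on self-consistent targets.  Degenerate inputs are handled
explicitly: single-expert vignettes are flagged and routed to the
sample-size method; empty pseudo-data is the flat prior; complete separation
under a flat prior warns and flags the fit; `classify_death` errors on a
codeless death with no override rather than guessing.

## Known limitations

* The random-walk sampler needs long chains for high-dimensional models;
  the drivers' default draw counts give R-hat ≲ 1.05 on 15-parameter
  models, adequate for marginal probabilities but not for fine tail
  quantiles of individual coefficients.
* The Low/High scenario algebra is a bound only on the protective domain
  (see above), and is not a probabilistic interval.
* The elicitation-to-regression bridge (pseudo-data at vignette profiles)
  is one defensible choice among several; coefficient-scale priors would
  weight vignettes differently.
* CDPS scores are passthrough covariates; computing them from diagnosis
  codes is out of scope, as are real claim formats and enrollment handling.
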
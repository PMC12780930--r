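---
title: "Age-mismatched grafts in adolescent liver transplantation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-mismatched grafts in adolescent liver transplantation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adolgraft)
```

## The estimand and the analytic chain

The package studies one exposure — receipt of a liver graft from a donor at
least 10 years older than the adolescent (12–17 year old) recipient — and
two outputs: the association of that exposure with long-term graft survival,
and a counterfactual estimate of how much sooner an age-matched graft would
have arrived under broader geographic sharing. The chain is

1. **cohort**: inclusion/exclusion and covariate derivation;
2. **psm**: propensity-score estimation and 1:1 caliper matching;
3. **survival**: Kaplan–Meier, log-rank, Cox, and landmark restriction;
4. **reallocation**: distance-ceiling scenarios over an observed stream of
   adolescent donor grafts transplanted into adults;
5. **pipeline**: orchestration and reporting.

Real national registry extracts of this kind are restricted-access, so the
first module is a **synthetic registry generator** whose defaults constitute
the package's stated world. Everything downstream is exercised, tested and
calibrated against that world plus closed-form and brute-force oracles.

## The synthetic registry: what it emulates

`generate_registry()` draws, per adolescent transplant:

- a **latent acuity score** $z \sim N(0,1)$. Thresholds on $z$ produce the
  pretransplant admission category (ICU above the 73.4th percentile, ward
  for the next 13.6 %, otherwise home), status 1 with probability
  $\operatorname{logit}^{-1}(-1.1 + 1.4z)$, MELD
  $\approx \operatorname{clip}(18 + 6.5 z + \varepsilon, 6, 40)$, and an
  acute-liver-failure diagnosis with probability
  $\operatorname{logit}^{-1}(-2.1 + 0.9 z)$. A single latent is the
  simplest structure that makes all acuity covariates jointly imbalanced
  between exposure arms, which is the qualitative pattern reported for the
  real cohort.
- **exposure assignment** with probability
  $\operatorname{logit}^{-1}(\alpha + \gamma z)$, where $\gamma$ is
  `confounding_strength` and $\alpha$ is calibrated by root-finding so the
  realized marginal exposure fraction equals `frac_mismatched_target`
  (default 0.303). This calibration is part of the stated world, not a
  tuning step: it pins the cohort composition the study design assumes.
- **donor age** equal to recipient age plus $10 + \text{Exp}(11)$ years
  (rounded) when exposed, and a peer-aged donor otherwise; donor body size
  from sex- and age-group-specific normal distributions clipped to
  plausible ranges. Ages are whole years, the registry convention.
- **graft survival** from a piecewise-constant annual hazard
  $\lambda_j \exp(\beta_a z + \beta_e(j) \cdot \text{exposed})$ with
  $\beta_e(j)$ equal to `exposure_log_hr_early` on (0,1] years, 0 on
  (1,5], and `exposure_log_hr_late` on (5,10]. Defaults: baseline
  $\lambda = (0.08, 0.025, \dots)$ per year, giving roughly 74 % 10-year
  graft survival in the unexposed arm; `acuity_log_hr` $= \log 1.3$ so that
  acuity is a true confounder (it must affect the outcome, or matching
  would have nothing to correct); early effect 0 and late effect
  $\log 1.67$, i.e. an effect that emerges only beyond five years.
  Sampling inverts the piecewise-linear cumulative hazard; the last annual
  rate extends beyond year 10.
- **censoring**: independent exponential loss to follow-up at
  `censor_rate` (default 0.02/year) plus administrative censoring at
  `admin_censor_date` (default 2025-04-04, with transplant dates uniform on
  2002-03-01 – 2024-12-31).
- an **adult-recipient stream** of adolescent (donor age 12–17) grafts with
  transplant dates uniform over the window and donor weights drawn from the
  adolescent body-size model, so they overlap the index recipients' weight
  range. This stream is generated independently of the adolescent cohort's
  outcomes: the reallocation analysis treats it as exogenous supply, which
  matches its retrospective design.

Small fractions of DCD, living-donor and multiorgan records (2–3 % each)
are included solely so the exclusion filters do real work in tests.

**What the generator does not emulate** — and hence what a green test does
not establish: real marginal distributions of any covariate; waiting-list
dynamics before transplant; correlation between donor quality and distance;
center-level practice variation beyond random volume weights; informative
censoring. Tests against this world validate the *estimators and rules*,
not any real-world effect size.

## Cohort rules and derived covariates

Inclusion: recipient age 12–17, donation after brain death only, liver-only
(no multiorgan), transplant date in the window. Rows missing a required
field are dropped into a JSON-lines validation log, and an attrition table
records counts per filter (the filters commute, which is tested by
permutation). Derived fields:

- BSA by Du Bois: $0.007184\,h^{0.725}\,w^{0.425}$ (h in cm, w in kg);
- BSA index = donor BSA / recipient BSA; size class small (< 0.78), normal
  (0.78–1.24, closed interval), large (> 1.24); undefined for
  split/reduced grafts, which form their own level of the combined
  graft-type-and-size factor;
- exposure: signed difference, donor minus recipient age ≥ 10 years (a
  donor ten years *younger* is not exposure);
- center volume tertiles at the published cutpoints (≥ 57 / 28–56 / < 28
  cases). On synthetic data the realized tertile boundaries need not fall
  there, so the cutpoints are a parameter; the defaults keep the published
  operational definition.
- graft survival time to the earliest of retransplant, death, last
  follow-up, administrative censoring; the 10-year horizon is applied after
  time computation (times capped, later events censored).

Missing height/weight makes the size covariates missing; such rows are
excluded from matching (complete-case) and logged. The handling of missing
covariates before matching is not specified in the study design this
follows; complete-case is the assumption, and it is visible in the logs.

## Propensity matching

The propensity model is a maximum-likelihood logistic regression of
exposure on the combined graft-type/size factor, donor sex, donor–recipient
sex mismatch, center volume class, and recipient age, sex, BSA, diagnosis,
MELD, status 1 and admission status, with one-hot encoding against first
levels. Constant covariates are dropped with a warning; (near-)separation
raises an error pointing to a ridge fallback (IRLS with a small
per-observation L2 penalty) rather than silently returning degenerate
scores.

Matching is greedy 1:1 nearest-neighbor without replacement. Three details
are genuinely open in the source design and were fixed as follows:

- **Caliper scale**: "0.1" is read literally as 0.1 on the propensity-score
  scale (the default); a `caliper_scale = "logit_sd"` option implements the
  other common convention, 0.1 × SD of the logit of the score. Both are
  tested.
- **Order**: exposed units are processed in a seeded random permutation —
  any fixed order would make results depend on accidental row ordering.
  Equidistant controls tie-break to the lowest row id.
- **Replacement**: without replacement, implied by equal matched-group
  sizes in the design this follows.

Balance is reported as standardized mean differences — continuous:
$(\bar x_a - \bar x_b)/\sqrt{(s_a^2 + s_b^2)/2}$ with unbiased variances;
binary: the proportion analogue; multi-level factors: the maximum absolute
SMD over indicator levels. Zero pooled variance with equal means is defined
as SMD 0. On the default confounded world (n = 8000), matching takes the
worst |SMD| from ≈ 0.84 to < 0.1, while at least one pre-matching |SMD|
exceeds 0.3 — the structural pattern the matched design requires.

## Survival analysis

Estimation is delegated to the `survival` package; this module pins the
conventions and is verified against independent hand oracles (direct
product-limit evaluation, O−E log-rank arithmetic, the score-test identity)
in the test suite:

- Kaplan–Meier product-limit with events counted before censorings at tied
  times; Greenwood standard errors; curves evaluated as right-continuous
  step functions.
- Two-group log-rank; the degenerate no-events case is defined as
  statistic 0, p = 1.
- Cox partial likelihood with **Efron** tie handling (lower bias than
  Breslow; the source design does not state a method) and **Wald** 95 % CIs
  on the log-HR scale (again unstated; Wald is what HR-with-CI tables
  conventionally report).
- **Landmark restriction**: subjects with an event *or censoring at or
  before* the landmark are excluded — a subject whose follow-up ends
  exactly at the landmark is not "under follow-up beyond" it, so the
  boundary goes to exclusion. Time 0 resets to the landmark and the horizon
  applies on the original scale (a 5-year landmark with a 10-year horizon
  analyzes 5 post-landmark years). Whether p-values should be computed on
  the truncated or full follow-up scale is left to the caller via the
  `horizon` argument.

Parameter recovery closes the loop on the generator: with the late effect
set to $\log 1.67$, no early effect and no confounding, the 5-year-landmark
Cox HR averages ≈ 1.65 over 20 replicates of n = 20 000 and the 1-to-5-year
window HR averages ≈ 1.00 — the "similar until 5 years, worse beyond"
pattern as a reproducible property. With confounding switched on, the
matched-cohort estimate is closer to the truth than the unmatched one; both
are tested. The confounded acceptance criterion is run without the acuity
hazard term because the marginal landmark HR would otherwise mix the
exposure effect with non-collapsibility of the acuity effect, turning an
estimator check into a check of the confounder.

## Reallocation simulation

For each age-mismatched index transplant on or after 2020-02-04, candidate
grafts are adult-stream records with donor age 12–17, DBD, whole liver,
transplanted on days 1–90 after the index date (day 0 excluded), donor
weight within ±20 kg of the index recipient's weight, and donor hospital
within the distance ceiling of the index recipient's hospital. Marked size
mismatch is operationalized solely by the ±20 kg rule — no additional BSA
screen — exactly as the scenario is defined. Distances are haversine
great-circle values (sphere radius 6371.0088 km, 1 NM = 1852 m) between
hospital coordinates; records with unknown coordinates are skipped and
logged.

Design choices:

- **No competition by default**: each index case is evaluated against the
  full stream. The alternative — consuming a graft once assigned — is
  available behind `consume = TRUE` for sensitivity analysis; whether the
  original design allowed one graft to satisfy several index recipients is
  not stated.
- **p90 wait** is the smallest day $d$ with empirical cumulative matched
  fraction ≥ 0.90, reported as `NA` (printed "> window") if never reached.
  The source's prose gloss of the percentile ("no transplant occurred on
  days 1..d in the remaining 10 %") does not correspond to a standard
  percentile; the standard empirical definition is used.
- Candidate sets are computed once with no distance limit and filtered per
  ceiling; nestedness (ceiling c sets equal the unlimited sets filtered at
  c) and monotonicity of p90 in the ceiling are asserted against an
  independent brute-force filter.

## Numerical and degenerate-input conventions

- All randomness flows from one user seed through deterministic sub-seed
  derivation; same config + seed gives byte-identical CSVs.
- Piecewise-exponential sampling inverts the cumulative hazard exactly;
  zero-rate pieces are handled (no events can fall in them).
- `match_1to1` uses a 1e-15 tolerance for distance ties and 1e-12 slack on
  the caliper boundary to keep floating-point round-off from flipping
  legitimate boundary pairs.
- Degenerate inputs fail loudly with classed conditions
  (`adolgraft_config_error`, `adolgraft_domain_error`,
  `adolgraft_separation_error`, `adolgraft_convergence_error`) naming the
  offending field or covariate.

## Known limitations

The generator's marginals are stand-ins; effect sizes estimated on it say
nothing about the real registry. The reallocation simulation ignores offer
refusal, cold-ischemia feasibility and allocation sequencing, by design.
The Cox module offers no proportional-hazards diagnostics or
competing-risks handling; the landmark structure is the intended tool for
non-proportionality of the exposure effect.
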
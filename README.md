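# adolgraft

Donor–recipient **age mismatch** in adolescent liver transplantation:
cohort derivation, propensity-score matching, landmark survival analysis,
and a counterfactual simulation of broader sharing of adolescent donor
grafts — driven end-to-end by a seeded synthetic registry generator, so the
whole analytic chain is testable without access to a restricted national
registry file.

## The scientific problem

Adolescent (age 12–17) liver-transplant candidates often accept grafts from
donors 10 or more years older than themselves because the adolescent donor
pool is small and the wait for an age-matched offer is unpredictable.
Acceptance of such *age-mismatched* grafts is strongly confounded by
pretransplant acuity (ICU admission, status 1 priority, MELD score): sicker
candidates take the first acceptable organ. The questions this package
operationalises are:

1. **Exposure effect.** Is an age-mismatched graft (donor age − recipient
   age ≥ 10 years) associated with worse long-term graft survival, after
   balancing acuity and size-matching covariates by 1:1 propensity-score
   matching (nearest neighbor, caliper 0.1), and does the effect emerge
   late? Landmark analyses at 1 and 5 years re-set time 0 at the landmark,
   keeping only recipients alive with a functioning graft and under
   follow-up, and fit Cox models (Efron ties, Wald CIs) within each window.
2. **Policy counterfactual.** For each age-mismatched index transplant
   after the distance-based allocation policy of 2020-02-04, how soon would
   an age-matched graft have arrived if adolescent DBD whole-liver grafts
   actually transplanted into adults (donor weight within 20 kg of the
   index recipient, donor hospital within a travel-distance ceiling of the
   index recipient's hospital) had been reallocated? Ceilings of 500, 1000,
   1500 NM and no limit are compared by the **p90 wait** — the smallest day
   by which ≥ 90 % of index cases would have received an offer within the
   90-day window. Distances are haversine great-circle distances on a
   sphere of radius 6371.0088 km, in nautical miles.

Core quantities: body surface area by the Du Bois formula
`BSA = 0.007184 · height^0.725 · weight^0.425`; graft size class from the
donor/recipient BSA index (small < 0.78, normal 0.78–1.24, large > 1.24,
undefined for split/reduced grafts); covariate balance by standardized mean
differences (|SMD| < 0.1 = balanced); graft survival from transplant to
retransplant or death, censored at 10 years, last follow-up, or the
administrative date, whichever is first.

Because the real registry is restricted, `generate_registry()` produces a
synthetic stand-in with the *structure* the analysis assumes — a latent
acuity score that drives both illness severity and mismatched-graft
acceptance, piecewise-exponential graft survival with a configurable
late-emerging exposure effect, an adult-recipient stream of adolescent
donor grafts, and hospital geography — all reproducible from one seed.

## Worked example

```r
library(adolgraft)
cfg <- run_config(registry = registry_config(seed = 1), out_dir = "demo", seed = 1)
summary <- run_pipeline(cfg)
#> [registry] simulated 2020 adolescent + 5401 adult transplants
#> [cohort] 1886 of 2020 rows retained (516 exposed)
#> [psm] 438 pairs, max |SMD| 0.838 -> 0.069
#> [survival] matched log-rank chi2 9.56; full-cohort exposure HR 1.40
#> [reallocation] 125 index cases, p90 waits: 38, 14, 9, 6
```

What the numbers mean, for this synthetic world (seed 1):

- 1886 of 2020 simulated adolescent transplants pass the inclusion rules
  (DBD, liver-only, age 12–17); 516 (27 %) are age-mismatched.
- Matching finds 438 pairs and reduces the worst covariate imbalance from
  SMD 0.84 (MELD/admission, the built-in confounding) to 0.069 — below the
  0.1 balance convention.
- In the matched cohort, 10-year graft survival is 0.607 in the
  age-mismatched arm vs 0.755 in the age-matched arm (log-rank p = 0.002);
  the adjusted full-cohort exposure hazard ratio is 1.40 (1.12–1.76) and
  the 5-year-landmark HR is 2.06 (1.39–3.06) — the late-emerging effect the
  generator embeds (true late HR 1.67) plus residual acuity confounding in
  the unmatched Cox adjustment set.
- Relaxing the reallocation ceiling from 500 NM to 1000/1500/no-limit
  shortens the p90 wait from 38 days to 14, 9 and 6 days.

Every artifact (cohort, matched pairs, balance table, KM curves, Cox
tables, per-ceiling first arrivals, trend tabulations, `summary.json`) is
written to `out_dir`. A thin CLI over the same functions is installed at
`inst/cli/adolgraft.R` (verbs `simulate`, `cohort`, `match`, `survive`,
`reallocate`, `run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline — registry simulation, cohort derivation,
matching, landmark survival and the reallocation scenarios — from scratch
at the given seed and writes the machine-readable report to `--out`.

## Package layout

- `R/registry-config.R`, `R/synthetic-registry.R` — seeded generator.
- `R/cohort.R` — inclusion rules, Du Bois BSA, size/volume/exposure classes,
  survival-time construction.
- `R/psm.R` — propensity model, greedy 1:1 caliper matching, SMD balance.
- `R/survival-analysis.R` — KM, log-rank, Cox (Efron), landmark restriction.
- `R/reallocation.R` — great-circle distances, candidate grafts, scenarios.
- `R/pipeline.R` — orchestration, trend tabulations, summary JSON.
- `vignettes/age-mismatch-methods.Rmd` — model, assumptions, design choices.
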
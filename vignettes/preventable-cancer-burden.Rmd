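---
title: "Modelling preventable cancer burden and costs of vitamin D supplementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preventable cancer burden and costs of vitamin D supplementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preventyll)
```

# The question and the model

Randomized trials of vitamin D supplementation have repeatedly shown a
reduction in total cancer mortality that misses significance trial by
trial but is significant when pooled. This package asks the follow-up
health-economic question: if everyone aged 50+ in a country the size of
Germany were supplemented, how many cancer deaths and life-years would
be saved each year, what would it cost, and would the saved end-of-life
cancer care pay for it?

The model is deliberately simple and fully deterministic:

1. **Effect size.** Trial risk ratios are pooled on the log scale with
   inverse-variance weights. The DerSimonian–Laird moment estimator
   supplies the between-study variance; the pooled RR converts to a
   preventable fraction $1 - RR$.
2. **Baseline burden.** Years of life lost are
   $\mathrm{YLL} = \sum_{s,a} D_{s,a}\, e_s(\mathrm{mid}(a))$ over sexes
   and 5-year age groups from 50, with $e_s$ the further life
   expectancy at the interval midpoint.
3. **Impact.** The preventable fraction applies proportionally to both
   deaths and YLL — one RR for all ages, sexes and cancer sites, with
   no latency between supplementation start and benefit.
4. **Accounting.** Cost $= P \times c$ (population 50+ times annual unit
   cost); savings $=$ prevented deaths $\times$ end-of-life cost per
   death; net cost is the difference, and cost-effectiveness is net (or
   gross) cost per prevented YLL.

## Assumptions worth keeping in view

- The pooled RR from trials with 3–7 years of follow-up is treated as a
  steady-state annual effect of ongoing supplementation.
- Everyone aged 50+ is supplemented without prior testing of vitamin D
  status, so cost has no laboratory component and the effect is the
  trial-average effect, not the (larger) effect in deficient subgroups.
- Savings are limited to end-of-life cancer care; non-cancer benefits
  are out of scope.
- No discounting or age-weighting of life-years is applied.

# Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| mortality reduction | 0.13 (range 0.04–0.21) | fraction | pooled RR 0.87 (95% CI 0.79–0.96) from the five trials in `keum_trials()`; CI bounds drive the sensitivity scenarios |
| dose-specific reductions | 0.11 (400 IU/d), 0.17 (2000 IU/d) | fraction | effects observed in the single trials at those doses; the dose→effect map is an assumption, not a fitted dose–response |
| annual unit cost | 25 (10 / 50) | € per person-year | market drug prices for 1000 (400 / 2000) IU per day |
| end-of-life cancer care cost | 40 000 (20 000 / 60 000) | € per death | literature-derived average, varied over a plausible range |
| population 50+ | 36 000 000 | persons | 16.8M men + 19.2M women (2016) |
| `min_age` | 50 | years | >96% of cancer deaths occur above 50 and trial populations were ≥50 |
| `open_ended_offset` | 2 | years | see below |

# Numerical and design choices

**CI → SE reconstruction.** Published trials report only RR and a 95%
CI, so the log-scale standard error is reconstructed as
$(\ln\mathrm{hi} - \ln\mathrm{lo}) / (2 \times 1.959964)$, assuming the
CI is symmetric on the log scale. This is the standard reconstruction;
whichever variant the original meta-analysts used, agreement is exact
to the two decimals at which pooled effects are reported, which is the
package's presentation surface.

**DL truncation.** When Cochran's $Q$ falls below its degrees of
freedom, $\tau^2$ is truncated at 0 (classical DL); the five-trial set
is homogeneous ($Q = 0.59$, df = 4), so random- and fixed-effect
pooling coincide there — a property the tests assert.

**Open-ended age group.** The midpoint rule is only stated for closed
5-year groups (52 for 50–54). The final 85+ group is treated like a
5-year group (midpoint 87) via `open_ended_offset = 2`, kept
configurable so the sensitivity of results to this choice is directly
testable. Because expectancy at 87 is ~5 years, plausible alternative
offsets move total YLL by well under 1%.

**Rounding discipline.** All computation uses exact euros and unrounded
counts; nearest-integer rounding (half away from zero, matching how
published tables round) happens only in the presentation layer. Chains
of pre-rounded intermediate values — e.g. dividing a net cost already
rounded to millions by a YLL count already rounded to integers — can
shift a €/YLL ratio or a scaled count by one unit; comparisons against
such published values therefore allow ±1 where the discrepancy is a
documented rounding-chain artifact (5 506 vs 5 507; 519 623 vs
519 622).

**Cost-saving sentinel.** When savings exceed costs, a cost-per-YLL
ratio is meaningless; `cost_per_yll()` returns `NA` and tables render
"Cost saving". The sentinel appears exactly when net cost is negative,
never alongside a ratio.

# The synthetic input tables

The sex- and age-specific deaths table and the national life table are
not redistributable inside the package, so `synthetic_config()` +
`synthetic_s1_tables()` generate stand-ins with the right structure:

- **Life tables**: further expectancy $e(a) = e_{52} \,
  \mathrm{e}^{-\rho (a - 52)}$ per sex, anchored at 28 (men) / 32
  (women) years at age 52 with $\rho = 0.049$/year over ages 50–99 —
  smooth, strictly decreasing, female ≥ male everywhere, and close to
  the German 2016/2018 period life table at the ages that matter.
- **Death counts**: a Gompertz-type age-at-death profile (modal age 77,
  dispersion 10 years) over the groups 50–54 … 85+, split 53%/47%
  male/female, with small seeded lognormal noise (log-sd 0.02) so
  replicate tables differ realistically while every stratum stays
  positive and the age profile unimodal.
- **Calibration**: counts are rescaled so the pipeline hits the
  aggregate totals implied by the base case — 221 862 deaths and
  2 474 392 YLL at ages 50+, the printed prevented quantities divided
  by 0.13. These targets are derived anchors, not authoritative
  registry values. Calibration is two-stage: an exponential age-tilt
  $d_i \mapsto d_i\,\mathrm{e}^{\theta a_i}$ solved (monotonically, by
  root-finding) so the YLL-per-death ratio matches the target ratio,
  then a global scale with largest-remainder integer rounding that
  meets the deaths target exactly, followed by greedy single-death
  transfers between strata that shrink the YLL residual below the
  granularity of expectancy differences (a few years out of 2.5
  million). The guaranteed contract is ±2 deaths and ±0.2% YLL; the
  achieved residuals are orders of magnitude smaller, which is what
  lets the full pipeline reproduce integer-rounded published counts.

What passing tests on these tables show — and what they do not: the
pipeline arithmetic (midpoint YLL, proportional impact, accounting) is
exercised end-to-end against the published aggregates, but the
synthetic age *distribution* is only plausible, not real. Per-stratum
outputs (e.g. YLL in the 60–64 group) have no claim to match registry
data; only the calibrated totals do.

# Problem sizes and determinism

Everything is desk scale: 5 trials, 16 strata (2 sexes × 8 age groups),
100-row life tables, 7 + 5 scenarios. The full test suite runs in
seconds; property-style tests use fixed seeds (100 random trial sets
against a brute-force pooling oracle at 1e-10; 50 random tables against
a nested-loop YLL oracle at 1e-9; 20 calibration seeds). Identical
configuration and seed give byte-identical CSV output.

# Worked run

```{r}
pooled <- pool_random_dl(keum_trials())
pooled

tabs <- synthetic_s1_tables(synthetic_config(seed = 1))
baseline <- as_baseline_burden(compute_yll(tabs$mortality, tabs$life_table))
render_table(run_scenarios(builtin_scenarios(), baseline), "with_savings")
render_table(run_scenarios(builtin_scenarios("no_savings"), baseline), "no_savings")
```

# Known limitations

- Proportional impact ignores effect heterogeneity by age, sex, site,
  stage and baseline vitamin D status, and any lag between
  supplementation start and mortality benefit.
- The dose scenarios re-use single-trial effect estimates; no
  dose–response model is fitted.
- The analysis is purely deterministic scenario-based; there is no
  probabilistic sensitivity analysis, and parameter uncertainty beyond
  the RR confidence bounds is not propagated.
- Costs exclude laboratory testing, non-cancer health effects, and any
  discounting or inflation adjustment.
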
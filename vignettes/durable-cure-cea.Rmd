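---
title: "Modelling a durable cure for sickle cell disease: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a durable cure for sickle cell disease: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicklecea)
```

## The decision problem

Sickle cell disease is an inherited disorder, present from birth, that
shortens life and imposes heavy lifelong treatment costs. A
single-administration cell or gene therapy that durably suppresses the
disease trades a very large upfront price against decades of avoided costs
and regained quality of life. `sicklecea` implements a cohort-level Markov
model of that trade-off: durable therapy (DT) given at birth versus the
standard-of-care (SOC) treatment bundle, evaluated as discounted cost per
quality-adjusted life year (QALY) from the US healthcare sector perspective
in 2018 USD.

## Model structure and assumptions

The cohort moves through five states — healthy (in remission), mild,
moderate and severe SCD, and dead — in annual cycles from birth (age 0 =
cycle 0) over a 100-cycle horizon. Severity is defined by the annualized
vaso-occlusive crisis count: mild means zero crises per year, moderate more
than zero but fewer than two, severe two or more.

Within a cycle, events are ordered: death first, from the state-appropriate
life table, then (for survivors only) relapse or severity transition. This
matters because the severity regressions are estimated conditional on
survival. Relapse always lands in mild SCD, and no affected patient can
return to remission — the cure cannot be repeated.

The model is an exact expected-proportion cohort computation, not a sampled
microsimulation: occupancy vectors are propagated through row-stochastic
matrices, so results are deterministic given the inputs. The nominal cohort
size of 10,000 patients is carried only for reporting totals.

### Transitions

Annual severity transitions use gender-specific cumulative-logit (ordered
logistic) regressions of next-year severity on current severity, age, and
severity-by-age interactions, with mild as the reference class:

$$x\beta = \alpha_1 \mathbb{1}[\text{mod}] + \alpha_2 \mathbb{1}[\text{sev}]
 + \alpha_3\,\text{age} + \alpha_4 \mathbb{1}[\text{mod}]\,\text{age}
 + \alpha_5 \mathbb{1}[\text{sev}]\,\text{age}$$

$$P(\text{mild}) = L(\kappa_1 - x\beta), \quad
  P(\text{mild or mod}) = L(\kappa_2 - x\beta), \quad
  L(z) = \frac{1}{1+e^{-z}}$$

The source table prints coefficients but not the parameterisation; we use
the standard cumulative-logit form with no separate intercept (the cut
points absorb it), the convention of the common estimation routines for
ordered outcomes, which keeps all probabilities strictly inside (0, 1). The
regressions were estimated on a two-year claims window but are applied at
every age through the age covariate; no age truncation is imposed, since
none is stated.

### Rewards

Annual direct cost is the mean of a gamma log-link GLM on severity
indicators, age, and interactions; the healthy state uses the
matched-control prediction (all indicators zero). Utility weights are
age-banded: normative-population values by gender for the healthy state
(bands 1–44, 45–54, 55–64, 65–74, 75+) and severity-invariant SCD values
for any affected state (1–18 and 19+). The printed bands start at age 1,
but the cohort starts at birth and accrues rewards from the first cycle, so
the first band is extended to age 0. Band edges are inclusive (45–54 means
45 ≤ age ≤ 54). Deceased patients incur zero cost and zero utility, and the
transition to death itself carries no cost (avoiding double counting).

Rewards accrue to the state occupied at cycle start, discounted by
$(1+r)^{-t}$ with $r = 3\%$/yr, so cycle-0 rewards are undiscounted —
consistent with the DT price being charged undiscounted at time zero. No
half-cycle correction is applied by default (none is stated in the source);
`run_cohort(half_cycle = TRUE)` averages start- and end-of-cycle occupancy
instead, for users who prefer it.

### Cure durability (waning)

The base case assumes a lifetime cure: annual relapse probability zero. The
scenario analyses assume the cure holds for a median of `T` years, i.e. a
cumulative relapse probability of 0.5 by year `T`, converted under a
constant exponential rate:

$$P_{\text{annual}} = 1 - (1 - P_T)^{1/T}$$

giving 0.06697 for `T` = 10 and 0.03406 for `T` = 20.

```{r waning}
annual_relapse_probability(0.5, c(10, 20))
```

### Mortality

The original analysis used simulated life tables (unaffected Black/African
American population, and an SCD-risk-adjusted variant) that are not
published. The package therefore synthesizes default tables from a
Gompertz–Makeham hazard, $q_x = 1 - \exp(-(a e^{b\,\text{age}} + c))$, with
slope $b = 0.085$ (a conventional adult log-mortality slope) and Makeham
constant $c = 0.001$, and calibrates the scale $a$ by bracketed
root-finding so each table's survivor-years over the 100-cycle horizon
match the published undiscounted life expectancies: 75.8 years for the
cured cohort and 54.9 under SOC, to within 0.05 years. Mortality is shared
across genders and across severity levels within the affected states, as in
the source. Users with access to real tables supply them as `age,qx` CSVs
via `read_life_table()`.

This substitution is the model's main limitation: absolute per-arm costs
and QALYs, and every result downstream of them (scenario ICERs as absolute
numbers, PSA acceptability percentages, the EVPI curve's height) depend on
the *shape* of mortality over age, not just its mean. Calibrating two
parameters to two life expectancies reproduces the published totals but not
necessarily the published age profile, so those absolute outputs are
checked as properties (ordering, conservation, identities) rather than
against the published numbers. The desk-scale published arithmetic —
waning conversions, incremental arithmetic, the linear price–ICER identity
and its threshold prices — is reproduced exactly.

## Parameters and uncertainty

`scd_parameters()` loads the packaged registry: every scalar input with its
base value, 95% CI, sampling distribution, and sensitivity-analysis rule.
Two values deserve comment:

- **Percent female.** The registry's printed value is 51 (Beta(49, 47)),
  but the reported cohort is 47% female; both appear in the source without
  reconciliation. The package defaults the base value to 0.47 (matching the
  reported cohort) while keeping Beta(49, 47) in the PSA and the printed CI
  (0.411, 0.609) in the DSA. Override via the config file to change this.
- **Regression coefficients.** Base values are the distribution means
  (e.g. −0.026), not the 2-decimal printed point values (−0.03), because
  the worked transition examples only reproduce under the former.

Deterministic sensitivity analysis varies each eligible parameter across
its 95% CI, or ±20% of base when no CI exists (the DT price and its
uniform(1.68M, 2.52M) PSA distribution are the same ±20% band). The
initial-severity Dirichlet rows are excluded from DSA and the discount rate
and cohort size from PSA, as flagged in the source table. Each regression
coefficient is varied independently in DSA (as the published tornado
labels imply), and drawn as an independent normal in PSA — no covariance
matrix is published. The two genders' severity mixes are each drawn jointly
as one Dirichlet vector. Truncated-normal utilities are sampled exactly on
[0, 1] by inverse-CDF. Draws that invert the ordered-logit cut points
(κ₁ ≥ κ₂) would break the transition model; they are rejected and redrawn,
preserving the stated marginals (at the default parameters this happens in
far less than 1% of draws, and the count is reported).

The PSA uses a master seed that spawns one sub-seed per iteration, so any
iteration can be reproduced in isolation and reruns are bit-identical.

## Decision rules

The CEAC awards each PSA iteration to the arm with the higher net monetary
benefit (NMB = λ·QALY − cost), with ties to the SOC incumbent for
deterministic reproducibility. The source counts iterations with ICER below
the threshold instead; the two rules coincide whenever DT gains QALYs at
extra cost — the regime all base-case results occupy — and the literal
counting rule is available as `ceac_ceaf(rule = "icer_threshold")`. The
CEAF marks the arm with the highest expected NMB, and EVPI is
E[max NMB] − max E[NMB], non-negative by construction. The default λ grid
(0 to 300,000 by 5,000) covers every threshold discussed.

Because the upfront price enters incremental cost one-for-one and
undiscounted, the ICER is linear in price and the value-based price at a
threshold λ is `p* = p0 + (λ·ΔQ − ΔC)`; `threshold_price()` implements
this, and a test drives the full engine at `p*` to confirm the round trip.

## The synthetic claims panel

`generate_panel()` stands in for the proprietary claims data. It emulates
exactly the structure the estimation stage assumes: year-1 severity from
the gender's initial mix, year-2 severity from the true ordered-logit row,
costs drawn from a gamma distribution around the GLM mean, and crisis
rates drawn within each class (0 for mild; uniform on (0, 2) for moderate;
2 + standard exponential for severe — artifact choices, since only the
class is used downstream). Ages are drawn uniformly over 0–64, a
commercially insured population; each patient contributes two panel years,
the window the transition regressions need. Unaffected controls are
generated directly (severity `"control"`, crisis rate `NA`) so the cost
regression's reference level is estimable; propensity-score matching is
not simulated. The gamma shape defaults to 1.5 — only the GLM mean
structure is published, not the dispersion — and `Inf` gives noiseless
costs for exact-recovery checks.

What passing recovery tests show: `MASS::polr` and `glm(family = Gamma)`
recover the generating coefficients from a 50,000-patient panel within
sampling error, and errors shrink as the panel grows. What they do not
show: robustness to real-claims features the generator omits — enrollment
gaps, coding noise, cost outliers beyond gamma tails, matching artefacts.

## Numerical choices and test scale

- Transition rows and cycle matrices are required to be row-stochastic to
  1e-12; traces conserve mass to 1e-10 over 100 cycles.
- Life-table calibration brackets the hazard scale in [1e-12, 1] and
  solves with `uniroot` at tolerance 1e-12, rejecting targets outside the
  achievable range for the fixed slope.
- The default test suite runs the PSA at 10,000 iterations (the published
  scale, and it completes in well under two minutes on one CPU), the
  recovery harness at 50,000 patients, and the consistency ladder at
  n = 5,000/20,000/80,000 over six seeds — sizes chosen so the whole suite
  stays fast while the statistics remain decisive.
- Costs are held in 2018 USD throughout; no inflation machinery is
  included (CPI adjustment belonged to the raw-claims stage, out of scope).

## A small end-to-end run

```{r run, eval = FALSE}
params <- scd_parameters()
tables <- default_life_tables()

base <- run_base_case(params, tables)
base$cea

psa <- run_psa(params, n_iter = 10000, seed = 1, life_tables = tables)
curves <- ceac_ceaf(psa)
autoplot(curves, "ceac")
autoplot(curves, "evpi")

run_full_report(params, "report", seed = 1)
```
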
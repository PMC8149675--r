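# sicklecea

A lifetime Markov cohort model of the cost-effectiveness of a hypothetical
single-administration durable (cell or gene) therapy cure for sickle cell
disease (SCD), compared against the standard-of-care (SOC) treatment bundle
from the US healthcare sector perspective. The package is aimed at health
economists and methodologists who want a fully scripted, testable version of
this class of decision model: every input is a registry entry with an
uncertainty distribution, every analysis (base case, scenarios, deterministic
and probabilistic sensitivity analysis, value of information) is a plain R
function returning tibbles, and the claims-data estimation stage is emulated
by a synthetic patient-year panel generator with parameter-recovery refits.

## The model

A closed birth cohort moves through five states — healthy (in remission),
mild SCD, moderate SCD, severe SCD, dead — in annual cycles over a 100-year
horizon. Severity classes are defined by annualized vaso-occlusive crisis
counts (mild = 0/yr, moderate in (0, 2)/yr, severe ≥ 2/yr).

- **Arms.** All durable-therapy (DT) patients are cured at birth and start
  healthy; under cure waning they relapse to mild SCD with a constant annual
  probability `P_annual = 1 − (1 − P_T)^(1/T)` (median durability `T` years,
  `P_T` = 0.5), and can never return to remission. SOC patients start
  distributed over the three severity states by the observed early-childhood
  mix and never reach the healthy state.
- **Transitions.** Death resolves first each cycle, from an unaffected life
  table (healthy state) or an SCD-adjusted table (affected states).
  Surviving affected patients move between severities by gender-specific
  cumulative-logit (ordered logistic) regressions on current severity, age,
  and their interactions: `P(Y ≤ k) = logis(κ_k − xβ)`.
- **Rewards.** Annual direct medical cost is the gamma log-link GLM mean
  `exp(β₀ + β₁·mild + β₂·moderate + β₃·severe + β₄·age + interactions)` in
  2018 USD (the healthy state uses the matched-control prediction); utility
  weights come from age-banded normative-population values (healthy) and
  child/adult SCD values (affected); the dead state earns nothing. The DT
  arm pays the upfront price (base $2.1M) once at time zero, undiscounted;
  everything else is discounted at 3%/yr.
- **Outputs.** Incremental cost-effectiveness ratio (ICER, $/QALY) against a
  $150,000/QALY willingness-to-pay threshold; net monetary benefit; tornado
  (one-way) and two-way DSA; 10,000-draw Monte Carlo PSA feeding CEAC/CEAF
  curves, EVPI, and threshold (value-based) prices via the linear
  price–ICER identity.

The published life tables behind the original analysis are not public, so
the default mortality is a Gompertz–Makeham stand-in calibrated so that the
two arms reproduce the published undiscounted life expectancies (75.8 years
cured, 54.9 years under SOC); real tables can be supplied as `age,qx` CSVs.

## Worked example

```r
library(sicklecea)

params <- scd_parameters()          # packaged input registry
tables <- default_life_tables()     # calibrated mortality stand-ins
base   <- run_base_case(params, tables)

dplyr::select(base$cea, gender, delta_cost, delta_qaly, icer)
#>   gender delta_cost delta_qaly   icer
#> 1 pooled    1171958       8.16 143696
#> 2 female    1246257       8.10 153783
#> 3 male      1106071       8.20 134858
```

Curing the pooled cohort (47% female) costs an extra $1.17M per patient over
a lifetime but returns 8.2 discounted QALYs, an ICER of about $143,700 per
QALY — cost-effective at the $150,000/QALY threshold. Shortening the cure's
median durability flips the conclusion:

```r
evaluate_model(params, tables, waning_spec(20))$cea$icer  # 428543
evaluate_model(params, tables, waning_spec(10))$cea$icer  # 752018

cea <- base$cea[base$cea$gender == "pooled", ]
threshold_price(cea$delta_cost, p0 = 2.1e6, lambda = 1.5e5,
                delta_qaly = cea$delta_qaly)
#> 2151411   # highest lifetime-durability price still worth $150K/QALY
```

`run_psa()` draws the full registry 10,000 times (beta, Dirichlet, normal,
truncated-normal and uniform distributions as specified per parameter) and
`ceac_ceaf()` / `evpi()` turn the sample into acceptability curves and the
expected value of perfect information; `one_way_dsa()` produces the tornado
table. `run_full_report()` writes the whole artifact set (base case,
scenarios, tornado, PSA draws and results, CEAC/EVPI curves, manifest) as
CSV/JSON. `generate_panel()`, `fit_transition_model()` and
`fit_cost_model()` generate and refit the synthetic claims panel behind the
transition and cost regressions.

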
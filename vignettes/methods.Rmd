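---
title: "Model and methods: long-term cost-effectiveness of family-based diabetes prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: long-term cost-effectiveness of family-based diabetes prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`heeprev` implements a two-part health-economic model for school- and
family-based lifestyle interventions that aim to prevent type 2 diabetes
(T2DM) in low socio-economic-status communities across six European
countries (Belgium, Bulgaria, Finland, Greece, Hungary, Spain).  A
*decision-analytic front end* converts trial-measured intervention effects
into arm-specific adult weight-status distributions; a *Markov cohort
model* then projects those distributions into lifetime health outcomes and
costs.  This vignette explains the model, its assumptions, the tunable
parameters, and the design choices taken where the design was genuinely
open.

## The decision-analytic front end

Excess weight is the surrogate marker: participants are classified as
normal weight (BMI < 25), overweight (25-30) or obese (> 30).  Two effect
modes feed the model, with the direct mode taking priority when both are
supplied:

* **Direct (BMI) mode** — relative risk reductions (RRR) in overweight and
  obesity measured on the trial population are applied to the control
  distribution: `p_ow' = p_ow (1 - RRR_ow)`, `p_ob' = p_ob (1 - RRR_ob)`,
  with the freed mass returned to normal weight (`apply_weight_rrr()`).
* **Behaviour-mediated (EBRB) mode** — the intervention shifts exposure to
  energy balance-related behaviours (screen time, sugared drinks, breakfast
  habit, ...), each with a published relative risk `RR_b` on overweight or
  obesity.  Per behaviour the attributable change is
  `delta_b = (p_ctrl - p_int)(RR_b - 1) / (1 + p_ctrl (RR_b - 1))`, and
  behaviours combine as `RRR = 1 - prod(1 - delta_b)` — a multiplicative
  survival-of-attributable-fractions rule that assumes independent
  behaviours.  The rule is isolated in `ebrb_weight_rrr()` so alternative
  combination schemes can be swapped in.  Behaviours with inconclusive
  literature (children: fruits/berries, vegetables, sweets; adults: water,
  sweets) are excluded.

Where only an odds ratio is published, `rr_from_or()` converts it
conservatively with `RR = OR / (1 - p0 + p0 OR)`.  The baseline risk `p0`
defaults to the control-group prevalence.  (The source material is
internally inconsistent here — body text mentions the risk in the *total*
sample, the table footnote the *control-group* prevalence; we follow the
footnote.)

Adult prevalence is adjusted for socio-economic status by scaling the
excess-weight proportions with the published relative risks for the
lower-educated half of the population (Bulgaria and Hungary need no
adjustment; Finland's factors lie below 1 for obese women).  Children's
trial-age distributions are extrapolated to adult age with a 3x3
row-stochastic tracking matrix (`child_to_adult()`); the matrix values are
config-supplied because the cited tracking study's numbers are not printed
in the source.

Parents enter the Markov model at their own age: the six age-group
proportions (<30, 30-34, ..., >50) are spread evenly over single ages,
with the under-30 mass entering at 30 and the over-50 mass at 50
(`parent_entry_schedule()`).

## The Markov cohort model

Eleven health states: at risk (entry), diabetes, and first-year /
follow-up tunnel pairs for stroke, CHD, CRC and breast cancer, plus an
absorbing death state.  Breast cancer is reachable by women only.  The
cohort starts entirely at risk and runs 70 one-year cycles from age 30.
Comorbidity combinations other than "diabetes + one disease" are not
modelled as states; diabetes-as-comorbidity is handled through cost
add-ons (below), keeping the model transparent.

Transition probabilities are functions of the weight-status distribution.
Because national incidence rates reflect the national weight mix, the
normal-weight baseline incidence is first calibrated as
`i_normal = i_pop / (p_n + p_ow RR_ow + p_ob RR_ob)` against the
*unadjusted national* prevalence, then re-mixed with the (SES-adjusted,
arm-specific) cohort distribution.  Re-mixing with the reference
distribution recovers the national rate exactly.  Diabetic members develop
comorbidities at the at-risk (weight-mixed) probability scaled by the
diabetic relative risk, and die at the all-cause rate scaled by the
diabetic mortality relative risk (1.57 men, 2.00 women); the weight mix is
not applied a second time inside the diabetes state.  First-year states
pass to their follow-up partner with probability one minus the
case-fatality; death is claimed first in every row, and should the disease
transitions ever exceed the residual mass they are rescaled proportionally
with a warning.

Relative risks are applied multiplicatively to annual probabilities with
capping at 1 (the spreadsheet-model idiom of the original); a constant-
hazard alternative `1 - (1 - p)^RR` is available via the manifest's
`transition_mode = "rate"` for robustness at high baseline risks.  No
half-cycle correction is applied (the source is silent); ages beyond the
oldest band (95+) reuse the oldest band's parameters.

A seeded microsimulation (`microsim_oracle()`) pushes individuals through
the identical matrices by multinomial sampling; the cohort trace is its
exact expectation, which the test suite exploits as an independent
validation path.  The agreement check uses 3 binomial standard errors per
state/cycle with a small-count floor of 5e-4 (about 25 of 50,000
individuals): for cells with near-zero expected counts the normal
approximation behind the 3-SE band is invalid, and the floor covers the
corresponding Poisson fluctuations without weakening the check anywhere it
matters (the maximum deviation must also stay below 0.01 absolute).

One property worth stating precisely: with all relative risks at or above
1, shifting weight mass from obese to normal *lowers every per-cycle
disease and death hazard*.  Cumulative disease-state occupancy over 70
years may nonetheless rise slightly, because the lighter cohort survives
longer and accrues disease later — a competing-risks effect, not a bug.
The test suite therefore asserts monotonicity at the hazard level and
survival dominance at the trace level.

## Outcomes

**QALYs** (`qalys_from_trace()`): occupancy x utility x discount, summed
over cycles 1..70.  Utilities are an age/sex baseline minus a disease
decrement; follow-up decrements are relapse-adjusted,
`(1 - p) d_followup + p d_first`, because follow-up patients risk a
relapse.  Death contributes zero.

**Costs** (`costs_from_trace()`): annual direct state costs (EUR 2016),
stratified at age 65 (diabetes at 55); indirect costs derived from direct
costs with multipliers 0.91 (T2DM), 0.71 (BC), 0.80 (CHD), stroke indirect
equal to direct, and CRC through a configurable direct/indirect ratio
(default 0.45, a synthetic placeholder for the unpublished Finnish-derived
ratio).  Diabetes-as-comorbidity adds 17.91 / 19.80 / 23.75 / 38.24% of
the total diabetes cost to CHD / stroke / BC / CRC.  Follow-up costs are
relapse-adjusted like utilities.  Deaths at ages 30-64 incur a friction
cost: hours worked within the 160-day friction period x hourly
productivity cost x (1 - unemployment) x labour-time elasticity 0.8
(production drops 8% when labour time drops 10%).  The "hours worked
within the period" quantity is not defined in the source; the generator
uses the working-days fraction of the period at 8 h/day
(160 x 5/7 x 8 ≈ 914 h), overridable per country.

**Discounting**: effects at 1.50%, costs at 3%.  Children's effects and
costs are additionally discounted over the lead time from the intervention
(mean age 8.2) to Markov entry at 30 — 21.8 years — which is why their
long-term benefits weigh so lightly.  Parents carry no lead time.
Intervention costs are booked undiscounted at cycle 0 (the source gives no
timing rule for spreading them over the two intervention years, so the 7th
HRF session and SMS-year costs are pooled into the single ledger).

**Reporting** (`run_cea()`): QALYs and costs per 1000 targeted boys or
girls, each child accompanied by two parents, stratified by component:
`all_families` carries the school-based component cost spread over all
families; `hrf` carries the school-based plus the high-risk-family
component cost per HRF family (HRF families receive both).  The ICER is
`(C_int - C_ctrl)/(Q_int - Q_ctrl)` with dominance flags instead of a
division when the QALY difference is zero or the signs make a ratio
misleading.

## Sensitivity and budget impact

The tornado analysis perturbs whole parameter classes by ±30% and ranks
the resulting output intervals by width.  The PSA draws costs from gamma,
probabilities and utilities from beta, and the effect multiplier from a
median-preserving lognormal, all parameterised by method of moments with a
default standard error of 30% of the base value (the source names the
families but no dispersions; 30% mirrors the tornado span and can be
overridden).  Draws with infeasible moments (probabilities at 0 or 1,
zero costs) are held fixed.  Draw `i` is deterministic given
`(seed, i)`.  Discount-rate scenarios are exposed as presets bounding both
rates at 0% and 5%.

The budget impact analysis is undiscounted (ISPOR convention; the source
is silent), payer-perspective: only ledger items borne by the healthcare
budget holder count, so families' transport and time costs drop out.  The
intervention recurs every three years over horizons of 1-30 years with a
stable target population; each implementation launches a fresh parent
cohort whose avoided *direct* healthcare costs offset the budget from that
cohort's own first year, stacking across implementations.  Children's
avoided costs fall beyond the horizon (their benefits start at adult age)
and contribute nothing.

## The synthetic parameter pack

No machine-readable parameter tables accompany the source (its
supplementary country tables are not reproduced), so
`synthetic_pack(seed)` generates complete packs in which every *printed*
constant is embedded exactly — the full weight-status/diabetic relative-
risk table, SES adjustment factors, behaviour effects, comorbidity cost
fractions, indirect multipliers, discount rates, friction settings, Markov
settings, and parent age-group proportions matching the reported shares of
parents under 45.  Everything unprinted — incidence and mortality curves,
utilities, annual disease costs, exposure prevalences, the tracking
matrix, labour statistics, cohort sizes, the intervention ledger — is
generated at magnitudes a European health-economic modeller would
recognise (Gompertz-like all-cause mortality, registry-scale cancer
incidences, EUR-2016 cost levels scaled by health expenditure per capita
with Belgium as reference) with seeded jitter, and is flagged
`source = "synthetic"` in the manifest.  Packs round-trip through a
directory of CSVs plus a YAML manifest, and user values can replace any
synthetic cell.

Passing tests on synthetic packs therefore demonstrate the *engine* —
conservation, calibration, discounting, dominance logic, distributional
machinery — not the real-world parameter values; country results from
synthetic packs are illustrative only.  Missing country cells can be
imputed Belgium-referenced: costs by the health-expenditure-per-capita
ratio, epidemiology by the disease-wise total incidence (or mortality)
ratio.

## Numerical choices and problem sizes

Row-stochasticity and trace conservation are enforced at 1e-9.  Weight
distributions validate to 1e-9.  The test suite runs the conservation
property over 100 random packs, compares the cohort trace against a
50,000-individual microsimulation, checks the odds-ratio conversion
against a brute-force 2x2 table on 1000 random pairs, and exercises the
PSA at small draw counts; the full suite completes in well under two
minutes on one CPU.  All randomness flows from explicit integer seeds; the
generator, the microsimulation and the PSA restore the caller's RNG state.

## Known limitations

* BMI is the surrogate for T2DM risk; hard endpoints are not modelled.
* One disease at a time after leaving the at-risk/diabetes states;
  diabetes comorbidity enters only through cost add-ons.
* Child-to-adult tracking and the behaviour-independence assumption in the
  EBRB combination rule carry structural uncertainty that the PSA does not
  capture.
* Synthetic packs cannot be validated against the unpublished country
  tables; conclusions about specific countries require user-supplied data.
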
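# heeprev

Long-term cost-effectiveness evaluation of school- and family-based
lifestyle interventions preventing type 2 diabetes (T2DM).

Health policy makers deciding whether to fund a childhood obesity /
diabetes prevention programme face a horizon problem: the intervention
costs fall today, the health benefits accrue over decades.  `heeprev`
bridges that gap with a two-part model, built for the multi-country
setting of European school-based prevention trials (Belgium, Bulgaria,
Finland, Greece, Hungary, Spain):

1. **Decision-analytic front end** — converts trial effects into per-arm
   adult weight-status distributions, either directly (relative risk
   reductions in overweight/obesity) or mediated through energy
   balance-related behaviours (EBRBs), combining behaviour-attributable
   fractions as `RRR = 1 - ∏(1 - δ_b)` with
   `δ_b = (p_ctrl - p_int)(RR_b - 1)/(1 + p_ctrl(RR_b - 1))`.
   Odds ratios convert conservatively via `RR = OR/(1 - p₀ + p₀·OR)`;
   children's distributions track to adulthood through a 3×3 matrix.
2. **Markov cohort model** — 11 health states (at risk, diabetes,
   first-year/follow-up tunnels for stroke, CHD, colorectal and breast
   cancer, death), 70 one-year cycles from age 30.  Transition
   probabilities are weight-mixed:
   `i = i_normal·(p_n + p_ow·RR_ow + p_ob·RR_ob)`, with `i_normal`
   calibrated so the national weight mix reproduces national rates.

On top sit discounted QALYs (1.50%) and costs (3%, EUR 2016, with
friction-cost productivity losses and diabetes-comorbidity add-ons), the
ICER `ΔC/ΔQ` with dominance flags, ±30% tornado diagrams, probabilistic
sensitivity analysis (gamma costs / beta probabilities / lognormal
effects) with CEAC, and a payer-perspective budget impact analysis with
triennial re-implementation.

Because the underlying country parameter tables are not published in
machine-readable form, `synthetic_pack()` generates complete, validated
parameter packs: all published constants embedded exactly, everything else
at realistic magnitudes, flagged synthetic, and replaceable cell-by-cell
with user data.

## Worked example

```r
library(heeprev)

pack <- synthetic_pack(1)        # deterministic synthetic parameter pack
nrow(validate_pack(pack))        # 0 -> valid
res <- run_cea(pack, "Belgium")  # base-case evaluation, societal perspective
res
#> <cea_result> Belgium - societal perspective
#>   per 1000 targeted children (EUR 2016, QALYs discounted at 1.5%)
#>        report    sex delta_cost delta_qaly      icer   status
#>  all_families   male  -642505.9   93.35341 -6882.511 dominant
#>  all_families female  -645257.1   92.94616 -6942.268 dominant
#>           hrf   male  -523673.1   93.35341 -5609.577 dominant
#>           hrf female  -526424.4   92.94616 -5663.756 dominant
```

Read: per 1000 targeted boys (plus their 2000 parents), this synthetic
intervention gains ~93 discounted QALYs and *saves* ~EUR 640k over the
70-year horizon — the avoided disease costs exceed the intervention cost,
so the intervention dominates (better and cheaper; no ICER price tag is
needed).  The `hrf` rows answer the same question for high-risk families,
who additionally carry the counseling-component cost per HRF family.
`tidy(res)` returns the arm-level breakdown (QALYs; disease, productivity
and intervention costs), `glance(res)` the summary above.

```r
bia <- run_bia(pack, "Belgium", horizon = 9)  # payer budget impact
head(as.data.frame(bia), 4)
#>   year intervention_cost   offset       net cumulative
#> 1    1          45777.85 1142.372 44635.478   44635.48
#> 2    2              0.00 2003.703 -2003.703   42631.77
#> 3    3              0.00 2875.928 -2875.928   39755.85
#> 4    4          45777.85 4898.729 40879.121   80634.97
```

The payer pays the (healthcare-borne) intervention cost in years 1, 4,
7, ...; between implementations the stacked parent cohorts' avoided direct
healthcare costs make the net annual impact negative.

Sensitivity analyses: `tornado(pack, "Belgium")`,
`run_psa(pack, "Belgium", psa_config(n_draws = 500, seed = 1))`; each
result has an `autoplot()` method (tornado bars, CE plane, CEAC, budget
bars).  A thin command-line wrapper with subcommands
`run | tornado | psa | bia | make-fixtures | validate` ships in
`inst/cli/heeprev`.

All numbers above come from a *synthetic* pack: they demonstrate the
machinery, not any country's actual cost-effectiveness.

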
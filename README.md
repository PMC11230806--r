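# perfuseCE

Cost-effectiveness and budget-impact modelling of **hypothermic machine
perfusion (HMP) for expanded criteria donor (ECD) kidneys** on a national
deceased-donor transplant waiting list, from the public payer's
perspective.

## The problem

ECD kidneys (donors >60 y, or 50–59 y with ≥2 of hypertension,
cerebrovascular death, terminal creatinine >1.5 mg/dL) are discarded far
more often than standard criteria donor (SCD) kidneys when preserved in
static cold storage: in the 2021 São Paulo donor service area only 62% of
offered ECD kidneys were transplanted, against 88% of SCD kidneys. Machine
perfusion can close that utilization gap. For a payer deciding whether to
fund perfusion equipment selectively for ECD kidneys, the question is what
the extra transplants cost once avoided dialysis, extra follow-up care, and
the perfusion program itself are netted out.

## The model

`perfuseCE` implements an annual-cycle Markov cohort model of the waiting
list. States: wait-listed (on dialysis), alive with functioning graft
(by donor type and years since transplant), dead on the list, dead with
graft. Two strategies share one pool of organ offers, recovered by
inverting the comparator's utilization identity

```
transplants = offers × (s_SCD·u_SCD + s_ECD·u_ECD)
```

so the comparator reproduces the registry's forecast transplant counts
exactly; the intervention differs *only* in raising ECD utilization from
0.62 to 0.88. Costs (hemodialysis USD 40.53/session × 156/y while
wait-listed, transplant episode USD 8254.39, follow-up USD 2715.60/y,
preservation per recovered kidney) use trapezoidal half-cycle correction
and mid-cycle discounting at 5%/y; incremental results are classified on
the cost-effectiveness plane against a USD 19 570.52 (3 GDP/capita)
threshold. One-way deterministic sensitivity analysis (tornado ordering),
a seed-deterministic second-order Monte Carlo PSA (1000 iterations), and
an undiscounted 5-year budget impact analysis round out the toolkit.

Post-transplant survival curves and the preservation/perfusion cost
breakdown are not public inputs: the package generates documented
**synthetic stand-ins** (flagged `source: synthetic`) for them. See
`vignettes/model-methods.Rmd` for the full account of structure,
assumptions and limitations.

## Worked example

```r
library(perfuseCE)

p <- default_params()          # base case, synthetic fields flagged
cmp <- compare_strategies(p)
cmp
#> <cea_comparison> machine perfusion for ECD kidneys vs universal cold storage
#> # A tibble: 4 × 5
#>   outcome               machine_perfusion cold_storage difference icer_usd
#>   <chr>                             <dbl>        <dbl>      <dbl>    <dbl>
#> 1 patients_alive                   73989.       73806.       183.   64261.
#> 2 transplants_performed            27785.       26225       1560.    7529.
#> 3 dialysis_dependent              193777.      196667.      2889.    4065.
#> 4 total_cost_usd              1432825292.  1421081349.  11743944.      NA
#>   per transplant gained: tradeoff_cost_effective (threshold USD 19570.52)
```

Under the synthetic defaults, perfusing ECD kidneys yields ~1560 extra
transplants and ~183 fewer deaths over five years for an extra discounted
USD 11.7M — about USD 7529 per additional transplant, well under the
threshold. (`dialysis_dependent` is waiting-list person-years, i.e. years
spent on dialysis; its `difference` row is years of dialysis avoided.)

```r
render_bia(run_bia(p))
#> # A tibble: 6 × 4
#>   year  current_usd proposed_usd impact_usd
#>   <chr>       <dbl>        <dbl>      <dbl>
#> 1 2023    231532882    235355197    3822315
#> 2 2024    278262411    281353023    3090612
#> 3 2025    324942324    327424515    2482191
#> 4 2026    371549153    373533047    1983895
#> 5 2027    418061178    419645011    1583833
#> 6 total  1624347947   1637310792   12962846
```

The budget impact declines every year as accumulated transplants convert
dialysis spending into cheaper follow-up care.

Configuration lives in YAML/JSON (see
`inst/extdata/base_case_synthetic.yaml`; regenerate with
`cmd_gen_params()`). A thin command-line wrapper ships at
`inst/cli/perfuse.R`:

```sh
Rscript inst/cli/perfuse.R run-psa --n 1000 --seed 42 --out psa_out
```

Exports are CSV: per-cycle traces and costs, the results table
(strategy columns / difference / ICER), tornado table
(`param, low, high, outcome_low, outcome_high, width`), CE-plane scatter
per outcome, the budget-impact table
(`year, current_usd, proposed_usd, impact_usd` with a totals row, rounded
to whole USD half-away-from-zero at render time only), and a
`manifest.json` with config hash, seed and file list.

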
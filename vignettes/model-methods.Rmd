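---
title: "A Markov cohort model of machine perfusion for expanded criteria donor kidneys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of machine perfusion for expanded criteria donor kidneys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfuseCE)
```

## The decision problem

Kidneys recovered from expanded criteria donors (ECD — donors older than
60 years, or 50–59 years with at least two of hypertension, cerebrovascular
cause of death, or terminal creatinine above 1.5 mg/dL) are discarded far
more often than standard criteria donor (SCD) kidneys when preserved in
static cold storage (SCS). Hypothermic machine perfusion (HMP) lets more of
these organs be transplanted. `perfuseCE` models a national waiting list
for deceased-donor kidney transplantation from the public payer's
perspective and compares two preservation policies over a five-year
horizon:

* **`ALL_SCS`** — every recovered kidney is kept in static cold storage
  (the comparator); 88% of SCD and 62% of ECD offers are utilized.
* **`HMP_FOR_ECD`** — SCD kidneys stay in cold storage; every ECD kidney is
  machine-perfused, raising ECD utilization to the SCD level of 88%.

No clinical benefit of perfusion is assumed: graft and patient survival and
the incidence of delayed graft function are identical across strategies.
The single lever is the discard rate of ECD kidneys.

## Model structure

The model is a discrete-time cohort state-transition model with a one-year
cycle. States are: on the waiting list (dialysis-dependent), alive with a
functioning graft (tracked separately by donor type and by years since
transplantation), dead on the waiting list, and dead with a functioning
graft. Within each cycle events occur in a fixed order:

1. the year's incident patients join the waiting list;
2. transplants are allocated;
3. annual mortality (8.08%) is applied to the remaining waiting list;
4. each graft compartment experiences that post-transplant year's death
   probability, then the death-censored graft-loss probability among
   survivors — graft losses return to the waiting list, indistinguishable
   from other candidates and eligible for re-transplantation from the next
   cycle;
5. surviving grafts advance one post-transplant year.

This order is a modelling choice (the source registry forecasts do not pin
it down): placing allocation before waiting-list mortality makes the
forecast yearly transplant counts achievable in every cycle, and prevents
within-cycle deaths from pre-empting organs already allocated. The engine
propagates expected values — occupancies are fractional persons — and every
test of the engine checks mass conservation: waiting list + grafts + deaths
always equals the initial list plus cumulative entrants to within 1e-6
relative tolerance.

### From transplant forecasts to organ offers

Registry forecasts give yearly *transplants performed* under current
practice, not organs offered. Under the comparator each yearly count obeys

$$\text{transplants} = \text{offers}\times(s_{SCD}\,u_{SCD} +
s_{ECD}\,u_{ECD}^{CS}),$$

with donor shares $s_{SCD}=0.81$, $s_{ECD}=0.19$ and utilizations
$u_{SCD}=0.88$, $u_{ECD}^{CS}=0.62$ (all recomputable from the 2021 São
Paulo recovery counts 1279/307 and transplant counts 1127/191).
`derive_offers()` inverts this identity, so the comparator reproduces the
forecast counts *exactly*, and both strategies draw on the same offer pool;
the intervention differs only in applying $u_{ECD}^{MP}=0.88$ to ECD
offers. Transplants are capped at the available waiting list, scaling donor
types proportionally if the cap ever binds (it does not in the base case).

## Parameters

| Parameter | Default | Units | Source class |
|---|---|---|---|
| Initial waiting list | 27 613 | persons | registry (Dec 2021) |
| Yearly entrants | 9949, 16 132, 10 913, 17 096, 11 877 | persons/y | registry forecast |
| Comparator transplants | 4994, 5117, 5242, 5370, 5502 | persons/y | registry forecast |
| Waiting-list mortality | 0.0808 | probability/y | single-centre cohort |
| Donor shares SCD/ECD | 0.81 / 0.19 | proportion | 2021 recovery counts |
| Utilization SCD, ECD-SCS, ECD-HMP | 0.88 / 0.62 / 0.88 | probability | 2021 activity |
| Transplant episode | 8254.39 | USD/event | payer reimbursement |
| Follow-up | 2715.60 | USD/graft-year | payer reimbursement |
| Hemodialysis session | 40.53 | USD/session | payer reimbursement |
| Sessions per year | 156 | sessions | 3/week × 52 |
| Cold storage per kidney | 250 | USD | **synthetic** |
| HMP per kidney | 1800 | USD | **synthetic** |
| HMP training program | 50 000 | USD/y | **synthetic** |
| Discount rate | 0.05 | fraction/y | base case (0–0.10 in DSA) |
| WTP threshold | 19 570.52 | USD | 3 GDP per capita |
| Exchange rate | 5.39 | BRL/USD | 2021 average |

Costs enter in USD; configuration files may supply any cost with a `_brl`
suffix, converted once at load. The hemodialysis schedule of 156
sessions/year is the standard thrice-weekly regimen; only the per-session
reimbursement is a published unit cost, so the schedule is an explicit,
configurable assumption.

### Synthetic stand-ins

Per-year post-transplant survival probabilities and the
preservation/perfusion cost breakdown are not public. The package
therefore generates them:

* `gen_survival_curves()` converts five-year patient and death-censored
  graft survival targets into per-year conditional probabilities whose
  cumulative product hits the target exactly. Both a constant-hazard
  (exponential) and a Weibull shape are supported because the original
  digitized annual probabilities could be either roughly constant or
  time-varying; shape 1 reduces the Weibull to the exponential. The default
  targets — patient 0.90 (SCD) / 0.85 (ECD), graft 0.88 / 0.80 — are
  plausible round numbers chosen once as fixtures and flagged
  `source: synthetic`; no package result that depends on their magnitude is
  presented as a reproduction of published survival.
* Preservation costs default to USD 250 per cold-stored kidney, USD 1800
  per perfused kidney and a USD 50 000/year program-level training cost,
  spread over the ECD kidneys perfused that year. These are order-of-
  magnitude placeholders for the unavailable itemized tables and are
  likewise flagged.

Background general-population mortality is exposed as a scalar switch
(`apply_background_to_graft`, default off): the post-transplant death
probabilities already represent all-cause mortality for graft patients, so
adding population mortality on top would double-count; the switch exists
because the interaction is not documented in the source material.

## Costing, half-cycle correction and discounting

Person-time costs — hemodialysis while wait-listed
(USD 40.53 × 156 × person-years) and post-transplant follow-up
(USD 2715.60 × graft-years) — are billed on trapezoidal person-years, the
mean of cycle-start and cycle-end occupancy. This is the standard
half-cycle correction: transitions happen mid-cycle on average. Event
costs — the transplant episode (which already includes dialysis during the
delayed-graft-function period, so no separate DGF cost is added) and
preservation per recovered kidney — are booked per event. Discounting uses
mid-cycle timing consistently: cycle $t$ (1-based) is divided by
$(1+r)^{t-0.5}$ at $r = 5\%$/year. The budget impact analysis uses the same
engine at $r = 0$ with no discounting anywhere.

## Outcomes and incremental analysis

Per strategy the model reports discounted total cost, transplants
performed, deaths (on-list and with graft), dialysis dependence, and
patients alive. Two outcome definitions were genuinely open:

* *Dialysis dependence* defaults to half-cycle-corrected waiting-list
  person-years over the horizon — time actually spent on dialysis — with an
  end-of-horizon head-count mode available, because the published table's
  basis is not stated.
* Counts are undiscounted by default while costs are discounted;
  `discount_outcomes = TRUE` discounts event counts identically to costs.
  The source material's "discount … for economic outcomes" supports either
  reading, and its printed outcome totals cannot be reconciled without the
  unavailable supplementary inputs, so both modes ship and neither is
  claimed to reproduce the printed counts.

`icer()` classifies a (Δcost, Δeffect) pair on the cost-effectiveness
plane: *dominant* (better, cheaper), *dominated* (worse, dearer), or a
tradeoff with ratio Δcost/Δeffect compared against the willingness-to-pay
threshold (USD 19 570.52 = 3 GDP per capita; 1 GDP per capita = a third of
that). When Δeffect is zero the classification rests on the cost sign
alone and no ratio is reported.

## Sensitivity analyses

**One-way DSA.** Each uncertain scalar moves to its low and high bound with
all others at base; parameters are ordered by the width of the induced
swing (tornado ordering, ties broken alphabetically). Default ranges are
±20% of base for costs, utilizations and waiting-list mortality (clipped to
valid probability ranges and to `util_ecd_mp ≥ util_ecd_cs`) and the full
0–10% for the discount rate; the published analysis's exact ranges are not
available, so all ranges are overridable. A structural note: because the
offer pool is derived by inverting the comparator's utilization identity,
moving `util_scd` rescales incremental costs and effects almost
proportionally, so the base-case ICER tornado is led by the ECD utilization
parameters — the proportion of ECD transplants in the non-perfusion cohort
is the model's dominant driver, as the source analysis also concluded in
its discussion.

**PSA.** A second-order Monte Carlo simulation (default 1000 iterations)
redraws every uncertain scalar per iteration: beta distributions for
probabilities and gamma for costs, moment-matched so each mean equals the
base value with standard deviation `cv × mean` (default `cv = 0.1`, a
synthetic choice standing in for the unavailable published distribution
table), and uniform(0, 0.10) for the discount rate. The random-number
contract is a per-iteration substream derived from the user seed by
counter, with a fixed documented parameter order: reruns are bit-identical,
reordering iterations cannot change summaries, and appending a new
parameter to the end of the draw order does not perturb existing draws.
Draws violating joint constraints (e.g. a perfused-ECD utilization below
the cold-storage draw) are redrawn within the iteration's stream, with a
bounded retry count. Summaries report, per outcome, the ICER of mean deltas
(the conventional PSA point estimate), the mean of per-iteration ratios,
and the proportions dominant, below 3 GDP and below 1 GDP per capita.

## Budget impact

`run_bia()` reruns both strategies undiscounted and tabulates per-year
scenario costs, yearly impacts (proposed − current) and five-year totals.
All identities (impact = difference, totals = column sums, total impact =
difference of totals) hold exactly on unrounded internals; rounding to
whole USD, half away from zero, happens only in `render_bia()` — published
budget-impact tables round per cell, which is why their printed cells can
disagree with their own sums by one unit. Under the synthetic defaults the
impact declines monotonically year over year as accumulated transplants
convert dialysis costs into cheaper follow-up care, reproducing the
qualitative "progressive reduction in costs" pattern.

## Validation strategy and problem sizes

The test suite validates the engine rather than any unavailable input:

* mass conservation across 100 random valid parameter sets;
* equivalence with an individual-level stochastic simulation oracle
  (integer persons, binomial transitions, the documented event order) at
  the cohort's natural scale of roughly 90 000 individuals entering the
  model, within three Monte Carlo standard errors per state per cycle for
  five random parameter sets;
* exact reproduction of every printed arithmetic identity in the published
  cost-effectiveness and budget-impact tables through the package's own
  assemblers;
* distributional calibration of the PSA (draw means within three standard
  errors at n = 1000) and byte-identical seed determinism;
* brute-force enumeration of the cost-effectiveness-plane classifier.

What passing these tests does *not* show: that the synthetic survival
curves or preservation costs match the unavailable originals, and hence
that the package's absolute deltas equal the published headline numbers
(1123 transplants, 120 deaths, USD 4 486 009). Those depend on
supplementary inputs that were never public; the package reproduces the
published *arithmetic* exactly and the published *directions* robustly,
and documents the rest as configuration.

## Known limitations

* No delayed-graft-function or graft-survival benefit of perfusion is
  modelled (deliberately, matching the conservative source design); if such
  benefits exist the intervention is undervalued here.
* No age structure, no allocation-priority rules, no uptake curve (all ECD
  kidneys switch to perfusion at once), no cost inflation over the horizon.
* Quality-adjusted life years are out of scope; ICERs are per natural unit
  (transplant, dialysis-year avoided, death avoided).
* Fractional-person cohort semantics mean small counts should be read as
  expectations, not integers.
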
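---
title: "Costing informal care: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing informal care: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecost)
```

This vignette explains the costing model `carecost` implements, the
assumptions baked into each component, the parameters worth knowing
about, what the synthetic survey generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The costing model

The pipeline is a bottom-up, prevalence-based cost-of-illness analysis
from a societal perspective over a one-year horizon (so no
discounting). Costs are quantity × unit cost per caregiver, then
survey-weighted sums over the sample. Two methodological axes are
crossed:

* **Care-time valuation.** The *opportunity cost* (OC) method values an
  hour of care at the value of the leisure hour it displaces — the
  conservative base case uses the monetary value of a non-business
  travel-time saving, with willingness-to-pay and willingness-to-accept
  estimates as sensitivity alternatives. The *proxy good* (PG) method
  values it at the market rate of the closest professional substitute,
  household care.
* **Productivity-loss horizon.** The *human capital* approach (HCA)
  counts losses over the whole remaining work year; the *friction cost*
  approach (FCA) confines them to the period an employer needs to
  replace a worker, 12 weeks here.

### Direct costs

Reported weekly care hours pass through a joint time cap before
valuation: with a floor of 6 leisure hours per day, work plus care can
occupy at most $(24-6)\times 7 = 126$ h/week, and any surplus is taken
out of *care* time only (reported paid work is never trimmed — it is the
better-measured quantity). The cap binds mostly for "around-the-clock"
reporters (168 h/week), whose reports reflect continuous availability
rather than continuous activity. Annual care-time cost is capped hours ×
weeks of care × hourly rate.

Out-of-pocket expenses arrive as monthly brackets. We value a bracket at
its midpoint, the open-ended top bracket at its lower bound (€300, a
deliberate underestimate), and convert weeks of care to months
continuously (months = weeks × 12/52) rather than rounding — rounding
would create artificial steps between caregivers who differ by a week.
A missing bracket is imputed with the value of the lowest positive
bracket (€25/month); setting `oop_missing_as_zero: true` in the
configuration switches to the strictly literal zero-cost reading.

### Indirect costs

Productivity items are assessed only for ages 16–75. All are valued at
gender-specific hourly labour costs. Three absenteeism forms:

* **PTO** (prolonged time off, workforce exit): the caregiver is not
  employed, so forgone weekly hours are imputed from a national average
  work-hours table by decadal age band (16–25 … 66–75) and gender.
  Annualisation: 46 work weeks (HCA) or 12 friction weeks (FCA).
* **TTO** (temporary time off): reported weekly work hours over an
  absence assumed to last half the caregiver's weeks of care (the median
  unemployment spell covered half the work year in the reference year);
  FCA caps the spell itself at 12 weeks.
* **RHW** (reduced hours): all reducers are assigned the *same* weekly
  loss — the weighted mean work-hour gap between employed non-caregivers
  and hour-reducing caregivers — because the survey records current, not
  counterfactual, hours. Annualisation deducts any TTO weeks already
  costed for the same person (no double counting); under FCA the
  effective weeks are additionally capped at 12.

The FCA capping is applied *per component* (PTO annualisation, TTO
spell, RHW effective weeks): the guidance merely confines losses to a
friction period, and per-component capping is the standard reading. The
TTO-week deduction inside RHW uses the duration in force under the same
approach (uncapped under HCA, capped under FCA) for internal
consistency.

**Presenteeism** converts two ordinal items into impaired weekly hours:
impairment 0/25/50% (concentration) × share of distracted working days
0/5/20/100% (frequency, on a 4-week, 5-day-week month) × weekly work
hours, annualised like RHW, HCA only — a friction period is not
meaningful for losses that occur while at work. Because the items are
not from a standardised instrument, presenteeism is computed always but
*excluded from base-case totals*; a scenario switches it on.

### Aggregation and the proxy-good netting

Under the proxy-good view, caregiving is productive work, so paid-work
time lost to caregiving is a reallocation, not a pure loss: per
caregiver, the PG care-time value is deducted from indirect costs to get
the net societal productivity loss. We floor the net at zero per
caregiver (`net_floor`, on by default): without the floor, caregivers
whose care-time value exceeds their productivity loss would appear as
net cost *reductions* and the aggregate indirect subtotal would go
negative for most populations, which contradicts how these net costs
are reported in practice. OC cells use unadjusted indirect costs in the
base case; the trade-off there is with leisure, not production.

The mean per caregiver is defined as weighted total / weighted caregiver
count. (Weighted means of per-caregiver costs differ from this by
rounding-level amounts; one convention had to be picked and this one
makes the printed tables internally consistent.) Shares are component
totals over the cell total; gender ratios are female over male weighted
totals. Context metrics divide a cell total by GDP, the weighted adult
population, and (if configured) the working population; care volume is
reported in hours and in 1836-hour FTE years.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `leisure_value` | €/h | config | OC shadow price; most conservative available estimate |
| `proxy_rate` | €/h | config | PG shadow price: household-care market rate |
| `labour_cost_by_gender` | €/h | config | productivity-loss unit cost; carries the gender wage gap |
| `work_weeks_per_year` | weeks | 46 | working year net of leave |
| `friction_weeks` | weeks | 12 | employer replacement period (FCA) |
| `leisure_floor_hours_per_day` | h/day | 6 | minimum personal time; sets the 126 h cap |
| `fte_hours_per_year` | h | 1836 | FTE conversion for context metrics |
| `net_floor` | flag | TRUE | floor PG net indirect cost at 0 per caregiver |
| `oop_missing_as_zero` | flag | FALSE | literal zero-cost imputation of missing brackets |

All monetary rates are configuration, never hard-coded: reference
prices of this kind live in national costing manuals and official
value-of-time tables that are revised over time. The shipped
`unit_costs_synthetic.yaml` carries illustrative placeholder rates in
the realistic Dutch range and is labelled as such.

## The synthetic survey generator

`generate_survey()` emulates the *marginal* structure a national
caregiving survey of ~12 000 respondents would deliver: ~36% caregiver
prevalence, 55% of caregivers female, weekly care hours with median 3
and a heavy right tail, care duration with median 52 and mean ~41
weeks, the out-of-pocket bracket distribution (59% none), employment at
~76% of caregivers aged 16–75, impact-item rates of 7% (PTO, among
non-employed), 6% (TTO, among employed) and 10% (RHW, among those who
worked in the past year), presenteeism item distributions, and gamma
expansion weights (non-informative by default; an informative mode
exists to exercise weighted-vs-unweighted divergence).

Design points:

* A shared latent severity variable couples care intensity to the
  impact flags (positively) and to employment (negatively). Joint
  distributions of this kind are not published for such surveys, so the
  coupling strengths (`severity_rho` = 0.30, `employment_rho` = 0.40)
  are modelling choices, documented as such, not empirical claims.
* Impact-flag rates are enforced by thresholding the severity-coupled
  latent score at its *within-group* quantile. A fixed marginal
  threshold would inflate, e.g., the PTO rate, because the non-employed
  group is severity-selected.
* The care-hours distribution is a log-normal body (median 3 h,
  `sdlog` = 1.12) plus a 1.5% point mass at 168 h, which exercises the
  cap logic. With that mass fixed, the capped and uncapped mean care
  hours cannot both match the population targets (the cap removes
  ~0.8 h/week in expectation here vs ~0.3 in the population, where
  around-the-clock reporters are almost all outside employment). We
  calibrated to the *capped* mean (~7.2 vs target 7.37), since capped
  hours are what every downstream cost uses; the uncapped mean runs
  ~0.4 h high.
* Weeks of care: point mass 0.574 at 52 weeks plus uniform 1–51,
  giving median 52 and mean 40.9; the realized spread (sd ≈ 16) is
  slightly tighter than survey data (≈ 17.7), which only matters for
  statistics the pipeline does not compute.

What passing tests on generated data do **not** show: fidelity of any
joint distribution (care hours × employment × gender), of item
non-response mechanisms, or of informative weighting — real expansion
weights correlate with demographics. National totals computed from the
generator are therefore *structurally* realistic (orders of magnitude,
component ranking, HCA/FCA and OC/PG orderings) but not estimates of
any real population.

## Numerical choices and degenerate inputs

* The cap floors at 0 (a 130-hour work week leaves no care budget).
* A dataset with no hour-reducing caregivers gets `rhw_delta = 0` with
  a warning rather than an error; no employed non-caregivers at all is
  an error (the comparison group is gone).
* Aggregating a file with zero weighted caregivers is an error.
* The adjusted-care-time scenario deducts annual lost work hours
  prorated over the caregiver's care weeks (lost/weeks per week),
  floored at 0, *before* capping and OC valuation; each approach uses
  its own lost-hours measure (an `adjust_approach` override pins one).
  Care time is recorded per week and lost time per year; proration is
  the minimal bridging assumption.
* CPI adjustment is a pure index ratio, multiplicative and invertible;
  unknown years fail with the list of available years.
* Scenario identity: a scenario with all-base settings reproduces the
  base case bit for bit (same code path, no re-randomisation).

## Problem sizes

The analysis scripts and the acceptance run use 12 348 respondents with
mean weight 14 222 458/12 348, i.e. a weighted population of ~14.2
million adults — the scale the costing is meant for. Generator
calibration and population-level property checks in the test suite use
100 000 respondents, where weighted marginals sit well inside their
tolerances (prevalence ±2 points, capped care hours ±0.5 h, care weeks
±1, no-OOP share ±3 points).

## Limitations

Intangible (well-being) costs, caregiver health-care utilisation, and
transaction costs of care allowances are out of scope, as are long-term
earnings losses after workforce exit — the one-year horizon cuts both
ways, also keeping HCA and FCA closer together than multi-year analyses
would find. Out-of-pocket costs above €300/month are truncated by the
bracket design. Care-time reports may include joint production with
housework; the cap mitigates only the extreme form. Standard errors for
weighted totals are not computed (point estimates only), matching how
such cost tables are conventionally reported.
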
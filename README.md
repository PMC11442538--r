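# carecost

Societal cost of informal care from caregiver survey microdata.

Informal caregivers — family members and friends providing unpaid help to
people with health problems — supply an enormous volume of care that never
appears in national accounts. `carecost` implements a bottom-up,
prevalence-based cost-of-illness pipeline that turns one year of caregiver
survey microdata into nationally representative estimates of what that care
costs society: who it is for is health economists and policy analysts doing
cost-of-illness or informal-care valuation work, who need every costing
assumption explicit, configurable and tested.

## The model

For each caregiver *i* with survey expansion weight *w<sub>i</sub>*, annual
cost is quantity × unit cost, summed over components and then over the
weighted sample:

**Direct costs**

- *Care time*: reported weekly care hours *h<sub>i</sub>* are first capped at
  the joint time budget for work plus care, 126 h/week = (24 − 6) × 7 (a
  6 h/day leisure floor); any surplus of work + care over 126 is subtracted
  from care time only. Annual cost = capped hours × weeks of care
  *k<sub>i</sub>* × unit cost, where the unit cost is the hourly value of
  leisure (opportunity cost method, OC) or the market rate of professional
  household care (proxy good method, PG).
- *Out-of-pocket*: monthly bracket midpoint (open top bracket at its lower
  bound €300; missing imputed at the lowest positive bracket) × months of
  care (*k<sub>i</sub>* × 12/52).

**Indirect (productivity) costs**, for caregivers aged 16–75, valued at
gender-specific hourly labour costs, under the human capital approach (HCA,
full losses over the 46-week work year) and the friction cost approach (FCA,
losses confined to a 12-week friction period):

- *Prolonged time off (PTO)*: workforce exit; forgone hours imputed from
  national age×gender average work hours.
- *Temporary time off (TTO)*: reported work hours over a spell assumed to
  last half the weeks of care.
- *Reduced hours at work (RHW)*: the weighted mean work-hour gap between
  non-caregivers and hour-reducing caregivers, annualised net of any TTO
  weeks already costed.
- *Presenteeism* (sensitivity only): impairment% (0/25/50) × distracted-days%
  (0/5/20/100) × work hours, HCA only.

Under the proxy-good method, indirect costs are netted per caregiver against
the production value of the care supplied (floored at zero). Weighted sums
give national totals for each of the four cells {OC, PG} × {HCA, FCA},
with means per caregiver, component shares, female-to-male ratios, and macro
context (share of GDP, FTE equivalents, per-adult contribution). A
deterministic one-way scenario engine covers the standard sensitivity
analyses (WTP/WTA leisure values, uncapped hours, care time adjusted for
lost work, presenteeism).

Because real caregiving surveys of this kind are access-restricted, the
package ships a calibrated synthetic survey generator
(`generator_spec()` / `generate_survey()`) whose weighted marginals match
the population structure the costing assumes.

## Worked example

```r
library(carecost)

costs   <- load_unit_costs(system.file("extdata", "unit_costs_synthetic.yaml",
                                       package = "carecost"))
spec    <- generator_spec(n_respondents = 12348, seed = 2019,
                          weight_mean = 14222458 / 12348)
records <- generate_survey(spec)
report  <- aggregate_costs(cost_breakdown(records, costs))
print(report)
```

The report prints one table per valuation cell; the opportunity-cost ×
human-capital cell looks like:

```
  cell oc_hca
         component       total mean share fm_ratio
         care_time 12106997575 2329    50     1.09
               oop  1465511388  282     6     1.23
   direct_subtotal 13572508962 2611    56     1.10
               rhw  1223093018  235     5     1.00
               tto  5338295005 1027    22     1.19
               pto  4028868523  775    17     0.72
 indirect_subtotal 10590256546 2037    44     0.96
             total 24162765508 4648   100     1.04
```

Reading: with the illustrative unit costs, informal care time is worth
€12.1bn a year (€2329 per caregiver, 50% of the total), out-of-pocket
spending €1.5bn, and productivity losses €10.6bn, of which temporary work
cessation is the largest piece; female caregivers bear 1.04× the costs of
male caregivers overall. Across all four cells the total runs from €17.8bn
(OC × FCA, the conservative base case) to €32.5bn (PG × HCA) — 2.2%–4.0% of
GDP, or €1251–€2286 per adult per year:

```r
ctx <- context_metrics(report$totals[["oc_fca"]],
                       cost_breakdown(records, costs), costs)
ctx$pct_of_gdp               # 2.19
ctx$fte_equivalents          # 824278 full-time care years
```

The same workflow, with narrative output and CSV tables under `results/`,
is in the numbered scripts `analysis/01_simulate.R`,
`analysis/02_base_case.R` and `analysis/03_sensitivity.R`.

All monetary rates live in a YAML/JSON configuration
(`inst/extdata/unit_costs_synthetic.yaml` is an illustrative example with
placeholder rates); structural constants default to 46 work weeks/year, a
12-week friction period, a 6 h/day leisure floor and 1836 hours/FTE.

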
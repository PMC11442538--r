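# Synthetic (illustrative) unit-cost configuration for the informal-care
# costing pipeline, expressed in 2019 euros. The monetary rates are
# placeholders in the realistic Dutch range, NOT official reference
# prices: substitute your own registry (costing-manual reference prices,
# official values of time, national accounts) for real analyses.

# hourly shadow prices for informal care time
leisure_value: 8.0        # opportunity cost: value of one leisure hour
                          # (non-business travel-time-saving equivalent)
leisure_wtp: 10.3         # willingness-to-pay value (sensitivity)
leisure_wta: 17.2         # willingness-to-accept value (sensitivity)
proxy_rate: 15.1          # proxy good: hourly rate of household care

# hourly labour cost (unit cost of productivity loss)
labour_cost_by_gender:
  male: 40.1
  female: 33.4

# national average weekly work hours by age band and gender, used to
# impute the forgone hours of caregivers who left the workforce
imputed_workhours:
  "16_25": {male: 25.0, female: 23.5}
  "26_35": {male: 37.5, female: 30.0}
  "36_45": {male: 38.0, female: 28.0}
  "46_55": {male: 37.0, female: 27.0}
  "56_65": {male: 34.0, female: 25.0}
  "66_75": {male: 20.0, female: 14.0}

# structural constants (package defaults shown; may be omitted)
work_weeks_per_year: 46
friction_weeks: 12
leisure_floor_hours_per_day: 6
fte_hours_per_year: 1836

# monthly out-of-pocket bracket valuation (midpoints; open top bracket
# at its lower bound; missing imputed with the lowest positive bracket)
oop_bracket_values:
  none: 0
  lt50: 25
  "50_100": 75
  "100_200": 150
  "200_300": 250
  gt300: 300

price_year: 2019
cpi_index:
  "2015": 100.0
  "2016": 100.3
  "2017": 101.7
  "2018": 103.4
  "2019": 106.2

# macro context constants (2019 Netherlands orders of magnitude)
macro:
  gdp: 8.13e+11
  adult_population_weighted: 14222458
  working_population_weighted: 9841000
  mean_gross_income: 36500
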
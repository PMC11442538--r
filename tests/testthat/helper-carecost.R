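# Fixtures built in code: a small unit-cost set with round numbers and
# a one-row record builder whose defaults describe an employed
# middle-aged caregiver.

make_costs <- function(...) {
  overrides <- list(...)
  base <- list(
    leisure_value = 10,
    leisure_wtp = 12,
    leisure_wta = 15,
    proxy_rate = 15,
    labour_cost_by_gender = list(male = 40, female = 30),
    imputed_workhours = list(
      `16_25` = list(male = 24, female = 22),
      `26_35` = list(male = 36, female = 30),
      `36_45` = list(male = 32, female = 28),
      `46_55` = list(male = 36, female = 27),
      `56_65` = list(male = 33, female = 24),
      `66_75` = list(male = 18, female = 12)
    ),
    price_year = 2019,
    cpi_index = list(`2015` = 100, `2018` = 104, `2019` = 105),
    macro = list(gdp = 813e9,
                 adult_population_weighted = 14222458,
                 working_population_weighted = 9841000,
                 mean_gross_income = 36500)
  )
  base[names(overrides)] <- overrides
  costs <- unit_cost_set(base)
  validate_unit_costs(costs)
  costs
}

make_record <- function(id = "c1", weight = 1, is_caregiver = TRUE,
                        gender = "female", age = 45,
                        care_hours_week = 10, care_weeks_year = 52,
                        oop_bracket = "none", employed_now = TRUE,
                        worked_past_year = TRUE, work_hours_week = 30,
                        stopped_work_prolonged = NA,
                        stopped_work_temporary = FALSE,
                        reduced_hours = FALSE,
                        distraction_freq = "rarely_never",
                        concentration_loss = "none") {
  data.frame(id = id, weight = weight, is_caregiver = is_caregiver,
             gender = gender, age = age,
             care_hours_week = care_hours_week,
             care_weeks_year = care_weeks_year,
             oop_bracket = oop_bracket, employed_now = employed_now,
             worked_past_year = worked_past_year,
             work_hours_week = work_hours_week,
             stopped_work_prolonged = stopped_work_prolonged,
             stopped_work_temporary = stopped_work_temporary,
             reduced_hours = reduced_hours,
             distraction_freq = distraction_freq,
             concentration_loss = concentration_loss,
             stringsAsFactors = FALSE)
}

make_noncaregiver <- function(id = "n1", weight = 1, gender = "male",
                              age = 40, work_hours_week = 31) {
  make_record(id = id, weight = weight, is_caregiver = FALSE,
              gender = gender, age = age, care_hours_week = NA,
              care_weeks_year = NA, oop_bracket = "missing",
              employed_now = TRUE, worked_past_year = TRUE,
              work_hours_week = work_hours_week,
              stopped_work_temporary = NA, reduced_hours = NA,
              distraction_freq = "missing",
              concentration_loss = "missing")
}
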
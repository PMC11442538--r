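test_that("the reduced-hours delta is the weighted work-hour difference", {
  recs <- rbind(
    make_noncaregiver(id = "n1", weight = 2, work_hours_week = 31.08),
    make_noncaregiver(id = "n2", weight = 1, work_hours_week = 31.08),
    make_record(id = "c1", weight = 3, reduced_hours = TRUE,
                work_hours_week = 28.93),
    make_record(id = "c2", weight = 1, reduced_hours = TRUE,
                work_hours_week = 28.93)
  )
  st <- compute_rhw_delta(recs)
  expect_equal(st$rhw_delta, 31.08 - 28.93)  # 2.15
  # identical means give a zero delta
  same <- recs
  same$work_hours_week <- 30
  expect_equal(compute_rhw_delta(same)$rhw_delta, 0)
})

test_that("weighted means agree with a spreadsheet-style oracle on a 5-row fixture", {
  recs <- rbind(
    make_noncaregiver(id = "n1", weight = 1.5, work_hours_week = 40),
    make_noncaregiver(id = "n2", weight = 0.5, work_hours_week = 20),
    make_noncaregiver(id = "n3", weight = 2.0, work_hours_week = 32),
    make_record(id = "c1", weight = 1.0, reduced_hours = TRUE,
                work_hours_week = 25),
    make_record(id = "c2", weight = 3.0, reduced_hours = TRUE,
                work_hours_week = 30)
  )
  # hand sums: non-caregivers (1.5*40 + 0.5*20 + 2*32) / 4 = 33.5
  #            reducers      (1*25 + 3*30) / 4            = 28.75
  st <- compute_rhw_delta(recs)
  expect_equal(st$mean_workhours_noncaregivers, 33.5)
  expect_equal(st$mean_workhours_reducers, 28.75)
  expect_equal(st$rhw_delta, 4.75)
})

test_that("delta is floored at zero and missing reducers warn", {
  recs <- rbind(make_noncaregiver(work_hours_week = 20),
                make_record(reduced_hours = TRUE, work_hours_week = 35))
  expect_equal(compute_rhw_delta(recs)$rhw_delta, 0)
  none <- rbind(make_noncaregiver(), make_record())
  expect_warning(st <- compute_rhw_delta(none), "no hour-reducing")
  expect_equal(st$rhw_delta, 0)
})

test_that("prolonged-cessation costs use imputed hours and the friction cap", {
  costs <- make_costs()  # imputed 36_45 male = 32, male rate 40
  rec <- make_record(gender = "male", age = 40, employed_now = FALSE,
                     work_hours_week = NA, stopped_work_prolonged = TRUE,
                     stopped_work_temporary = NA, worked_past_year = FALSE,
                     reduced_hours = FALSE)
  rec$reduced_hours <- NA
  expect_equal(pto_cost(rec, costs, "HCA"), 32 * 40 * 46)  # 58880
  expect_equal(pto_cost(rec, costs, "FCA"), 32 * 40 * 12)  # 15360
  # without the flag, or outside the 16-75 window, the cost is zero
  expect_equal(pto_cost(make_record(), costs, "HCA"), 0)
  old <- rec; old$age <- 80
  expect_equal(pto_cost(old, costs, "HCA"), 0)
  # a missing imputation cell is a configuration error
  sparse <- make_costs(imputed_workhours = list(`16_25` = list(male = 24)))
  expect_error(pto_cost(rec, sparse, "HCA"), "36_45")
})

test_that("temporary-cessation costs span half the care weeks, friction-capped", {
  costs <- make_costs()  # male rate 40
  rec <- make_record(gender = "male", care_weeks_year = 40,
                     work_hours_week = 30, stopped_work_temporary = TRUE)
  expect_equal(tto_cost(rec, costs, "HCA"), 30 * 20 * 40)  # 24000
  expect_equal(tto_cost(rec, costs, "FCA"), 30 * 12 * 40)  # min(20,12)=12
  short <- rec; short$care_weeks_year <- 20
  expect_equal(tto_cost(short, costs, "FCA"), 30 * 10 * 40)  # under cap
  # missing work hours for a flagged record is a record-level error
  broken <- rec; broken$work_hours_week <- NA
  expect_error(tto_cost(broken, costs, "HCA"), "work hours")
})

test_that("reduced-hours costs deduct time off to avoid double counting", {
  costs <- make_costs()
  st <- structure(list(rhw_delta = 2.15), class = "population_work_stats")
  rec <- make_record(gender = "male", reduced_hours = TRUE)
  expect_equal(rhw_cost(rec, st, costs, "HCA"), 2.15 * 40 * 46)  # 3956
  # with a 40-week care year and temporary time off, 20 weeks come off
  both <- make_record(gender = "male", reduced_hours = TRUE,
                      stopped_work_temporary = TRUE, care_weeks_year = 40)
  expect_equal(rhw_cost(both, st, costs, "HCA"), 2.15 * 40 * 26)  # 2236
  # friction approach: effective weeks capped at 12
  expect_equal(rhw_cost(rec, st, costs, "FCA"), 2.15 * 40 * 12)
  zero <- structure(list(rhw_delta = 0), class = "population_work_stats")
  expect_equal(rhw_cost(rec, zero, costs, "HCA"), 0)
})

test_that("presenteeism converts item levels to impaired hours", {
  costs <- make_costs()
  # a bit (25%) x weekly (20%) x 30 h = 1.5 impaired hours per week
  rec <- make_record(gender = "male", concentration_loss = "a_bit",
                     distraction_freq = "weekly", work_hours_week = 30)
  expect_equal(presenteeism_cost(rec, costs), 0.25 * 0.20 * 30 * 40 * 46)
  worst <- make_record(gender = "male", concentration_loss = "very_much",
                       distraction_freq = "daily", work_hours_week = 40)
  expect_equal(presenteeism_cost(worst, costs), 0.5 * 1 * 40 * 40 * 46)  # 36800
  # no impairment, or missing items, means no presenteeism cost
  expect_equal(presenteeism_cost(make_record(), costs), 0)
  missing <- make_record(concentration_loss = "missing",
                         distraction_freq = "daily")
  expect_equal(presenteeism_cost(missing, costs), 0)
})

test_that("friction-cost components never exceed their human-capital twins", {
  costs <- make_costs()
  rec <- generate_survey(generator_spec(n_respondents = 5000, seed = 19))
  ind <- indirect_costs(rec, costs)
  expect_true(all(ind$pto_fca <= ind$pto_hca))
  expect_true(all(ind$tto_fca <= ind$tto_hca))
  expect_true(all(ind$rhw_fca <= ind$rhw_hca))
  expect_true(all(ind$lost_work_hours_fca <= ind$lost_work_hours_hca))
  # equality exactly when the duration already sits within the friction period
  short_tto <- tto_mask(rec) & rec$care_weeks_year / 2 <= costs$friction_weeks
  expect_equal(ind$tto_hca[short_tto], ind$tto_fca[short_tto])
  long_tto <- tto_mask(rec) & rec$care_weeks_year / 2 > costs$friction_weeks
  expect_true(all(ind$tto_fca[long_tto] < ind$tto_hca[long_tto]))
  # costs and forgone hours are proportional through the gender rate
  rate <- ifelse(rec$gender == "female", 30, 40)
  expect_equal(ind$pto_hca + ind$tto_hca + ind$rhw_hca,
               ind$lost_work_hours_hca * rate)
})

test_that("zeroing every impact flag zeroes all indirect costs", {
  rec <- generate_survey(generator_spec(n_respondents = 2000, seed = 23))
  rec$stopped_work_prolonged[!is.na(rec$stopped_work_prolonged)] <- FALSE
  rec$stopped_work_temporary[!is.na(rec$stopped_work_temporary)] <- FALSE
  rec$reduced_hours[!is.na(rec$reduced_hours)] <- FALSE
  rec$concentration_loss[rec$concentration_loss != "missing"] <- "none"
  ind <- suppressWarnings(indirect_costs(rec, make_costs()))
  expect_true(all(as.matrix(ind[, !grepl("lost", names(ind))]) == 0))
})
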
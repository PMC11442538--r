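test_that("an all-base scenario reproduces the base case bit-for-bit", {
  costs <- make_costs()
  rec <- generate_survey(generator_spec(n_respondents = 3000, seed = 47))
  st <- compute_rhw_delta(rec)
  base <- aggregate_costs(cost_breakdown(rec, costs, work_stats = st))
  res <- run_scenario(rec, costs, scenario("base"), base = base,
                      work_stats = st)
  expect_identical(res$totals, base$totals)
  expect_equal(unname(res$pct_change_vs_base), rep(0, 4))
})

test_that("a leisure-rate override changes only care time, linearly", {
  costs <- make_costs()  # base 10, wtp 12
  rec <- generate_survey(generator_spec(n_respondents = 3000, seed = 53))
  st <- compute_rhw_delta(rec)
  base <- aggregate_costs(cost_breakdown(rec, costs, work_stats = st))
  res <- run_scenario(rec, costs, scenario("wtp", "wtp"), base = base,
                      work_stats = st)
  caretime <- base$cells$oc_hca$total[
    base$cells$oc_hca$component == "care_time"]
  expect_equal(unname(res$totals["oc_hca"] - base$totals["oc_hca"]),
               caretime * (12 / 10 - 1))
  # proxy-good cells do not use the leisure value at all
  expect_equal(res$totals["pg_hca"], base$totals["pg_hca"])
  # WTA >= WTP >= base implies ordered opportunity-cost totals
  wta <- run_scenario(rec, costs, scenario("wta", "wta"), base = base,
                      work_stats = st)
  expect_gte(unname(wta$totals["oc_hca"]), unname(res$totals["oc_hca"]))
  expect_gte(unname(res$totals["oc_hca"]), unname(base$totals["oc_hca"]))
  # requesting an unconfigured rate is an error
  no_wta <- make_costs(leisure_wta = NULL)
  expect_error(run_scenario(rec, no_wta, scenario("wta", "wta"),
                            base = base, work_stats = st),
               "not configured")
})

test_that("removing the weekly cap never decreases the total", {
  costs <- make_costs()
  rec <- generate_survey(generator_spec(n_respondents = 5000, seed = 59))
  st <- compute_rhw_delta(rec)
  base <- aggregate_costs(cost_breakdown(rec, costs, work_stats = st))
  res <- run_scenario(rec, costs, scenario("uncapped", apply_cap = FALSE),
                      base = base, work_stats = st)
  expect_true(all(res$pct_change_vs_base >= 0))
  # with no cap violations in the data the change is exactly zero
  tame <- rec
  tame$care_hours_week[tame$is_caregiver] <-
    pmin(tame$care_hours_week[tame$is_caregiver], 20)
  tame$work_hours_week <- pmin(tame$work_hours_week, 40)
  st2 <- compute_rhw_delta(tame)
  base2 <- aggregate_costs(cost_breakdown(tame, costs, work_stats = st2))
  res2 <- run_scenario(tame, costs, scenario("uncapped", apply_cap = FALSE),
                       base = base2, work_stats = st2)
  expect_equal(unname(res2$pct_change_vs_base), rep(0, 4))
})

test_that("adjusting care time for lost work never raises the OC total", {
  costs <- make_costs()
  rec <- generate_survey(generator_spec(n_respondents = 5000, seed = 61))
  st <- compute_rhw_delta(rec)
  base <- aggregate_costs(cost_breakdown(rec, costs, work_stats = st))
  res <- run_scenario(rec, costs,
                      scenario("adjusted", adjust_care_time = TRUE),
                      base = base, work_stats = st)
  expect_lte(unname(res$totals["oc_hca"]), unname(base$totals["oc_hca"]))
  expect_lte(unname(res$totals["oc_fca"]), unname(base$totals["oc_fca"]))
  # bounded by the opportunity-cost value of the lost work hours
  ind <- indirect_costs(rec, costs, st)
  bound <- sum(rec$weight * ind$lost_work_hours_hca) * costs$leisure_value
  expect_lte(unname(base$totals["oc_hca"] - res$totals["oc_hca"]), bound)
  # with all impact flags cleared there is nothing to deduct
  calm <- rec
  calm$stopped_work_prolonged[!is.na(calm$stopped_work_prolonged)] <- FALSE
  calm$stopped_work_temporary[!is.na(calm$stopped_work_temporary)] <- FALSE
  calm$reduced_hours[!is.na(calm$reduced_hours)] <- FALSE
  st3 <- suppressWarnings(compute_rhw_delta(calm))
  base3 <- aggregate_costs(cost_breakdown(calm, costs, work_stats = st3))
  res3 <- run_scenario(calm, costs,
                       scenario("adjusted", adjust_care_time = TRUE),
                       base = base3, work_stats = st3)
  expect_equal(unname(res3$pct_change_vs_base), rep(0, 4))
})

test_that("including presenteeism adds exactly its weighted total", {
  costs <- make_costs()
  rec <- generate_survey(generator_spec(n_respondents = 4000, seed = 67))
  st <- compute_rhw_delta(rec)
  base <- aggregate_costs(cost_breakdown(rec, costs, work_stats = st))
  res <- run_scenario(rec, costs,
                      scenario("presenteeism", include_presenteeism = TRUE),
                      base = base, work_stats = st)
  pres_total <- sum(rec$weight * presenteeism_cost(rec, costs))
  expect_equal(unname(res$totals["oc_hca"] - base$totals["oc_hca"]),
               pres_total)
  # proxy-good cells may absorb part of it through the net floor
  expect_lte(unname(res$totals["pg_hca"] - base$totals["pg_hca"]),
             pres_total + 1e-9)
})

test_that("the scenario table is tornado-ordered by change magnitude", {
  costs <- make_costs()
  rec <- generate_survey(generator_spec(n_respondents = 2000, seed = 71))
  st <- compute_rhw_delta(rec)
  base <- aggregate_costs(cost_breakdown(rec, costs, work_stats = st))
  only_base <- scenario_table(list(
    run_scenario(rec, costs, scenario("base"), base = base,
                 work_stats = st)))
  expect_equal(nrow(only_base), 4)
  expect_true(all(only_base$pct_change == 0))
  results <- list(
    run_scenario(rec, costs, scenario("wtp", "wtp"), base = base,
                 work_stats = st),
    run_scenario(rec, costs, scenario("wta", "wta"), base = base,
                 work_stats = st))
  tab <- scenario_table(results)
  expect_equal(nrow(tab), 8)
  expect_true(!is.unsorted(rev(abs(tab$pct_change))))
  expect_equal(tab$scenario[1], "wta")
})
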
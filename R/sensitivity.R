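#' Define a one-way sensitivity scenario
#'
#' A scenario is the base-case pipeline with one assumption varied:
#' an alternative leisure-time value (willingness-to-pay or
#' willingness-to-accept instead of the travel-time-saving base value)
#' in the opportunity-cost valuation, removal of the 126-hour weekly
#' time cap, deduction of lost paid-work time from reported care time
#' before the opportunity-cost valuation, or inclusion of presenteeism
#' in the indirect costs. Multi-way combinations are allowed but should
#' be labelled as such.
#'
#' @param name Scenario label.
#' @param leisure_rate_override `"base"`, `"wtp"`, or `"wta"`.
#' @param apply_cap Keep the weekly time cap (default `TRUE`).
#' @param adjust_care_time Deduct lost paid-work time from care time in
#'   the opportunity-cost valuation.
#' @param include_presenteeism Add presenteeism to indirect costs.
#' @param adjust_approach Optional `"HCA"`/`"FCA"` override for the
#'   lost-hours measure used by `adjust_care_time` (each approach uses
#'   its own by default).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name,
                     leisure_rate_override = c("base", "wtp", "wta"),
                     apply_cap = TRUE,
                     adjust_care_time = FALSE,
                     include_presenteeism = FALSE,
                     adjust_approach = NULL) {
  structure(list(name = name,
                 leisure_rate_override = match.arg(leisure_rate_override),
                 apply_cap = apply_cap,
                 adjust_care_time = adjust_care_time,
                 include_presenteeism = include_presenteeism,
                 adjust_approach = adjust_approach),
            class = "scenario")
}

#' Percentage change of a scenario total against the base case
#' @param total Scenario total.
#' @param base Base-case total.
#' @export
pct_change <- function(total, base) {
  (total - base) / base * 100
}

scenario_leisure_rate <- function(sc, costs) {
  switch(sc$leisure_rate_override,
         base = costs$leisure_value,
         wtp = costs$leisure_wtp,
         wta = costs$leisure_wta)
}

#' Run a sensitivity scenario over the full costing pipeline
#'
#' Re-runs [cost_breakdown()] and [aggregate_costs()] under the
#' scenario's assumptions and reports the national total of every
#' method-by-approach cell together with its percentage change against
#' the base case. A scenario with all-base settings reproduces the base
#' case exactly.
#'
#' @param records `caregiver_microdata`.
#' @param costs A [unit_cost_set()]; must supply `leisure_wtp`/
#'   `leisure_wta` when the scenario requests them.
#' @param sc A [scenario()].
#' @param base Optional base-case [aggregate_costs()] report; computed
#'   when omitted.
#' @param work_stats Optional precomputed [compute_rhw_delta()].
#' @return A list of class `scenario_result`: `scenario`, `totals`
#'   (named per cell), `pct_change_vs_base` (named per cell), `report`.
#' @export
run_scenario <- function(records, costs, sc, base = NULL,
                         work_stats = NULL) {
  stopifnot(inherits(sc, "scenario"))
  rate <- scenario_leisure_rate(sc, costs)
  if (is.null(rate)) {
    stop("scenario '", sc$name, "' requests the ",
         sc$leisure_rate_override, " leisure value, which is not ",
         "configured", call. = FALSE)
  }
  if (is.null(work_stats)) work_stats <- compute_rhw_delta(records)
  if (is.null(base)) {
    base <- aggregate_costs(cost_breakdown(records, costs,
                                           work_stats = work_stats))
  }
  bd <- cost_breakdown(records, costs,
                       include_presenteeism = sc$include_presenteeism,
                       apply_cap = sc$apply_cap,
                       leisure_rate = rate,
                       adjust_care_time = sc$adjust_care_time,
                       adjust_approach = sc$adjust_approach,
                       work_stats = work_stats)
  rep <- aggregate_costs(bd)
  structure(list(scenario = sc,
                 totals = rep$totals,
                 pct_change_vs_base = pct_change(rep$totals,
                                                 base$totals),
                 report = rep),
            class = "scenario_result")
}

#' Tornado-ordered sensitivity table
#'
#' One row per scenario and method-by-approach cell, sorted by the
#' magnitude of the percentage change against the base case.
#'
#' @param results List of [run_scenario()] results (the base case may be
#'   among them).
#' @return Data frame with columns `scenario`, `cell`, `total`,
#'   `pct_change`, ordered by decreasing `|pct_change|`.
#' @export
scenario_table <- function(results) {
  stopifnot(length(results) >= 1)
  rows <- do.call(rbind, lapply(results, function(res) {
    data.frame(scenario = res$scenario$name,
               cell = names(res$totals),
               total = unname(res$totals),
               pct_change = unname(res$pct_change_vs_base),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rows[order(-abs(rows$pct_change)), , drop = FALSE]
}
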
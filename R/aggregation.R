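#' Net indirect (productivity) cost under the proxy-good view
#'
#' The proxy-good method treats informal care as productive work, so
#' shifting time from paid work to caregiving is a reallocation of
#' labour, not a pure loss. The net societal productivity loss per
#' caregiver deducts the proxy-good value of their care time from their
#' indirect (productivity) costs. By default the result is floored at
#' zero per caregiver — the reallocation never turns a caregiver into a
#' net cost reduction — controllable via the `net_floor` configuration
#' switch.
#'
#' @param indirect Annual indirect (productivity) cost per caregiver.
#' @param caretime_pg Annual proxy-good care-time cost per caregiver.
#' @param floor Floor the net cost at zero (default `TRUE`).
#' @return Net indirect cost, vectorised.
#' @examples
#' net_indirect_proxy(1000, 400)  # 600
#' net_indirect_proxy(400, 1000)  # 0 (floored)
#' @export
net_indirect_proxy <- function(indirect, caretime_pg, floor = TRUE) {
  net <- indirect - caretime_pg
  if (floor) net <- pmax(0, net)
  net
}

#' Per-caregiver cost breakdown for every method-by-approach cell
#'
#' Runs the direct- and indirect-cost modules over a survey file and
#' assembles, for each respondent, the component costs and the
#' direct/indirect/total subtotals of each of the four cells:
#' {opportunity cost, proxy good} x {human capital, friction cost}.
#' Opportunity-cost cells use unadjusted indirect costs; proxy-good
#' cells use the net indirect cost ([net_indirect_proxy()]).
#' Non-caregivers carry zero cost but stay in the table.
#'
#' @param records `caregiver_microdata`.
#' @param costs A [unit_cost_set()].
#' @param include_presenteeism Add the human-capital presenteeism cost
#'   to the indirect subtotal of every cell (sensitivity scenario;
#'   excluded from the base case).
#' @param apply_cap Apply the 126-hour weekly time budget to care hours.
#' @param leisure_rate Override for the opportunity-cost hourly rate.
#' @param adjust_care_time Deduct each caregiver's lost paid-work time
#'   (prorated over their care weeks) from their reported care hours
#'   before the opportunity-cost valuation; each approach uses its own
#'   lost-hours measure unless `adjust_approach` pins one.
#' @param adjust_approach Optional `"HCA"`/`"FCA"` forcing both
#'   opportunity-cost cells to deduct the same lost-hours measure.
#' @param work_stats Optional precomputed [compute_rhw_delta()].
#' @return A data frame of class `cost_breakdown`, one row per
#'   respondent, with id/weight/gender columns, component costs, and
#'   `direct_`, `indirect_`, `total_` columns for each cell
#'   (`oc_hca`, `oc_fca`, `pg_hca`, `pg_fca`).
#' @export
cost_breakdown <- function(records, costs,
                           include_presenteeism = FALSE,
                           apply_cap = TRUE,
                           leisure_rate = NULL,
                           adjust_care_time = FALSE,
                           adjust_approach = NULL,
                           work_stats = NULL) {
  if (is.null(work_stats)) work_stats <- compute_rhw_delta(records)
  ind <- indirect_costs(records, costs, work_stats)
  dc <- direct_costs(records, costs, apply_cap = apply_cap,
                     leisure_rate = leisure_rate)

  oc_caretime <- list(hca = dc$care_time_cost_oc,
                      fca = dc$care_time_cost_oc)
  if (adjust_care_time) {
    for (app in c("hca", "fca")) {
      src <- if (is.null(adjust_approach)) app else tolower(adjust_approach)
      lost <- ind[[paste0("lost_work_hours_", src)]]
      adj_hours <- pmax(0, records$care_hours_week -
                          lost / records$care_weeks_year)
      dca <- direct_costs(records, costs, apply_cap = apply_cap,
                          leisure_rate = leisure_rate,
                          care_hours_override = adj_hours)
      oc_caretime[[app]] <- dca$care_time_cost_oc
    }
  }

  pres <- if (include_presenteeism) ind$presenteeism_hca else 0
  ind_total <- list(hca = ind$pto_hca + ind$tto_hca + ind$rhw_hca + pres,
                    fca = ind$pto_fca + ind$tto_fca + ind$rhw_fca + pres)
  floor_net <- !isFALSE(costs$net_floor)

  out <- data.frame(id = records$id,
                    weight = records$weight,
                    is_caregiver = records$is_caregiver,
                    gender = records$gender,
                    care_weeks_year = records$care_weeks_year,
                    stringsAsFactors = FALSE)
  out <- cbind(out, dc, ind)
  for (app in c("hca", "fca")) {
    direct_oc <- oc_caretime[[app]] + dc$oop_cost
    out[[paste0("care_time_cost_oc_", app)]] <- oc_caretime[[app]]
    out[[paste0("direct_oc_", app)]] <- direct_oc
    out[[paste0("indirect_oc_", app)]] <- ind_total[[app]]
    out[[paste0("total_oc_", app)]] <- direct_oc + ind_total[[app]]
    direct_pg <- dc$care_time_cost_pg + dc$oop_cost
    net <- net_indirect_proxy(ind_total[[app]], dc$care_time_cost_pg,
                              floor = floor_net)
    out[[paste0("direct_pg_", app)]] <- direct_pg
    out[[paste0("indirect_pg_", app)]] <- net
    out[[paste0("total_pg_", app)]] <- direct_pg + net
  }
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

#' Mean annual cost per caregiver
#'
#' Convention: national (weighted) total divided by the weighted number
#' of caregivers.
#' @param total National total cost.
#' @param weighted_caregivers Weighted caregiver count.
#' @return Mean cost per caregiver.
#' @export
mean_per_caregiver <- function(total, weighted_caregivers) {
  total / weighted_caregivers
}

#' Share of a component in a cell total, in percent
#' @param component_total,cell_total National totals.
#' @export
component_share <- function(component_total, cell_total) {
  component_total / cell_total * 100
}

#' Female-to-male cost ratio
#' @param female_total,male_total National totals by gender.
#' @export
female_male_ratio <- function(female_total, male_total) {
  female_total / male_total
}

#' Survey-weighted national aggregate report
#'
#' Aggregates a [cost_breakdown()] into Table-style national estimates
#' for each requested cell: component totals (weighted sums), mean per
#' caregiver (total over the weighted caregiver count), component
#' shares of the cell total, and female-to-male cost ratios.
#' Opportunity-cost cells itemise the indirect components; proxy-good
#' cells report the net indirect subtotal.
#'
#' @param breakdown A [cost_breakdown()].
#' @param cells Character vector among `"oc_hca"`, `"oc_fca"`,
#'   `"pg_hca"`, `"pg_fca"`.
#' @return A list of class `aggregate_report`: `cells` (named list of
#'   data frames with columns `component`, `total`, `mean`, `share`,
#'   `fm_ratio`), `weighted_caregivers`, `weighted_population`, and
#'   `totals` (named numeric of cell totals).
#' @export
aggregate_costs <- function(breakdown,
                            cells = c("oc_hca", "oc_fca",
                                      "pg_hca", "pg_fca")) {
  w <- breakdown$weight
  n_cg <- sum(w[breakdown$is_caregiver %in% TRUE])
  if (n_cg <= 0) {
    stop("weighted caregiver count is zero; nothing to aggregate",
         call. = FALSE)
  }
  female <- breakdown$gender == "female"
  wtot <- function(x) sum(w * x)
  cell_table <- function(cell) {
    method <- sub("_.*", "", cell)
    app <- sub(".*_", "", cell)
    comps <- if (method == "oc") {
      list(care_time = breakdown[[paste0("care_time_cost_oc_", app)]],
           oop = breakdown$oop_cost,
           direct_subtotal = breakdown[[paste0("direct_oc_", app)]],
           rhw = breakdown[[paste0("rhw_", app)]],
           tto = breakdown[[paste0("tto_", app)]],
           pto = breakdown[[paste0("pto_", app)]],
           indirect_subtotal = breakdown[[paste0("indirect_oc_", app)]],
           total = breakdown[[paste0("total_oc_", app)]])
    } else {
      list(care_time = breakdown$care_time_cost_pg,
           oop = breakdown$oop_cost,
           direct_subtotal = breakdown[[paste0("direct_pg_", app)]],
           indirect_subtotal = breakdown[[paste0("indirect_pg_", app)]],
           total = breakdown[[paste0("total_pg_", app)]])
    }
    totals <- vapply(comps, wtot, numeric(1))
    f_tot <- vapply(comps, function(x) sum((w * x)[female]), numeric(1))
    m_tot <- vapply(comps, function(x) sum((w * x)[!female]), numeric(1))
    data.frame(component = names(comps),
               total = unname(totals),
               mean = mean_per_caregiver(unname(totals), n_cg),
               share = component_share(unname(totals),
                                       totals[["total"]]),
               fm_ratio = female_male_ratio(unname(f_tot),
                                            unname(m_tot)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  cell_list <- lapply(stats::setNames(cells, cells), cell_table)
  totals <- vapply(cell_list, function(tb) {
    tb$total[tb$component == "total"]
  }, numeric(1))
  structure(list(cells = cell_list,
                 weighted_caregivers = n_cg,
                 weighted_population = sum(w),
                 totals = totals),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("Survey-weighted national informal-care cost report\n")
  cat(sprintf("  weighted population: %.0f  (caregivers: %.0f)\n",
              x$weighted_population, x$weighted_caregivers))
  for (nm in names(x$cells)) {
    cat("\n  cell", nm, "\n")
    tb <- x$cells[[nm]]
    tb$total <- round(tb$total)
    tb$mean <- round(tb$mean)
    tb$share <- round(tb$share)
    tb$fm_ratio <- round(tb$fm_ratio, 2)
    print(tb, row.names = FALSE)
  }
  invisible(x)
}

#' Full-time-equivalent work years represented by a volume of hours
#' @param hours Total annual hours.
#' @param fte_hours_per_year Hours per FTE year (default 1836).
#' @export
fte_equivalents <- function(hours, fte_hours_per_year = 1836) {
  hours / fte_hours_per_year
}

#' Cost as a percentage of GDP
#' @param total National total cost.
#' @param gdp Gross domestic product, same units.
#' @export
pct_of_gdp <- function(total, gdp) {
  total / gdp * 100
}

#' Cost per adult if spread uniformly over the adult population
#' @param total National total cost.
#' @param adults Weighted adult population count.
#' @export
per_adult_cost <- function(total, adults) {
  total / adults
}

#' Total weighted annual hours of informal care
#'
#' Sum over caregivers of weight x capped weekly care hours x weeks of
#' care.
#' @param breakdown A [cost_breakdown()].
#' @export
total_care_hours <- function(breakdown) {
  cg <- breakdown$is_caregiver %in% TRUE
  sum(breakdown$weight[cg] * breakdown$care_hours_capped[cg] *
        breakdown$care_weeks_year[cg])
}

#' Macro context metrics for a national cost estimate
#'
#' Places a national informal-care cost total in context: total annual
#' care hours and their full-time-equivalent work years, the share of
#' GDP, the per-adult contribution were the cost spread over the adult
#' population, and (when a working population is configured) the
#' per-worker tax-equivalent contribution.
#'
#' @param total National total cost for one cell.
#' @param breakdown The [cost_breakdown()] behind it (for care hours).
#' @param costs A [unit_cost_set()] whose `macro` block supplies `gdp`,
#'   `adult_population_weighted`, and optionally
#'   `working_population_weighted` and `mean_gross_income`.
#' @return A list with `total_care_hours`, `fte_equivalents`,
#'   `pct_of_gdp`, `per_adult_contribution`,
#'   `per_worker_tax_equivalent` (NA when not configured), and
#'   `tax_equivalent_pct_income` (NA when not configured).
#' @export
context_metrics <- function(total, breakdown, costs) {
  macro <- costs$macro
  if (is.null(macro$gdp) || is.null(macro$adult_population_weighted)) {
    stop("macro context constants (gdp, adult_population_weighted) are ",
         "not configured", call. = FALSE)
  }
  hours <- total_care_hours(breakdown)
  per_worker <- NA_real_
  tax_pct <- NA_real_
  if (!is.null(macro$working_population_weighted)) {
    per_worker <- total / macro$working_population_weighted
    if (!is.null(macro$mean_gross_income)) {
      tax_pct <- per_worker / macro$mean_gross_income * 100
    }
  }
  list(total_care_hours = hours,
       fte_equivalents = fte_equivalents(hours, costs$fte_hours_per_year),
       pct_of_gdp = pct_of_gdp(total, macro$gdp),
       per_adult_contribution = per_adult_cost(
         total, macro$adult_population_weighted),
       per_worker_tax_equivalent = per_worker,
       tax_equivalent_pct_income = tax_pct)
}
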
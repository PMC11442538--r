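#' Cap weekly care hours at the joint work-plus-care time budget
#'
#' Caregivers of severely dependent people sometimes report providing
#' care around the clock. With a minimum of 6 leisure hours per day, at
#' most (24 - 6) x 7 = 126 hours per week are available for paid work and
#' informal care together. When reported work plus care exceeds that
#' budget, the surplus is subtracted from the reported care time only
#' (work time is never reduced), floored at zero.
#'
#' @param care_hours Reported weekly care hours (1-168), vectorised.
#' @param work_hours Weekly paid work hours (0 for non-workers).
#' @param costs Optional [unit_cost_set()] supplying the leisure floor;
#'   when omitted, `cap` is used directly.
#' @param cap Weekly time budget in hours (default 126).
#' @return Capped weekly care hours.
#' @examples
#' cap_care_hours(168, 0)   # 126
#' cap_care_hours(100, 60)  # 66
#' cap_care_hours(50, 40)   # 50, under the budget
#' @export
cap_care_hours <- function(care_hours, work_hours, costs = NULL,
                           cap = 126) {
  if (!is.null(costs)) cap <- weekly_time_cap(costs)
  ifelse(care_hours + work_hours <= cap,
         care_hours,
         pmax(0, cap - work_hours))
}

#' Annual cost of informal care time
#'
#' Unit-cost times quantity: weekly (capped) care hours times the hourly
#' shadow price, annualised over the reported weeks of care. The same
#' operation serves both valuation methods — pass the leisure-time value
#' for the opportunity-cost method or the household-care market rate for
#' the proxy-good method.
#'
#' @param capped_hours Weekly care hours after [cap_care_hours()].
#' @param weeks Weeks of care in the year (1-52).
#' @param rate Hourly shadow price.
#' @return Annual cost, vectorised.
#' @export
care_time_cost <- function(capped_hours, weeks, rate) {
  capped_hours * rate * weeks
}

#' Annual out-of-pocket cost from a monthly expense bracket
#'
#' The monthly amount is the midpoint of the reported bracket (none 0,
#' lt50 25, 50_100 75, 100_200 150, 200_300 250) with the open-ended top
#' bracket valued at 300; a missing bracket is imputed with the lowest
#' positive bracket's value. The annual cost multiplies the monthly
#' amount by the months of care, converted continuously from care weeks
#' (months = weeks x 12/52).
#'
#' @param bracket Character vector of bracket labels.
#' @param weeks Weeks of care in the year.
#' @param costs A [unit_cost_set()] supplying `oop_bracket_values`.
#' @return Annual out-of-pocket cost.
#' @export
oop_cost <- function(bracket, weeks, costs) {
  values <- unlist(costs$oop_bracket_values)
  unknown <- setdiff(unique(bracket), names(values))
  if (length(unknown)) {
    stop("unknown out-of-pocket bracket label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  monthly <- values[bracket]
  unname(monthly * weeks * 12 / 52)
}

#' Per-caregiver annual direct costs
#'
#' Computes, for every caregiver row, the jointly capped weekly care
#' hours, the annual care-time cost under both the opportunity-cost
#' (leisure value) and proxy-good (household-care rate) methods, and the
#' annual out-of-pocket cost. Non-caregiver rows get zeros.
#'
#' @param records `caregiver_microdata`.
#' @param costs A [unit_cost_set()].
#' @param apply_cap Apply the 126-hour weekly time budget (disabled in
#'   the uncapped sensitivity scenario).
#' @param leisure_rate Override for the opportunity-cost hourly rate
#'   (used by the willingness-to-pay/accept scenarios); defaults to
#'   `costs$leisure_value`.
#' @param care_hours_override Optional vector of adjusted weekly care
#'   hours (aligned with `records`) replacing the reported hours in the
#'   opportunity-cost valuation only, as in the adjusted-care-time
#'   scenario.
#' @return Data frame with columns `care_hours_capped`,
#'   `care_time_cost_oc`, `care_time_cost_pg`, `oop_cost`.
#' @export
direct_costs <- function(records, costs, apply_cap = TRUE,
                         leisure_rate = NULL,
                         care_hours_override = NULL) {
  if (is.null(leisure_rate)) leisure_rate <- costs$leisure_value
  n <- nrow(records)
  out <- data.frame(care_hours_capped = numeric(n),
                    care_time_cost_oc = numeric(n),
                    care_time_cost_pg = numeric(n),
                    oop_cost = numeric(n))
  cg <- records$is_caregiver %in% TRUE
  if (!any(cg)) return(out)
  r <- records[cg, ]
  work_for_cap <- ifelse(r$employed_now %in% TRUE &
                           !is.na(r$work_hours_week),
                         r$work_hours_week, 0)
  cap_fn <- function(h) {
    if (apply_cap) cap_care_hours(h, work_for_cap, costs) else h
  }
  capped <- cap_fn(r$care_hours_week)
  out$care_hours_capped[cg] <- capped
  out$care_time_cost_pg[cg] <-
    care_time_cost(capped, r$care_weeks_year, costs$proxy_rate)
  oc_hours <- capped
  if (!is.null(care_hours_override)) {
    oc_hours <- cap_fn(care_hours_override[cg])
  }
  out$care_time_cost_oc[cg] <-
    care_time_cost(oc_hours, r$care_weeks_year, leisure_rate)
  out$oop_cost[cg] <- oop_cost(r$oop_bracket, r$care_weeks_year, costs)
  out
}
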
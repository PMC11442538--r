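PRESENTEEISM_IMPAIRMENT <- c(none = 0, a_bit = 0.25, very_much = 0.50,
                             missing = 0)
PRESENTEEISM_DISTRACTION <- c(daily = 1.00, weekly = 0.20, monthly = 0.05,
                              rarely_never = 0, missing = 0)

#' Population work-hours statistics for the reduced-hours costing
#'
#' The weekly productivity loss of caregivers who reduced their working
#' hours is valued at the mean difference in weekly work hours between
#' employed non-caregivers and hour-reducing caregivers, computed once
#' per dataset (survey-weighted) and applied uniformly to all reducers.
#'
#' @param records `caregiver_microdata` containing both caregivers and
#'   non-caregivers.
#' @return A list of class `population_work_stats` with
#'   `mean_workhours_noncaregivers`, `mean_workhours_reducers`, and
#'   `rhw_delta` (their difference, floored at 0).
#' @export
compute_rhw_delta <- function(records) {
  nc <- records[!records$is_caregiver %in% TRUE &
                  !is.na(records$work_hours_week), ]
  elig <- productivity_eligible(records)
  red <- records[records$is_caregiver %in% TRUE & elig &
                   records$reduced_hours %in% TRUE &
                   !is.na(records$work_hours_week), ]
  if (nrow(nc) == 0) {
    stop("no employed non-caregivers in the data; cannot compute the ",
         "reduced-hours work-hour difference", call. = FALSE)
  }
  mean_nc <- stats::weighted.mean(nc$work_hours_week, nc$weight)
  if (nrow(red) == 0) {
    warning("no hour-reducing caregivers; reduced-hours delta set to 0")
    mean_red <- mean_nc
  } else {
    mean_red <- stats::weighted.mean(red$work_hours_week, red$weight)
  }
  structure(list(mean_workhours_noncaregivers = mean_nc,
                 mean_workhours_reducers = mean_red,
                 rhw_delta = max(0, mean_nc - mean_red)),
            class = "population_work_stats")
}

check_approach <- function(approach) {
  match.arg(toupper(approach), c("HCA", "FCA"))
}

# annualisation weeks for prolonged time off under each approach
pto_weeks <- function(costs, approach) {
  if (approach == "HCA") costs$work_weeks_per_year
  else min(costs$work_weeks_per_year, costs$friction_weeks)
}

# per-record temporary-time-off duration in weeks (0 without the flag)
tto_weeks <- function(records, costs, approach) {
  has <- tto_mask(records)
  dur <- ifelse(has, records$care_weeks_year / 2, 0)
  if (approach == "FCA") dur <- pmin(dur, costs$friction_weeks)
  dur
}

pto_mask <- function(records) {
  records$is_caregiver %in% TRUE & productivity_eligible(records) &
    records$stopped_work_prolonged %in% TRUE &
    !records$employed_now %in% TRUE
}

tto_mask <- function(records) {
  records$is_caregiver %in% TRUE & productivity_eligible(records) &
    records$stopped_work_temporary %in% TRUE &
    records$employed_now %in% TRUE
}

rhw_mask <- function(records) {
  records$is_caregiver %in% TRUE & productivity_eligible(records) &
    records$reduced_hours %in% TRUE &
    records$worked_past_year %in% TRUE
}

presenteeism_mask <- function(records) {
  records$is_caregiver %in% TRUE & productivity_eligible(records) &
    records$worked_past_year %in% TRUE
}

#' Annual cost of prolonged work cessation (PTO)
#'
#' Caregivers who left the workforce to provide care forgo their
#' potential work hours, imputed from the national average weekly work
#' hours for their age band and gender, valued at the gender-specific
#' hourly labour cost, and annualised over the work year (46 weeks under
#' the human-capital approach) or the friction period (12 weeks under
#' the friction-cost approach). Applies only to currently non-employed
#' caregivers aged 16-75 with the prolonged-cessation flag; everyone
#' else gets 0.
#'
#' @param records `caregiver_microdata`.
#' @param costs A [unit_cost_set()] with an `imputed_workhours` table.
#' @param approach `"HCA"` or `"FCA"`.
#' @return Annual cost per record.
#' @export
pto_cost <- function(records, costs, approach = c("HCA", "FCA")) {
  approach <- check_approach(approach[1])
  out <- numeric(nrow(records))
  m <- pto_mask(records)
  if (!any(m)) return(out)
  hrs <- imputed_work_hours(age_band(records$age[m]), records$gender[m],
                            costs)
  out[m] <- hrs * labour_rate(records$gender[m], costs) *
    pto_weeks(costs, approach)
  out
}

#' Annual cost of temporary work cessation (TTO)
#'
#' Employed caregivers who temporarily stopped working lose their
#' reported weekly work hours for the duration of the absence, assumed
#' to span half of their weeks of care (mirroring the median
#' unemployment spell of half a working year), capped at the friction
#' period under the friction-cost approach, valued at the
#' gender-specific hourly labour cost.
#'
#' @inheritParams pto_cost
#' @return Annual cost per record.
#' @export
tto_cost <- function(records, costs, approach = c("HCA", "FCA")) {
  approach <- check_approach(approach[1])
  out <- numeric(nrow(records))
  m <- tto_mask(records)
  if (!any(m)) return(out)
  if (anyNA(records$work_hours_week[m])) {
    stop("temporary work cessation flagged without reported work hours ",
         "(row(s) ", paste(which(m & is.na(records$work_hours_week)),
                           collapse = ", "), ")", call. = FALSE)
  }
  dur <- tto_weeks(records, costs, approach)
  out[m] <- records$work_hours_week[m] * dur[m] *
    labour_rate(records$gender[m], costs)
  out
}

#' Annual cost of reduced working hours (RHW)
#'
#' Caregivers who reduced their working hours lose the population-level
#' mean work-hour difference ([compute_rhw_delta()]) each week, valued
#' at the gender-specific hourly labour cost. Annualisation uses the
#' work year minus any temporary time off already costed (avoiding
#' double counting), capped at the friction period under the
#' friction-cost approach.
#'
#' @inheritParams pto_cost
#' @param work_stats A `population_work_stats` from
#'   [compute_rhw_delta()].
#' @return Annual cost per record.
#' @export
rhw_cost <- function(records, work_stats, costs,
                     approach = c("HCA", "FCA")) {
  approach <- check_approach(approach[1])
  out <- numeric(nrow(records))
  m <- rhw_mask(records)
  if (!any(m)) return(out)
  eff <- rhw_effective_weeks(records, costs, approach)
  out[m] <- work_stats$rhw_delta * labour_rate(records$gender[m], costs) *
    eff[m]
  out
}

# work weeks a reducer still attends after deducting time off; the
# deduction uses the duration in force under the same approach
rhw_effective_weeks <- function(records, costs, approach) {
  eff <- costs$work_weeks_per_year - tto_weeks(records, costs, approach)
  eff <- pmax(0, eff)
  if (approach == "FCA") eff <- pmin(eff, costs$friction_weeks)
  eff
}

#' Annual cost of presenteeism
#'
#' Diminished on-the-job productivity: weekly presenteeism hours are the
#' product of the work-impairment percentage from the concentration item
#' (none 0%, a bit 25%, very much 50%), the share of working days with
#' caregiving distractions from the frequency item (daily 100%, weekly
#' 20%, monthly 5%, rarely/never 0%), and the reported weekly work
#' hours. Annualised and monetised like reduced hours, under the
#' human-capital approach only (a friction-period reading is not
#' meaningful for presenteeism). Missing items imply zero presenteeism.
#' Excluded from base-case totals; included by the presenteeism
#' sensitivity scenario.
#'
#' @inheritParams pto_cost
#' @return Annual cost per record (human-capital approach).
#' @export
presenteeism_cost <- function(records, costs) {
  out <- numeric(nrow(records))
  m <- presenteeism_mask(records)
  if (!any(m)) return(out)
  imp <- PRESENTEEISM_IMPAIRMENT[records$concentration_loss[m]]
  dis <- PRESENTEEISM_DISTRACTION[records$distraction_freq[m]]
  wh <- ifelse(is.na(records$work_hours_week[m]), 0,
               records$work_hours_week[m])
  eff <- rhw_effective_weeks(records, costs, "HCA")
  out[m] <- imp * dis * wh * labour_rate(records$gender[m], costs) *
    eff[m]
  out
}

#' Per-caregiver annual indirect (productivity) costs
#'
#' Computes every absenteeism component (prolonged cessation, temporary
#' cessation, reduced hours) under both the human-capital and
#' friction-cost approaches, presenteeism under the human-capital
#' approach, and the forgone paid-work hours behind the absenteeism
#' components.
#'
#' @param records `caregiver_microdata`.
#' @param costs A [unit_cost_set()].
#' @param work_stats Optional precomputed [compute_rhw_delta()] result;
#'   computed from `records` when omitted.
#' @return Data frame with columns `pto_hca`, `pto_fca`, `tto_hca`,
#'   `tto_fca`, `rhw_hca`, `rhw_fca`, `presenteeism_hca`,
#'   `lost_work_hours_hca`, `lost_work_hours_fca`.
#' @export
indirect_costs <- function(records, costs, work_stats = NULL) {
  if (is.null(work_stats)) work_stats <- compute_rhw_delta(records)
  out <- data.frame(
    pto_hca = pto_cost(records, costs, "HCA"),
    pto_fca = pto_cost(records, costs, "FCA"),
    tto_hca = tto_cost(records, costs, "HCA"),
    tto_fca = tto_cost(records, costs, "FCA"),
    rhw_hca = rhw_cost(records, work_stats, costs, "HCA"),
    rhw_fca = rhw_cost(records, work_stats, costs, "FCA"),
    presenteeism_hca = presenteeism_cost(records, costs)
  )
  rate <- labour_rate(records$gender, costs)
  rate[is.na(rate)] <- 1
  out$lost_work_hours_hca <-
    (out$pto_hca + out$tto_hca + out$rhw_hca) / rate
  out$lost_work_hours_fca <-
    (out$pto_fca + out$tto_fca + out$rhw_fca) / rate
  out
}
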
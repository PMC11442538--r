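#' Specification for the synthetic caregiver survey generator
#'
#' Builds the parameter set from which [generate_survey()] draws
#' microdata with the statistical structure the costing pipeline assumes:
#' a caregiver prevalence of about 36% of the adult population, a
#' right-skewed weekly care-hours distribution (log-normal body with
#' median 3 h plus a small around-the-clock point mass at 168 h), care
#' durations with median 52 and mean about 41 weeks/year, the
#' out-of-pocket bracket distribution, employment and work-hours
#' structure, and the rates of the productivity-impact items (prolonged
#' cessation 7% of non-employed, temporary cessation 6% of employed,
#' reduced hours 10% of those who worked in the past year).
#'
#' A shared latent severity variable couples care intensity positively to
#' the impact flags and negatively to employment, so high-intensity
#' caregivers are both more likely to report work impacts and less likely
#' to be employed. Survey weights are drawn independently of outcomes
#' (non-informative) unless `informative_weights = TRUE`.
#'
#' @param n_respondents Number of survey rows (caregivers and
#'   non-caregivers).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param caregiver_prevalence Probability a respondent is a caregiver.
#' @param female_share_caregivers,female_share_noncaregivers Probability
#'   of `gender == "female"` in each group.
#' @param care_hours_meanlog,care_hours_sdlog Log-normal body of weekly
#'   care hours (median `exp(meanlog)` = 3 h).
#' @param around_clock_mass Point mass reporting 168 h/week.
#' @param care_weeks_full_year Probability of a full 52-week care year;
#'   the remainder is uniform on 1-51 weeks.
#' @param oop_bracket_probs Probabilities over the six observed expense
#'   brackets (none, lt50, 50_100, 100_200, 200_300, gt300).
#' @param oop_missing_rate Probability the bracket is missing.
#' @param employed_rate_caregivers,employed_rate_noncaregivers Current
#'   employment probability for ages 16-75.
#' @param worked_past_year_nonemployed Probability a currently
#'   non-employed 16-75-year-old worked for pay in the past year.
#' @param work_hours_mean_noncaregivers,work_hours_sd_noncaregivers
#'   Weekly work-hours distribution of employed non-caregivers.
#' @param work_hours_mean_caregivers,work_hours_sd_caregivers Weekly
#'   work hours of caregivers who did not reduce their hours.
#' @param rhw_gap Hours by which reducers' mean weekly work hours fall
#'   below employed non-caregivers' (drives the reduced-hours costing).
#' @param impact_rates Named list `pto`, `tto`, `rhw` of impact-item
#'   rates within their eligible groups.
#' @param distraction_probs,concentration_probs Presenteeism item
#'   distributions over their observed levels.
#' @param presenteeism_missing_rate Item non-response rate for the
#'   presenteeism questions.
#' @param severity_rho Latent-severity correlation of the impact flags.
#' @param employment_rho Latent-severity correlation (negative
#'   association) of current employment.
#' @param weight_mean,weight_cv Mean and coefficient of variation of the
#'   gamma-distributed survey expansion weights.
#' @param informative_weights If `TRUE`, weights are tilted by severity
#'   (to exercise weighted-vs-unweighted divergence); default
#'   non-informative.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(
    n_respondents,
    seed = 1L,
    caregiver_prevalence = 0.36,
    female_share_caregivers = 0.55,
    female_share_noncaregivers = 0.48,
    care_hours_meanlog = log(3),
    care_hours_sdlog = 1.12,
    around_clock_mass = 0.015,
    care_weeks_full_year = 0.574,
    oop_bracket_probs = c(none = 0.59, lt50 = 0.20, `50_100` = 0.12,
                          `100_200` = 0.05, `200_300` = 0.02, gt300 = 0.02),
    oop_missing_rate = 0.12,
    employed_rate_caregivers = 0.76,
    employed_rate_noncaregivers = 0.75,
    worked_past_year_nonemployed = 0.25,
    work_hours_mean_noncaregivers = 31.08,
    work_hours_sd_noncaregivers = 13.57,
    work_hours_mean_caregivers = 30.44,
    work_hours_sd_caregivers = 12.82,
    rhw_gap = 2.15,
    impact_rates = list(pto = 0.07, tto = 0.06, rhw = 0.10),
    distraction_probs = c(rarely_never = 0.77, monthly = 0.08,
                          weekly = 0.10, daily = 0.05),
    concentration_probs = c(none = 0.77, a_bit = 0.21, very_much = 0.02),
    presenteeism_missing_rate = 0.003,
    severity_rho = 0.30,
    employment_rho = 0.40,
    weight_mean = 1152,
    weight_cv = 0.5,
    informative_weights = FALSE) {
  spec <- as.list(environment())
  if (spec$n_respondents <= 0) {
    stop("n_respondents must be positive", call. = FALSE)
  }
  check_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8) {
      stop(what, " probabilities must sum to 1", call. = FALSE)
    }
    if (any(p < 0)) stop(what, " probabilities must be >= 0", call. = FALSE)
  }
  check_probs(spec$oop_bracket_probs, "out-of-pocket bracket")
  check_probs(spec$distraction_probs, "distraction")
  check_probs(spec$concentration_probs, "concentration")
  probs <- c(spec$caregiver_prevalence, spec$female_share_caregivers,
             spec$oop_missing_rate, unlist(spec$impact_rates),
             spec$employed_rate_caregivers, spec$around_clock_mass)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "generator_spec")
}

# Latent-coupled Bernoulli with the target rate enforced within the
# eligible group: the latent score is severity-correlated, and the
# threshold is its within-group quantile, so selection effects (e.g.
# the non-employed being higher-severity) do not inflate the item rate.
severity_flag <- function(z, rate, rho) {
  n <- length(z)
  if (n == 0) return(logical(0))
  lat <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  lat > stats::quantile(lat, 1 - rate, names = FALSE)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate synthetic caregiver survey microdata
#'
#' Draws a full survey file (one row per respondent) from a
#' [generator_spec()]. Output is deterministic given the spec's seed,
#' satisfies every microdata invariant, and its weighted marginals
#' converge to the spec's targets as `n_respondents` grows (see
#' [marginal_report()]).
#'
#' @param spec A [generator_spec()].
#' @return A validated `caregiver_microdata` data frame.
#' @examples
#' rec <- generate_survey(generator_spec(n_respondents = 500, seed = 7))
#' mean(rec$is_caregiver)
#' @export
generate_survey <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed, generate_survey_impl(spec))
}

generate_survey_impl <- function(spec) {
  n <- spec$n_respondents
  cg <- stats::runif(n) < spec$caregiver_prevalence
  gender <- ifelse(
    stats::runif(n) < ifelse(cg, spec$female_share_caregivers,
                             spec$female_share_noncaregivers),
    "female", "male")
  age <- round(ifelse(cg,
                      stats::rnorm(n, 49.65, 17.04),
                      stats::rnorm(n, 47.48, 20.11)))
  age <- clamp(age, 16, 95)
  eligible <- age >= 16 & age <= 75

  # shared latent severity for caregivers (care intensity and impacts)
  z <- stats::rnorm(n)

  # weekly care hours: log-normal body quantile-coupled to severity,
  # with an around-the-clock point mass at 168 in the upper tail
  u <- stats::pnorm(z)
  atc <- cg & u > 1 - spec$around_clock_mass
  body <- stats::qlnorm(pmin(u / (1 - spec$around_clock_mass), 1 - 1e-12),
                        spec$care_hours_meanlog, spec$care_hours_sdlog)
  care_hours <- ifelse(atc, 168, clamp(round(body), 1, 168))
  care_hours[!cg] <- NA_real_

  # weeks of care: point mass at the full year, else uniform 1-51
  full_year <- stats::runif(n) < spec$care_weeks_full_year
  care_weeks <- ifelse(full_year, 52, sample(1:51, n, replace = TRUE))
  care_weeks[!cg] <- NA_real_

  # out-of-pocket bracket (caregivers only)
  oop <- rep("missing", n)
  observed <- stats::runif(n) >= spec$oop_missing_rate
  oop[observed] <- sample(names(spec$oop_bracket_probs), sum(observed),
                          replace = TRUE, prob = spec$oop_bracket_probs)
  oop[!cg] <- "missing"

  # employment: negatively coupled to severity for caregivers
  employed <- logical(n)
  emp_rate <- ifelse(cg, spec$employed_rate_caregivers,
                     spec$employed_rate_noncaregivers)
  lat <- ifelse(cg, spec$employment_rho * z +
                  sqrt(1 - spec$employment_rho^2) * stats::rnorm(n),
                stats::rnorm(n))
  employed <- eligible & (lat <= stats::qnorm(emp_rate))
  worked_py <- employed |
    (eligible & stats::runif(n) < spec$worked_past_year_nonemployed)

  # impact flags within their eligible groups, severity-coupled
  pto <- rep(NA, n)
  m <- cg & eligible & !employed
  pto[m] <- severity_flag(z[m], spec$impact_rates$pto, spec$severity_rho)
  tto <- rep(NA, n)
  m <- cg & eligible & employed
  tto[m] <- severity_flag(z[m], spec$impact_rates$tto, spec$severity_rho)
  rhw <- rep(NA, n)
  m <- cg & eligible & worked_py
  rhw[m] <- severity_flag(z[m], spec$impact_rates$rhw, spec$severity_rho)

  # weekly work hours for everyone who worked in the past year
  wh_mean <- ifelse(!cg, spec$work_hours_mean_noncaregivers,
                    ifelse(rhw %in% TRUE,
                           spec$work_hours_mean_noncaregivers - spec$rhw_gap,
                           spec$work_hours_mean_caregivers))
  wh_sd <- ifelse(cg, spec$work_hours_sd_caregivers,
                  spec$work_hours_sd_noncaregivers)
  work_hours <- clamp(round(stats::rnorm(n, wh_mean, wh_sd)), 1, 80)
  work_hours[!worked_py] <- NA_real_

  # presenteeism items for caregivers who worked in the past year
  distraction <- rep("missing", n)
  concentration <- rep("missing", n)
  m <- cg & eligible & worked_py &
    stats::runif(n) >= spec$presenteeism_missing_rate
  distraction[m] <- sample(names(spec$distraction_probs), sum(m),
                           replace = TRUE, prob = spec$distraction_probs)
  concentration[m] <- sample(names(spec$concentration_probs), sum(m),
                             replace = TRUE, prob = spec$concentration_probs)

  # gamma expansion weights, non-informative unless requested
  shape <- 1 / spec$weight_cv^2
  weight <- stats::rgamma(n, shape = shape,
                          scale = spec$weight_mean / shape)
  if (isTRUE(spec$informative_weights)) {
    tilt <- exp(0.25 * z)
    weight <- weight * tilt / mean(tilt)
  }

  records <- data.frame(
    id = sprintf("r%06d", seq_len(n)),
    weight = weight,
    is_caregiver = cg,
    gender = gender,
    age = age,
    care_hours_week = care_hours,
    care_weeks_year = care_weeks,
    oop_bracket = oop,
    employed_now = employed,
    worked_past_year = worked_py,
    work_hours_week = work_hours,
    stopped_work_prolonged = pto,
    stopped_work_temporary = tto,
    reduced_hours = rhw,
    distraction_freq = distraction,
    concentration_loss = concentration,
    stringsAsFactors = FALSE
  )
  validate_microdata(records)
}

#' Realized vs target marginals of a generated survey
#'
#' Survey-weighted summary of every generator-controlled marginal,
#' alongside its target and absolute deviation: caregiver prevalence,
#' female share of caregivers, mean capped and uncapped weekly care
#' hours, mean care weeks, the share with no out-of-pocket costs (among
#' observed brackets), the three impact-item rates, and the work-hours
#' gap between employed non-caregivers and hour-reducing caregivers.
#'
#' @param records Generated `caregiver_microdata`.
#' @param spec The [generator_spec()] the records were drawn from
#'   (supplies the targets).
#' @param capped_hours_target Calibration target for the weighted mean of
#'   jointly capped weekly care hours.
#' @return A data frame with columns `marginal`, `target`, `realized`,
#'   `abs_dev`.
#' @export
marginal_report <- function(records, spec,
                            capped_hours_target = 7.37) {
  stopifnot(nrow(records) > 0)
  wmean <- function(x, w) stats::weighted.mean(x, w, na.rm = TRUE)
  cgr <- records[records$is_caregiver, ]
  work_for_cap <- ifelse(cgr$employed_now %in% TRUE &
                           !is.na(cgr$work_hours_week),
                         cgr$work_hours_week, 0)
  capped <- cap_care_hours(cgr$care_hours_week, work_for_cap)
  oop_obs <- cgr[cgr$oop_bracket != "missing", ]
  elig <- productivity_eligible(cgr)
  pto_grp <- cgr[elig & !cgr$employed_now, ]
  tto_grp <- cgr[elig & cgr$employed_now, ]
  rhw_grp <- cgr[elig & cgr$worked_past_year, ]
  nc_emp <- records[!records$is_caregiver &
                      !is.na(records$work_hours_week), ]
  red <- rhw_grp[rhw_grp$reduced_hours %in% TRUE, ]
  gap <- wmean(nc_emp$work_hours_week, nc_emp$weight) -
    wmean(red$work_hours_week, red$weight)
  weeks_target <- spec$care_weeks_full_year * 52 +
    (1 - spec$care_weeks_full_year) * 26

  rows <- rbind(
    data.frame(marginal = "caregiver_prevalence",
               target = spec$caregiver_prevalence,
               realized = wmean(records$is_caregiver, records$weight)),
    data.frame(marginal = "female_share_caregivers",
               target = spec$female_share_caregivers,
               realized = wmean(cgr$gender == "female", cgr$weight)),
    data.frame(marginal = "mean_care_hours_capped",
               target = capped_hours_target,
               realized = wmean(capped, cgr$weight)),
    data.frame(marginal = "mean_care_hours_uncapped",
               target = NA_real_,
               realized = wmean(cgr$care_hours_week, cgr$weight)),
    data.frame(marginal = "mean_care_weeks",
               target = weeks_target,
               realized = wmean(cgr$care_weeks_year, cgr$weight)),
    data.frame(marginal = "oop_none_share",
               target = unname(spec$oop_bracket_probs["none"]),
               realized = wmean(oop_obs$oop_bracket == "none",
                                oop_obs$weight)),
    data.frame(marginal = "pto_rate",
               target = spec$impact_rates$pto,
               realized = wmean(pto_grp$stopped_work_prolonged %in% TRUE,
                                pto_grp$weight)),
    data.frame(marginal = "tto_rate",
               target = spec$impact_rates$tto,
               realized = wmean(tto_grp$stopped_work_temporary %in% TRUE,
                                tto_grp$weight)),
    data.frame(marginal = "rhw_rate",
               target = spec$impact_rates$rhw,
               realized = wmean(rhw_grp$reduced_hours %in% TRUE,
                                rhw_grp$weight)),
    data.frame(marginal = "work_hours_gap",
               target = spec$rhw_gap,
               realized = gap)
  )
  rows$abs_dev <- abs(rows$realized - rows$target)
  rows
}
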
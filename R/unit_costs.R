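#' Unit-cost and structural-constant registry
#'
#' A `unit_cost_set` holds every shadow price, imputation table and
#' structural constant the costing pipeline needs: the hourly value of
#' leisure time (opportunity-cost shadow price for care time, with
#' willingness-to-pay and willingness-to-accept alternatives for
#' sensitivity analysis), the hourly rate of professional household care
#' (proxy-good shadow price), gender-specific hourly labour costs
#' (productivity-loss unit cost), a national average work-hours table by
#' age band and gender (for imputing the hours of caregivers who left the
#' workforce), out-of-pocket bracket midpoints, CPI factors for price-year
#' adjustment, and macro context constants (GDP, weighted adult
#' population, mean gross income).
#'
#' Structural defaults applied when a configuration omits them:
#' 46 work weeks per year, a 12-week friction period, a 6 h/day leisure
#' floor (hence a 126 h/week joint cap on work plus care), and 1836
#' working hours per full-time equivalent.
#'
#' @param config Named list of configuration values (see
#'   [load_unit_costs()] for the file-based constructor and the field
#'   list).
#' @return An object of class `unit_cost_set`.
#' @seealso [load_unit_costs()], [cpi_adjust()]
#' @export
unit_cost_set <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(
    work_weeks_per_year = 46,
    friction_weeks = 12,
    leisure_floor_hours_per_day = 6,
    fte_hours_per_year = 1836,
    net_floor = TRUE,
    oop_missing_as_zero = FALSE
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$oop_bracket_values)) {
    config$oop_bracket_values <- default_oop_bracket_values()
  }
  ob <- as.list(config$oop_bracket_values)
  if (is.null(ob[["missing"]])) {
    ob[["missing"]] <- if (isTRUE(config$oop_missing_as_zero)) 0 else ob[["lt50"]]
  }
  config$oop_bracket_values <- ob
  structure(config, class = "unit_cost_set")
}

#' Default out-of-pocket bracket valuation (EUR per month)
#'
#' Midpoint of each reported monthly expense bracket; the open-ended top
#' bracket is valued at its lower bound (300) and missing responses are
#' imputed with the value of the lowest positive bracket.
#' @return Named numeric vector of monthly euro amounts.
#' @keywords internal
default_oop_bracket_values <- function() {
  c(none = 0, lt50 = 25, `50_100` = 75, `100_200` = 150,
    `200_300` = 250, gt300 = 300)
}

MANDATORY_RATES <- c("leisure_value", "proxy_rate")

#' Load and validate a unit-cost configuration
#'
#' Reads a YAML (or JSON) unit-cost configuration file, applies the
#' structural defaults (46 work weeks, 12 friction weeks, 6 h/day leisure
#' floor, 1836 FTE hours) for omitted fields, and validates the result.
#'
#' Mandatory fields: `leisure_value`, `proxy_rate`,
#' `labour_cost_by_gender` (named `male`/`female`), `imputed_workhours`
#' (nested map age band -> gender -> weekly hours), `price_year`.
#' Optional: `leisure_wtp`, `leisure_wta` (needed only by the leisure-value
#' scenarios), `cpi_index` (year -> index), `oop_bracket_values`,
#' `macro` (`gdp`, `adult_population_weighted`, `working_population_weighted`,
#' `mean_gross_income`), and the switches `net_floor`,
#' `oop_missing_as_zero`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [unit_cost_set()].
#' @examples
#' cfg <- system.file("extdata", "unit_costs_synthetic.yaml",
#'                    package = "carecost")
#' costs <- load_unit_costs(cfg)
#' costs$work_weeks_per_year  # 46 unless overridden
#' @export
load_unit_costs <- function(path) {
  if (!file.exists(path)) {
    stop("unit-cost configuration file not found: ", path, call. = FALSE)
  }
  config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  costs <- unit_cost_set(config)
  validate_unit_costs(costs)
  costs
}

#' Validate a unit-cost set
#'
#' Checks presence of mandatory rates, positivity of all monetary rates,
#' and the structural-constant ranges (work weeks in (0, 52], friction
#' period no longer than the work year, leisure floor in [0, 24)).
#'
#' @param costs A [unit_cost_set()].
#' @return `costs`, invisibly, if valid; otherwise an error.
#' @export
validate_unit_costs <- function(costs) {
  for (nm in MANDATORY_RATES) {
    if (is.null(costs[[nm]])) {
      stop("unit-cost configuration is missing mandatory field '", nm, "'",
           call. = FALSE)
    }
  }
  if (is.null(costs$labour_cost_by_gender)) {
    stop("unit-cost configuration is missing mandatory field ",
         "'labour_cost_by_gender'", call. = FALSE)
  }
  if (is.null(costs$price_year)) {
    stop("unit-cost configuration is missing mandatory field 'price_year'",
         call. = FALSE)
  }
  rates <- c(costs$leisure_value, costs$leisure_wtp, costs$leisure_wta,
             costs$proxy_rate, unlist(costs$labour_cost_by_gender))
  if (any(rates <= 0)) {
    stop("all monetary rates must be strictly positive", call. = FALSE)
  }
  lab <- costs$labour_cost_by_gender
  if (!all(c("male", "female") %in% names(lab))) {
    stop("labour_cost_by_gender must name both 'male' and 'female'",
         call. = FALSE)
  }
  if (costs$work_weeks_per_year <= 0 || costs$work_weeks_per_year > 52) {
    stop("work_weeks_per_year must lie in (0, 52]", call. = FALSE)
  }
  if (costs$friction_weeks > costs$work_weeks_per_year) {
    stop("friction_weeks must not exceed work_weeks_per_year", call. = FALSE)
  }
  if (costs$leisure_floor_hours_per_day < 0 ||
      costs$leisure_floor_hours_per_day >= 24) {
    stop("leisure_floor_hours_per_day must lie in [0, 24)", call. = FALSE)
  }
  ob <- costs$oop_bracket_values
  needed <- c(names(default_oop_bracket_values()), "missing")
  if (!all(needed %in% names(ob))) {
    stop("oop_bracket_values must cover brackets: ",
         paste(setdiff(needed, names(ob)), collapse = ", "), call. = FALSE)
  }
  if (any(unlist(ob) < 0)) {
    stop("out-of-pocket bracket values must be non-negative", call. = FALSE)
  }
  if (!is.null(costs$imputed_workhours)) {
    iw <- unlist(costs$imputed_workhours)
    if (any(iw < 0 | iw > 168)) {
      stop("imputed work hours must lie in [0, 168]", call. = FALSE)
    }
  }
  invisible(costs)
}

#' Adjust an amount to the configured price year with the CPI
#'
#' Multiplicative Consumer Price Index adjustment:
#' `amount * cpi_index[price_year] / cpi_index[from_year]`.
#'
#' @param amount Monetary amount (vectorised).
#' @param from_year Calendar year the amount is expressed in.
#' @param costs A [unit_cost_set()] whose `cpi_index` covers both years.
#' @return The amount in `costs$price_year` prices.
#' @export
cpi_adjust <- function(amount, from_year, costs) {
  idx <- costs$cpi_index
  if (is.null(idx)) stop("no cpi_index configured", call. = FALSE)
  to_year <- as.character(costs$price_year)
  from_year <- as.character(from_year)
  for (y in c(from_year, to_year)) {
    if (is.null(idx[[y]])) {
      stop("year ", y, " not in CPI index; available years: ",
           paste(names(idx), collapse = ", "), call. = FALSE)
    }
  }
  amount * idx[[to_year]] / idx[[from_year]]
}

#' Weekly joint time cap on work plus informal care
#'
#' With a leisure floor of 6 h/day the cap is (24 - 6) x 7 = 126 h/week.
#' @param costs A [unit_cost_set()].
#' @return Hours per week.
#' @export
weekly_time_cap <- function(costs) {
  (24 - costs$leisure_floor_hours_per_day) * 7
}

#' Look up the hourly labour cost for a gender
#' @param gender Character vector of `"male"`/`"female"`.
#' @param costs A [unit_cost_set()].
#' @return Hourly labour cost, vectorised over `gender`.
#' @keywords internal
labour_rate <- function(gender, costs) {
  unlist(costs$labour_cost_by_gender)[gender]
}

#' Look up imputed weekly work hours by age band and gender
#'
#' National average weekly working hours used to impute the forgone work
#' time of caregivers who left the workforce (prolonged time off).
#'
#' @param age_band Character vector of age bands (`"16_25"` ... `"66_75"`).
#' @param gender Character vector, recycled against `age_band`.
#' @param costs A [unit_cost_set()].
#' @return Hours per week.
#' @export
imputed_work_hours <- function(age_band, gender, costs) {
  tbl <- costs$imputed_workhours
  if (is.null(tbl)) {
    stop("no imputed_workhours table configured", call. = FALSE)
  }
  n <- max(length(age_band), length(gender))
  age_band <- rep_len(age_band, n)
  gender <- rep_len(gender, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cell <- tbl[[age_band[i]]][[gender[i]]]
    if (is.null(cell)) {
      stop("imputed_workhours has no entry for age band '", age_band[i],
           "', gender '", gender[i], "'", call. = FALSE)
    }
    out[i] <- cell
  }
  out
}
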
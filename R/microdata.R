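#' Caregiver survey microdata schema
#'
#' One row per survey respondent (caregivers and non-caregivers alike;
#' non-caregivers stay in the file because the reduced-hours costing
#' compares caregivers' work hours against theirs). Columns:
#'
#' * `id` — respondent identifier.
#' * `weight` — survey expansion weight (>= 0); weighted sums are
#'   national totals.
#' * `is_caregiver` — provided unpaid care to family/friends with health
#'   problems in the past 12 months.
#' * `gender` — `"male"`/`"female"`.
#' * `age` — years; productivity items are assessed only for ages 16-75.
#' * `care_hours_week` — reported weekly hours of care, 1-168
#'   (caregivers only, `NA` otherwise).
#' * `care_weeks_year` — weeks of care in the past year, 1-52.
#' * `oop_bracket` — monthly out-of-pocket expense bracket: `none`,
#'   `lt50`, `50_100`, `100_200`, `200_300`, `gt300`, `missing`.
#' * `employed_now`, `worked_past_year` — employment flags.
#' * `work_hours_week` — reported weekly paid work hours (`NA` when not
#'   working).
#' * `stopped_work_prolonged` — left the workforce to provide care
#'   (asked of the currently non-employed).
#' * `stopped_work_temporary` — temporarily stopped working in the past
#'   year (asked of the currently employed).
#' * `reduced_hours` — reduced working hours in the past year (asked of
#'   those who worked for pay in the past year).
#' * `distraction_freq` — distracted at work by caregiving: `daily`,
#'   `weekly`, `monthly`, `rarely_never`, `missing`.
#' * `concentration_loss` — worked with less concentration: `none`,
#'   `a_bit`, `very_much`, `missing`.
#'
#' @name microdata-schema
NULL

OOP_LEVELS <- c("none", "lt50", "50_100", "100_200", "200_300", "gt300",
                "missing")
DISTRACTION_LEVELS <- c("daily", "weekly", "monthly", "rarely_never",
                        "missing")
CONCENTRATION_LEVELS <- c("none", "a_bit", "very_much", "missing")
GENDER_LEVELS <- c("male", "female")

MICRODATA_COLUMNS <- c(
  "id", "weight", "is_caregiver", "gender", "age",
  "care_hours_week", "care_weeks_year", "oop_bracket",
  "employed_now", "worked_past_year", "work_hours_week",
  "stopped_work_prolonged", "stopped_work_temporary", "reduced_hours",
  "distraction_freq", "concentration_loss"
)

#' Decadal age band used for work-hours imputation
#'
#' Bands `16_25`, `26_35`, ..., `66_75` covering the productivity-cost
#' eligibility window; ages outside 16-75 return `NA`.
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of band labels.
#' @export
age_band <- function(age) {
  lower <- c(16, 26, 36, 46, 56, 66)
  upper <- c(25, 35, 45, 55, 65, 75)
  labels <- paste0(lower, "_", upper)
  idx <- findInterval(age, c(lower, 76))
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & age >= 16 & age <= 75
  out[ok] <- labels[idx[ok]]
  out
}

#' Eligibility window for productivity-cost items
#' @param records Microdata data frame.
#' @return Logical vector: age within 16-75.
#' @keywords internal
productivity_eligible <- function(records) {
  !is.na(records$age) & records$age >= 16 & records$age <= 75
}

#' Read caregiver survey microdata from CSV
#'
#' Reads a comma-separated, UTF-8, headered file following the
#' [microdata-schema], types every column, maps empty categorical cells
#' to `"missing"`, and validates all row-level constraints. Invalid rows
#' are reported together with their row numbers.
#'
#' @param path CSV file path.
#' @return A validated data frame of class `caregiver_microdata`.
#' @seealso [write_microdata()], [validate_microdata()]
#' @export
read_microdata <- function(path) {
  if (!file.exists(path)) {
    stop("microdata file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(MICRODATA_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("microdata is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  lgl <- function(x) ifelse(x == "", NA, toupper(x) == "TRUE")
  cat_ <- function(x) ifelse(x == "" | is.na(x), "missing", x)
  records <- data.frame(
    id = raw$id,
    weight = num(raw$weight),
    is_caregiver = lgl(raw$is_caregiver),
    gender = raw$gender,
    age = num(raw$age),
    care_hours_week = num(raw$care_hours_week),
    care_weeks_year = num(raw$care_weeks_year),
    oop_bracket = cat_(raw$oop_bracket),
    employed_now = lgl(raw$employed_now),
    worked_past_year = lgl(raw$worked_past_year),
    work_hours_week = num(raw$work_hours_week),
    stopped_work_prolonged = lgl(raw$stopped_work_prolonged),
    stopped_work_temporary = lgl(raw$stopped_work_temporary),
    reduced_hours = lgl(raw$reduced_hours),
    distraction_freq = cat_(raw$distraction_freq),
    concentration_loss = cat_(raw$concentration_loss),
    stringsAsFactors = FALSE
  )
  validate_microdata(records)
}

#' Write caregiver survey microdata to CSV
#'
#' Inverse of [read_microdata()]: the written file reads back
#' field-for-field identical.
#'
#' @param records Microdata data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(records, path) {
  out <- records[MICRODATA_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate caregiver microdata
#'
#' Enforces the row-level constraints of the [microdata-schema]: weights
#' present and non-negative, care fields present iff the respondent is a
#' caregiver, care hours in 1-168 and care weeks in 1-52, known
#' categorical codes, and the skip-logic implications
#' (prolonged cessation only for the non-employed, temporary cessation
#' only for the employed, reduced hours only for those who worked in the
#' past year).
#'
#' @param records Microdata data frame.
#' @return `records` with class `caregiver_microdata`; errors list the
#'   offending row numbers.
#' @export
validate_microdata <- function(records) {
  problems <- character(0)
  bad <- function(mask, msg) {
    rows <- which(mask)
    if (length(rows)) {
      shown <- paste(utils::head(rows, 5), collapse = ", ")
      if (length(rows) > 5) shown <- paste0(shown, ", ...")
      problems <<- c(problems,
                     sprintf("%s (%d row(s): %s)", msg, length(rows), shown))
    }
  }
  bad(is.na(records$weight), "missing survey weight")
  bad(!is.na(records$weight) & records$weight < 0, "negative survey weight")
  bad(is.na(records$is_caregiver), "missing caregiver flag")
  bad(!records$gender %in% GENDER_LEVELS, "unknown gender code")
  bad(is.na(records$age) | records$age < 16 | records$age > 120,
      "age missing or outside 16-120")
  cg <- records$is_caregiver %in% TRUE
  bad(cg & is.na(records$care_hours_week),
      "caregiver without reported care hours")
  bad(cg & !is.na(records$care_hours_week) &
        (records$care_hours_week < 1 | records$care_hours_week > 168),
      "care_hours_week outside the survey range 1-168")
  bad(cg & (is.na(records$care_weeks_year) | records$care_weeks_year < 1 |
              records$care_weeks_year > 52),
      "care_weeks_year missing or outside 1-52")
  bad(!cg & (!is.na(records$care_hours_week) |
               !is.na(records$care_weeks_year)),
      "care fields reported by a non-caregiver")
  bad(cg & !records$oop_bracket %in% OOP_LEVELS,
      "unknown out-of-pocket bracket label")
  bad(!records$distraction_freq %in% DISTRACTION_LEVELS,
      "unknown distraction code")
  bad(!records$concentration_loss %in% CONCENTRATION_LEVELS,
      "unknown concentration code")
  bad(records$stopped_work_prolonged %in% TRUE &
        records$employed_now %in% TRUE,
      "prolonged work cessation flagged for an employed respondent")
  bad(records$stopped_work_temporary %in% TRUE &
        !records$employed_now %in% TRUE,
      "temporary work cessation flagged for a non-employed respondent")
  bad(records$reduced_hours %in% TRUE &
        !records$worked_past_year %in% TRUE,
      "reduced hours flagged without paid work in the past year")
  bad(!is.na(records$work_hours_week) &
        (records$work_hours_week < 0 | records$work_hours_week > 168),
      "work_hours_week outside 0-168")
  if (length(problems)) {
    stop("invalid microdata:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  class(records) <- c("caregiver_microdata", "data.frame")
  records
}
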
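# Internal calendar helpers. All event logic runs on integer day indices
# anchored at a fixed Monday so that weekday/weekend structure is
# reproducible across simulation, labeling and feature extraction.

.BP_ORIGIN <- as.Date("2017-01-02")  # a Monday; day index 0

#' Calendar origin of the day index
#'
#' Day indices used throughout the package count days from a fixed Monday.
#' This function returns that date, so `bp_origin() + day` converts a day
#' index back to a calendar date.
#'
#' @return A `Date` of length 1 (a Monday).
#' @export
bp_origin <- function() .BP_ORIGIN

# 0 = Monday ... 6 = Sunday
day_of_week <- function(day) day %% 7L

is_weekend <- function(day) day_of_week(day) >= 5L

day_to_date <- function(day) .BP_ORIGIN + day

date_to_day <- function(date) as.integer(as.Date(date) - .BP_ORIGIN)

# fractional age in years at a given day index, from "YYYY-MM" birth field
age_at_day <- function(birth_ym, day) {
  birth <- as.Date(paste0(birth_ym, "-01"))
  as.numeric(day_to_date(day) - birth) / 365.25
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
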
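#' Back-estimate active drug users from a measured load
#'
#' The inverse of the forward prescription model: the number of people
#' actively taking a drug is the measured daily excreted mass divided by the
#' mass one user excretes per day (daily dose times excreted fraction).
#' Estimates are real numbers, not rounded counts — a small catchment
#' legitimately yields fractional user-day equivalents.
#'
#' @param load_mg_d Measured 24-h influent load, mg/d (vectorised).
#' @param dose_g_d Daily consumed dose per user, grams/day (e.g. 0.150 g/d
#'   for the standard adult oseltamivir regime of 0.075 g twice daily).
#' @param excreted_fraction Fraction of the dose excreted in the measured
#'   form, in (0, 1].
#' @return Estimated number of active users.
#' @export
#' @examples
#' estimate_users(18600, 0.150, 0.8) # ~155 users
estimate_users <- function(load_mg_d, dose_g_d, excreted_fraction) {
  if (any(dose_g_d <= 0)) abort("dose_g_d must be positive")
  if (any(excreted_fraction <= 0 | excreted_fraction > 1)) {
    abort("excreted_fraction must lie in (0, 1]")
  }
  if (any(load_mg_d < 0)) abort("load must be nonnegative")
  (load_mg_d / 1000) / (dose_g_d * excreted_fraction)
}

#' Users predicted from syndromic or dispensing surveillance
#'
#' Multiplies the catchment population by a surveillance rate: either a
#' dispensing rate (e.g. the National Pandemic Flu Service peak of 0.13% of
#' the population of England on oseltamivir) or an influenza-like-illness
#' rate (e.g. 54.2 per 100,000).
#'
#' @param population Catchment population.
#' @param rate Fraction of the population in `[0, 1]`.
#' @return Predicted number of users.
#' @export
#' @examples
#' surveillance_predicted_users(208000, 0.0013) # 270.4
surveillance_predicted_users <- function(population, rate) {
  if (any(rate < 0 | rate > 1)) abort("rate must lie in [0, 1]")
  population * rate
}

#' Compliance: wastewater-estimated users over surveillance-predicted users
#'
#' @param estimated_users Users back-estimated from the wastewater load.
#' @param predicted_users Users predicted from surveillance statistics.
#' @return Compliance as a percentage; `NA` when `predicted_users` is zero.
#' @export
#' @examples
#' compliance(155, 270.4) # ~57%
compliance <- function(estimated_users, predicted_users) {
  ifelse(predicted_users > 0, 100 * estimated_users / predicted_users, NA_real_)
}

# National surveillance rates usable as defaults for oseltamivir:
# NPFS peak dispensing (week 43, 2009) and the QSurveillance ILI rate for the
# sampling week; ILI declined to ~33/100,000 by week 49, so the pair brackets
# a sensitivity range.
NPFS_DISPENSING_RATE <- 0.0013
QSURVEILLANCE_ILI_RATE <- 54.2e-5

#' Build a user-estimate table for one or more analytes
#'
#' @param loads Tibble with `analyte` and `daily_load_mg_d` (influent).
#' @param dosing Tibble with `analyte`, `dose_g_d`, `excreted_fraction`.
#' @param population Catchment population (for the surveillance prediction).
#' @param rate Surveillance rate; default the NPFS national dispensing rate
#'   0.13%.
#' @return One row per analyte: measured load, estimated users, predicted
#'   users, `compliance_percent`.
#' @export
user_estimate_table <- function(loads, dosing, population = NA_real_,
                                rate = NPFS_DISPENSING_RATE) {
  merged <- dplyr::inner_join(
    dplyr::select(loads, "analyte", "daily_load_mg_d"),
    dosing,
    by = "analyte"
  )
  merged$estimated_users <- estimate_users(
    merged$daily_load_mg_d, merged$dose_g_d, merged$excreted_fraction
  )
  merged$predicted_users <- if (is.na(population)) {
    NA_real_
  } else {
    surveillance_predicted_users(population, rate)
  }
  merged$compliance_percent <- compliance(
    merged$estimated_users, merged$predicted_users
  )
  merged
}
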
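#' Describe a prescription-statistics input
#'
#' Prescription statistics arrive either as a mass of drug dispensed over a
#' period (grams) or as a count of Average Daily Quantities (ADQs),
#' convertible to grams through the analyte's ADQ mass. Sources are either
#' spatially resolved monthly Primary Care Trust (PCT) figures or national
#' annual NHS Business Services Authority (NHS BSA) figures.
#'
#' @param analyte Analyte name.
#' @param source `"pct_monthly"` or `"nhsbsa_annual"`.
#' @param mass_g Mass dispensed over the period, grams. Give exactly one of
#'   `mass_g` and `adq_count`.
#' @param adq_count Number of ADQs dispensed over the period.
#' @param period_days Length of the source period in days (e.g. 365 for
#'   annual statistics, 30 for a monthly extract).
#' @return A list with class `wbe_prescription`.
#' @export
prescription_input <- function(analyte,
                               source = c("pct_monthly", "nhsbsa_annual"),
                               mass_g = NA_real_,
                               adq_count = NA_real_,
                               period_days) {
  source <- match.arg(source)
  if (is.na(mass_g) == is.na(adq_count)) {
    abort("give exactly one of mass_g and adq_count")
  }
  if (!is.finite(period_days) || period_days <= 0) {
    abort("period_days must be positive")
  }
  structure(
    list(
      analyte = analyte, source = source, mass_g = mass_g,
      adq_count = adq_count, period_days = period_days
    ),
    class = "wbe_prescription"
  )
}

#' Convert a prescription input to grams of drug per day
#'
#' @param input A [prescription_input()].
#' @param analyte One-row analyte spec (see [analyte_spec()]), used for the
#'   ADQ-to-gram conversion when the input is an ADQ count.
#' @param winter_uplift Apply the seasonal uplift of [winter_adjust()] to
#'   annual (NHS BSA) sources before dividing by the period. Default `TRUE`,
#'   matching the treatment of annual national statistics; monthly PCT
#'   figures are never adjusted.
#' @return Mass prescribed per day, grams/day.
#' @export
adq_to_daily_mass <- function(input, analyte, winter_uplift = TRUE) {
  stopifnot(inherits(input, "wbe_prescription"))
  mass <- if (!is.na(input$mass_g)) {
    input$mass_g
  } else {
    input$adq_count * analyte$adq_g
  }
  if (mass < 0) abort("prescribed mass must be nonnegative")
  if (winter_uplift && input$source == "nhsbsa_annual") {
    mass <- winter_adjust(mass)
  }
  mass / input$period_days
}

#' Winter uplift for annual prescription statistics
#'
#' Antibiotic consumption in the UK swings roughly 18.75% between summer and
#' winter; sampling in November therefore sits about half that swing —
#' 9.375% — above the annual mean. For an annual mass M_a the adjusted mass
#' is M = M_a + M_s with M_s = M_a * 0.09375.
#'
#' @param annual_mass_g Annual mass prescribed, grams.
#' @return The winter-adjusted mass, grams.
#' @export
#' @examples
#' winter_adjust(1200) # 1312.5
winter_adjust <- function(annual_mass_g) {
  if (any(annual_mass_g < 0)) abort("mass must be nonnegative")
  annual_mass_g * (1 + WINTER_UPLIFT_FRACTION)
}

# half of the ~18.75% summer-winter swing in UK antibiotic consumption
WINTER_UPLIFT_FRACTION <- 0.09375

#' Split co-trimoxazole ADQs into component masses
#'
#' Trimethoprim and sulfamethoxazole are routinely dispensed together as
#' co-trimoxazole; one ADQ of the mixture contains 0.16 g trimethoprim and
#' 0.8 g sulfamethoxazole.
#'
#' @param adq_count Number of co-trimoxazole ADQs.
#' @return Named numeric: `trimethoprim_g`, `sulfamethoxazole_g`.
#' @export
#' @examples
#' split_cotrimoxazole(10)
split_cotrimoxazole <- function(adq_count) {
  if (any(adq_count < 0)) abort("adq_count must be nonnegative")
  c(trimethoprim_g = 0.16 * adq_count, sulfamethoxazole_g = 0.8 * adq_count)
}

#' Forward-predict an influent concentration from prescribed mass
#'
#' The forward model of wastewater epidemiology: the concentration C_w
#' (ng/L) expected in WWTP influent is the daily prescribed mass M (g/d)
#' times the excreted fraction E and catchment correction factor F, divided
#' by the daily wastewater volume — population P times per-capita wastewater
#' L (L/cap/d):
#'
#'   C_w = M * E * F * 1e9 / (P * L)
#'
#' The matching predicted excreted mass is M * E * F * 1000 mg/d.
#'
#' @param m_daily_g Daily prescribed mass, grams/day (vectorised).
#' @param analyte One-row analyte spec carrying `excreted_fraction`.
#' @param catchment A validated [catchment_config()].
#' @return A tibble with `analyte`, `predicted_influent_conc_ng_l`,
#'   `predicted_excreted_mass_mg_d` and the model components
#'   (`m_daily_g`, `excreted_fraction`, `correction_factor`,
#'   `population`, `l_per_capita`).
#' @export
predict_influent_concentration <- function(m_daily_g, analyte, catchment) {
  catchment <- validate_catchment(catchment)
  e <- analyte$excreted_fraction
  f <- catchment$correction_factor
  p <- catchment$population_served
  l <- catchment$wastewater_per_capita_l_per_d
  if (p * l <= 0) abort("catchment daily wastewater volume must be positive")
  tibble::tibble(
    analyte = analyte$analyte,
    predicted_influent_conc_ng_l = m_daily_g * e * f * 1e9 / (p * l),
    predicted_excreted_mass_mg_d = m_daily_g * e * f * 1000,
    m_daily_g = m_daily_g,
    excreted_fraction = e,
    correction_factor = f,
    population = p,
    l_per_capita = l
  )
}

#' Compare predicted with measured environmental loads
#'
#' Joins forward predictions (per prescription source) against measured 24-h
#' influent loads (MELs), giving the prediction/measurement ratio and an
#' over/under flag per analyte. Analytes measured entirely below the LOQ
#' have no defined ratio and are reported `NA` (rendered "na").
#'
#' @param predictions Tibble with `analyte`, `source` and
#'   `predicted_excreted_mass_mg_d`.
#' @param measured Load summaries (see [summarise_loads()]) for the influent
#'   stream: `analyte`, `daily_load_mg_d`, `n_above_loq`.
#' @return One row per analyte and source: predicted and measured mg/d,
#'   `ratio`, `direction` (`"over"`, `"under"`, `"equal"` or `NA`).
#' @export
compare_mel <- function(predictions, measured) {
  meas <- dplyr::select(measured, "analyte",
    measured_load_mg_d = "daily_load_mg_d",
    n_above_loq = dplyr::any_of("n_above_loq")
  )
  out <- dplyr::left_join(predictions, meas, by = "analyte")
  defined <- !is.na(out$measured_load_mg_d) & out$measured_load_mg_d > 0
  if ("n_above_loq" %in% names(out)) {
    defined <- defined & (is.na(out$n_above_loq) | out$n_above_loq > 0)
  }
  out$ratio <- ifelse(defined,
    out$predicted_excreted_mass_mg_d / out$measured_load_mg_d, NA_real_
  )
  out$direction <- ifelse(is.na(out$ratio), NA_character_,
    ifelse(out$ratio > 1, "over", ifelse(out$ratio < 1, "under", "equal"))
  )
  out
}
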
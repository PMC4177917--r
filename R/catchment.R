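#' Describe a WWTP catchment
#'
#' A catchment configuration holds the quantities needed to move between
#' mass loads and per-capita figures, and to forward-predict influent
#' concentrations from prescription statistics: the population served by the
#' plant (P), the volume of wastewater produced per person per day (L,
#' default 230 L/cap/d), optionally the patient population of the Primary
#' Care Trust (PCT) whose prescription statistics cover the catchment, and a
#' correction factor (F) for the fraction of the PCT population actually
#' served by this plant.
#'
#' @param wwtp_id Character identifier for the plant.
#' @param population_served Resident population connected to the plant (P).
#' @param wastewater_per_capita_l_per_d Wastewater produced per person per
#'   day, in litres (L). Default 230.
#' @param pct_population Patient population of the local PCT, or `NA` when
#'   prescription statistics are national.
#' @param correction_factor Fraction F in (0, 1] of the prescription-statistic
#'   population served by this plant, or `NA` to have [validate_catchment()]
#'   derive it.
#' @return A list with class `wbe_catchment`.
#' @export
#' @examples
#' benson <- catchment_config("benson", 6230, pct_population = 16000)
#' validate_catchment(benson)$correction_factor
catchment_config <- function(wwtp_id,
                             population_served,
                             wastewater_per_capita_l_per_d = 230,
                             pct_population = NA_real_,
                             correction_factor = NA_real_) {
  structure(
    list(
      wwtp_id = as.character(wwtp_id),
      population_served = as.numeric(population_served),
      wastewater_per_capita_l_per_d = as.numeric(wastewater_per_capita_l_per_d),
      pct_population = as.numeric(pct_population),
      correction_factor = as.numeric(correction_factor)
    ),
    class = "wbe_catchment"
  )
}

#' Validate a catchment and resolve its correction factor
#'
#' Fills the correction factor F when it was not given: F is the ratio of the
#' WWTP population to the PCT patient population when the latter is known
#' (the plant serves only part of the prescribing population), and 1
#' otherwise (national statistics, or a PCT wholly served by this plant).
#'
#' @param config A [catchment_config()].
#' @return The validated config, with `correction_factor` filled in.
#' @export
validate_catchment <- function(config) {
  stopifnot(inherits(config, "wbe_catchment"))
  p <- config$population_served
  if (!is.finite(p) || p <= 0) {
    abort("population_served must be a positive count")
  }
  if (!is.finite(config$wastewater_per_capita_l_per_d) ||
    config$wastewater_per_capita_l_per_d <= 0) {
    abort("wastewater_per_capita_l_per_d must be positive")
  }
  if (is.na(config$correction_factor)) {
    if (is.finite(config$pct_population) && config$pct_population > 0) {
      config$correction_factor <- p / config$pct_population
    } else {
      config$correction_factor <- 1
    }
  }
  f <- config$correction_factor
  if (!is.finite(f) || f <= 0 || f > 1) {
    abort("correction_factor must lie in (0, 1]")
  }
  config
}

#' @export
print.wbe_catchment <- function(x, ...) {
  cat(
    "<wbe_catchment> ", x$wwtp_id,
    ": P = ", format(x$population_served, big.mark = ","),
    ", L = ", x$wastewater_per_capita_l_per_d, " L/cap/d",
    if (!is.na(x$correction_factor)) paste0(", F = ", signif(x$correction_factor, 3)),
    "\n",
    sep = ""
  )
  invisible(x)
}
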
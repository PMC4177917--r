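#' Per-site daily river loads and per-capita usage
#'
#' A single grab sample is treated as the day's representative
#' concentration: the site's daily load is concentration times the daily
#' mean gauged flow, and the per-capita figure divides by the population
#' upstream of the site. Censored samples carry zero load under the default
#' policy.
#'
#' @param river River sample tibble with columns `site`, `analyte`, `date`,
#'   `conc_ng_l`, `censored`, `loq_ng_l`, `flow_m3_d`,
#'   `upstream_population` (as produced by [simulate_river_network()]).
#' @param policy Censoring substitution policy, see [censored_value()].
#' @return The input with `daily_load_mg_d` and `per_capita_ug_cap_d`
#'   appended.
#' @export
site_daily_load <- function(river, policy = "zero") {
  if (any(river$flow_m3_d[!river$censored] <= 0)) {
    abort("river flow must be positive where a concentration was quantified")
  }
  conc <- ifelse(river$censored,
    censored_value(river$loq_ng_l, policy), river$conc_ng_l
  )
  river$daily_load_mg_d <- conc * river$flow_m3_d * UG_PER_NG_M3
  river$per_capita_ug_cap_d <- per_capita_load(
    river$daily_load_mg_d, river$upstream_population
  )
  river
}

#' Regress river load on upstream population
#'
#' Ordinary least squares of a site's daily load on its upstream population,
#' for one analyte and sampling date. A tight positive relationship is the
#' signature of a conservative, widely used analyte whose river load simply
#' accumulates people downstream.
#'
#' @param site_loads Output of [site_daily_load()] filtered to one analyte
#'   and date (rows with censored samples are dropped before fitting).
#' @param min_sites Minimum number of quantified sites required (default 3);
#'   below it the fit is undefined and all results are `NA`.
#' @return A one-row tibble: `slope` (mg/d per person), `intercept`,
#'   `r_squared`, `n_sites`.
#' @export
population_load_regression <- function(site_loads, min_sites = 3) {
  pts <- site_loads[!site_loads$censored, ]
  if (nrow(pts) < min_sites) {
    return(tibble::tibble(
      slope = NA_real_, intercept = NA_real_,
      r_squared = NA_real_, n_sites = nrow(pts)
    ))
  }
  fit <- lm(daily_load_mg_d ~ upstream_population, data = pts)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n_sites = nrow(pts)
  )
}

#' Summarise sampling periods (pandemic vs non-pandemic)
#'
#' Splits labelled river samples into periods and reports, per period and
#' analyte, the detection fraction and the mean/maximum quantified
#' concentration; and per period the mean and standard deviation of the
#' number of distinct analytes detected per site (sites where nothing was
#' detected count as zero).
#'
#' @param samples River sample tibble with `site`, `analyte`, `conc_ng_l`,
#'   `censored`.
#' @param period Character vector (recycled) labelling each row, e.g.
#'   `"pandemic"`, `"late_pandemic"`, `"inter_pandemic"`.
#' @return A list of two tibbles: `analyte_stats` (`period`, `analyte`,
#'   `detection_fraction`, `mean_conc_above_loq`, `max_conc`) and
#'   `site_counts` (`period`, `mean_analytes_per_site`,
#'   `sd_analytes_per_site`).
#' @export
period_summary <- function(samples, period) {
  if (nrow(samples) == 0) abort("empty sample set")
  samples$period <- rep_len(period, nrow(samples))
  analyte_stats <- dplyr::summarise(
    dplyr::group_by(samples, .data$period, .data$analyte),
    detection_fraction = mean(!.data$censored),
    mean_conc_above_loq = ifelse(any(!.data$censored),
      mean(.data$conc_ng_l[!.data$censored]), NA_real_
    ),
    max_conc = ifelse(any(!.data$censored),
      max(.data$conc_ng_l[!.data$censored]), NA_real_
    ),
    .groups = "drop"
  )
  per_site <- dplyr::summarise(
    dplyr::group_by(samples, .data$period, .data$site),
    n_detected = dplyr::n_distinct(.data$analyte[!.data$censored]),
    .groups = "drop"
  )
  site_counts <- dplyr::summarise(
    dplyr::group_by(per_site, .data$period),
    mean_analytes_per_site = mean(.data$n_detected),
    sd_analytes_per_site = sd(.data$n_detected),
    .groups = "drop"
  )
  list(analyte_stats = analyte_stats, site_counts = site_counts)
}
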
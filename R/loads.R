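#' Convert a concentration and flow to an hourly mass load
#'
#' A concentration in ng/L times a volume in m^3 gives micrograms; divided by
#' 1000 this is the hourly load in mg/h.
#'
#' @param conc_ng_l Concentration in ng/L (vectorised).
#' @param flow_m3_h Flow over the hour in m^3/h (vectorised).
#' @return Load in mg/h.
#' @export
#' @examples
#' hourly_load(100, 10) # 1 mg/h
hourly_load <- function(conc_ng_l, flow_m3_h) {
  if (any(conc_ng_l < 0, na.rm = TRUE) || any(flow_m3_h < 0, na.rm = TRUE)) {
    abort("concentrations and flows must be nonnegative")
  }
  conc_ng_l * flow_m3_h * UG_PER_NG_M3
}

#' Substitute a value for censored measurements under a named policy
#'
#' Censored (<LOQ) measurements carry no numeric value at the storage layer;
#' any substitution for load arithmetic is explicit. `"zero"` (the default
#' everywhere) treats a censored hour as contributing no mass — a
#' conservative lower bound on the load; `"half_loq"` and `"loq"` bound the
#' load from above.
#'
#' @param loq_ng_l The analyte's limit of quantification, ng/L.
#' @param policy One of `"zero"`, `"half_loq"`, `"loq"`.
#' @return The substituted concentration in ng/L.
#' @export
censored_value <- function(loq_ng_l, policy = c("zero", "half_loq", "loq")) {
  policy <- match.arg(policy)
  switch(policy,
    zero = 0 * loq_ng_l,
    half_loq = loq_ng_l / 2,
    loq = loq_ng_l
  )
}

#' Summarise one day of hourly samples into a load summary
#'
#' Computes the quantities reported per analyte and stream: the 24-h mass
#' load (sum of hourly loads, censored hours substituted under `policy`), the
#' maximum hourly load and the clock time at which it occurred, the mean and
#' standard deviation of concentrations above the LOQ, and detection counts.
#'
#' @param series Tibble for one site/matrix/analyte with columns `timestamp`,
#'   `conc_ng_l`, `censored`, `loq_ng_l` (as from [read_sample_series()]).
#' @param flows Tibble with `timestamp` and `flow_m3_h`, covering the same
#'   hours.
#' @param policy Censoring substitution policy, see [censored_value()].
#' @param expected_hours Number of hourly samples that constitute a complete
#'   day (default 24).
#' @param allow_gaps If `TRUE`, missing hours are tolerated and the daily
#'   load is renormalised by the covered fraction of the day; otherwise
#'   missing hours are an error.
#' @return A one-row tibble: `daily_load_mg_d`, `max_hourly_load_mg_h`,
#'   `max_hour`, `mean_conc_above_loq_ng_l`, `sd_conc_above_loq`,
#'   `n_above_loq`, `n_total`.
#' @export
daily_load <- function(series, flows, policy = c("zero", "half_loq", "loq"),
                       expected_hours = 24, allow_gaps = FALSE) {
  policy <- match.arg(policy)
  joined <- dplyr::inner_join(series, flows[, c("timestamp", "flow_m3_h")],
    by = "timestamp"
  )
  if (nrow(joined) < nrow(series)) {
    abort("flow series does not cover every sample timestamp")
  }
  n <- nrow(joined)
  if (n < expected_hours && !allow_gaps) {
    abort(paste0(
      "incomplete day: ", n, " of ", expected_hours,
      " hourly samples present (set allow_gaps = TRUE to renormalise)"
    ))
  }
  conc <- ifelse(joined$censored,
    censored_value(joined$loq_ng_l, policy),
    joined$conc_ng_l
  )
  loads <- hourly_load(conc, joined$flow_m3_h)
  total <- sum(loads)
  if (n < expected_hours) total <- total * expected_hours / n

  above <- joined$conc_ng_l[!joined$censored]
  i_max <- if (n > 0 && any(loads > 0)) which.max(loads) else NA_integer_
  tibble::tibble(
    daily_load_mg_d = total,
    max_hourly_load_mg_h = if (is.na(i_max)) 0 else loads[i_max],
    max_hour = if (is.na(i_max)) as.POSIXct(NA) else joined$timestamp[i_max],
    mean_conc_above_loq_ng_l = if (length(above)) mean(above) else NA_real_,
    sd_conc_above_loq = if (length(above) > 1) sd(above) else NA_real_,
    n_above_loq = length(above),
    n_total = n
  )
}

#' Summarise all analytes and streams of a WWTP sampling day
#'
#' Applies [daily_load()] per site/matrix/analyte and appends the per-capita
#' load when a population is given.
#'
#' @param samples Sample tibble from [read_sample_series()] (influent and/or
#'   effluent rows).
#' @param flows Hourly flow tibble with `site`, `timestamp`, `flow_m3_h`.
#' @param population Population served, for the per-capita column; `NA` to
#'   skip it.
#' @inheritParams daily_load
#' @return A tibble with one row per site/matrix/analyte, the [daily_load()]
#'   columns and `per_capita_ug_cap_d`.
#' @export
summarise_loads <- function(samples, flows, population = NA_real_,
                            policy = "zero", expected_hours = 24,
                            allow_gaps = FALSE) {
  groups <- dplyr::group_split(
    dplyr::group_by(samples, .data$site, .data$matrix, .data$analyte)
  )
  rows <- lapply(groups, function(g) {
    fl <- flows[flows$site == g$site[1], ]
    res <- daily_load(g, fl,
      policy = policy, expected_hours = expected_hours,
      allow_gaps = allow_gaps
    )
    dplyr::bind_cols(
      tibble::tibble(site = g$site[1], matrix = g$matrix[1], analyte = g$analyte[1]),
      res
    )
  })
  out <- dplyr::bind_rows(rows)
  out$per_capita_ug_cap_d <- per_capita_load(out$daily_load_mg_d, population)
  out
}

#' Percent loss of an analyte across a WWTP
#'
#' The removal mass balance: the relative change in 24-h load between
#' influent and effluent, as a signed percentage. Negative values mean the
#' effluent load exceeded the influent load (an apparent in-plant increase).
#' When the influent load is zero (every influent sample censored) but the
#' effluent carries mass, no percentage is defined; the result is `NA` with
#' `influent_below_loq = TRUE`, rendered as `"<"` in reports.
#'
#' @param influent_mg_d Influent 24-h load, mg/d (vectorised).
#' @param effluent_mg_d Effluent 24-h load, mg/d (vectorised).
#' @return A tibble: `influent_load_mg_d`, `effluent_load_mg_d`,
#'   `percent_loss` (full precision), `influent_below_loq`.
#' @export
#' @examples
#' percent_loss(410, 206)$percent_loss # ~50
percent_loss <- function(influent_mg_d, effluent_mg_d) {
  n <- max(length(influent_mg_d), length(effluent_mg_d))
  influent_mg_d <- rep_len(influent_mg_d, n)
  effluent_mg_d <- rep_len(effluent_mg_d, n)
  sentinel <- influent_mg_d == 0 & effluent_mg_d > 0
  pct <- ifelse(influent_mg_d > 0,
    100 * (influent_mg_d - effluent_mg_d) / influent_mg_d,
    ifelse(effluent_mg_d == 0, 0, NA_real_)
  )
  tibble::tibble(
    influent_load_mg_d = influent_mg_d,
    effluent_load_mg_d = effluent_mg_d,
    percent_loss = pct,
    influent_below_loq = sentinel
  )
}

#' Pair influent and effluent load summaries into a removal table
#'
#' @param summaries Output of [summarise_loads()] containing both `influent`
#'   and `effluent` rows for one site.
#' @return One row per analyte with the [percent_loss()] columns.
#' @export
removal_table <- function(summaries) {
  infl <- summaries[summaries$matrix == "influent", ]
  effl <- summaries[summaries$matrix == "effluent", ]
  merged <- dplyr::inner_join(
    dplyr::select(infl, "site", "analyte", infl_load = "daily_load_mg_d"),
    dplyr::select(effl, "site", "analyte", effl_load = "daily_load_mg_d"),
    by = c("site", "analyte")
  )
  dplyr::bind_cols(
    dplyr::select(merged, "site", "analyte"),
    percent_loss(merged$infl_load, merged$effl_load)
  )
}

#' Per-capita daily load
#'
#' @param daily_load_mg_d Daily load in mg/d (vectorised).
#' @param population Population contributing to the flow.
#' @return Load in ug per capita per day.
#' @export
#' @examples
#' per_capita_load(18600, 208000) # ~89 ug/cap/d
per_capita_load <- function(daily_load_mg_d, population) {
  if (any(!is.na(population) & population <= 0)) {
    abort("population must be positive")
  }
  daily_load_mg_d * UG_PER_MG / population
}

#' Fraction of samples above the limit of quantification
#'
#' @param series Sample tibble with a logical `censored` column, or a logical
#'   vector of censoring flags.
#' @return Fraction of measurements above the LOQ, in `[0, 1]`.
#' @export
detection_frequency <- function(series) {
  censored <- if (is.data.frame(series)) series$censored else series
  if (length(censored) == 0) abort("empty series")
  mean(!censored)
}
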
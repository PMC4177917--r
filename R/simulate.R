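#' Configure a synthetic WWTP / river study
#'
#' The generator reproduces the statistical structure a 24-h composite
#' sampling campaign sees in a sewer catchment: a bimodal diurnal flow,
#' drug mass arriving as discrete toilet-flush pulses from a finite number of
#' users, multiplicative lognormal measurement noise, left-censoring at each
#' analyte's LOQ, first-order in-plant removal with a hydraulic retention
#' shift, and downstream river sites diluting the summed upstream per-capita
#' load. Simulation truth (exact excreted mass, removal and user counts) is
#' recorded so downstream estimators can be validated.
#'
#' @param seed Integer seed; a fixed seed and config give identical output.
#' @param population Population connected to the plant. Default 6230, a
#'   small trickling-filter catchment.
#' @param l_per_capita Wastewater produced per person, L/cap/d (default 230).
#' @param analytes Tibble with one row per simulated analyte: `analyte`
#'   (must appear in [analyte_table()]), `n_users` (people actively taking
#'   the drug), `dose_g_d` (consumed dose per user per day, grams) and
#'   `removal_fraction` (fraction of the load removed in the plant, in
#'   `[0, 1]`). Default: [default_sim_analytes()].
#' @param flushes_per_user_per_d Mean number of flush events per user per
#'   day (default 4).
#' @param diurnal_amplitude Relative amplitude of the flow's diurnal
#'   modulation, in `[0, 1)` (default 0.4).
#' @param retention_h Hydraulic retention time in hours (default 8).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.3).
#' @param river_sites Tibble `site_id`, `upstream_population` (nondecreasing
#'   downstream), `flow_m3_d`. Default: [default_river_sites()].
#' @param date Date of the simulated sampling day.
#' @return A list with class `wbe_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              population = 6230,
                              l_per_capita = 230,
                              analytes = default_sim_analytes(population),
                              flushes_per_user_per_d = 4,
                              diurnal_amplitude = 0.4,
                              retention_h = 8,
                              noise_cv = 0.3,
                              river_sites = default_river_sites(),
                              date = as.Date("2009-11-10")) {
  if (!is.finite(population) || population <= 0) abort("population must be positive")
  if (diurnal_amplitude < 0 || diurnal_amplitude >= 1) {
    abort("diurnal_amplitude must lie in [0, 1)")
  }
  if (retention_h < 0) abort("retention_h must be nonnegative")
  if (noise_cv < 0) abort("noise_cv must be nonnegative")
  stopifnot(all(c("analyte", "n_users", "dose_g_d", "removal_fraction")
  %in% names(analytes)))
  if (any(analytes$removal_fraction < 0 | analytes$removal_fraction > 1)) {
    abort("removal fractions must lie in [0, 1]")
  }
  ref <- analyte_table()
  unknown <- setdiff(analytes$analyte, ref$analyte)
  if (length(unknown) > 0) {
    abort(paste0("unknown analyte(s): ", paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      seed = as.integer(seed), population = population,
      l_per_capita = l_per_capita, analytes = analytes,
      flushes_per_user_per_d = flushes_per_user_per_d,
      diurnal_amplitude = diurnal_amplitude, retention_h = retention_h,
      noise_cv = noise_cv, river_sites = river_sites, date = as.Date(date)
    ),
    class = "wbe_sim_config"
  )
}

#' Default analyte roster for the simulator
#'
#' Four analytes spanning the behaviours the pipeline must handle: a
#' conservative antiviral under pandemic-scale use (oseltamivir carboxylate,
#' user rate between the national 0.13% dispensing rate and observed
#' compliance), a heavily used and moderately removed antibiotic
#' (erythromycin), a fully excreted antibiotic (trimethoprim) and a
#' well-removed decongestant (naphazoline). Doses are daily adult regimes;
#' removal fractions are typical of a small trickling-filter plant.
#'
#' @param population Catchment population the user counts scale with.
#' @return A tibble suitable for [simulation_config()]'s `analytes`.
#' @export
default_sim_analytes <- function(population) {
  tibble::tibble(
    analyte = c(
      "Oseltamivir carboxylate", "Erythromycin", "Trimethoprim", "Naphazoline"
    ),
    n_users = pmax(1L, as.integer(round(population * c(7.5e-4, 2e-3, 1.5e-3, 5e-4)))),
    dose_g_d = c(0.150, 1, 0.4, 0.4),
    removal_fraction = c(0.5, 0.72, 0.84, 0.95)
  )
}

#' Default river network for the simulator
#'
#' Eight nested sites whose upstream populations span a small tributary to a
#' large lowland river, with roughly 2,000 L of river flow available per
#' upstream capita per day.
#'
#' @return A tibble `site_id`, `upstream_population`, `flow_m3_d`.
#' @export
default_river_sites <- function() {
  pop <- c(5e3, 2e4, 5e4, 1e5, 2.5e5, 5e5, 1e6, 2.3e6)
  tibble::tibble(
    site_id = sprintf("TC%02d", seq_along(pop)),
    upstream_population = pop,
    flow_m3_d = pop * 2
  )
}

# Relative diurnal weights of toilet use (flush probability per hour slot
# 0..23), with a strong morning peak (07-09) and a broad evening peak
# (18-22) over a low overnight baseline.
toilet_use_profile <- function() {
  h <- 0:23
  w <- 0.25 +
    2.0 * exp(-((h - 8)^2) / (2 * 1.5^2)) +
    1.2 * exp(-((h - 20)^2) / (2 * 2.5^2))
  w[h <= 4] <- 0.08
  w / sum(w)
}

# sdlog of a lognormal with mean 1 and coefficient of variation cv
lognorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

# multiplicative noise factors with mean 1
noise_factors <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  s <- lognorm_sdlog(cv)
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

hour_timestamps <- function(date, site = NULL) {
  # sample at the end of each covered hour: 01:00 ... 24:00 local clock
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 3600 * (1:24)
}

#' Simulate a 24-h diurnal WWTP flow
#'
#' Hourly dry-weather flows whose daily total is exactly population times
#' per-capita wastewater volume, modulated by a mean-zero bimodal diurnal
#' shape (morning and evening peaks) scaled by `diurnal_amplitude`. With
#' amplitude 0 the flow is flat. The series is deterministic given the
#' config.
#'
#' @param config A [simulation_config()].
#' @param site_id Site label for the output (default `"sim"`).
#' @return Tibble `site`, `timestamp`, `flow_m3_h` with 24 rows.
#' @export
simulate_diurnal_flow <- function(config, site_id = "sim") {
  stopifnot(inherits(config, "wbe_sim_config"))
  base <- config$population * config$l_per_capita / 24 / 1000 # m3/h
  shape <- toilet_use_profile()
  s <- shape - mean(shape)
  s <- s / max(abs(s))
  flows <- base * (1 + config$diurnal_amplitude * s)
  # the mean-zero shape keeps the daily total exact; re-centre defensively
  flows <- flows + (base * 24 - sum(flows)) / 24
  tibble::tibble(
    site = site_id,
    timestamp = hour_timestamps(config$date),
    flow_m3_h = flows
  )
}

#' Simulate influent concentrations for one sampling day
#'
#' Each simulated user consumes their daily dose and excretes
#' `dose * excreted_fraction` into the sewer as discrete flush pulses: the
#' user's flush count for the day is Poisson-distributed around
#' `flushes_per_user_per_d` (minimum one flush, so every user's full daily
#' mass reaches the sewer and mass is conserved exactly), and each flush
#' falls into an hour drawn from the diurnal toilet-use profile. The hourly
#' concentration is the mass arriving in the hour over the hour's flow, with
#' multiplicative lognormal noise; values below the analyte's LOQ are
#' censored. Small catchments therefore show the high hour-to-hour
#' variability that single flush events cause in real small-sewer sampling.
#'
#' @param config A [simulation_config()].
#' @param site_id Site label.
#' @return A list: `samples` (influent sample tibble in the
#'   [read_sample_series()] layout), `flows` (hourly flow tibble), `truth`
#'   (per analyte: `true_mass_mg_d` = n_users * dose * excreted_fraction
#'   exactly, `true_removal`, `true_users`), and `hourly_mass_mg`
#'   (noise-free hourly mass per analyte, used by [simulate_effluent()]).
#' @export
simulate_influent <- function(config, site_id = "sim") {
  stopifnot(inherits(config, "wbe_sim_config"))
  set.seed(config$seed)
  flows <- simulate_diurnal_flow(config, site_id)
  if (any(flows$flow_m3_h <= 0)) abort("simulated flow must stay positive")
  ref <- analyte_table()
  profile <- toilet_use_profile()
  ts <- flows$timestamp

  per_analyte <- lapply(seq_len(nrow(config$analytes)), function(i) {
    row <- config$analytes[i, ]
    spec <- analyte_spec(row$analyte, ref)
    user_mass_mg <- row$dose_g_d * spec$excreted_fraction * 1000
    hourly_mass <- numeric(24)
    if (row$n_users > 0) {
      k <- pmax(1L, rpois(row$n_users, config$flushes_per_user_per_d))
      for (u in seq_len(row$n_users)) {
        hrs <- sample.int(24, size = k[u], replace = TRUE, prob = profile)
        tab <- tabulate(hrs, nbins = 24)
        hourly_mass <- hourly_mass + tab * (user_mass_mg / k[u])
      }
    }
    conc <- hourly_mass / flows$flow_m3_h * NG_L_PER_MG_M3
    conc <- conc * noise_factors(24, config$noise_cv)
    censored <- conc < spec$loq_ng_l
    list(
      samples = tibble::tibble(
        site = site_id, matrix = "influent", analyte = row$analyte,
        timestamp = ts,
        conc_ng_l = ifelse(censored, NA_real_, conc),
        censored = censored, loq_ng_l = spec$loq_ng_l
      ),
      truth = tibble::tibble(
        analyte = row$analyte,
        true_mass_mg_d = row$n_users * row$dose_g_d * spec$excreted_fraction * 1000,
        true_removal = row$removal_fraction,
        true_users = row$n_users
      ),
      hourly = tibble::tibble(
        analyte = row$analyte, timestamp = ts, mass_mg = hourly_mass
      )
    )
  })

  list(
    samples = dplyr::bind_rows(lapply(per_analyte, `[[`, "samples")),
    flows = flows,
    truth = dplyr::bind_rows(lapply(per_analyte, `[[`, "truth")),
    hourly_mass_mg = dplyr::bind_rows(lapply(per_analyte, `[[`, "hourly"))
  )
}

#' Simulate effluent concentrations from a simulated influent
#'
#' The effluent hourly load is the noise-free influent hourly load shifted
#' circularly by the hydraulic retention time (influent and effluent are
#' sampled simultaneously over the same day) and scaled by
#' `1 - removal_fraction`, then re-noised and re-censored against the LOQ.
#'
#' @param influent Output of [simulate_influent()].
#' @param config The same [simulation_config()].
#' @return An effluent sample tibble in the [read_sample_series()] layout.
#' @export
simulate_effluent <- function(influent, config) {
  stopifnot(inherits(config, "wbe_sim_config"))
  if (config$retention_h < 0) abort("retention_h must be nonnegative")
  set.seed(config$seed + 1L)
  flows <- influent$flows
  shift <- as.integer(round(config$retention_h)) %% 24
  ref <- analyte_table()
  rows <- lapply(seq_len(nrow(config$analytes)), function(i) {
    row <- config$analytes[i, ]
    spec <- analyte_spec(row$analyte, ref)
    hm <- influent$hourly_mass_mg$mass_mg[
      influent$hourly_mass_mg$analyte == row$analyte
    ]
    shifted <- if (shift == 0) hm else c(utils::tail(hm, shift), utils::head(hm, 24 - shift))
    out_mass <- shifted * (1 - row$removal_fraction)
    conc <- out_mass / flows$flow_m3_h * NG_L_PER_MG_M3
    conc <- conc * noise_factors(24, config$noise_cv)
    censored <- conc < spec$loq_ng_l
    tibble::tibble(
      site = flows$site[1], matrix = "effluent", analyte = row$analyte,
      timestamp = flows$timestamp,
      conc_ng_l = ifelse(censored, NA_real_, conc),
      censored = censored, loq_ng_l = spec$loq_ng_l
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a river network fed by upstream catchments
#'
#' Every person upstream of a site contributes the same per-capita excreted
#' load as in the simulated WWTP catchment; in-plant removal is applied
#' before discharge and the analyte is treated as conservative in the river.
#' Each site's concentration is its summed daily load over its daily flow,
#' observed through one noisy grab sample per site and censored at the LOQ.
#'
#' @param config A [simulation_config()] (uses `river_sites`, the analyte
#'   roster and `noise_cv`).
#' @param truth Per-analyte truth tibble from [simulate_influent()]; its
#'   per-capita excreted load (true mass / population) scales the network.
#' @return A tibble: one row per site and analyte with
#'   `upstream_population`, `flow_m3_d`, `true_load_mg_d`, `conc_ng_l`
#'   (`NA` when censored), `censored`, `loq_ng_l`, `date`.
#' @export
simulate_river_network <- function(config, truth) {
  stopifnot(inherits(config, "wbe_sim_config"))
  sites <- config$river_sites
  if (is.unsorted(sites$upstream_population)) {
    abort("river sites must be ordered downstream with nondecreasing population")
  }
  if (any(sites$flow_m3_d <= 0)) abort("river flow must be positive")
  set.seed(config$seed + 2L)
  ref <- analyte_table()
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    spec <- analyte_spec(tr$analyte, ref)
    pc_load <- tr$true_mass_mg_d / config$population # mg/cap/d excreted
    load <- pc_load * sites$upstream_population * (1 - tr$true_removal)
    conc <- load / sites$flow_m3_d * NG_L_PER_MG_M3
    conc <- conc * noise_factors(nrow(sites), config$noise_cv)
    censored <- conc < spec$loq_ng_l
    tibble::tibble(
      site = sites$site_id, matrix = "river", analyte = tr$analyte,
      date = config$date,
      upstream_population = sites$upstream_population,
      flow_m3_d = sites$flow_m3_d,
      true_load_mg_d = load,
      conc_ng_l = ifelse(censored, NA_real_, conc),
      censored = censored, loq_ng_l = spec$loq_ng_l
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full synthetic study
#'
#' Convenience wrapper: influent, effluent and river network from one
#' config.
#'
#' @param config A [simulation_config()].
#' @param site_id WWTP site label.
#' @return A list `samples` (influent + effluent rows), `flows`, `river`,
#'   `truth`, `hourly_mass_mg`.
#' @export
simulate_study <- function(config, site_id = "sim") {
  infl <- simulate_influent(config, site_id)
  effl <- simulate_effluent(infl, config)
  river <- simulate_river_network(config, infl$truth)
  list(
    samples = dplyr::bind_rows(infl$samples, effl),
    flows = infl$flows,
    river = river,
    truth = infl$truth,
    hourly_mass_mg = infl$hourly_mass_mg
  )
}

#' Write a simulated study to CSV files
#'
#' Emits the same CSV dialects the readers consume: `samples.csv`
#' (influent/effluent), `flows.csv`, `river.csv` and `truth.csv`.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_series(sim$samples, file.path(dir, "samples.csv"))
  write_flow_series(sim$flows, file.path(dir, "flows.csv"))
  river <- sim$river
  river$value <- ifelse(river$censored, "<LOQ",
    format(river$conc_ng_l, trim = TRUE, scientific = FALSE)
  )
  readr::write_csv(
    river[, c(
      "site", "matrix", "analyte", "date", "upstream_population",
      "flow_m3_d", "value"
    )],
    file.path(dir, "river.csv")
  )
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
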
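#' Display formatting helpers
#'
#' Reports follow the conventions of published WWTP monitoring tables:
#' above-LOQ mean and standard deviation as integer ng/L (`"433±472"`),
#' daily loads to three significant figures, percent loss to the nearest
#' integer with a leading minus for in-plant increases, `"<"` where the
#' influent was entirely below the LOQ while the effluent was not, and
#' `"na"` where a quantity is undefined. Full precision is always available
#' in the machine-readable summaries; rounding happens only here.
#'
#' @param mean_conc,sd_conc Mean and sd of above-LOQ concentrations, ng/L.
#' @return A character vector.
#' @export
fmt_mean_sd <- function(mean_conc, sd_conc) {
  ifelse(is.na(mean_conc), "<LOQ",
    ifelse(is.na(sd_conc),
      sprintf("%d", round(mean_conc)),
      sprintf("%d±%d", round(mean_conc), round(sd_conc))
    )
  )
}

#' @rdname fmt_mean_sd
#' @param load_mg_d Daily load, mg/d.
#' @export
fmt_load <- function(load_mg_d) {
  vapply(load_mg_d, function(x) {
    if (is.na(x)) {
      "na"
    } else {
      format(signif(x, 3), trim = TRUE, scientific = FALSE, big.mark = "")
    }
  }, character(1))
}

#' @rdname fmt_mean_sd
#' @param percent_loss Signed percent loss, full precision.
#' @param influent_below_loq Logical sentinel flag from [percent_loss()].
#' @export
fmt_percent_loss <- function(percent_loss, influent_below_loq = FALSE) {
  n <- max(length(percent_loss), length(influent_below_loq))
  percent_loss <- rep_len(percent_loss, n)
  influent_below_loq <- rep_len(influent_below_loq, n)
  ifelse(influent_below_loq, "<",
    ifelse(is.na(percent_loss), "na",
      sprintf("%d%%", round(percent_loss))
    )
  )
}

#' Round a percent loss the way reports print it
#'
#' @param percent_loss Signed percent loss, full precision.
#' @return Nearest-integer percent, sign preserved.
#' @export
display_percent_loss <- function(percent_loss) round(percent_loss)

#' Render the WWTP fate table
#'
#' One row per analyte and site: influent and effluent above-LOQ
#' mean±sd concentrations, 24-h loads and the percent loss, formatted
#' as in published monitoring tables (see [fmt_mean_sd()]).
#'
#' @param summaries Output of [summarise_loads()] with influent and effluent
#'   rows.
#' @param removals Output of [removal_table()] for the same summaries.
#' @return A tibble of display strings: `site`, `analyte`,
#'   `influent_conc`, `effluent_conc`, `influent_load`, `effluent_load`,
#'   `percent_loss`.
#' @export
render_table2 <- function(summaries, removals) {
  infl <- summaries[summaries$matrix == "influent", ]
  effl <- summaries[summaries$matrix == "effluent", ]
  if (nrow(infl) == 0 || nrow(effl) == 0) {
    abort("summaries must contain both influent and effluent rows")
  }
  merged <- dplyr::full_join(
    dplyr::select(infl, "site", "analyte",
      infl_mean = "mean_conc_above_loq_ng_l", infl_sd = "sd_conc_above_loq",
      infl_load = "daily_load_mg_d"
    ),
    dplyr::select(effl, "site", "analyte",
      effl_mean = "mean_conc_above_loq_ng_l", effl_sd = "sd_conc_above_loq",
      effl_load = "daily_load_mg_d"
    ),
    by = c("site", "analyte")
  )
  merged <- dplyr::left_join(merged,
    dplyr::select(removals, "site", "analyte", "percent_loss", "influent_below_loq"),
    by = c("site", "analyte")
  )
  tibble::tibble(
    site = merged$site,
    analyte = merged$analyte,
    influent_conc = fmt_mean_sd(merged$infl_mean, merged$infl_sd),
    effluent_conc = fmt_mean_sd(merged$effl_mean, merged$effl_sd),
    influent_load = fmt_load(merged$infl_load),
    effluent_load = fmt_load(merged$effl_load),
    percent_loss = ifelse(is.na(merged$percent_loss) & !merged$influent_below_loq %in% TRUE,
      "na",
      fmt_percent_loss(merged$percent_loss, merged$influent_below_loq %in% TRUE)
    )
  )
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a study (or reads previously written CSV inputs), computes load
#' summaries, the removal table, user estimates and river loads with the
#' population regression, and writes every artefact as CSV. Progress is
#' logged to stderr with per-stage row counts. Outputs are deterministic
#' given the config seed.
#'
#' @param config A [simulation_config()].
#' @param out_dir Directory for output artefacts (created if needed).
#' @param input_dir Optional directory holding `samples.csv` and `flows.csv`
#'   (and optionally `river.csv`) to analyse instead of simulating; missing
#'   files are an error naming the path.
#' @param policy Censoring policy for all load arithmetic.
#' @param surveillance_rate Rate for the surveillance user prediction.
#' @return Invisibly, a list with the main tibbles (`summaries`, `removals`,
#'   `table2`, `users`, `river_loads`, `regressions`, `truth`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         out_dir,
                         input_dir = NULL,
                         policy = "zero",
                         surveillance_rate = NPFS_DISPENSING_RATE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[wbepi] ", ...)

  truth <- NULL
  river_raw <- NULL
  if (is.null(input_dir)) {
    log_stage("simulating study (seed ", config$seed, ")")
    sim <- simulate_study(config)
    sim_dir <- file.path(out_dir, "sim")
    write_simulation(sim, sim_dir)
    input_dir <- sim_dir
    truth <- sim$truth
    river_raw <- sim$river
  }
  sample_path <- file.path(input_dir, "samples.csv")
  flow_path <- file.path(input_dir, "flows.csv")
  for (p in c(sample_path, flow_path)) {
    if (!file.exists(p)) abort(paste0("pipeline input missing: ", p))
  }
  samples <- read_sample_series(sample_path)
  flows <- read_flow_series(flow_path)
  log_stage("read ", nrow(samples), " samples, ", nrow(flows), " flow records")

  summaries <- summarise_loads(samples, flows,
    population = config$population, policy = policy
  )
  removals <- removal_table(summaries)
  table2 <- render_table2(summaries, removals)
  log_stage("load summaries: ", nrow(summaries), " rows; removals: ", nrow(removals))

  ref <- analyte_table()
  dosing <- dplyr::left_join(
    dplyr::select(config$analytes, "analyte", "dose_g_d"),
    dplyr::select(ref, "analyte", "excreted_fraction"),
    by = "analyte"
  )
  users <- user_estimate_table(
    summaries[summaries$matrix == "influent", ], dosing,
    population = config$population, rate = surveillance_rate
  )
  log_stage("user estimates: ", nrow(users), " rows")

  river_loads <- NULL
  regressions <- NULL
  if (!is.null(river_raw)) {
    river_loads <- site_daily_load(river_raw, policy = policy)
    regressions <- dplyr::bind_rows(lapply(
      split(river_loads, river_loads$analyte),
      function(x) {
        dplyr::bind_cols(
          tibble::tibble(analyte = x$analyte[1]),
          population_load_regression(x)
        )
      }
    ))
    log_stage("river: ", nrow(river_loads), " site loads")
  }

  readr::write_csv(summaries, file.path(out_dir, "load_summaries.csv"))
  readr::write_csv(removals, file.path(out_dir, "removals.csv"))
  readr::write_csv(table2, file.path(out_dir, "table2.csv"))
  readr::write_csv(users, file.path(out_dir, "users.csv"))
  if (!is.null(river_loads)) {
    readr::write_csv(river_loads, file.path(out_dir, "river_loads.csv"))
    readr::write_csv(regressions, file.path(out_dir, "regressions.csv"))
  }
  log_stage("artefacts written to ", out_dir)

  invisible(list(
    summaries = summaries, removals = removals, table2 = table2,
    users = users, river_loads = river_loads, regressions = regressions,
    truth = truth, out_dir = out_dir
  ))
}
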
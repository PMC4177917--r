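# shared fixture builders -----------------------------------------------

# single-analyte simulation config (oseltamivir carboxylate unless told
# otherwise), small enough for fast property loops
oc_config <- function(seed = 1L, n_users = 5L, dose_g_d = 0.150,
                      removal = 0.5, noise_cv = 0, population = 6230,
                      analyte = "Oseltamivir carboxylate", ...) {
  simulation_config(
    seed = seed,
    population = population,
    analytes = tibble::tibble(
      analyte = analyte, n_users = as.integer(n_users),
      dose_g_d = dose_g_d, removal_fraction = removal
    ),
    noise_cv = noise_cv,
    ...
  )
}

# a hand-built 24-h sample series for one analyte (conc NA where censored)
make_series <- function(conc, censored = is.na(conc), loq = 2,
                        date = as.Date("2009-11-10"),
                        site = "wwtp", matrix = "influent",
                        analyte = "Oseltamivir carboxylate") {
  ts <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 3600 * seq_along(conc)
  tibble::tibble(
    site = site, matrix = matrix, analyte = analyte, timestamp = ts,
    conc_ng_l = ifelse(censored, NA_real_, conc), censored = censored,
    loq_ng_l = loq
  )
}

make_flows <- function(flow_m3_h, n = 24, date = as.Date("2009-11-10"),
                       site = "wwtp") {
  flow <- rep_len(flow_m3_h, n)
  ts <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 3600 * seq_len(n)
  tibble::tibble(site = site, timestamp = ts, flow_m3_h = flow)
}

# write a sample CSV in the on-disk dialect and return its path
write_sample_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("site,matrix,analyte,timestamp,value", rows), path)
  path
}
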
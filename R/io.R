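#' Read a concentration sample file
#'
#' Reads the package's sample CSV dialect: columns
#' `site,matrix,analyte,timestamp,value`, one row per hourly (WWTP) or grab
#' (river) measurement. `value` is a concentration in ng/L or the literal
#' token `"<LOQ"` for a left-censored measurement. Numeric values below the
#' analyte's limit of quantification are also flagged as censored; censored
#' rows carry no numeric concentration downstream — substitution happens only
#' in the load calculations, under an explicit, named policy.
#'
#' Timestamps are ISO 8601 local clock time. Hourly composite samples
#' represent the preceding hour: the 18:00 sample covers 17:00-18:00.
#'
#' @param path Path to the CSV file.
#' @param analytes Analyte reference table (see [analyte_table()]); analyte
#'   names in the file must appear in it.
#' @return A tibble with columns `site`, `matrix`, `analyte`, `timestamp`
#'   (POSIXct, UTC-encoded local clock time), `conc_ng_l` (`NA` when
#'   censored), `censored`, `loq_ng_l`, sorted by site, matrix, analyte and
#'   time.
#' @export
read_sample_series <- function(path, analytes = analyte_table()) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      site = readr::col_character(),
      matrix = readr::col_character(),
      analyte = readr::col_character(),
      timestamp = readr::col_character(),
      value = readr::col_character()
    )
  )
  required <- c("site", "matrix", "analyte", "timestamp", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("sample file missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_matrix <- setdiff(unique(raw$matrix), c("influent", "effluent", "river"))
  if (length(bad_matrix) > 0) {
    abort(paste0("unknown matrix value(s): ", paste(bad_matrix, collapse = ", ")))
  }
  unknown <- setdiff(unique(raw$analyte), analytes$analyte)
  if (length(unknown) > 0) {
    abort(paste0("unknown analyte(s) in sample file: ", paste(unknown, collapse = ", ")))
  }
  ts <- suppressWarnings(readr::parse_datetime(raw$timestamp))
  if (anyNA(ts)) {
    abort(paste0(
      "unparseable timestamp(s): ",
      paste(head(unique(raw$timestamp[is.na(ts)]), 3), collapse = ", ")
    ))
  }

  censored <- trimws(raw$value) == "<LOQ"
  conc <- suppressWarnings(as.numeric(raw$value))
  if (any(!censored & is.na(conc))) {
    abort(paste0(
      "unparseable concentration value(s): ",
      paste(head(unique(raw$value[!censored & is.na(conc)]), 3), collapse = ", ")
    ))
  }
  if (any(conc[!censored] < 0)) {
    abort("negative concentration value(s) in sample file")
  }

  out <- tibble::tibble(
    site = raw$site,
    matrix = raw$matrix,
    analyte = raw$analyte,
    timestamp = ts,
    conc_ng_l = ifelse(censored, NA_real_, conc),
    censored = censored
  )
  out <- dplyr::left_join(out,
    dplyr::select(analytes, "analyte", "loq_ng_l"),
    by = "analyte"
  )
  # numeric values below the LOQ are censored too
  below <- !out$censored & out$conc_ng_l < out$loq_ng_l
  out$censored[below] <- TRUE
  out$conc_ng_l[below] <- NA_real_
  out <- dplyr::arrange(out, .data$site, .data$matrix, .data$analyte, .data$timestamp)
  dup <- dplyr::summarise(
    dplyr::group_by(out, .data$site, .data$matrix, .data$analyte),
    dup = anyDuplicated(.data$timestamp) > 0, .groups = "drop"
  )
  if (any(dup$dup)) {
    abort("duplicated timestamps within a site/matrix/analyte series")
  }
  out
}

#' Write a concentration sample file
#'
#' Inverse of [read_sample_series()]: censored rows are written back as the
#' `"<LOQ"` token, so a read/write round trip reproduces the file row for
#' row.
#'
#' @param x A sample tibble as returned by [read_sample_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_series <- function(x, path) {
  out <- tibble::tibble(
    site = x$site,
    matrix = x$matrix,
    analyte = x$analyte,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = ifelse(x$censored, "<LOQ", format(x$conc_ng_l, trim = TRUE, scientific = FALSE))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a flow file
#'
#' Accepts either hourly records (`site,timestamp,flow_m3_h`) or daily
#' records (`site,date,flow_m3_d`).
#'
#' @param path Path to the CSV file.
#' @return A tibble; hourly files yield `site`, `timestamp`, `flow_m3_h`,
#'   daily files `site`, `date`, `flow_m3_d`.
#' @export
read_flow_series <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (all(c("site", "timestamp", "flow_m3_h") %in% names(raw))) {
    ts <- suppressWarnings(readr::parse_datetime(raw$timestamp))
    if (anyNA(ts)) abort("unparseable timestamp(s) in flow file")
    flow <- as.numeric(raw$flow_m3_h)
    if (anyNA(flow) || any(flow < 0)) abort("flows must be nonnegative numbers")
    out <- tibble::tibble(site = raw$site, timestamp = ts, flow_m3_h = flow)
    return(dplyr::arrange(out, .data$site, .data$timestamp))
  }
  if (all(c("site", "date", "flow_m3_d") %in% names(raw))) {
    flow <- as.numeric(raw$flow_m3_d)
    if (anyNA(flow) || any(flow < 0)) abort("flows must be nonnegative numbers")
    return(tibble::tibble(
      site = raw$site, date = as.Date(raw$date), flow_m3_d = flow
    ))
  }
  abort("flow file must have columns site,timestamp,flow_m3_h or site,date,flow_m3_d")
}

#' Write an hourly flow file
#' @param x Tibble with `site`, `timestamp`, `flow_m3_h`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_series <- function(x, path) {
  out <- tibble::tibble(
    site = x$site,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    flow_m3_h = x$flow_m3_h
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read catchment configuration from a YAML file
#'
#' The file holds one block per WWTP, e.g.:
#' ```yaml
#' benson:
#'   population_served: 6230
#'   wastewater_per_capita_l_per_d: 230
#'   pct_population: 16000
#' ```
#'
#' @param path Path to the YAML file.
#' @return A named list of validated [catchment_config()] objects.
#' @export
read_catchment_config <- function(path) {
  spec <- yaml::read_yaml(path)
  out <- lapply(names(spec), function(id) {
    s <- spec[[id]]
    validate_catchment(catchment_config(
      wwtp_id = id,
      population_served = s$population_served,
      wastewater_per_capita_l_per_d = s$wastewater_per_capita_l_per_d %||% 230,
      pct_population = s$pct_population %||% NA_real_,
      correction_factor = s$correction_factor %||% NA_real_
    ))
  })
  setNames(out, names(spec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
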
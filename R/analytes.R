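#' The packaged analyte reference table
#'
#' Dosing, pharmacokinetic and quantification metadata for the fifteen study
#' analytes: eleven antibiotics, three vasoconstrictor decongestants and the
#' antiviral metabolite oseltamivir carboxylate (OC). For each analyte the
#' table carries the Average Daily Quantity (ADQ, grams per prescribing-unit
#' day, an England-specific analogue of the WHO defined daily dose), the
#' fraction of the parent dose excreted in bioactive form, and the analytical
#' limit of quantification (LOQ, ng/L).
#'
#' @return A tibble with one row per analyte and columns `analyte`,
#'   `atc_code`, `drug_class`, `adq_g`, `excreted_fraction`, `loq_ng_l`.
#' @export
#' @examples
#' analyte_table()
analyte_table <- function() {
  path <- system.file("extdata", "analyte_table.csv",
    package = "wbepi", mustWork = TRUE
  )
  tab <- readr::read_csv(path,
    col_types = readr::cols(
      analyte = readr::col_character(),
      atc_code = readr::col_character(),
      drug_class = readr::col_character(),
      adq_g = readr::col_double(),
      excreted_fraction = readr::col_double(),
      loq_ng_l = readr::col_double()
    )
  )
  required <- c(
    "analyte", "atc_code", "drug_class", "adq_g",
    "excreted_fraction", "loq_ng_l"
  )
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0(
      "analyte table fixture is corrupt; missing field(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(!is.finite(tab$adq_g)) || any(tab$adq_g <= 0)) {
    abort("analyte table fixture is corrupt: adq_g must be > 0")
  }
  if (any(tab$excreted_fraction <= 0 | tab$excreted_fraction > 1)) {
    abort("analyte table fixture is corrupt: excreted_fraction must be in (0, 1]")
  }
  if (any(tab$loq_ng_l <= 0)) {
    abort("analyte table fixture is corrupt: loq_ng_l must be > 0")
  }
  tab
}

#' Look up one analyte's metadata
#'
#' @param name Analyte name, matched exactly (case-insensitively) against the
#'   reference table.
#' @param analytes Analyte reference table, defaults to [analyte_table()].
#' @return A one-row tibble.
#' @export
#' @examples
#' analyte_spec("Oseltamivir carboxylate")$adq_g
analyte_spec <- function(name, analytes = analyte_table()) {
  hit <- analytes[tolower(analytes$analyte) == tolower(name), ]
  if (nrow(hit) != 1) {
    abort(paste0("unknown analyte: '", name, "'"))
  }
  hit
}
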
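#' Read a factorial extraction design
#'
#' Reads the table of supercritical-extraction conditions: one row per
#' condition with its temperature (deg C), pressure (bar) and ethanol
#' cosolvent flow (mL/min). The CO2 flow column is optional and defaults to
#' 5 mL/min, the pump setting the design assumes.
#'
#' @param path CSV file with columns `id, temperature, pressure, ethanol_flow`
#'   and optionally `co2_flow`.
#' @return A tibble with one row per condition, in file order.
#' @export
read_design <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_design(df)
}

#' Validate an extraction design table
#'
#' Checks the invariants every design must satisfy: unique condition ids and
#' strictly positive temperature, pressure and flows. Fills in the default
#' CO2 flow when the column is absent.
#'
#' @param design A data frame with columns `id, temperature, pressure,
#'   ethanol_flow` (and optionally `co2_flow`).
#' @param co2_flow_default Default CO2 pump flow in mL/min.
#' @return The validated design as a tibble.
#' @export
validate_design <- function(design, co2_flow_default = 5.0) {
  design <- as_tibble(design)
  if (nrow(design) == 0L) {
    stop_sfelip("design contains no conditions", "no_conditions")
  }
  needed <- c("id", "temperature", "pressure", "ethanol_flow")
  missing <- setdiff(needed, names(design))
  if (length(missing)) {
    stop_sfelip(paste0("design is missing column(s): ",
                       paste(missing, collapse = ", ")), "design_columns")
  }
  if (!"co2_flow" %in% names(design)) design$co2_flow <- co2_flow_default
  design$id <- as.character(design$id)
  if (anyDuplicated(design$id)) {
    stop_sfelip("duplicate condition id in design", "duplicate_condition")
  }
  for (col in c("temperature", "pressure", "ethanol_flow", "co2_flow")) {
    v <- design[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_sfelip(sprintf("design column '%s' must be strictly positive", col),
                  "nonpositive_design")
    }
  }
  design[, c("id", "temperature", "pressure", "ethanol_flow", "co2_flow")]
}

#' Write an extraction design to CSV
#'
#' @param design Validated design tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_csv(validate_design(design), path, progress = FALSE)
  invisible(path)
}

#' The bundled 12-condition factorial design
#'
#' Three temperatures (40, 50, 60 deg C) crossed with two pressures (150,
#' 250 bar) and two ethanol flows (0.6, 0.9 mL/min), labelled SC1..SC12,
#' with CO2 flow fixed at 5 mL/min. This is the default design of the
#' synthetic generator and the worked examples.
#'
#' @return A 12-row design tibble.
#' @export
default_design <- function() {
  read_design(system.file("extdata", "design_sc12.csv", package = "sfelip"))
}
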
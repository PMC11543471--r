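#' Read a lipid recovery table
#'
#' Reads the lipid-by-condition matrix of relative abundances measured in the
#' lipidomic characterisation of the supercritical extracts. The file has one
#' row per annotated lipid (`lipid_id`, `shorthand`, `lipid_class`) followed
#' by one numeric column per extraction condition. Zero cells (no recovery,
#' below the instrument's detection capacity) are preserved as exact `0.0`;
#' the package never rescales abundances at load time.
#'
#' @param path CSV file as described above.
#' @return A `recovery_tbl`: a tibble with the three annotation columns and
#'   one abundance column per condition, carrying the condition ids in
#'   `attr(, "condition_ids")`.
#' @export
read_recovery_table <- function(path) {
  df <- suppressWarnings(     # parse problems handled as classed errors below
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      lipid_id = readr::col_character(),
                      shorthand = readr::col_character(),
                      lipid_class = readr::col_character(),
                      .default = readr::col_double()
                    )))
  prob <- readr::problems(df)
  if (nrow(prob) > 0L) {
    stop_sfelip(sprintf(
      "malformed recovery table: %s at line %d",
      prob$expected[1], prob$row[1]), "malformed_recovery")
  }
  validate_recovery(df)
}

#' Validate a recovery table
#'
#' @param df Data frame with columns `lipid_id`, `shorthand`, `lipid_class`
#'   and one numeric abundance column per condition.
#' @return A validated `recovery_tbl` tibble.
#' @export
validate_recovery <- function(df) {
  df <- as_tibble(df)
  meta <- c("lipid_id", "shorthand", "lipid_class")
  missing <- setdiff(meta, names(df))
  if (length(missing)) {
    stop_sfelip(paste0("recovery table is missing column(s): ",
                       paste(missing, collapse = ", ")), "recovery_columns")
  }
  cond <- setdiff(names(df), meta)
  if (length(cond) == 0L) {
    stop_sfelip("recovery table has no condition columns", "no_conditions")
  }
  if (anyDuplicated(cond)) {
    stop_sfelip("duplicate condition id in recovery table header",
                "duplicate_condition")
  }
  if (anyDuplicated(df$lipid_id)) {
    stop_sfelip("duplicate lipid_id in recovery table", "duplicate_lipid")
  }
  bad_class <- setdiff(unique(df$lipid_class), lipid_classes())
  if (length(bad_class)) {
    stop_sfelip(paste0("unknown lipid class: ",
                       paste(bad_class, collapse = ", ")), "lipid_class")
  }
  for (col in cond) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(!is.finite(v))) {
      stop_sfelip(sprintf("non-numeric or missing abundance in column '%s'", col),
                  "nonnumeric_abundance")
    }
    if (any(v < 0)) {
      stop_sfelip(sprintf("negative abundance in column '%s'", col),
                  "negative_abundance")
    }
  }
  structure(df[, c(meta, cond)],
            condition_ids = cond,
            class = c("recovery_tbl", class(as_tibble(df))))
}

#' Write a recovery table to CSV
#'
#' Inverse of [read_recovery_table()]; valid tables round-trip losslessly.
#'
#' @param recovery A `recovery_tbl`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recovery_table <- function(recovery, path) {
  recovery <- validate_recovery(recovery)
  readr::write_csv(as_tibble(unclass_recovery(recovery)), path, progress = FALSE)
  invisible(path)
}

unclass_recovery <- function(recovery) {
  attr(recovery, "condition_ids") <- NULL
  class(recovery) <- setdiff(class(recovery), "recovery_tbl")
  recovery
}

#' Condition ids of a recovery table
#' @param recovery A `recovery_tbl`.
#' @return Character vector of condition ids, in column order.
#' @export
condition_ids <- function(recovery) {
  attr(recovery, "condition_ids") %||%
    setdiff(names(recovery), c("lipid_id", "shorthand", "lipid_class"))
}

#' Pivot a recovery table to long form
#'
#' One row per (lipid, condition) cell, the shape consumed by
#' [assemble_dataset()] and [class_abundance_summary()].
#'
#' @param recovery A `recovery_tbl`.
#' @return Tibble with columns `lipid_id`, `shorthand`, `lipid_class`,
#'   `condition_id`, `abundance`.
#' @export
recovery_long <- function(recovery) {
  cond <- condition_ids(recovery)
  as_tibble(unclass_recovery(recovery)) |>
    pivot_longer(all_of(cond), names_to = "condition_id",
                 values_to = "abundance")
}
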
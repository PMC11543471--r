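#' Read candidate structure sets
#'
#' Reads the two-column file mapping each lipid shorthand annotation (e.g.
#' `"DG 36:2"`) to its candidate isomeric SMILES, one candidate per line.
#' A shorthand names a sum-composition that several positional or
#' constitutional isomers share, so a family can hold many structures; file
#' order within a family is preserved because it is the tie-break key for
#' the downstream representative selectors.
#'
#' @param path CSV or TSV file with columns `shorthand, smiles` (header row
#'   optional when the two columns are unambiguous).
#' @param validate Check every SMILES with the cheminformatics backend and
#'   fail on the first syntactically invalid one, naming its line.
#' @return Tibble with columns `shorthand`, `candidate_id`, `smiles`;
#'   `candidate_id` is `"<shorthand>#<k>"` with `k` the in-family file order.
#' @export
read_candidate_sets <- function(path, validate = TRUE) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("^\\s*shorthand", first, ignore.case = TRUE)
  df <- readr::read_delim(path, delim = delim, col_names = has_header == TRUE,
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (!has_header) names(df) <- c("shorthand", "smiles")[seq_len(ncol(df))]
  if (!all(c("shorthand", "smiles") %in% names(df))) {
    stop_sfelip("candidate file must have columns shorthand, smiles",
                "candidate_columns")
  }
  df <- as_tibble(df)[, c("shorthand", "smiles")]
  if (validate && nrow(df) > 0L) {
    ok <- smiles_is_valid(df$smiles)
    if (any(!ok)) {
      line <- which(!ok)[1] + as.integer(has_header)
      stop_sfelip(sprintf("invalid SMILES '%s' at line %d",
                          df$smiles[which(!ok)[1]], line), "invalid_smiles")
    }
  }
  df |>
    group_by(.data$shorthand) |>
    mutate(candidate_id = sprintf("%s#%d", .data$shorthand, row_number())) |>
    ungroup() |>
    select("shorthand", "candidate_id", "smiles")
}

#' Write candidate structure sets
#' @param candidates Tibble with columns `shorthand`, `smiles` (extra columns
#'   are dropped).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_sets <- function(candidates, path) {
  readr::write_csv(as_tibble(candidates)[, c("shorthand", "smiles")], path,
                   progress = FALSE)
  invisible(path)
}

#' Check SMILES syntactic validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector, `TRUE` where the backend parses the string into a
#'   valid molecule.
#' @export
smiles_is_valid <- function(smiles) {
  if (length(smiles) == 0L) return(logical(0))
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(setNames(smiles, paste0("m", seq_along(smiles))))
  )
  ok <- rep(FALSE, length(smiles))
  # smiles2sdf drops nothing but marks unparseable entries as invalid SDFs
  valid <- ChemmineR::validSDF(sdf)
  ok[seq_along(valid)] <- valid
  ok & !is.na(smiles) & nzchar(smiles)
}

# Parse SMILES into an SDFset, with a classed error naming the offender.
smiles_to_sdf <- function(smiles, ids = NULL) {
  ids <- ids %||% paste0("m", seq_along(smiles))
  ok <- smiles_is_valid(smiles)
  if (any(!ok)) {
    stop_sfelip(sprintf("invalid SMILES for molecule '%s'", ids[which(!ok)[1]]),
                "invalid_smiles")
  }
  suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids)))
}
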
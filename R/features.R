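#' Assemble the supervised dataset
#'
#' Joins the recovery table, the per-lipid descriptor matrix, the
#' extraction design and (optionally) the IDAC table into one row per
#' (lipid, condition) cell. The target is `log10(abundance)`; exact-zero
#' cells — no recovery, below the instrument's detection capacity — are
#' assigned the arbitrary floor value `censored_value` (default -7, chosen
#' to sit below any detectable abundance) and flagged in `censored`.
#'
#' @param recovery A `recovery_tbl`.
#' @param descriptors Descriptor tibble keyed by `id` = `lipid_id`,
#'   covering every lipid.
#' @param design Extraction design covering every condition.
#' @param idac Optional tibble `lipid_id`, `condition_id`, `idac`.
#' @param censored_value Imputed log10 value for zero cells.
#' @param log_base Base of the logarithmic transform (default 10).
#' @return A `feature_tbl`: tibble with `lipid_id`, `condition_id`,
#'   `censored`, target `y`, then the feature columns (descriptors +
#'   `temperature`, `pressure`, `ethanol_flow` [+ `idac`]); feature names
#'   in `attr(, "feature_cols")`.
#' @export
assemble_dataset <- function(recovery, descriptors, design, idac = NULL,
                             censored_value = -7, log_base = 10) {
  long <- recovery_long(recovery)
  design <- validate_design(design)
  miss_l <- setdiff(long$lipid_id, descriptors$id)
  if (length(miss_l)) {
    stop_sfelip(paste0("lipid(s) missing from descriptors: ",
                       paste(head(miss_l, 3), collapse = ", ")),
                "missing_lipid")
  }
  miss_c <- setdiff(long$condition_id, design$id)
  if (length(miss_c)) {
    stop_sfelip(paste0("condition(s) missing from design: ",
                       paste(miss_c, collapse = ", ")), "missing_condition")
  }
  desc_cols <- descriptor_cols(descriptors)
  out <- long |>
    mutate(censored = .data$abundance == 0,
           y = ifelse(.data$censored, censored_value,
                      log(.data$abundance, base = log_base))) |>
    left_join(rename(descriptors, lipid_id = "id"), by = "lipid_id") |>
    left_join(select(design, "id", "temperature", "pressure", "ethanol_flow"),
              by = c("condition_id" = "id"))
  feat <- c(desc_cols, "temperature", "pressure", "ethanol_flow")
  if (!is.null(idac)) {
    out <- left_join(out, idac, by = c("lipid_id", "condition_id"))
    if (anyNA(out$idac)) {
      stop_sfelip("idac table does not cover every (lipid, condition) cell",
                  "missing_idac")
    }
    feat <- c(feat, "idac")
  }
  out <- out[, c("lipid_id", "condition_id", "censored", "y", feat)]
  if (anyNA(out[, feat])) {
    stop_sfelip("assembled features contain missing values", "missing_features")
  }
  structure(out, feature_cols = feat, censored_value = censored_value,
            class = c("feature_tbl", class(tibble())))
}

#' Feature column names of an assembled dataset
#' @param ft A `feature_tbl`.
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(ft) attr(ft, "feature_cols")

#' Split the dataset for the leave-one-condition-out protocol
#'
#' All rows of the held-out condition form the validation set — the probe
#' of generalisation to unseen process settings; the remaining rows are
#' split uniformly at random into train and test at
#' `(1 - test_fraction) : test_fraction`. The three sets partition the
#' table.
#'
#' @param ft A `feature_tbl`.
#' @param holdout_condition Condition id to hold out entirely (default
#'   `"SC5"`).
#' @param test_fraction Fraction of non-holdout rows assigned to test.
#' @param seed Integer seed for the random split.
#' @return `ft` with a `split` column (`"train"`, `"test"`,
#'   `"validation"`).
#' @export
split_dataset <- function(ft, holdout_condition = "SC5", test_fraction = 0.2,
                          seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_sfelip("test_fraction must lie in (0, 1)", "test_fraction")
  }
  if (!holdout_condition %in% ft$condition_id) {
    stop_sfelip(sprintf("holdout condition '%s' absent from data",
                        holdout_condition), "holdout_absent")
  }
  split <- rep("train", nrow(ft))
  split[ft$condition_id == holdout_condition] <- "validation"
  rest <- which(split == "train")
  n_test <- round(length(rest) * test_fraction)
  test_idx <- withr::with_seed(seed, sample(rest, n_test))
  split[test_idx] <- "test"
  ft$split <- split
  ft
}

#' Per-feature correlation with the IDAC column
#'
#' Ranks every other feature by the absolute Pearson correlation of its
#' values with the IDAC feature and flags pairs above the
#' descriptor-pruning threshold — the diagnostic that explains why adding
#' IDAC can be redundant with structure-derived descriptors.
#'
#' @param ft A `feature_tbl` containing an `idac` feature.
#' @param threshold Flagging threshold on `|r|`.
#' @return Tibble `feature`, `r`, `flagged`, sorted by `|r|` descending.
#' @export
feature_redundancy_report <- function(ft, threshold = 0.75) {
  feats <- feature_cols(ft)
  if (!"idac" %in% feats) stop_sfelip("table lacks an idac column", "no_idac")
  others <- setdiff(feats, "idac")
  r <- vapply(others, function(f) {
    suppressWarnings(cor(ft[[f]], ft$idac))
  }, 1)
  r[is.na(r)] <- 0
  tibble(feature = others, r = unname(r), flagged = abs(r) > threshold) |>
    arrange(dplyr::desc(abs(.data$r)))
}
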
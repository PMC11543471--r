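#' The built-in 2D molecular descriptor catalogue
#'
#' Names of the 29 two-dimensional descriptors the package computes from
#' SMILES: Open Babel bulk properties (molecular weight, logP, molar
#' refractivity, topological polar surface area, hydrogen-bond acceptor and
#' donor counts, fluorine count), element counts, bond-order and ring
#' counts, derived size/composition indices, formal-charge counts, and
#' SMARTS-defined functional-group counts that separate the lipid classes
#' (esters, amides, hydroxyls).
#'
#' @return Character vector of descriptor names.
#' @export
descriptor_catalogue <- function() {
  c("MW", "logP", "MR", "TPSA", "HBA1", "HBA2", "HBD", "nF",
    "nC", "nH", "nN", "nO", "nP", "nS",
    "n_bonds", "n_double_bonds", "n_triple_bonds",
    "n_rings", "n_aromatic_rings",
    "n_heavy_atoms", "n_heteroatoms", "frac_heteroatoms",
    "degree_unsaturation", "mw_per_heavy",
    "n_pos_charge", "n_neg_charge",
    "n_ester", "n_amide", "n_hydroxyl")
}

group_smarts <- function() {
  c(n_ester = "[CX3](=O)[OX2][#6]",
    n_amide = "[CX3](=O)[NX3]",
    n_hydroxyl = "[OX2H]")
}

#' Compute molecular descriptors from SMILES
#'
#' One row per molecule, in input order. Descriptors that fail for a
#' molecule are recorded as `NA` rather than aborting the whole matrix;
#' syntactically invalid SMILES are a hard error naming the molecule.
#'
#' @param x Either a character vector of SMILES or a data frame holding one.
#' @param smiles_col,id_col When `x` is a data frame, the columns holding
#'   the SMILES and the molecule ids. Ids default to names of `x` or
#'   `m1, m2, ...`.
#' @param descriptors Which descriptors to compute; defaults to the full
#'   catalogue from [descriptor_catalogue()].
#' @return A tibble with an `id` column followed by one numeric column per
#'   requested descriptor.
#' @export
compute_descriptors <- function(x, smiles_col = "smiles", id_col = NULL,
                                descriptors = descriptor_catalogue()) {
  if (is.data.frame(x)) {
    smiles <- x[[smiles_col]]
    ids <- if (!is.null(id_col)) as.character(x[[id_col]]) else NULL
  } else {
    smiles <- as.character(x)
    ids <- names(x)
  }
  ids <- ids %||% paste0("m", seq_along(smiles))
  unknown <- setdiff(descriptors, descriptor_catalogue())
  if (length(unknown)) {
    stop_sfelip(paste0("unknown descriptor(s): ", paste(unknown, collapse = ", ")),
                "unknown_descriptor")
  }
  # duplicate SMILES are computed once and rows replicated (determinism)
  uniq <- !duplicated(smiles)
  sdf <- smiles_to_sdf(smiles[uniq], ids[uniq])
  full <- descriptor_table(sdf)
  idx <- match(smiles, smiles[uniq])
  out <- full[idx, descriptors, drop = FALSE]
  bind_cols(tibble(id = ids), as_tibble(out))
}

# All 29 catalogue descriptors for an SDFset, as a plain data.frame.
descriptor_table <- function(sdf) {
  n <- length(sdf)
  prop <- ChemmineR::propOB(sdf)
  ac <- ChemmineR::atomcountMA(sdf, addH = TRUE)
  cnt <- function(el) if (el %in% colnames(ac)) ac[, el] else rep(0, n)
  bond_orders <- t(vapply(seq_len(n), function(i) {
    bb <- ChemmineR::bondblock(sdf[[i]])
    ord <- as.numeric(bb[, 3])
    c(total = length(ord), double = sum(ord == 2), triple = sum(ord == 3))
  }, c(total = 0, double = 0, triple = 0)))
  ring <- ChemmineR::rings(sdf, type = "count", arom = TRUE, inner = FALSE)
  if (is.null(dim(ring))) {
    ring <- matrix(ring, nrow = 1, dimnames = list(NULL, names(ring)))
  }
  n_pos <- as.numeric(ChemmineR::smartsSearchOB(sdf, "[*+]", uniqueMatches = FALSE))
  n_neg <- as.numeric(ChemmineR::smartsSearchOB(sdf, "[*-]", uniqueMatches = FALSE))
  grp <- vapply(group_smarts(), function(sm) {
    as.numeric(ChemmineR::smartsSearchOB(sdf, sm, uniqueMatches = FALSE))
  }, numeric(n))
  if (n == 1L) grp <- matrix(grp, nrow = 1, dimnames = list(NULL, names(group_smarts())))
  heavy <- rowSums(ac) - cnt("H")
  hetero <- heavy - cnt("C")
  num <- function(v) suppressWarnings(as.numeric(v))
  data.frame(
    MW = num(prop$MW), logP = num(prop$logP), MR = num(prop$MR),
    TPSA = num(prop$TPSA), HBA1 = num(prop$HBA1), HBA2 = num(prop$HBA2),
    HBD = num(prop$HBD), nF = num(prop$nF),
    nC = cnt("C"), nH = cnt("H"), nN = cnt("N"), nO = cnt("O"),
    nP = cnt("P"), nS = cnt("S"),
    n_bonds = bond_orders[, "total"],
    n_double_bonds = bond_orders[, "double"],
    n_triple_bonds = bond_orders[, "triple"],
    n_rings = as.numeric(ring[, "RINGS"]),
    n_aromatic_rings = as.numeric(ring[, "AROMATIC"]),
    n_heavy_atoms = heavy,
    n_heteroatoms = hetero,
    frac_heteroatoms = ifelse(heavy > 0, hetero / heavy, NA_real_),
    degree_unsaturation = (2 * cnt("C") + 2 + cnt("N") - cnt("H") - cnt("F")) / 2,
    mw_per_heavy = ifelse(heavy > 0, num(prop$MW) / heavy, NA_real_),
    n_pos_charge = n_pos, n_neg_charge = n_neg,
    n_ester = grp[, "n_ester"], n_amide = grp[, "n_amide"],
    n_hydroxyl = grp[, "n_hydroxyl"]
  )
}

descriptor_cols <- function(tbl, id_col = "id") setdiff(names(tbl), id_col)

#' Drop degenerate descriptor columns
#'
#' Removes descriptors with too many missing values or too few distinct
#' values to carry signal. By default any missing value disqualifies a
#' column and constants are removed.
#'
#' @param tbl Descriptor tibble from [compute_descriptors()] (first column
#'   is the molecule id).
#' @param max_missing_fraction Maximum tolerated fraction of missing cells.
#' @param min_unique Minimum number of distinct non-missing values.
#' @return The pruned tibble; the per-column report (`column`, `reason`) is
#'   attached as `attr(, "dropped")` and via [dropped_columns()].
#' @export
drop_degenerate <- function(tbl, max_missing_fraction = 0, min_unique = 2) {
  cols <- descriptor_cols(tbl)
  dropped <- list()
  keep <- character(0)
  for (col in cols) {
    v <- tbl[[col]]
    miss <- mean(is.na(v))
    n_uniq <- length(unique(v[!is.na(v)]))
    if (miss > max_missing_fraction) {
      dropped[[col]] <- tibble(column = col, reason = "missing")
    } else if (n_uniq < min_unique) {
      dropped[[col]] <- tibble(column = col, reason = "constant")
    } else {
      keep <- c(keep, col)
    }
  }
  out <- tbl[, c("id", keep)]
  attr(out, "dropped") <- if (length(dropped)) list_rbind(dropped) else
    tibble(column = character(0), reason = character(0))
  out
}

#' Prune pairwise-correlated descriptors
#'
#' Greedy scan in column order: a column is dropped when its absolute
#' Pearson correlation with any *retained* earlier column exceeds the
#' threshold, so the earlier column of a redundant pair survives. The
#' surviving set has all pairwise `|r| <= threshold`; the scan is
#' deterministic given column order and uses no randomness.
#'
#' @param tbl Cleaned descriptor tibble (no missing values, no constants).
#' @param threshold Absolute Pearson correlation above which a pair is
#'   redundant; must lie in `(0, 1]`. Default 0.75.
#' @return The pruned tibble with the drop report (`column`, `partner`, `r`)
#'   in `attr(, "dropped")`.
#' @export
prune_correlated <- function(tbl, threshold = 0.75) {
  if (!is_number(threshold) || threshold <= 0 || threshold > 1) {
    stop_sfelip("threshold must lie in (0, 1]", "threshold")
  }
  cols <- descriptor_cols(tbl)
  X <- as.matrix(tbl[, cols])
  if (anyNA(X)) stop_sfelip("prune_correlated requires a complete matrix",
                            "missing_values")
  r <- suppressWarnings(cor(X))
  keep <- character(0)
  dropped <- list()
  for (col in cols) {
    partners <- keep[abs(r[col, keep]) > threshold]
    if (length(partners)) {
      dropped[[col]] <- tibble(column = col, partner = partners[1],
                               r = r[col, partners[1]])
    } else {
      keep <- c(keep, col)
    }
  }
  out <- tbl[, c("id", keep)]
  attr(out, "dropped") <- if (length(dropped)) list_rbind(dropped) else
    tibble(column = character(0), partner = character(0), r = numeric(0))
  out
}

#' Drop report of a cleaning step
#' @param tbl Result of [drop_degenerate()] or [prune_correlated()].
#' @return The attached report tibble.
#' @export
dropped_columns <- function(tbl) attr(tbl, "dropped")

#' Standardize descriptor columns
#'
#' Centres each descriptor to zero mean and scales to unit variance; the
#' transform is stored so it can be inverted. Required before Euclidean
#' distance computations in the representative selectors.
#'
#' @param tbl Cleaned descriptor tibble.
#' @return Tibble of z-scores with `attr(, "center")` and `attr(, "scale")`.
#' @export
standardize_descriptors <- function(tbl) {
  cols <- descriptor_cols(tbl)
  if (nrow(tbl) < 2L) stop_sfelip("cannot standardize n=1", "too_few_rows")
  X <- as.matrix(tbl[, cols])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) {
    stop_sfelip(sprintf("constant column '%s' cannot be standardized (drop it first)",
                        cols[which(scl == 0)[1]]), "constant_column")
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  out <- bind_cols(tbl[, "id"], as_tibble(Z))
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert a standardization
#' @param tbl Result of [standardize_descriptors()].
#' @return Tibble on the original descriptor scale.
#' @export
invert_standardize <- function(tbl) {
  ctr <- attr(tbl, "center")
  scl <- attr(tbl, "scale")
  if (is.null(ctr)) stop_sfelip("not a standardized table", "not_standardized")
  X <- as.matrix(tbl[, names(ctr)])
  bind_cols(tbl[, "id"], as_tibble(sweep(sweep(X, 2, scl, "*"), 2, ctr, "+")))
}

#' Clean a descriptor matrix end to end
#'
#' Convenience wrapper: [drop_degenerate()] then [prune_correlated()], the
#' standard redundancy-reduction recipe applied before modelling or
#' clustering.
#'
#' @inheritParams drop_degenerate
#' @inheritParams prune_correlated
#' @return The cleaned tibble; both drop reports combined in
#'   `attr(, "dropped")`.
#' @export
clean_descriptors <- function(tbl, max_missing_fraction = 0, min_unique = 2,
                              threshold = 0.75) {
  step1 <- drop_degenerate(tbl, max_missing_fraction, min_unique)
  step2 <- prune_correlated(step1, threshold)
  rep1 <- dropped_columns(step1)
  rep2 <- dropped_columns(step2)
  attr(step2, "dropped") <- bind_rows(
    mutate(rep1, partner = NA_character_, r = NA_real_),
    mutate(rep2, reason = "correlated"))
  step2
}
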
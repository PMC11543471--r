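#' Build a candidate family
#'
#' A candidate family bundles everything the representative selectors need
#' for one shorthand annotation: the ordered candidate structures, their
#' (standardized) descriptor rows, optional fingerprints and optional
#' activity-coefficient curves. Candidate order is significant — it is the
#' tie-break key of every selector.
#'
#' @param shorthand Annotation string (e.g. `"DG 36:2"`).
#' @param candidates Tibble with columns `candidate_id`, `smiles` (smiles
#'   may be `NA` when descriptors are supplied directly).
#' @param descriptors Optional descriptor tibble (id column + numeric
#'   columns) whose rows align with candidate order.
#' @param fingerprints Optional logical/0-1 matrix, one row per candidate.
#' @param idac_curves Optional numeric matrix, one row per candidate, of
#'   ln(gamma-infinity) values on a shared evaluation grid.
#' @return A `candidate_family` object.
#' @export
candidate_family <- function(shorthand, candidates, descriptors = NULL,
                             fingerprints = NULL, idac_curves = NULL) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) < 1L) stop_sfelip("empty candidate family", "empty_family")
  if (!"candidate_id" %in% names(candidates)) {
    candidates$candidate_id <- sprintf("%s#%d", shorthand, seq_len(nrow(candidates)))
  }
  if (!is.null(descriptors) && nrow(descriptors) != nrow(candidates)) {
    stop_sfelip("descriptor rows do not align with candidates", "misaligned")
  }
  if (!is.null(idac_curves) && nrow(idac_curves) != nrow(candidates)) {
    stop_sfelip("idac_curves rows do not align with candidates", "misaligned")
  }
  structure(list(shorthand = shorthand, candidates = candidates,
                 descriptors = descriptors, fingerprints = fingerprints,
                 idac_curves = idac_curves),
            class = "candidate_family")
}

#' @export
print.candidate_family <- function(x, ...) {
  cat(sprintf("<candidate_family> %s: %d candidate(s)\n",
              x$shorthand, nrow(x$candidates)))
  invisible(x)
}

selection_result <- function(family, method, scores, minimize = TRUE,
                             tol = 1e-12) {
  if (any(!is.finite(scores))) stop_sfelip("non-finite selection scores", "scores")
  best <- if (minimize) min(scores) else max(scores)
  hits <- which(abs(scores - best) <= tol)
  tibble(shorthand = family$shorthand, method = method,
         chosen_id = family$candidates$candidate_id[hits[1]],
         chosen_smiles = family$candidates$smiles[hits[1]] %||% NA_character_,
         tie = length(hits) > 1L,
         scores = list(setNames(scores, family$candidates$candidate_id)))
}

#' Select a representative by descriptor-space clustering
#'
#' The proposed unsupervised selector: K-medoids (PAM) partitions the
#' family's candidates in standardized descriptor space; within the target
#' cluster (the largest, ties going to the one containing the earliest
#' candidate) the mean descriptor vector (centroid) is computed and the
#' candidate nearest to it in Euclidean distance is the representative.
#' With the default `k = 1` the "cluster" is the whole family, making the
#' selection deterministic and seed-free. Scores are distances to the
#' target-cluster centroid for every candidate.
#'
#' @param family A [candidate_family()] with standardized descriptors.
#' @param k Number of K-medoids clusters, `1 <= k <= n` candidates.
#' @param use_medoid Select the PAM medoid itself instead of the
#'   centroid-nearest candidate (the two differ in general; the default
#'   follows centroid-nearest selection).
#' @return One-row selection tibble (`shorthand`, `method`, `chosen_id`,
#'   `chosen_smiles`, `tie`, list-column `scores`).
#' @export
select_by_clustering <- function(family, k = 1, use_medoid = FALSE) {
  n <- nrow(family$candidates)
  if (k < 1 || k > n) stop_sfelip("k must lie in [1, n_candidates]", "bad_k")
  if (n == 1L) {
    return(selection_result(family, "kmedoids_centroid", scores = 0))
  }
  if (is.null(family$descriptors)) {
    stop_sfelip("family has no descriptors", "no_descriptors")
  }
  X <- as.matrix(family$descriptors[, descriptor_cols(family$descriptors)])
  if (k == 1L) {
    clus <- rep(1L, n)
    medoids <- which.min(colSums(as.matrix(stats::dist(X))))
  } else {
    pam <- cluster::pam(X, k = k, variant = "original")
    clus <- pam$clustering
    medoids <- pam$id.med
  }
  sizes <- tabulate(clus, nbins = k)
  target <- which(sizes == max(sizes))
  if (length(target) > 1L) {
    # tie: the cluster holding the earliest candidate wins
    first_member <- vapply(target, function(g) min(which(clus == g)), 1L)
    target <- target[which.min(first_member)]
  }
  centroid <- colMeans(X[clus == target, , drop = FALSE])
  d <- sqrt(colSums((t(X) - centroid)^2))
  if (use_medoid) {
    med <- medoids[target]
    res <- selection_result(family, "kmedoids_medoid", scores = d)
    res$chosen_id <- family$candidates$candidate_id[med]
    res$chosen_smiles <- family$candidates$smiles[med] %||% NA_character_
    return(res)
  }
  selection_result(family, "kmedoids_centroid", scores = d)
}

#' Tanimoto similarity matrix from fingerprint bits
#'
#' `T(A, B) = |A & B| / |A | B|` on bit-set rows. A molecule with an empty
#' fingerprint has undefined similarity; against itself it is defined as 1.
#'
#' @param bits Logical or 0/1 matrix, one row per molecule.
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
tanimoto_matrix <- function(bits) {
  B <- (as.matrix(bits) != 0) * 1
  inter <- tcrossprod(B)
  ones <- rowSums(B)
  uni <- outer(ones, ones, "+") - inter
  t <- ifelse(uni > 0, inter / uni, 1)
  diag(t) <- 1
  t
}

#' Compute structure fingerprints for a set of SMILES
#'
#' Path-based 1024-bit fingerprints (Open Babel FP2) suited to Tanimoto
#' comparisons of close structural analogues such as lipid isomers.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional molecule ids.
#' @return 0/1 matrix, one row per molecule.
#' @export
compute_fingerprints <- function(smiles, ids = NULL) {
  sdf <- smiles_to_sdf(smiles, ids)
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  fp@fpma
}

#' Rank candidates by mean Tanimoto similarity
#'
#' Pairwise Tanimoto scores over the family's fingerprints; each candidate
#' is scored by its mean similarity to the other members, and the highest
#' mean (closest to 1) wins, i.e. the candidate most structurally typical
#' of the family. Singleton families return themselves with an empty score.
#'
#' @param family A [candidate_family()]. Fingerprints are computed from the
#'   candidate SMILES when not supplied.
#' @return One-row selection tibble; `attr(, "tanimoto")` carries the full
#'   pairwise matrix.
#' @export
rank_by_tanimoto <- function(family) {
  n <- nrow(family$candidates)
  if (n == 1L) {
    res <- selection_result(family, "tanimoto", scores = 1, minimize = FALSE)
    attr(res, "tanimoto") <- matrix(1, 1, 1)
    return(res)
  }
  bits <- family$fingerprints %||%
    compute_fingerprints(family$candidates$smiles, family$candidates$candidate_id)
  tm <- tanimoto_matrix(bits)
  score <- (rowSums(tm) - 1) / (n - 1)
  res <- selection_result(family, "tanimoto", scores = score, minimize = FALSE)
  attr(res, "tanimoto") <- tm
  res
}

#' Rank candidates by activity-coefficient concordance
#'
#' Each candidate's infinite-dilution activity-coefficient curve (ln
#' gamma-infinity over a shared temperature/composition grid) is compared
#' with the family's pointwise mean curve; the candidate with the lowest
#' summed squared error against the mean is taken to carry the
#' representative thermodynamic behaviour under extraction conditions.
#'
#' @param family A [candidate_family()] with `idac_curves` present, or
#'   supplied through `curves`.
#' @param curves Optional matrix overriding `family$idac_curves`.
#' @return One-row selection tibble.
#' @export
rank_by_idac <- function(family, curves = NULL) {
  curves <- curves %||% family$idac_curves
  n <- nrow(family$candidates)
  if (n == 1L) return(selection_result(family, "idac", scores = 0))
  if (is.null(curves)) stop_sfelip("family has no idac_curves", "no_curves")
  if (nrow(curves) != n) stop_sfelip("curve rows do not align", "misaligned")
  if (anyNA(curves)) stop_sfelip("curves are not on a shared grid", "grid_mismatch")
  mean_curve <- colMeans(curves)
  score <- rowSums((sweep(curves, 2, mean_curve))^2)
  selection_result(family, "idac", scores = score)
}

#' Compare representative selections across methods
#'
#' Lines up the per-family choices of two or more selection methods and
#' reports, per family, whether all methods agree; the overall concordance
#' (fraction of families with full agreement) is attached as an attribute
#' and returned by [glance()].
#'
#' @param results Tibble of stacked selection rows (from the selectors or
#'   [select_representatives()]) covering the same families per method.
#' @return Tibble with one row per family, one column per method plus
#'   `agree`; `attr(, "concordance")` holds the agreement fraction.
#' @export
compare_selections <- function(results) {
  methods <- unique(results$method)
  if (length(methods) < 2L) {
    stop_sfelip("need at least two methods to compare", "too_few_methods")
  }
  per_method <- split(results, results$method)
  fams <- sort(unique(results$shorthand))
  for (m in per_method) {
    if (!setequal(m$shorthand, fams)) {
      stop_sfelip("family sets differ across methods", "mismatched_families")
    }
  }
  wide <- results |>
    select("shorthand", "method", "chosen_id") |>
    pivot_wider(names_from = "method", values_from = "chosen_id") |>
    arrange(.data$shorthand)
  wide$agree <- apply(wide[, methods, drop = FALSE], 1,
                      function(r) length(unique(r)) == 1L)
  attr(wide, "concordance") <- mean(wide$agree)
  class(wide) <- c("selection_comparison", class(wide))
  wide
}

#' @exportS3Method generics::glance
glance.selection_comparison <- function(x, ...) {
  tibble(n_families = nrow(x), concordance = attr(x, "concordance"))
}

#' Select representatives for every shorthand family
#'
#' High-level driver mirroring the study workflow: descriptors are computed
#' over *all* candidates, cleaned (degeneracy + correlation pruning) and
#' standardized globally, then each shorthand family is resolved with the
#' requested method(s). Families are clustered independently of one another.
#'
#' @param candidates Tibble from [read_candidate_sets()] (columns
#'   `shorthand`, `candidate_id`, `smiles`).
#' @param method One or more of `"kmedoids"`, `"tanimoto"`, `"idac"`, or
#'   `"all"`.
#' @param idac_curves Optional named list (by shorthand) of curve matrices,
#'   required for the `"idac"` method.
#' @param threshold Correlation-pruning threshold for the descriptor step.
#' @return Tibble of selection rows, one per family x method.
#' @export
select_representatives <- function(candidates,
                                   method = c("kmedoids", "tanimoto", "idac", "all"),
                                   idac_curves = NULL, threshold = 0.75) {
  method <- match.arg(method, several.ok = TRUE)
  if ("all" %in% method) method <- c("kmedoids", "tanimoto", "idac")
  desc <- NULL
  if ("kmedoids" %in% method) {
    desc <- compute_descriptors(candidates, smiles_col = "smiles",
                                id_col = "candidate_id")
    desc <- clean_descriptors(desc, threshold = threshold)
    desc <- standardize_descriptors(desc)
  }
  out <- list()
  for (sh in unique(candidates$shorthand)) {
    rows <- candidates[candidates$shorthand == sh, ]
    fam_desc <- if (!is.null(desc)) desc[match(rows$candidate_id, desc$id), ]
    fam <- candidate_family(sh, rows, descriptors = fam_desc,
                            idac_curves = idac_curves[[sh]])
    if ("kmedoids" %in% method) out <- c(out, list(select_by_clustering(fam)))
    if ("tanimoto" %in% method) out <- c(out, list(rank_by_tanimoto(fam)))
    if ("idac" %in% method) {
      if (!is.null(fam$idac_curves)) out <- c(out, list(rank_by_idac(fam)))
    }
  }
  list_rbind(out)
}
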
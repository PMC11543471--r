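# Independent oracles, written from the definitions rather than via the
# package's code paths.

# Textbook Pearson correlation from the sum formulas.
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Brute-force descriptor cleaning: test every column against the
# definitions (missingness, distinct values), then scan pairs in order with
# the from-scratch Pearson above.
oracle_clean <- function(X, threshold = 0.75, max_missing = 0, min_unique = 2) {
  cols <- colnames(X)
  keep1 <- cols[vapply(cols, function(cl) {
    v <- X[, cl]
    mean(is.na(v)) <= max_missing && length(unique(v[!is.na(v)])) >= min_unique
  }, TRUE)]
  keep2 <- character(0)
  for (cl in keep1) {
    redundant <- FALSE
    for (k in keep2) {
      if (abs(pearson_sums(X[, cl], X[, k])) > threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep2 <- c(keep2, cl)
  }
  keep2
}

# Brute-force solution of the 2-bin segment self-consistency system by
# coarse grid scan plus nested refinement on (ln Gamma_1, ln Gamma_2).
oracle_two_bin_gamma <- function(p, K, rounds = 20, n_grid = 41) {
  resid <- function(l1, l2) {
    g1 <- exp(l1); g2 <- exp(l2)
    r1 <- l1 + log(p[1] * g1 * K[1, 1] + p[2] * g2 * K[1, 2])
    r2 <- l2 + log(p[1] * g1 * K[2, 1] + p[2] * g2 * K[2, 2])
    max(abs(r1), abs(r2))
  }
  centre <- c(0, 0)
  width <- 12          # coarse pass covers ln Gamma in [-6, 6]
  for (r in seq_len(rounds)) {
    l1s <- seq(centre[1] - width / 2, centre[1] + width / 2,
               length.out = n_grid)
    l2s <- seq(centre[2] - width / 2, centre[2] + width / 2,
               length.out = n_grid)
    vals <- outer(l1s, l2s, Vectorize(resid))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    centre <- c(l1s[ix[1]], l2s[ix[2]])
    width <- width / 4
  }
  exp(centre)
}

# Random descriptor-style matrix with optionally planted degenerate and
# duplicated columns.
random_descriptor_matrix <- function(n_rows, n_cols, seed,
                                     plant_constant = FALSE,
                                     plant_missing = FALSE,
                                     plant_duplicate = FALSE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
    colnames(X) <- sprintf("c%02d", seq_len(n_cols))
    if (plant_constant) X[, sample(n_cols, 1)] <- 1.5
    if (plant_missing) X[sample(n_rows, 1), sample(n_cols, 1)] <- NA
    if (plant_duplicate && n_cols >= 2) {
      ij <- sample(n_cols, 2)
      X[, ij[2]] <- X[, ij[1]] * runif(1, 0.5, 2)
    }
    X
  })
}

as_desc_tbl <- function(X) {
  dplyr::bind_cols(tibble::tibble(id = sprintf("m%d", seq_len(nrow(X)))),
                   tibble::as_tibble(X))
}

# Random synthetic sigma profile built only through the exported
# constructor.
random_sigma_profile <- function(seed, name = paste0("p", seed)) {
  withr::with_seed(seed, {
    grid <- sfelip::sigma_grid()
    mus <- runif(3, -0.015, 0.015)
    ss <- runif(3, 0.002, 0.006)
    ws <- runif(3, 0.1, 1)
    dens <- Reduce(`+`, lapply(1:3, function(i) {
      ws[i] * exp(-(grid - mus[i])^2 / (2 * ss[i]^2))
    }))
    area <- runif(1, 60, 400)
    sfelip::sigma_profile(name = name, p = dens / sum(dens) * area,
                          area = area, volume = runif(1, 40, 350),
                          grid = grid)
  })
}
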
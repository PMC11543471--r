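test_that("regression metrics match the standard formulas", {
  m <- regression_metrics(c(0, 1), c(0, 1))
  expect_equal(unlist(m), c(mse = 0, rmse = 0, mae = 0, r2 = 1))
  m2 <- regression_metrics(c(0, 2), c(1, 1))
  expect_equal(unlist(m2), c(mse = 1, rmse = 1, mae = 1, r2 = 0))
  # formula oracle on random vectors
  for (s in 1:25) {
    withr::with_seed(s, {
      y <- rnorm(40); p <- rnorm(40)
    })
    m3 <- regression_metrics(y, p)
    expect_equal(m3$mse, sum((y - p)^2) / 40, tolerance = 1e-12)
    expect_equal(m3$rmse^2, m3$mse, tolerance = 1e-12)
    expect_equal(m3$mae, sum(abs(y - p)) / 40, tolerance = 1e-12)
    expect_equal(m3$r2, 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
  }
  expect_error(regression_metrics(numeric(0), numeric(0)),
               class = "sfelip_error_empty_split")
})

linear_ft <- function(n = 120, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, c("f1", "f2", "f3", "f4")))
    y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3] + rnorm(n, 0, noise)
  })
  ft <- dplyr::bind_cols(
    tibble::tibble(lipid_id = sprintf("L%d", seq_len(n)),
                   condition_id = "SC1", censored = FALSE, y = y),
    tibble::as_tibble(X))
  attr(ft, "feature_cols") <- colnames(X)
  class(ft) <- c("feature_tbl", class(tibble::tibble()))
  ft
}

test_that("tuning reduces to a direct fit for single-point grids", {
  ft <- linear_ft()
  f1 <- tune_and_train(ft, "lasso", grid = tibble::tibble(lambda = 1e-4),
                       seed = 5)
  f2 <- tune_and_train(ft, "lasso", grid = tibble::tibble(lambda = 1e-4),
                       seed = 5)
  expect_equal(predict(f1, ft), predict(f2, ft), tolerance = 1e-12)
  expect_true(all(is.na(f1$cv$cv_rmse)))
  # realizable linear target: near-perfect train fit
  expect_gte(regression_metrics(ft$y, predict(f1, ft))$r2, 0.999)
  expect_error(tune_and_train(ft, "ridge"))
  expect_error(tune_and_train(ft, "lasso", grid = tibble::tibble()),
               class = "sfelip_error_empty_grid")
})

test_that("grid search selects by cross-validated error, deterministically", {
  ft <- linear_ft(noise = 0.3)
  grid <- tibble::tibble(lambda = c(1e-4, 10))  # 10 shrinks everything away
  f <- tune_and_train(ft, "lasso", grid = grid, cv_folds = 4, seed = 2)
  expect_equal(f$best_params$lambda, 1e-4)
  expect_equal(nrow(f$cv), 2)
  expect_true(all(is.finite(f$cv$cv_rmse)))
  f2 <- tune_and_train(ft, "lasso", grid = grid, cv_folds = 4, seed = 2)
  expect_identical(f$cv, f2$cv)
})

test_that("gradient boosting beats lasso on a piecewise-constant response", {
  withr::with_seed(7, {
    n <- 200
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
    y <- ifelse(X[, 1] > 0, 2, -1) * ifelse(X[, 2] > 0.5, 1.5, 0.5)
  })
  ft <- dplyr::bind_cols(
    tibble::tibble(lipid_id = sprintf("L%d", 1:n), condition_id = "SC1",
                   censored = FALSE, y = y), tibble::as_tibble(X))
  attr(ft, "feature_cols") <- colnames(X)
  class(ft) <- c("feature_tbl", class(tibble::tibble()))
  las <- tune_and_train(ft, "lasso", grid = tibble::tibble(lambda = 1e-4),
                        seed = 1)
  xgb <- tune_and_train(ft, "xgboost", grid = default_grid("xgboost", TRUE),
                        seed = 1)
  r2 <- function(f) regression_metrics(ft$y, predict(f, ft))$r2
  expect_gt(r2(xgb), r2(las))
})

protocol_fixture <- function(seed = 8, idac = FALSE) {
  cfg <- generator_config(n_lipids = 15, seed = seed)
  lib <- generate_lipid_library(cfg)
  surf <- generate_recovery_surface(lib, cfg)
  desc <- compute_descriptors(lib$records, smiles_col = "smiles",
                              id_col = "lipid_id")
  idac_tbl <- NULL
  if (idac) {
    idac_tbl <- withr::with_seed(seed, tibble::tibble(
      lipid_id = rep(lib$records$lipid_id, each = 12),
      condition_id = rep(cfg$design$id, times = 15),
      idac = rnorm(15 * 12)))
  }
  assemble_dataset(surf$recovery, desc, cfg$design, idac = idac_tbl)
}

test_that("evaluation reports all three splits with consistent rmse", {
  ft <- split_dataset(protocol_fixture(), "SC5", seed = 3)
  fit <- tune_and_train(ft[ft$split == "train", ], "random_forest",
                        grid = default_grid("random_forest", TRUE), seed = 3)
  rep <- evaluate(fit, ft)
  expect_equal(rep$split, c("train", "test", "validation"))
  expect_equal(rep$rmse, sqrt(rep$mse), tolerance = 1e-12)
  expect_true(all(rep$r2 <= 1))
  expect_equal(unique(rep$model), "random_forest")
})

test_that("the IDAC ablation pairs runs with identical seeds", {
  ft <- protocol_fixture(idac = TRUE)
  models <- c("lasso", "xgboost")
  ab <- ablation_idac(ft, models = models, seed = 4, small_grids = TRUE)
  expect_equal(nrow(ab$report), 2 * length(models) * 3)
  expect_setequal(unique(ab$report$idac_included), c(TRUE, FALSE))
  # dropping the column up front reproduces the "without" half exactly
  direct <- run_protocol(sfelip:::drop_idac(ft), models = models, seed = 4,
                         small_grids = TRUE)
  without <- ab$report[!ab$report$idac_included, ]
  expect_equal(as.data.frame(without), as.data.frame(direct$report))
  expect_error(ablation_idac(protocol_fixture(), seed = 1),
               class = "sfelip_error_no_idac")
})

test_that("whole-protocol runs are bit-reproducible for a fixed seed", {
  ft <- protocol_fixture(seed = 12)
  models <- c("lasso", "random_forest", "xgboost", "svr", "ann",
              "gaussian_process")
  r1 <- run_protocol(ft, models = models, seed = 7, small_grids = TRUE)
  r2 <- run_protocol(ft, models = models, seed = 7, small_grids = TRUE)
  expect_identical(r1$report, r2$report)
})

test_that("profile prediction is consistent with the fitted model", {
  ft <- split_dataset(protocol_fixture(), "SC5", seed = 5)
  fit <- tune_and_train(ft[ft$split == "train", ], "xgboost",
                        grid = default_grid("xgboost", TRUE), seed = 5)
  cond <- default_design()[3, ]
  lipids <- ft[ft$condition_id == cond$id, ]
  prof <- predict_profile(fit, lipids, cond)
  expect_equal(nrow(prof), nrow(lipids))
  expect_equal(prof$y_hat, predict(fit, lipids), tolerance = 1e-12)
  expect_equal(prof$abundance_hat, 10^prof$y_hat)
  expect_identical(prof$below_detection, prof$y_hat <= -6.5)
  bad <- lipids[, setdiff(names(lipids), "MW")]
  expect_error(predict_profile(fit, bad, cond),
               class = "sfelip_error_feature_mismatch")
})
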
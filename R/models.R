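#' Regression metrics
#'
#' Standard formulas: `MSE = mean((y - yhat)^2)`, `RMSE = sqrt(MSE)`,
#' `MAE = mean(|y - yhat|)`, `R^2 = 1 - SS_res / SS_tot` with the
#' evaluated split's own mean as baseline.
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @return One-row tibble `mse`, `rmse`, `mae`, `r2`.
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) == 0L) stop_sfelip("empty split", "empty_split")
  mse <- mean((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble(mse = mse, rmse = sqrt(mse), mae = mean(abs(y - y_hat)),
         r2 = 1 - sum((y - y_hat)^2) / ss_tot)
}

#' Supported model names
#' @return Character vector of the six model identifiers.
#' @export
model_names <- function() {
  c("lasso", "gaussian_process", "svr", "random_forest", "xgboost", "ann")
}

# Models that require standardized inputs (distance/penalty based).
needs_scaling <- function(model) {
  model %in% c("lasso", "gaussian_process", "svr", "ann")
}

#' Default hyperparameter grids
#'
#' Small, documented grids per model for the grid-search step. Each grid is
#' a tibble whose rows are candidate configurations.
#'
#' @param model One of [model_names()].
#' @param small Use a single-row grid (the default configuration only),
#'   for fast runs; grid search over a single row is a direct fit.
#' @return Tibble of hyperparameter combinations.
#' @export
default_grid <- function(model, small = FALSE) {
  g <- switch(model,
    lasso = expand.grid(lambda = c(1e-4, 1e-3, 1e-2, 1e-1)),
    gaussian_process = expand.grid(sigma = c(0.01, 0.05, 0.1), var = 0.01),
    svr = expand.grid(cost = c(0.1, 1, 10), epsilon = 0.1),
    random_forest = expand.grid(num_trees = 300, min_node = c(1, 5)),
    xgboost = expand.grid(max_depth = c(3, 6, 9), eta = c(0.05, 0.1, 0.3),
                          nrounds = 300),
    ann = expand.grid(size = c(32, 64), decay = c(1e-3, 1e-2)),
    stop_sfelip(sprintf("unknown model name '%s'", model), "unknown_model"))
  g <- as_tibble(g)
  if (small) {
    g <- switch(model,
      lasso = tibble(lambda = 1e-3),
      gaussian_process = tibble(sigma = 0.05, var = 0.01),
      svr = tibble(cost = 1, epsilon = 0.1),
      random_forest = tibble(num_trees = 300, min_node = 5),
      xgboost = tibble(max_depth = 6, eta = 0.1, nrounds = 300),
      ann = tibble(size = 32, decay = 1e-3))
  }
  g
}

# Fit one model configuration on a (possibly pre-scaled) matrix.
fit_engine <- function(model, X, y, pars, seed) {
  withr::with_seed(seed, switch(model,
    lasso = glmnet::glmnet(X, y, alpha = 1, lambda = pars$lambda),
    gaussian_process = kernlab::gausspr(
      x = X, y = y, kernel = "rbfdot", kpar = list(sigma = pars$sigma),
      var = pars$var, scaled = FALSE),
    svr = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", cost = pars$cost,
                     epsilon = pars$epsilon, scale = FALSE),
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = pars$num_trees,
      min.node.size = pars$min_node, seed = seed, num.threads = 1),
    xgboost = xgboost::xgb.train(
      params = list(max_depth = pars$max_depth, eta = pars$eta,
                    objective = "reg:squarederror", nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = pars$nrounds, verbose = 0),
    ann = nnet::nnet(X, y, size = pars$size, decay = pars$decay,
                     linout = TRUE, maxit = 500, trace = FALSE,
                     MaxNWts = 20000)))
}

predict_engine <- function(model, fit, X) {
  switch(model,
    lasso = as.vector(predict(fit, X)),
    gaussian_process = as.vector(kernlab::predict(fit, X)),
    svr = as.vector(predict(fit, X)),
    random_forest = predict(fit, data = as.data.frame(X),
                            num.threads = 1)$predictions,
    xgboost = as.vector(predict(fit, xgboost::xgb.DMatrix(X, nthread = 1))),
    ann = as.vector(predict(fit, X)))
}

ft_matrix <- function(ft, feats) {
  X <- as.matrix(as.data.frame(ft)[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Grid-search tuning and final fit
#'
#' Exhaustive grid search scored by K-fold cross-validated RMSE on the
#' training rows, followed by a refit of the best configuration on the
#' full training set. Distance- and penalty-based models (lasso, Gaussian
#' process, SVR, neural network) see standardized features (scaler fitted
#' on the training rows and stored); tree ensembles see raw features. All
#' randomness (fold assignment, stochastic fitters) derives from `seed`.
#' A single-row grid is equivalent to a direct fit.
#'
#' @param train A `feature_tbl` (or subset of rows) to train on.
#' @param model One of [model_names()].
#' @param grid Hyperparameter tibble; defaults to [default_grid()].
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return An `sfe_model`: list with the fitted engine, scaler, feature
#'   names, chosen hyperparameters and the CV table.
#' @export
tune_and_train <- function(train, model, grid = default_grid(model),
                           cv_folds = 5, seed = 1) {
  model <- match.arg(model, model_names())
  grid <- as_tibble(grid)
  if (nrow(grid) == 0L) stop_sfelip("empty hyperparameter grid", "empty_grid")
  feats <- feature_cols(train)
  X <- ft_matrix(train, feats)
  y <- train$y
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- if (needs_scaling(model)) sweep(sweep(X, 2, ctr), 2, scl, "/") else X
  cv_rmse <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    folds <- withr::with_seed(child_seed(seed, 11),
                              sample(rep(seq_len(cv_folds), length.out = nrow(Xs))))
    for (gi in seq_len(nrow(grid))) {
      errs <- vapply(seq_len(cv_folds), function(k) {
        tr <- folds != k
        fit <- fit_engine(model, Xs[tr, , drop = FALSE], y[tr], grid[gi, ],
                          seed = child_seed(seed, 100 + k))
        pred <- predict_engine(model, fit, Xs[!tr, , drop = FALSE])
        sqrt(mean((y[!tr] - pred)^2))
      }, 1)
      cv_rmse[gi] <- mean(errs)
    }
    best <- which.min(cv_rmse)
  } else {
    best <- 1L
  }
  fit <- fit_engine(model, Xs, y, grid[best, ], seed = child_seed(seed, 7))
  structure(list(model = model, fit = fit, feature_names = feats,
                 center = ctr, scale = scl, scaled = needs_scaling(model),
                 best_params = grid[best, ],
                 cv = bind_cols(grid, tibble(cv_rmse = cv_rmse)),
                 seed = seed),
            class = "sfe_model")
}

#' @export
print.sfe_model <- function(x, ...) {
  cat(sprintf("<sfe_model> %s, %d features; params: %s\n", x$model,
              length(x$feature_names),
              paste(names(x$best_params), unlist(x$best_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
predict.sfe_model <- function(object, newdata, ...) {
  feats <- object$feature_names
  missing <- setdiff(feats, names(newdata))
  if (length(missing)) {
    stop_sfelip(paste0("newdata lacks feature(s): ",
                       paste(head(missing, 3), collapse = ", ")),
                "feature_mismatch")
  }
  X <- ft_matrix(newdata, feats)
  if (object$scaled) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  }
  predict_engine(object$model, object$fit, X)
}

#' @exportS3Method generics::glance
glance.sfe_model <- function(x, ...) {
  bind_cols(tibble(model = x$model,
                   cv_rmse = if (all(is.na(x$cv$cv_rmse))) NA_real_ else
                     min(x$cv$cv_rmse, na.rm = TRUE)),
            x$best_params)
}

#' @exportS3Method generics::tidy
tidy.sfe_model <- function(x, ...) {
  if (x$model == "lasso") {
    b <- as.matrix(coef(x$fit))
    return(tibble(term = rownames(b), estimate = b[, 1]))
  }
  if (x$model == "random_forest") {
    fit2 <- x$fit
    imp <- tryCatch(ranger::importance(fit2), error = function(e) NULL)
    if (!is.null(imp) && length(imp)) {
      return(tibble(term = names(imp), importance = unname(imp)))
    }
  }
  if (x$model == "xgboost") {
    imp <- xgboost::xgb.importance(model = x$fit)
    return(tibble(term = imp$Feature, importance = imp$Gain))
  }
  tibble(term = x$feature_names, importance = NA_real_)
}

#' Evaluate a fitted model on the protocol splits
#'
#' @param fit An `sfe_model`.
#' @param ft A `feature_tbl` carrying a `split` column from
#'   [split_dataset()].
#' @param idac_included Bookkeeping flag recorded in the report.
#' @return A `model_report` tibble: one row per split with `mse`, `rmse`,
#'   `mae`, `r2`.
#' @export
evaluate <- function(fit, ft, idac_included = "idac" %in% fit$feature_names) {
  rows <- lapply(c("train", "test", "validation"), function(s) {
    sub <- ft[ft$split == s, ]
    if (nrow(sub) == 0L) stop_sfelip(sprintf("empty split '%s'", s),
                                     "empty_split")
    bind_cols(tibble(model = fit$model, idac_included = idac_included,
                     split = s, n = nrow(sub)),
              regression_metrics(sub$y, predict(fit, sub)))
  })
  rep <- list_rbind(rows)
  class(rep) <- c("model_report", class(rep))
  rep
}

#' @exportS3Method ggplot2::autoplot
autoplot.model_report <- function(object, metric = "r2", ...) {
  object$label <- paste0(object$model, ifelse(object$idac_included, "+", "-"))
  ggplot(object, aes(x = .data$label, y = .data[[metric]],
                     fill = .data$split)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = metric) + theme_minimal()
}

# Strip the idac feature from an assembled table.
drop_idac <- function(ft) {
  feats <- setdiff(feature_cols(ft), "idac")
  out <- ft[, c("lipid_id", "condition_id", "censored", "y", feats)]
  attr(out, "feature_cols") <- feats
  attr(out, "censored_value") <- attr(ft, "censored_value")
  class(out) <- class(ft)
  out
}

#' Run the full split/tune/evaluate protocol
#'
#' Splits the table (leave-one-condition-out validation + random
#' train/test), tunes and fits each requested model, and stacks their
#' reports.
#'
#' @param ft A `feature_tbl`.
#' @param models Character vector of model names.
#' @param grids Optional named list of grids per model.
#' @param holdout_condition,test_fraction,seed,cv_folds Protocol settings.
#' @param small_grids Use single-row default grids.
#' @return List with `report` (stacked `model_report`) and `fits` (named
#'   list of `sfe_model`s).
#' @export
run_protocol <- function(ft, models = model_names(), grids = NULL,
                         holdout_condition = "SC5", test_fraction = 0.2,
                         seed = 1, cv_folds = 5, small_grids = FALSE) {
  ft <- split_dataset(ft, holdout_condition, test_fraction,
                      seed = child_seed(seed, 1))
  train <- ft[ft$split == "train", ]
  fits <- list()
  reports <- list()
  for (m in models) {
    g <- grids[[m]] %||% default_grid(m, small = small_grids)
    fit <- tune_and_train(train, m, grid = g, cv_folds = cv_folds,
                          seed = child_seed(seed, 2))
    fits[[m]] <- fit
    reports[[m]] <- evaluate(fit, ft)
  }
  rep <- list_rbind(reports)
  class(rep) <- c("model_report", class(rep))
  list(report = rep, fits = fits)
}

#' IDAC inclusion ablation
#'
#' Runs the full protocol twice with identical seeds — once with the IDAC
#' feature, once without — and stacks the paired reports, tagged by
#' `idac_included`. This operationalises the question of whether the
#' thermodynamic feature adds information beyond the structural
#' descriptors or merely invites overfitting.
#'
#' @param ft A `feature_tbl` that carries an `idac` feature.
#' @inheritParams run_protocol
#' @return List with `report` (2 x models rows per split) and `fits`
#'   (named list with `$with` and `$without`).
#' @export
ablation_idac <- function(ft, models = model_names(), grids = NULL,
                          holdout_condition = "SC5", test_fraction = 0.2,
                          seed = 1, cv_folds = 5, small_grids = FALSE) {
  if (!"idac" %in% feature_cols(ft)) {
    stop_sfelip("table lacks an idac column", "no_idac")
  }
  with_ <- run_protocol(ft, models, grids, holdout_condition, test_fraction,
                        seed, cv_folds, small_grids)
  without <- run_protocol(drop_idac(ft), models, grids, holdout_condition,
                          test_fraction, seed, cv_folds, small_grids)
  rep <- bind_rows(with_$report, without$report)
  class(rep) <- c("model_report", class(rep))
  list(report = rep, fits = list(with = with_$fits, without = without$fits))
}

#' Predict a full lipid profile at one condition
#'
#' Applies a fitted model to feature rows for every lipid at a given
#' extraction condition and reports both the log-scale prediction and the
#' back-transformed abundance, flagging predictions at or near the
#' censoring floor as below detection.
#'
#' @param fit An `sfe_model`.
#' @param lipid_features Tibble of per-lipid feature rows (must contain
#'   `lipid_id` and all training features except the condition columns).
#' @param condition One-row design tibble (or list) with `temperature`,
#'   `pressure`, `ethanol_flow`.
#' @param censored_value The imputation floor used at assembly.
#' @param epsilon Margin above the floor still reported as below
#'   detection.
#' @param log_base Base of the logarithmic transform.
#' @return Tibble `lipid_id`, `y_hat`, `abundance_hat`,
#'   `below_detection`.
#' @export
predict_profile <- function(fit, lipid_features, condition,
                            censored_value = -7, epsilon = 0.5,
                            log_base = 10) {
  nd <- as_tibble(lipid_features)
  nd$temperature <- condition$temperature
  nd$pressure <- condition$pressure
  nd$ethanol_flow <- condition$ethanol_flow
  y_hat <- predict(fit, nd)
  tibble(lipid_id = nd$lipid_id, y_hat = y_hat,
         abundance_hat = log_base^y_hat,
         below_detection = y_hat <= censored_value + epsilon)
}
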
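test_that("library generation is deterministic and emits valid structures", {
  cfg <- generator_config(n_lipids = 10, seed = 42)
  a <- generate_lipid_library(cfg)
  b <- generate_lipid_library(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$records), 10)
  expect_true(all(a$records$lipid_class %in% lipid_classes()))

  # validity + in-family uniqueness sweep
  for (s in 1:15) {
    lib <- generate_lipid_library(generator_config(n_lipids = 8, seed = s))
    expect_true(all(smiles_is_valid(lib$candidates$smiles)))
    dup <- lib$candidates |>
      dplyr::count(shorthand, smiles) |>
      dplyr::filter(n > 1)
    expect_equal(nrow(dup), 0)
  }
})

test_that("class composition tracks the sampling weights", {
  cfg0 <- generator_config(seed = 1)
  counts <- setNames(numeric(length(cfg0$class_weights)),
                     names(cfg0$class_weights))
  n_seeds <- 15
  for (s in 1:n_seeds) {
    lib <- generate_lipid_library(generator_config(n_lipids = 40, seed = s))
    tab <- table(lib$records$lipid_class)
    counts[names(tab)] <- counts[names(tab)] + tab
  }
  expected <- cfg0$class_weights * sum(counts)
  chisq <- sum((counts - expected)^2 / expected)
  # 4 df; the shorthand-space spill-over keeps this approximate, not exact
  expect_lt(chisq, qchisq(0.99, df = length(counts) - 1))
})

test_that("recovery surfaces honour the latent model and the censoring contract", {
  # deterministic limit: no noise, no interactions, no intercept spread
  cfg <- generator_config(n_lipids = 12, noise_sd = 0, intercept_sd = 0,
                          interactions = FALSE, seed = 2)
  lib <- generate_lipid_library(cfg)
  surf <- generate_recovery_surface(lib, cfg)
  long <- recovery_long(surf$recovery)
  design <- cfg$design
  for (i in seq(1, nrow(long), by = 7)) {
    row <- long[i, ]
    d <- design[design$id == row$condition_id, ]
    mu <- cfg$class_baseline[[row$lipid_class]] +
      cfg$beta_T * (d$temperature - 50) / 10 +
      cfg$beta_P * (d$pressure - 200) / 50 +
      cfg$beta_flow * (d$ethanol_flow - 0.75) / 0.15
    want <- if (10^mu < cfg$detection_floor) 0 else 10^mu
    expect_equal(row$abundance, unname(want), tolerance = 1e-12)
  }

  # floor above everything: all cells censored
  hi <- generator_config(n_lipids = 5, detection_floor = 1e6, seed = 3)
  lib_hi <- generate_lipid_library(hi)
  surf_hi <- generate_recovery_surface(lib_hi, hi)
  expect_true(all(recovery_long(surf_hi$recovery)$abundance == 0))

  # observed censored fraction close to the analytic probability
  cfg_d <- generator_config(seed = 4)
  lib_d <- generate_lipid_library(cfg_d)
  surf_d <- generate_recovery_surface(lib_d, cfg_d)
  obs <- mean(recovery_long(surf_d$recovery)$abundance == 0)
  expect_lt(abs(obs - expected_censored_fraction(surf_d$truth)), 0.05)
})

test_that("generated sigma profiles satisfy the profile invariants", {
  cfg <- generator_config(n_lipids = 6, seed = 5)
  lib <- generate_lipid_library(cfg)
  prof <- generate_sigma_profiles(lib$records, cfg)
  expect_identical(generate_sigma_profiles(lib$records, cfg), prof)
  path <- withr::local_tempfile(fileext = ".sigma")
  for (pr in prof) {
    expect_s3_class(validate_sigma_profile(pr), "sigma_profile")
    write_sigma_profile(pr, path)
    expect_equal(read_sigma_profile(path)$p, pr$p, tolerance = 1e-12)
  }
  # polar classes carry more wing mass than an apolar-dominated profile
  recs <- tibble::tibble(lipid_id = c("fa", "pc"), shorthand = c("x", "y"),
                         lipid_class = c("fatty acyls", "glycerophospholipids"),
                         smiles = NA, total_c = 16, n_db = 0)
  pp <- generate_sigma_profiles(recs, cfg)
  wing <- function(p) sum(p$p[abs(p$sigma) > 0.008]) / sum(p$p)
  expect_gt(wing(pp$pc), wing(pp$fa))
})

test_that("planted linear condition effects are recoverable by lasso", {
  cfg <- generator_config(n_lipids = 60, noise_sd = 0.02, intercept_sd = 0.3,
                          interactions = FALSE, detection_floor = 1e-12,
                          seed = 6)
  lib <- generate_lipid_library(cfg)
  surf <- generate_recovery_surface(lib, cfg)
  desc <- compute_descriptors(lib$records, smiles_col = "smiles",
                              id_col = "lipid_id")
  ft <- assemble_dataset(surf$recovery, desc, cfg$design)
  ft$split <- "train"
  fit <- tune_and_train(ft, "lasso", grid = tibble::tibble(lambda = 1e-5),
                        seed = 6)
  b <- tidy(fit)
  est <- function(term) {
    unname(b$estimate[b$term == term] / fit$scale[[term]])
  }
  expect_equal(est("temperature"), cfg$beta_T / 10, tolerance = 0.1)
  expect_equal(est("pressure"), cfg$beta_P / 50, tolerance = 0.1)
  expect_equal(est("ethanol_flow"), cfg$beta_flow / 0.15, tolerance = 0.1)
})
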
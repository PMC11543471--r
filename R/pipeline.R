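#' Per-condition lipid class composition
#'
#' For every extraction condition, the fraction of total recovered
#' abundance contributed by each lipid class — the stacked-bar summary of
#' how process settings shift the extract's composition.
#'
#' @param recovery A `recovery_tbl`.
#' @return A `class_composition` tibble: `condition_id`, `lipid_class`,
#'   `abundance`, `fraction`. A condition whose total abundance is zero
#'   has `fraction = NA` and is flagged in `attr(, "undefined")`.
#' @export
class_abundance_summary <- function(recovery) {
  long <- recovery_long(recovery)
  out <- long |>
    group_by(.data$condition_id, .data$lipid_class) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop_last") |>
    mutate(total = sum(.data$abundance),
           fraction = ifelse(.data$total > 0,
                             .data$abundance / .data$total, NA_real_)) |>
    ungroup() |>
    select(-"total") |>
    mutate(condition_id = factor(.data$condition_id,
                                 levels = condition_ids(recovery))) |>
    arrange(.data$condition_id, .data$lipid_class)
  undef <- unique(as.character(out$condition_id[is.na(out$fraction)]))
  if (length(undef)) {
    warn(paste0("condition(s) with zero total abundance: ",
                paste(undef, collapse = ", ")))
  }
  structure(out, undefined = undef,
            class = c("class_composition", class(out)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.class_composition <- function(object, ...) {
  ggplot(object, aes(x = .data$condition_id, y = .data$fraction,
                     fill = .data$lipid_class)) +
    geom_col() +
    labs(x = "extraction condition", y = "fraction of recovered abundance",
         fill = "lipid class") +
    theme_minimal()
}

#' Default pipeline configuration
#'
#' The bundled end-to-end configuration: simulate the default synthetic
#' study, resolve representatives by clustering and Tanimoto, compute
#' IDAC, and run the six-model protocol both with and without the IDAC
#' feature using the single-row default grids.
#'
#' @param seed Integer seed propagated to every stage.
#' @param out_dir Output directory for stage artifacts.
#' @return Named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempfile("sfelip_run")) {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(),                     # generator_config() overrides
    representative = list(method = c("kmedoids", "tanimoto")),
    idac = "both",                         # "on", "off" or "both"
    models = model_names(),
    split = list(holdout = "SC5", test_fraction = 0.2),
    cv_folds = 5,
    small_grids = TRUE
  )
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the full workflow from one configuration: synthetic-data
#' generation (or CSV inputs), representative selection, descriptor
#' computation, IDAC evaluation, dataset assembly, the split/tune/evaluate
#' protocol (with the IDAC ablation when requested) and the class
#' composition summary. Every stage artifact is written as CSV under
#' `out_dir`; a JSON manifest records the configuration hash, seed and
#' stage outputs. Reruns with the same configuration are byte-identical —
#' no stage consults the clock or ambient RNG state.
#'
#' @param config List as produced by [default_pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @return The manifest, invisibly a list; element `outputs` names every
#'   artifact written.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_sfelip("config must set an explicit seed",
                                        "config_seed")
  cfg <- utils::modifyList(default_pipeline_config(seed = config$seed), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_sfelip(sprintf("stage '%s' failed: %s", name,
                          conditionMessage(e)), "stage_failure")
    })
  }

  # -- simulate ------------------------------------------------------------
  gen_cfg <- do.call(generator_config,
                     c(cfg$simulate, list(seed = cfg$seed)))
  lib <- stage("simulate", generate_lipid_library(gen_cfg))
  surf <- stage("simulate", generate_recovery_surface(lib, gen_cfg))
  write_recovery_table(surf$recovery, out("recovery.csv"))
  write_candidate_sets(lib$candidates, out("candidates.csv"))
  write_design(gen_cfg$design, out("design.csv"))
  outputs <- c(outputs, "recovery.csv", "candidates.csv", "design.csv")

  # -- representatives -----------------------------------------------------
  reps <- stage("representatives", select_representatives(
    lib$candidates, method = cfg$representative$method))
  readr::write_csv(select(reps, -"scores"), out("representatives.csv"),
                   progress = FALSE)
  outputs <- c(outputs, "representatives.csv")
  chosen <- reps |>
    filter(.data$method == .data$method[1]) |>
    select("shorthand", "chosen_smiles")
  records <- lib$records |>
    left_join(chosen, by = "shorthand") |>
    mutate(smiles = dplyr::coalesce(.data$chosen_smiles, .data$smiles)) |>
    select(-"chosen_smiles")

  # -- descriptors ---------------------------------------------------------
  desc <- stage("descriptors", compute_descriptors(
    records, smiles_col = "smiles", id_col = "lipid_id"))
  readr::write_csv(desc, out("descriptors.csv"), progress = FALSE)
  outputs <- c(outputs, "descriptors.csv")

  # -- idac ----------------------------------------------------------------
  idac_tbl <- NULL
  if (cfg$idac %in% c("on", "both")) {
    profiles <- generate_sigma_profiles(records, gen_cfg)
    solv <- solvent_profiles()
    idac_tbl <- stage("idac", compute_idac_table(
      profiles, gen_cfg$design, solv$co2, solv$ethanol))
    readr::write_csv(idac_tbl, out("idac.csv"), progress = FALSE)
    outputs <- c(outputs, "idac.csv")
  }

  # -- assemble + protocol -------------------------------------------------
  report <- stage("train", {
    if (cfg$idac == "both") {
      ft <- assemble_dataset(surf$recovery, desc, gen_cfg$design,
                             idac = idac_tbl)
      ablation_idac(ft, models = cfg$models,
                    holdout_condition = cfg$split$holdout,
                    test_fraction = cfg$split$test_fraction,
                    seed = cfg$seed, cv_folds = cfg$cv_folds,
                    small_grids = cfg$small_grids)$report
    } else {
      ft <- assemble_dataset(surf$recovery, desc, gen_cfg$design,
                             idac = idac_tbl)
      run_protocol(ft, models = cfg$models,
                   holdout_condition = cfg$split$holdout,
                   test_fraction = cfg$split$test_fraction,
                   seed = cfg$seed, cv_folds = cfg$cv_folds,
                   small_grids = cfg$small_grids)$report
    }
  })
  readr::write_csv(report, out("metrics.csv"), progress = FALSE)
  outputs <- c(outputs, "metrics.csv")

  # -- reporting -----------------------------------------------------------
  comp <- stage("report", class_abundance_summary(surf$recovery))
  readr::write_csv(as_tibble(comp), out("class_composition.csv"),
                   progress = FALSE)
  outputs <- c(outputs, "class_composition.csv")

  manifest <- list(
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    n_lipids = nrow(lib$records),
    n_conditions = nrow(gen_cfg$design),
    idac = cfg$idac,
    models = cfg$models,
    outputs = outputs)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
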
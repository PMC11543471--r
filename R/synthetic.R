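#' Configuration of the synthetic lipidomics generator
#'
#' Bundles every knob of the synthetic stand-in for a microalgal SFE
#' lipidomic study: library size and composition, the factorial design,
#' the latent recovery-surface coefficients (on log10 scale per unit of
#' the scaled condition variables), measurement noise and the detection
#' floor below which a cell is recorded as exact zero.
#'
#' Defaults emulate the statistical shape of such studies: ~89 annotated
#' lipids over 12 conditions, five classes dominated by
#' glycerophospholipids and glycerolipids, recovery responding
#' non-additively to temperature, pressure and cosolvent flow (the
#' cosolvent helps polar classes and suppresses fatty acyls at low
#' pressure only), and a small fraction of below-detection cells.
#'
#' @param n_lipids Number of shorthand families (default 89).
#' @param candidates_range Range of candidates per family (default 1..6).
#' @param class_weights Named sampling weights over the five lipid classes;
#'   must sum to 1.
#' @param design Extraction design tibble (default: the bundled 12
#'   conditions).
#' @param class_baseline Named log10-abundance baselines per class.
#' @param beta_T,beta_P,beta_flow Linear effects per scaled unit of
#'   temperature (`(T-50)/10`), pressure (`(P-200)/50`) and ethanol flow
#'   (`(flow-0.75)/0.15`).
#' @param beta_flow_class Named class-specific additional flow effects.
#' @param beta_fa_lowP Extra flow effect for fatty acyls at 150 bar only
#'   (the pressure x class threshold interaction).
#' @param beta_flow_polarity Coefficient of the flow x polarity-proxy
#'   interaction; the proxy is `0.3 * (n_double_bonds - 2)`, a
#'   deterministic function of structure so models can learn it.
#' @param intercept_sd SD of the per-lipid random intercept (log10).
#' @param noise_sd Measurement noise SD (log10).
#' @param detection_floor Relative abundance below which a cell is
#'   censored to exact 0.
#' @param interactions Logical: include the non-additive terms.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_lipids = 89,
    candidates_range = c(1, 6),
    class_weights = c("glycerophospholipids" = 0.38, "glycerolipids" = 0.30,
                      "sphingolipids" = 0.14, "prenols" = 0.10,
                      "fatty acyls" = 0.08),
    design = default_design(),
    class_baseline = c("glycerophospholipids" = -0.8, "glycerolipids" = -1.0,
                       "sphingolipids" = -1.6, "prenols" = -1.9,
                       "fatty acyls" = -2.0),
    beta_T = 0.15, beta_P = 0.20, beta_flow = 0.10,
    beta_flow_class = c("glycerophospholipids" = 0.25, "glycerolipids" = 0.15,
                        "sphingolipids" = 0, "prenols" = -0.05,
                        "fatty acyls" = 0),
    beta_fa_lowP = -0.25,
    beta_flow_polarity = 0.12,
    intercept_sd = 0.45, noise_sd = 0.15,
    detection_floor = 10^-2.9,
    interactions = TRUE,
    seed = 1) {
  if (abs(sum(class_weights) - 1) > 1e-8) {
    stop_sfelip("class_weights must sum to 1", "class_weights")
  }
  if (noise_sd < 0) stop_sfelip("noise_sd must be >= 0", "noise_sd")
  if (detection_floor <= 0) stop_sfelip("detection_floor must be > 0", "floor")
  structure(as.list(environment()), class = "generator_config")
}

# ---- SMILES templates ------------------------------------------------------

# Acyl chain written from the methyl end; db_pos are bond indices counted
# from the carbonyl (delta-x nomenclature), the carbonyl carbon itself being
# supplied by the template.
chain_smiles <- function(len, db_pos = integer(0)) {
  atoms <- rep("C", len - 1)                # carbons len, len-1, ..., 2
  bonds <- rep("", len - 2)
  # string bond i joins carbons (len - i + 1, len - i); db between (p+1, p)
  for (p in db_pos) bonds[len - p] <- "="
  paste0(atoms[1], paste0(bonds, atoms[-1], collapse = ""))
}

# Build the SMILES of one candidate given class and chain layout.
candidate_smiles <- function(class, chains) {
  ch <- lapply(chains, function(c_) chain_smiles(c_$len, c_$db %||% integer(0)))
  switch(class,
    "glycerophospholipids" = sprintf(
      "%sC(=O)OCC(COP(=O)([O-])OCC[N+](C)(C)C)OC(=O)%s",
      ch[[1]], rev_chain(chains[[2]])),
    "glycerolipids" = sprintf(
      "%sC(=O)OCC(O)COC(=O)%s", ch[[1]], rev_chain(chains[[2]])),
    "sphingolipids" = sprintf(
      "CCCCCCCCCCCCCC=CC(O)C(CO)NC(=O)%s", rev_chain(chains[[1]])),
    "prenols" = paste0(strrep("CC(C)=CC", chains[[1]]$len), "O"),
    "fatty acyls" = sprintf("%sC(=O)O", ch[[1]])
  )
}

# Chain written from the carbonyl end (carbonyl carbon supplied by template).
rev_chain <- function(c_) {
  atoms <- rep("C", c_$len - 1)
  bonds <- rep("", c_$len - 2)
  for (p in c_$db) bonds[p - 1] <- "="
  paste0(atoms[1], paste0(bonds, atoms[-1], collapse = ""))
}

class_prefix <- c("glycerophospholipids" = "PC", "glycerolipids" = "DG",
                  "sphingolipids" = "Cer", "prenols" = "Prenol",
                  "fatty acyls" = "FA")

# Distinct double-bond position sets for a chain (positions 2..len-2).
db_position_sets <- function(len, n_db, n_sets, rng_offset = 0) {
  if (n_db == 0) return(list(integer(0)))
  slots <- seq(3, len - 2)
  sets <- list()
  k <- 0
  while (length(sets) < n_sets && k < 50) {
    cand <- sort(sample(slots, n_db))
    if (min(diff(c(0, cand))) >= 2 &&
        !any(vapply(sets, identical, TRUE, y = cand))) {
      sets <- c(sets, list(cand))
    }
    k <- k + 1
  }
  sets
}

#' Generate a synthetic lipid library
#'
#' Builds `n_lipids` shorthand families from class-specific SMILES
#' templates (phosphatidylcholine-like glycerophospholipids,
#' diacylglycerol-like glycerolipids, ceramide-like sphingolipids,
#' isoprenoid prenols, free fatty acids) with acyl chain lengths 12-22 and
#' 0-6 double bonds. Candidates within a family share the shorthand's sum
#' composition and differ only in double-bond positions or the split of
#' carbons between the two chains — the ambiguity mode of real lipid
#' annotation. All emitted SMILES are syntactically valid.
#'
#' @param config A [generator_config()].
#' @return List with `records` (tibble `lipid_id`, `shorthand`,
#'   `lipid_class`, `smiles` of the first candidate, `total_c`, `n_db`)
#'   and `candidates` (tibble `shorthand`, `candidate_id`, `smiles`).
#' @export
generate_lipid_library <- function(config = generator_config()) {
  withr::with_seed(child_seed(config$seed, 1), {
    classes <- sample(names(config$class_weights), config$n_lipids,
                      replace = TRUE, prob = config$class_weights)
    recs <- list()
    cands <- list()
    seen <- character(0)
    for (i in seq_len(config$n_lipids)) {
      cl <- classes[i]
      attempts <- 0
      repeat {
        attempts <- attempts + 1
        # a class with a small shorthand space can fill up; spill over into
        # the roomiest class rather than rejecting forever
        if (attempts > 50) cl <- "glycerolipids"
        if (cl == "prenols") {
          units <- sample(2:12, 1)
          total_c <- units * 5
          n_db <- units
          sh <- sprintf("Prenol C%d", total_c)
        } else if (cl == "fatty acyls") {
          total_c <- sample(seq(12, 22, 2), 1)
          n_db <- sample(0:3, 1)
          sh <- sprintf("FA %d:%d", total_c, n_db)
        } else if (cl == "sphingolipids") {
          total_c <- 16 + sample(seq(12, 22, 2), 1)
          n_db <- 1 + sample(0:2, 1)
          sh <- sprintf("Cer %d:%d", total_c, n_db)
        } else {
          c1 <- sample(seq(12, 22, 2), 1); c2 <- sample(seq(12, 22, 2), 1)
          total_c <- c1 + c2
          n_db <- sample(0:6, 1)
          sh <- sprintf("%s %d:%d", class_prefix[cl], total_c, n_db)
        }
        if (!sh %in% seen) break
      }
      seen <- c(seen, sh)
      n_cand <- sample(seq(config$candidates_range[1],
                           config$candidates_range[2]), 1)
      smis <- family_candidates(cl, total_c, n_db, n_cand)
      recs[[i]] <- tibble(
        lipid_id = sprintf("L%03d", i), shorthand = sh, lipid_class = cl,
        smiles = smis[1], total_c = total_c, n_db = n_db)
      cands[[i]] <- tibble(
        shorthand = sh,
        candidate_id = sprintf("%s#%d", sh, seq_along(smis)),
        smiles = smis)
    }
    list(records = list_rbind(recs), candidates = list_rbind(cands))
  })
}

# Enumerate up to n_cand distinct candidate SMILES for one family.
family_candidates <- function(class, total_c, n_db, n_cand) {
  smis <- character(0)
  if (class %in% c("glycerophospholipids", "glycerolipids")) {
    splits <- list()
    for (c1 in seq(12, min(22, total_c - 12), 2)) {
      c2 <- total_c - c1
      if (c2 >= 12 && c2 <= 22) splits <- c(splits, list(c(c1, c2)))
    }
    for (sp in splits) {
      for (d1 in 0:n_db) {
        d2 <- n_db - d1
        if (d1 > (sp[1] - 6) / 2 || d2 > (sp[2] - 6) / 2) next
        p1 <- db_position_sets(sp[1], d1, 1)
        p2 <- db_position_sets(sp[2], d2, 1)
        if (!length(p1) || !length(p2)) next
        smis <- c(smis, candidate_smiles(class, list(
          list(len = sp[1], db = p1[[1]]), list(len = sp[2], db = p2[[1]]))))
        if (length(unique(smis)) >= n_cand) break
      }
      if (length(unique(smis)) >= n_cand) break
    }
  } else if (class == "fatty acyls") {
    sets <- db_position_sets(total_c, n_db, n_cand + 2)
    for (s in sets) {
      smis <- c(smis, candidate_smiles(class, list(list(len = total_c, db = s))))
    }
  } else if (class == "sphingolipids") {
    acyl <- total_c - 16
    sets <- db_position_sets(acyl, n_db - 1, n_cand + 2)
    for (s in sets) {
      smis <- c(smis, candidate_smiles(class, list(list(len = acyl, db = s))))
    }
  } else { # prenols: rigid template, single candidate
    smis <- candidate_smiles(class, list(list(len = total_c / 5, db = NULL)))
  }
  unique(smis)[seq_len(min(n_cand, length(unique(smis))))]
}

#' Generate a synthetic recovery surface
#'
#' Draws the lipid x condition table of relative abundances from a latent
#' log10 model: class baseline + linear effects of the scaled condition
#' variables + non-additive terms (class-specific cosolvent response, a
#' fatty-acyl flow penalty active only at low pressure, and a flow x
#' unsaturation-proxy interaction) + a per-lipid random intercept +
#' Gaussian noise. Cells whose abundance falls below the detection floor
#' are recorded as exact `0.0`, the contract consumed by the -7 imputation
#' in [assemble_dataset()]. The uncensored surface, the latent means and
#' every coefficient are returned as ground truth.
#'
#' @param library Result of [generate_lipid_library()].
#' @param config A [generator_config()].
#' @return List with `recovery` (a `recovery_tbl`) and `truth` (list:
#'   `latent` long tibble with `mu` and uncensored `y`, `intercepts`,
#'   `config`).
#' @export
generate_recovery_surface <- function(library, config = generator_config()) {
  recs <- library$records
  design <- validate_design(config$design)
  withr::with_seed(child_seed(config$seed, 2), {
    icpt <- rnorm(nrow(recs), 0, config$intercept_sd)
    grid <- tidyr::expand_grid(lipid_id = recs$lipid_id,
                               condition_id = design$id) |>
      left_join(recs, by = "lipid_id") |>
      left_join(design, by = c("condition_id" = "id"))
    t_s <- (grid$temperature - 50) / 10
    p_s <- (grid$pressure - 200) / 50
    f_s <- (grid$ethanol_flow - 0.75) / 0.15
    mu <- config$class_baseline[grid$lipid_class] +
      config$beta_T * t_s + config$beta_P * p_s + config$beta_flow * f_s +
      icpt[match(grid$lipid_id, recs$lipid_id)]
    if (config$interactions) {
      polarity <- 0.3 * (grid$n_db - 2)
      mu <- mu + config$beta_flow_class[grid$lipid_class] * f_s +
        config$beta_fa_lowP * f_s *
          (grid$lipid_class == "fatty acyls") * (p_s < 0) +
        config$beta_flow_polarity * f_s * polarity
    }
    mu <- unname(mu)
    y <- mu + rnorm(nrow(grid), 0, config$noise_sd)
    abundance <- 10^y
    censored <- abundance < config$detection_floor
    abundance[censored] <- 0
    wide <- tibble(lipid_id = grid$lipid_id, condition_id = grid$condition_id,
                   abundance = abundance) |>
      pivot_wider(names_from = "condition_id", values_from = "abundance")
    recovery <- recs |>
      select("lipid_id", "shorthand", "lipid_class") |>
      left_join(wide, by = "lipid_id") |>
      validate_recovery()
    truth <- list(
      latent = tibble(lipid_id = grid$lipid_id,
                      condition_id = grid$condition_id,
                      mu = unname(mu), y = y, censored = censored),
      intercepts = setNames(icpt, recs$lipid_id),
      config = config)
    list(recovery = recovery, truth = truth)
  })
}

#' Analytic censoring probability of the generator
#'
#' Given the ground truth of [generate_recovery_surface()], the
#' probability that a cell falls below the detection floor is
#' `pnorm((log10(floor) - mu) / noise_sd)` per cell; this returns the mean
#' over cells — the closed-form counterpart of the observed censored
#' fraction.
#'
#' @param truth The `truth` element returned by the surface generator.
#' @return Scalar probability.
#' @export
expected_censored_fraction <- function(truth) {
  cfg <- truth$config
  if (cfg$noise_sd == 0) {
    return(mean(truth$latent$mu < log10(cfg$detection_floor)))
  }
  mean(pnorm((log10(cfg$detection_floor) - truth$latent$mu) / cfg$noise_sd))
}

#' Generate synthetic sigma profiles for a lipid library
#'
#' Each profile is a Gaussian mixture on the sigma grid: a dominant apolar
#' peak near zero plus class-dependent polar side lobes (head-group oxygens
#' and hydroxyls push surface area into the wings). Cavity area and volume
#' scale with chain length. These are statistical stand-ins for
#' quantum-chemistry COSMO output, not chemically accurate surfaces; they
#' satisfy all `sigma_profile` invariants by construction.
#'
#' @param records `records` tibble from [generate_lipid_library()].
#' @param config A [generator_config()].
#' @param grid Sigma grid.
#' @return Named list of `sigma_profile`s keyed by `lipid_id`.
#' @export
generate_sigma_profiles <- function(records, config = generator_config(),
                                    grid = sigma_grid()) {
  polar_mass <- c("glycerophospholipids" = 0.30, "glycerolipids" = 0.18,
                  "sphingolipids" = 0.22, "prenols" = 0.10,
                  "fatty acyls" = 0.15, "other" = 0.12)
  withr::with_seed(child_seed(config$seed, 3), {
    out <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      area <- 120 + 14 * r$total_c * runif(1, 0.95, 1.05)
      volume <- 90 + 16 * r$total_c * runif(1, 0.95, 1.05)
      pm <- polar_mass[[r$lipid_class]]
      mix_profile(grid, area, volume, name = r$lipid_id,
                  lobes = list(c(w = 1 - pm, mu = 0.000, s = 0.004),
                               c(w = pm / 2, mu = 0.013, s = 0.003),
                               c(w = pm / 2, mu = -0.013, s = 0.003)))
    })
    setNames(out, records$lipid_id)
  })
}

# Gaussian-mixture profile normalised to a given area.
mix_profile <- function(grid, area, volume, name, lobes) {
  dens <- Reduce(`+`, lapply(lobes, function(l) {
    l["w"] * exp(-(grid - l["mu"])^2 / (2 * l["s"]^2))
  }))
  sigma_profile(name = name, p = dens / sum(dens) * area, area = area,
                volume = volume, grid = grid)
}

#' Synthetic solvent sigma profiles
#'
#' Stand-ins for the CO2 and ethanol profiles: CO2 is a small symmetric
#' quadrupolar surface; ethanol has an apolar body plus strong
#' hydrogen-bond donor/acceptor lobes beyond the HB cutoff.
#'
#' @param grid Sigma grid.
#' @return Named list with elements `co2` and `ethanol`.
#' @export
solvent_profiles <- function(grid = sigma_grid()) {
  list(
    co2 = mix_profile(grid, area = 75, volume = 45, name = "co2",
                      lobes = list(c(w = 0.5, mu = 0.010, s = 0.003),
                                   c(w = 0.5, mu = -0.010, s = 0.003))),
    ethanol = mix_profile(grid, area = 112, volume = 75, name = "ethanol",
                          lobes = list(c(w = 0.70, mu = -0.001, s = 0.004),
                                       c(w = 0.15, mu = 0.015, s = 0.002),
                                       c(w = 0.15, mu = -0.014, s = 0.002))))
}

#' Generate a pure positional-isomer family
#'
#' Builds one candidate family whose members share the class, chain split
#' and double-bond count and differ *only* in double-bond positions — the
#' narrowest (and commonest) ambiguity mode of shorthand annotation, and
#' the regime in which fingerprint similarity between candidates is
#' characteristically high.
#'
#' @param class One of the two-chain classes (`"glycerophospholipids"` or
#'   `"glycerolipids"`) or `"fatty acyls"`.
#' @param total_c Total acyl carbons (split evenly for two-chain classes).
#' @param n_db Number of double bonds, all placed on one chain.
#' @param n_candidates Number of distinct position variants requested.
#' @param seed Integer seed for position sampling.
#' @return Candidate tibble (`shorthand`, `candidate_id`, `smiles`).
#' @export
positional_isomer_family <- function(class = "glycerophospholipids",
                                     total_c = 34, n_db = 1,
                                     n_candidates = 4, seed = 1) {
  sh <- sprintf("%s %d:%d", class_prefix[class], total_c, n_db)
  withr::with_seed(seed, {
    if (class == "fatty acyls") {
      sets <- db_position_sets(total_c, n_db, n_candidates)
      smis <- vapply(sets, function(s) {
        candidate_smiles(class, list(list(len = total_c, db = s)))
      }, "")
    } else {
      c1 <- 2 * floor(total_c / 4)
      c2 <- total_c - c1
      sets <- db_position_sets(c1, n_db, n_candidates)
      smis <- vapply(sets, function(s) {
        candidate_smiles(class, list(list(len = c1, db = s),
                                     list(len = c2, db = integer(0))))
      }, "")
    }
  })
  smis <- unique(smis)
  tibble(shorthand = sh,
         candidate_id = sprintf("%s#%d", sh, seq_along(smis)),
         smiles = smis)
}

#' Build a numeric family with a planted representative
#'
#' Constructs a descriptor-space candidate family in which one candidate
#' sits (up to a small jitter) at the mean of the others — the ground-truth
#' representative the clustering selector should recover.
#'
#' @param n_candidates Family size (>= 3).
#' @param n_descriptors Descriptor dimension.
#' @param jitter_sd SD of the perturbation applied to the planted
#'   candidate.
#' @param seed Integer seed.
#' @return List with the `candidate_family` (`family`) and the planted
#'   candidate's id (`planted`).
#' @export
make_planted_family <- function(n_candidates = 5, n_descriptors = 8,
                                jitter_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n_candidates - 1) * n_descriptors), n_candidates - 1)
    planted <- colMeans(X) + rnorm(n_descriptors, 0, jitter_sd)
    pos <- sample(n_candidates, 1)
    ids <- sprintf("cand%d", seq_len(n_candidates))
    M <- matrix(NA_real_, n_candidates, n_descriptors)
    M[-pos, ] <- X
    M[pos, ] <- planted
    desc <- bind_cols(tibble(id = ids),
                      as_tibble(M, .name_repair = ~ sprintf("d%d", seq_len(n_descriptors))))
    fam <- candidate_family(
      "planted", tibble(candidate_id = ids, smiles = NA_character_),
      descriptors = desc)
    list(family = fam, planted = ids[pos])
  })
}
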
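#' Universal parameters of the segment-activity model
#'
#' The COSMO-SAC functional form needs a handful of universal constants:
#' the effective segment contact area `a_eff` (A^2), the electrostatic
#' misfit constant `alpha_prime` (kcal A^4 mol^-1 e^-2), the
#' hydrogen-bonding constant `c_hb` (same units) and cutoff `sigma_hb`
#' (e/A^2), the lattice coordination number `z` and the area/volume
#' normalisation parameters `q0` (A^2) and `r0` (A^3) of the
#' Staverman-Guggenheim combinatorial term, plus the segment-averaging
#' radius `r_av` (A). Defaults are the widely used literature values; all
#' are overridable so variant parameterisations can be explored.
#'
#' @param a_eff Effective segment surface area, A^2.
#' @param alpha_prime Misfit energy constant, kcal A^4 mol^-1 e^-2.
#' @param c_hb Hydrogen-bond energy constant, kcal A^4 mol^-1 e^-2.
#' @param sigma_hb Hydrogen-bond cutoff, e/A^2.
#' @param z Coordination number.
#' @param q0 Standard segment area, A^2.
#' @param r0 Standard segment volume, A^3.
#' @param r_av Averaging radius, A.
#' @param R_kcal Gas constant, kcal mol^-1 K^-1.
#' @return Named list of parameters.
#' @export
cosmo_parameters <- function(a_eff = 7.5, alpha_prime = 16466.72,
                             c_hb = 85580.0, sigma_hb = 0.0084,
                             z = 10, q0 = 79.53, r0 = 66.69,
                             r_av = 0.81764, R_kcal = 1.9872042586e-3) {
  list(a_eff = a_eff, alpha_prime = alpha_prime, c_hb = c_hb,
       sigma_hb = sigma_hb, z = z, q0 = q0, r0 = r0, r_av = r_av,
       R_kcal = R_kcal)
}

#' Segment exchange energy
#'
#' Pair interaction energy of two surface segments with screening charge
#' densities `sigma_m`, `sigma_n`: an electrostatic misfit term
#' proportional to `(sigma_m + sigma_n)^2` plus a hydrogen-bonding term
#' that only activates for opposite-sign pairs whose densities exceed the
#' cutoff (an acceptor-like positive density paired with a donor-like
#' negative one). Symmetric in its arguments; vectorised/outer-safe.
#'
#' @param sigma_m,sigma_n Charge densities, e/A^2 (scalars or arrays).
#' @param params Parameter list from [cosmo_parameters()].
#' @return Exchange energy in kcal/mol (per `a_eff` contact).
#' @export
exchange_energy <- function(sigma_m, sigma_n, params = cosmo_parameters()) {
  misfit <- (params$alpha_prime / 2) * (sigma_m + sigma_n)^2
  sigma_acc <- pmax(sigma_m, sigma_n)
  sigma_don <- pmin(sigma_m, sigma_n)
  hb <- params$c_hb * pmax(0, sigma_acc - params$sigma_hb) *
    pmin(0, sigma_don + params$sigma_hb)
  misfit + hb
}

# Boltzmann-weighted interaction matrix exp(-dW/RT) on a grid.
exchange_kernel <- function(grid, T_K, params) {
  dW <- outer(grid, grid, exchange_energy, params = params)
  exp(-dW / (params$R_kcal * T_K))
}

#' Solve the segment self-consistency equation
#'
#' The segment activity coefficients Gamma(sigma) of a (mixture or pure)
#' normalised sigma profile satisfy the implicit closure
#' `ln Gamma(sigma_m) = -ln sum_n p(sigma_n) Gamma(sigma_n)
#'  exp(-dW(sigma_m, sigma_n) / RT)`.
#' Solved by damped successive substitution; convergence is measured as the
#' infinity norm of the change in `ln Gamma` between sweeps.
#'
#' @param p_norm Normalised profile (sums to 1) on `grid`.
#' @param T_K Temperature, K.
#' @param grid Sigma grid; defaults to the standard 51-point grid.
#' @param params Parameter list.
#' @param tol Convergence tolerance on the residual infinity norm.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   last residual.
#' @param damping Fraction of the new iterate blended in per sweep,
#'   in `(0, 1]`.
#' @param kernel Optional precomputed [exchange_kernel()] (performance).
#' @return List with `grid`, `ln_gamma`, `residual`, `iterations`.
#' @export
solve_segment_gammas <- function(p_norm, T_K, grid = sigma_grid(),
                                 params = cosmo_parameters(), tol = 1e-10,
                                 max_iter = 5000, damping = 0.6,
                                 kernel = NULL) {
  stopifnot(length(p_norm) == length(grid))
  K <- kernel %||% exchange_kernel(grid, T_K, params)
  ln_g <- numeric(length(grid))
  for (it in seq_len(max_iter)) {
    ln_new <- -log(as.vector(K %*% (p_norm * exp(ln_g))))
    resid <- max(abs(ln_new - ln_g))
    ln_g <- damping * ln_new + (1 - damping) * ln_g
    if (resid <= tol) {
      return(list(grid = grid, ln_gamma = ln_g, residual = resid,
                  iterations = it))
    }
  }
  stop_sfelip(sprintf(
    "segment equation did not converge in %d iterations (residual %.3e)",
    max_iter, resid), "no_convergence")
}

# Mixture profile p_S(sigma), normalised to 1, plus total mixture area.
mixture_profile <- function(profiles, x) {
  areas <- vapply(profiles, function(p) attr(p, "area"), 1)
  P <- vapply(profiles, function(p) p$p, numeric(nrow(profiles[[1]])))
  p_mix <- as.vector(P %*% x)
  list(p_norm = p_mix / sum(p_mix), area = sum(x * areas))
}

# Staverman-Guggenheim combinatorial term for all components.
sg_combinatorial <- function(profiles, x, params) {
  r <- vapply(profiles, function(p) attr(p, "volume"), 1) / params$r0
  q <- vapply(profiles, function(p) attr(p, "area"), 1) / params$q0
  l <- (params$z / 2) * (r - q) - (r - 1)
  phi_x <- r / sum(x * r)        # phi_i / x_i
  theta_phi <- (q / sum(x * q)) / phi_x
  log(phi_x) + (params$z / 2) * q * log(theta_phi) + l -
    phi_x * sum(x * l)
}

#' Activity coefficients in a mixture from sigma profiles
#'
#' Full model: residual (segment) part plus Staverman-Guggenheim
#' combinatorial part. The residual part area-weights the difference
#' between the segment activities of the mixture and of the pure component
#' over the component's own profile.
#'
#' @param profiles List of `sigma_profile`s sharing one grid.
#' @param x Mole fractions (must sum to 1).
#' @param T_K Temperature, K.
#' @param params Parameter list from [cosmo_parameters()].
#' @param component Optional index; when given, only that component's
#'   ln(gamma) is returned.
#' @param ... Passed to [solve_segment_gammas()] (`tol`, `max_iter`,
#'   `damping`).
#' @return Numeric vector of ln(gamma) per component (or a scalar).
#' @export
ln_activity_coefficient <- function(profiles, x, T_K,
                                    params = cosmo_parameters(),
                                    component = NULL, ...) {
  if (abs(sum(x) - 1) > 1e-12) stop_sfelip("mole fractions must sum to 1", "x_sum")
  if (any(x < 0)) stop_sfelip("mole fractions must be non-negative", "x_negative")
  assert_positive(T_K, "temperature")
  grid <- profiles[[1]]$sigma
  for (p in profiles) {
    if (!isTRUE(all.equal(p$sigma, grid, tolerance = 1e-12))) {
      stop_sfelip("profiles are not on a shared sigma grid", "grid_mismatch")
    }
  }
  K <- exchange_kernel(grid, T_K, params)
  mix <- mixture_profile(profiles, x)
  g_mix <- solve_segment_gammas(mix$p_norm, T_K, grid, params, kernel = K, ...)
  idx <- component %||% seq_along(profiles)
  sg <- sg_combinatorial(profiles, x, params)
  out <- vapply(idx, function(i) {
    pi_ <- profiles[[i]]$p
    Ai <- attr(profiles[[i]], "area")
    g_pure <- solve_segment_gammas(pi_ / sum(pi_), T_K, grid, params,
                                   kernel = K, ...)
    resid <- (1 / params$a_eff) *
      sum(pi_ * (g_mix$ln_gamma - g_pure$ln_gamma))
    resid + sg[i]
  }, 1)
  if (!is.null(component)) out else setNames(out, vapply(
    profiles, function(p) attr(p, "name"), ""))
}

#' Infinite-dilution activity-coefficient curve of a lipid
#'
#' Computes ln(gamma-infinity) of a lipid in a CO2-ethanol solvent as a
#' function of the ethanol mole fraction, at fixed temperature. The lipid
#' is pinned at a vanishing mole fraction (default 1e-5) to realise
#' infinite dilution, and the two solvent fractions are scaled to fill the
#' remaining `1 - x_lipid`.
#'
#' @param lipid Sigma profile of the lipid.
#' @param co2,ethanol Sigma profiles of the solvents.
#' @param T_K Temperature, K (use [celsius_to_kelvin()] at the boundary).
#' @param x_ethanol Grid of solvent-basis ethanol mole fractions in `[0, 1)`.
#' @param x_lipid Lipid mole fraction (default 1e-5).
#' @param params,... Passed to [ln_activity_coefficient()].
#' @return Tibble with columns `x_ethanol`, `ln_gamma`, classed
#'   `idac_curve`.
#' @export
idac_curve <- function(lipid, co2, ethanol, T_K,
                       x_ethanol = seq(0, 0.95, by = 0.05), x_lipid = 1e-5,
                       params = cosmo_parameters(), ...) {
  if (any(x_ethanol < 0 | x_ethanol >= 1)) {
    stop_sfelip("x_ethanol grid values must lie in [0, 1)", "x_grid")
  }
  ln_g <- vapply(x_ethanol, function(xe) {
    x <- c((1 - xe) * (1 - x_lipid), xe * (1 - x_lipid), x_lipid)
    ln_activity_coefficient(list(co2, ethanol, lipid), x, T_K,
                            params = params, component = 3L, ...)
  }, 1)
  structure(tibble(x_ethanol = x_ethanol, ln_gamma = ln_g),
            lipid = attr(lipid, "name"), T_K = T_K,
            class = c("idac_curve", class(tibble())))
}

#' @exportS3Method ggplot2::autoplot
autoplot.idac_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$x_ethanol, y = .data$ln_gamma)) +
    geom_line(color = "firebrick") + geom_point(size = 1) +
    labs(x = "ethanol mole fraction",
         y = expression(ln ~ gamma^infinity),
         title = attr(object, "lipid")) +
    theme_minimal()
}

#' Convert pump flows to solvent mole fractions
#'
#' The extraction design specifies volumetric pump flows; the
#' thermodynamic model needs mole fractions. The conversion uses molar
#' flows `Q * rho / M` with pump-side liquid densities, so it is invariant
#' to scaling both flows.
#'
#' @param design Design tibble (or any data frame with `ethanol_flow` and
#'   `co2_flow` columns, mL/min).
#' @param rho_ethanol,rho_co2 Pump-side densities, g/mL.
#' @param M_ethanol,M_co2 Molar masses, g/mol.
#' @return The design with `x_ethanol` and `x_co2` columns appended.
#' @export
flows_to_mole_fractions <- function(design, rho_ethanol = 0.789,
                                    rho_co2 = 0.90, M_ethanol = 46.07,
                                    M_co2 = 44.01) {
  design <- as_tibble(design)
  if (any(design$co2_flow <= 0) || any(design$ethanol_flow < 0)) {
    stop_sfelip("flows must be positive (ethanol flow may be zero)",
                "nonpositive_flow")
  }
  n_eth <- design$ethanol_flow * rho_ethanol / M_ethanol
  n_co2 <- design$co2_flow * rho_co2 / M_co2
  design |>
    mutate(x_ethanol = n_eth / (n_eth + n_co2),
           x_co2 = n_co2 / (n_eth + n_co2))
}

#' Scan activity coefficients of a binary mixture over composition
#'
#' Computes ln(gamma) of both components on an `x1` grid, reusing the
#' temperature-dependent interaction kernel and the two pure-component
#' segment solutions across the whole scan (they do not depend on
#' composition), which makes fine grids cheap.
#'
#' @param profile_1,profile_2 Sigma profiles of the two components.
#' @param x1 Grid of component-1 mole fractions in `(0, 1)`.
#' @param T_K Temperature, K.
#' @param params Parameter list from [cosmo_parameters()].
#' @param ... Passed to [solve_segment_gammas()].
#' @return Tibble with columns `x1`, `ln_gamma_1`, `ln_gamma_2`.
#' @export
binary_gamma_scan <- function(profile_1, profile_2, x1, T_K,
                              params = cosmo_parameters(), ...) {
  profiles <- list(profile_1, profile_2)
  grid <- profile_1$sigma
  K <- exchange_kernel(grid, T_K, params)
  pure <- lapply(profiles, function(p) {
    solve_segment_gammas(p$p / sum(p$p), T_K, grid, params, kernel = K,
                         ...)$ln_gamma
  })
  res <- vapply(x1, function(x) {
    xs <- c(x, 1 - x)
    mix <- mixture_profile(profiles, xs)
    g_mix <- solve_segment_gammas(mix$p_norm, T_K, grid, params,
                                  kernel = K, ...)$ln_gamma
    sg <- sg_combinatorial(profiles, xs, params)
    vapply(1:2, function(i) {
      (1 / params$a_eff) * sum(profiles[[i]]$p * (g_mix - pure[[i]])) + sg[i]
    }, 1)
  }, c(0, 0))
  tibble(x1 = x1, ln_gamma_1 = res[1, ], ln_gamma_2 = res[2, ])
}

#' Gibbs-Duhem residual of a binary activity-coefficient scan
#'
#' At constant temperature and pressure a binary system must satisfy
#' `x1 d(ln gamma1) + x2 d(ln gamma2) = 0`. Given ln(gamma) curves on an
#' `x1` grid, this evaluates the relation on each interval with trapezoid
#' (midpoint) weights and returns the largest absolute violation per unit
#' of `x1` — a stringent internal-consistency oracle for the model.
#'
#' @param x1 Grid of component-1 mole fractions.
#' @param ln_g1,ln_g2 ln(gamma) of the two components on the grid.
#' @return Maximum absolute residual (dimensionless).
#' @export
gibbs_duhem_residual <- function(x1, ln_g1, ln_g2) {
  dx <- diff(x1)
  x1_mid <- (head(x1, -1) + tail(x1, -1)) / 2
  r <- x1_mid * diff(ln_g1) / dx + (1 - x1_mid) * diff(ln_g2) / dx
  max(abs(r))
}

#' Compute an IDAC feature table over a design
#'
#' Evaluates ln(gamma-infinity) of every lipid at every extraction
#' condition's temperature and ethanol mole fraction (pressure does not
#' enter the model). Conditions sharing `(T, x_ethanol)` reuse one solve.
#'
#' @param lipid_profiles Named list of lipid sigma profiles (names =
#'   lipid ids).
#' @param design Design tibble.
#' @param co2,ethanol Solvent sigma profiles.
#' @param x_lipid Lipid mole fraction for infinite dilution.
#' @param params,... Passed down to the solver.
#' @return Tibble with columns `lipid_id`, `condition_id`, `idac` (ln
#'   gamma-infinity).
#' @export
compute_idac_table <- function(lipid_profiles, design, co2, ethanol,
                               x_lipid = 1e-5, params = cosmo_parameters(),
                               ...) {
  design <- flows_to_mole_fractions(design)
  key <- sprintf("%.6f|%.6f", design$temperature, design$x_ethanol)
  out <- vector("list", length(unique(key)))
  names(out) <- unique(key)
  for (k in unique(key)) {
    row <- design[match(k, key), ]
    T_K <- celsius_to_kelvin(row$temperature)
    xe <- row$x_ethanol
    vals <- vapply(lipid_profiles, function(lp) {
      x <- c((1 - xe) * (1 - x_lipid), xe * (1 - x_lipid), x_lipid)
      ln_activity_coefficient(list(co2, ethanol, lp), x, T_K,
                              params = params, component = 3L, ...)
    }, 1)
    out[[k]] <- tibble(lipid_id = names(lipid_profiles), key = k, idac = vals)
  }
  map <- tibble(condition_id = design$id, key = key)
  list_rbind(out) |>
    left_join(map, by = "key", relationship = "many-to-many") |>
    select("lipid_id", "condition_id", "idac")
}
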
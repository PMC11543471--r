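test_that("exchange energy matches a by-hand evaluation and is symmetric", {
  p <- cosmo_parameters()
  # straight-line re-derivation at (0.01, -0.02):
  # misfit = alpha'/2 * (0.01 - 0.02)^2
  # hb     = c_hb * max(0, 0.01 - sigma_hb) * min(0, -0.02 + sigma_hb)
  misfit <- 16466.72 / 2 * (0.01 - 0.02)^2
  hb <- 85580 * (0.01 - 0.0084) * (-0.02 + 0.0084)
  expect_equal(exchange_energy(0.01, -0.02, p), misfit + hb, tolerance = 1e-12)
  expect_equal(exchange_energy(-0.02, 0.01, p), exchange_energy(0.01, -0.02, p))
  # opposite small densities: misfit vanishes, hb inactive below cutoff
  expect_equal(exchange_energy(0.005, -0.005, p), 0)
  # grid symmetry of the whole kernel
  g <- sigma_grid(11, 0.02)
  M <- outer(g, g, exchange_energy, params = p)
  expect_equal(M, t(M))
})

test_that("segment solver reduces to the ideal limit and matches the 2-bin oracle", {
  # all exchange energies zero -> ln Gamma identically 0
  p0 <- cosmo_parameters(alpha_prime = 0, c_hb = 0)
  sol0 <- solve_segment_gammas(c(0.3, 0.7), T_K = 320, grid = c(-0.01, 0.01),
                               params = p0)
  expect_equal(sol0$ln_gamma, c(0, 0), tolerance = 1e-12)

  # 2-bin toy profile vs brute-force grid search
  params <- cosmo_parameters()
  grid2 <- c(-0.012, 0.012)
  K <- exp(-outer(grid2, grid2, exchange_energy, params = params) /
             (params$R_kcal * 310))
  for (p1 in c(0.2, 0.5, 0.8)) {
    p <- c(p1, 1 - p1)
    sol <- solve_segment_gammas(p, T_K = 310, grid = grid2, params = params,
                                tol = 1e-12)
    oracle <- oracle_two_bin_gamma(p, K)
    expect_equal(exp(sol$ln_gamma), oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # convergence failure carries a classed error
  expect_error(
    solve_segment_gammas(c(0.5, 0.5), T_K = 310, grid = grid2,
                         params = params, tol = 1e-10, max_iter = 2),
    class = "sfelip_error_no_convergence")
})

test_that("pure-component and indistinguishable-mixture identities hold", {
  profs <- c(solvent_profiles(),
             lapply(1:4, random_sigma_profile) |>
               stats::setNames(paste0("r", 1:4)))
  for (pr in profs) {
    expect_lt(abs(ln_activity_coefficient(list(pr), 1, T_K = 323.15)), 1e-10)
  }
  co2 <- profs$co2
  for (x1 in c(0.1, 0.5, 0.9)) {
    lg <- ln_activity_coefficient(list(co2, co2), c(x1, 1 - x1), T_K = 323.15)
    expect_lt(max(abs(lg)), 1e-10)
  }
})

test_that("binary scans satisfy the Gibbs-Duhem relation", {
  solv <- solvent_profiles()
  x1 <- seq(0.02, 0.98, by = 0.005)
  scan <- binary_gamma_scan(solv$co2, solv$ethanol, x1, T_K = 323.15)
  expect_lt(gibbs_duhem_residual(x1, scan$ln_gamma_1, scan$ln_gamma_2), 1e-3)
  # the scan agrees with the general mixture route
  direct <- ln_activity_coefficient(list(solv$co2, solv$ethanol),
                                    c(0.5, 0.5), T_K = 323.15)
  mid <- scan[abs(scan$x1 - 0.5) < 1e-9, ]
  expect_equal(c(mid$ln_gamma_1, mid$ln_gamma_2), unname(direct),
               tolerance = 1e-9)
})

test_that("infinite dilution is numerically attained at x_lipid = 1e-5", {
  solv <- solvent_profiles()
  lip <- random_sigma_profile(21, "lip")
  xls <- c(1e-5, 5e-6, 2.5e-6)
  curves <- lapply(xls, function(xl) {
    idac_curve(lip, solv$co2, solv$ethanol, T_K = 323.15,
               x_ethanol = c(0.1, 0.5), x_lipid = xl)$ln_gamma
  })
  d1 <- max(abs(curves[[2]] - curves[[1]]))
  d2 <- max(abs(curves[[3]] - curves[[2]]))
  # within a few milli-units of the x -> 0 limit, and converging
  # linearly: each halving halves the remaining distance
  expect_lt(d1, 5e-3)
  expect_lt(d2, 0.6 * d1)

  # a lipid identical to the cosolvent approaches ln gamma = 0 as the
  # solvent becomes pure cosolvent
  same <- idac_curve(solv$ethanol, solv$co2, solv$ethanol, T_K = 323.15,
                     x_ethanol = c(0.5, 0.99999))
  expect_lt(abs(same$ln_gamma[2]), 1e-3)
  expect_error(idac_curve(lip, solv$co2, solv$ethanol, 323.15,
                          x_ethanol = c(0.2, 1)),
               class = "sfelip_error_x_grid")
})

test_that("flow-to-mole-fraction conversion is exact and scale invariant", {
  d <- tibble::tibble(id = "SC5", temperature = 60, pressure = 150,
                      ethanol_flow = 0.6, co2_flow = 5)
  x <- flows_to_mole_fractions(d)
  n_eth <- 0.6 * 0.789 / 46.07
  n_co2 <- 5 * 0.90 / 44.01
  expect_equal(x$x_ethanol, n_eth / (n_eth + n_co2), tolerance = 1e-12)
  expect_equal(round(x$x_ethanol, 3), 0.091)
  expect_equal(x$x_ethanol + x$x_co2, 1)

  z <- flows_to_mole_fractions(dplyr::mutate(d, ethanol_flow = 0))
  expect_equal(z$x_ethanol, 0)
  dbl <- flows_to_mole_fractions(
    dplyr::mutate(d, ethanol_flow = 1.2, co2_flow = 10))
  expect_equal(dbl$x_ethanol, x$x_ethanol, tolerance = 1e-12)
})

test_that("segment averaging respects locality, symmetry and mirroring", {
  # one segment: all area lands in its own bin
  one <- tibble::tibble(x = 0, y = 0, z = 0, area = 3, sigma = 0)
  pr <- average_segments(one, name = "one")
  expect_equal(pr$p[which(pr$sigma == 0)], 3)
  expect_equal(sum(pr$p), 3)

  # two equal, spatially distant segments at +/- sigma0: symmetric profile
  two <- tibble::tibble(x = c(0, 100), y = 0, z = 0, area = 2,
                        sigma = c(-0.01, 0.01))
  pr2 <- average_segments(two, name = "two")
  expect_equal(pr2$p, rev(pr2$p), tolerance = 1e-12)

  # mirroring the input mirrors the output
  seg <- tibble::tibble(x = c(0, 5, 50), y = 0, z = 0,
                        area = c(1, 2, 1.5), sigma = c(-0.012, 0.004, 0.009))
  a <- average_segments(seg, name = "a")
  b <- average_segments(dplyr::mutate(seg, sigma = -sigma), name = "b")
  expect_equal(a$p, rev(b$p), tolerance = 1e-12)

  expect_error(average_segments(one[0, ]),
               class = "sfelip_error_empty_segments")
})
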
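# Closed-form model quantities: back-calculated plasticity, critical rates,
# responses to selection, optimal plasticity, adaptive ranges, lags.

test_that("type constructors enforce their invariants", {
  expect_error(genetic_architecture(G_f = -1, G_m = 1), "G_f")
  expect_error(genetic_architecture(G_f = 2, G_m = 2, G_fm = 3),
               "correlation")
  expect_error(genetic_architecture(G_f = 2, G_m = 2, rho = 1.2), "rho")
  expect_error(genetic_architecture(G_f = 2, G_m = 2, G_fm = 1, rho = 0.5),
               "not both")
  # rho normalizes to G_fm: single source of truth
  a <- genetic_architecture(G_f = 4, G_m = 9, rho = 0.5)
  expect_equal(a$G_fm, 0.5 * sqrt(36))
  expect_equal(cross_sex_correlation(a), 0.5)
  expect_error(demography(r_max = 0, T = 2), "r_max")
  expect_error(demography(r_max = 0.5, T = -1), "T")
  expect_warning(fitness_landscape(0.005, B_f = -5, B_m = 2), "opposing")
  expect_error(critical_rate(-0.1), ">= 0")
  expect_false(critical_rate(Inf)$finite)
})

test_that("social plasticity back-calculates from variance components", {
  # published variance components: gull, great tit, and a null covariance
  expect_equal(round(psi_from_components(-1.380, 1.49), 2), -0.93)
  expect_equal(psi_from_components(-1.380, 1.49), -0.9261745,
               tolerance = 1e-6)
  expect_equal(round(psi_from_components(1.011, 1.57), 2), 0.64)
  expect_equal(psi_from_components(0, 3.6), 0)
  expect_error(psi_from_components(1, 0), "G_i")
  expect_error(psi_from_components(1, -2), "G_i")
})

test_that("cross-sex regression is rho * sqrt(G_f / G_m)", {
  expect_equal(cross_sex_regression(0, 6, 2), 0)
  expect_equal(cross_sex_regression(1, 4, 4), 1)
  # frozen from exact arithmetic: 0.7 * sqrt(5.96 / 1.57)
  expect_equal(cross_sex_regression(0.7, 5.96, 1.57), 1.3638648718018335,
               tolerance = 1e-12)
  expect_error(cross_sex_regression(1.5, 4, 4), "rho")
})

test_that("reference critical rate matches direct arithmetic and scalings", {
  cr <- eta_critical_reference(ref_dem(), ref_gamma, ref_G_f, ref_B_f)
  expect_true(cr$finite)
  expect_equal(cr$value, 0.03, tolerance = 1e-12)
  # eta_c proportional to G_f
  cr2 <- eta_critical_reference(ref_dem(), ref_gamma, 2 * ref_G_f, ref_B_f)
  expect_equal(cr2$value, 2 * cr$value, tolerance = 1e-12)
  # invariant under the sign of B_f
  expect_equal(eta_critical_reference(ref_dem(), ref_gamma, ref_G_f, 5)$value,
               cr$value)
  # a temperature-insensitive optimum never accrues a lag
  flat <- eta_critical_reference(ref_dem(), ref_gamma, ref_G_f, 0)
  expect_false(flat$finite)
  expect_identical(flat$value, Inf)
})

test_that("IGE critical rate extends the reference denominator", {
  cr <- eta_critical_ige(ref_dem(), ref_gamma, ref_G_f, ref_B_f,
                         psi = 0.64, B_m = -5)
  expect_equal(cr$value, 0.025 * 6 / abs(-5 + 3.2), tolerance = 1e-12)
  expect_equal(cr$value, 0.08333333333333333, tolerance = 1e-12)
  # psi = 0 reduces exactly to the reference model
  expect_identical(
    eta_critical_ige(ref_dem(), ref_gamma, ref_G_f, ref_B_f, 0, -5)$value,
    eta_critical_reference(ref_dem(), ref_gamma, ref_G_f, ref_B_f)$value)
  # tracking entirely through the IGE: unbounded tolerance
  unb <- eta_critical_ige(ref_dem(), ref_gamma, ref_G_f, -5, psi = 0.8,
                          B_m = -5 / 0.8)
  expect_false(unb$finite)
})

test_that("full-model critical rate reduces along the model chain and
           matches the arbitrary-precision oracle", {
  dem <- ref_dem()
  # G_fm = 0 collapses to the IGE model on identical inputs
  a_ige <- genetic_architecture(G_f = 6, G_m = 1.57, G_fm = 0, psi = 0.64)
  expect_identical(
    eta_critical_full(dem, ref_gamma, a_ige, -5, -5)$value,
    eta_critical_ige(dem, ref_gamma, 6, -5, 0.64, -5)$value)
  # ... and with psi = 0 all the way to the reference model
  a_ref <- genetic_architecture(G_f = 6, G_m = 1.57)
  expect_identical(
    eta_critical_full(dem, ref_gamma, a_ref, -5, -5)$value,
    eta_critical_reference(dem, ref_gamma, 6, -5)$value)
  # frozen from a symbolic evaluation of the full expression at
  # G_f = 6, G_m = 1.57, rho = 0.7, psi = 0.64, B_f = B_m = -5
  a_full <- genetic_architecture(G_f = 6, G_m = 1.57, rho = 0.7, psi = 0.64)
  expect_equal(eta_critical_full(dem, ref_gamma, a_full, -5, -5)$value,
               0.015172039833103572, tolerance = 1e-12)
  # |rho| = 1 leaves no sex-independent variance
  a_sat <- genetic_architecture(G_f = 4, G_m = 4, rho = 1, psi = 0.2)
  expect_warning(cr <- eta_critical_full(dem, ref_gamma, a_sat, -5, -5),
                 "rho")
  expect_equal(cr$value, 0)
})

test_that("critical rates are invariant under joint negation of the
           sensitivities and decrease with the tracking mismatch", {
  dem <- ref_dem()
  a <- genetic_architecture(G_f = 6, G_m = 2, rho = 0.4, psi = 0.7)
  expect_equal(eta_critical_full(dem, ref_gamma, a, -5, -3)$value,
               eta_critical_full(dem, ref_gamma, a, 5, 3)$value)
  # widening |B_f - (psi + xi) B_m| strictly lowers eta_c
  vals <- vapply(c(-4, -6, -8), function(B_f)
    eta_critical_full(dem, ref_gamma, a, B_f, -1)$value, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("response to selection follows the two-sex Lande form", {
  # univariate reduction: no covariance, no plasticity
  a <- genetic_architecture(G_f = 6, G_m = 2)
  expect_equal(response_to_selection(a, beta_f = 0.1, beta_m = 0.7)[["dz_f"]],
               0.5 * 6 * 0.1)
  # hand-computed: dz_m = 0.5 * 2 * 0.2 = 0.2, dz_f = 0.3 + 0.5 * 0.2 = 0.4
  a2 <- genetic_architecture(G_f = 6, G_m = 2, G_fm = 0, psi = 0.5)
  dz <- response_to_selection(a2, beta_f = 0.1, beta_m = 0.2)
  expect_equal(dz, c(dz_f = 0.4, dz_m = 0.2))
  expect_equal(response_to_selection(a2, 0, 0), c(dz_f = 0, dz_m = 0))
})

test_that("optimal plasticity is the sensitivity ratio less the genetic
           regression, and is the argmax of the critical rate", {
  expect_equal(psi_optimal(-5, -5), 1)
  expect_equal(psi_optimal(-5, -7.8125), 0.64)
  expect_equal(psi_optimal(-5, -5, xi = 1.3638648718018335),
               1 - 1.3638648718018335)
  expect_error(psi_optimal(-5, 0), "B_m")
  # argmax: unbounded at psi_opt, strictly declining moving away from it
  dem <- ref_dem()
  for (p in random_param_sets(5, seed = 11)) {
    xi <- cross_sex_regression(cross_sex_correlation(p$arch),
                               p$arch$G_f, p$arch$G_m)
    opt <- psi_optimal(p$B_f, p$B_m, xi)
    at <- function(psi) {
      a <- genetic_architecture(p$arch$G_f, p$arch$G_m, G_fm = p$arch$G_fm,
                                psi = psi)
      eta_critical_full(p$dem, p$gamma_f, a, p$B_f, p$B_m)$value
    }
    # at psi_opt the denominator vanishes (up to rounding): the rate there
    # dominates both neighbors
    for (delta in c(1e-3, 1e-2)) {
      expect_true(at(opt) > at(opt + delta))
      expect_true(at(opt) > at(opt - delta))
      expect_true(at(opt + delta) > at(opt + 10 * delta))
      expect_true(at(opt - delta) > at(opt - 10 * delta))
    }
  }
})

test_that("adaptive range endpoints match the uncorrelated closed form and a
           dense-grid comparison against the reference rate", {
  expect_equal(psi_adaptive_range(-5, -5), c(lower = 0, upper = 2))
  expect_equal(psi_adaptive_range(-5, -2.5), c(lower = 0, upper = 4))
  expect_error(psi_adaptive_range(-5, 0), "B_m")
  expect_error(psi_adaptive_range(-5, -5, rho = 1), "rho")
  # grid oracle: the full-model curve crosses the reference value exactly at
  # the endpoints (resolution 1e-4)
  for (p in random_param_sets(100, seed = 7)) {
    rho <- cross_sex_correlation(p$arch)
    xi <- cross_sex_regression(rho, p$arch$G_f, p$arch$G_m)
    rng <- psi_adaptive_range(p$B_f, p$B_m, rho, xi)
    grid <- seq(rng[["lower"]] - 0.25, rng[["upper"]] + 0.25, by = 1e-4)
    curve <- psi_curve(p$dem, p$gamma_f, p$arch$G_f, p$arch$G_m, rho,
                       p$B_f, p$B_m, grid)
    above <- curve$table$eta_c > curve$reference_eta_c
    flips <- which(diff(above) != 0)
    expect_length(flips, 2)
    expect_lt(abs(grid[flips[1] + 1] - rng[["lower"]]), 2e-4)
    expect_lt(abs(grid[flips[2] + 1] - rng[["upper"]]), 2e-4)
  }
})

test_that("lag load is quadratic and symmetric", {
  expect_equal(lag_load(ref_gamma, 0), 0)
  expect_equal(lag_load(ref_gamma, 10), 0.25)
  expect_equal(lag_load(ref_gamma, -10), lag_load(ref_gamma, 10))
  expect_error(lag_load(0, 1), "gamma_f")
})

test_that("equilibrium lag vanishes in a static environment and hits the
           extinction-threshold magnitude at the critical rate", {
  for (p in random_param_sets(10, seed = 3)) {
    expect_equal(equilibrium_lag(0, p$dem, p$gamma_f, p$arch, p$B_f, p$B_m),
                 0)
    eta_c <- eta_critical_full(p$dem, p$gamma_f, p$arch, p$B_f, p$B_m)
    if (!eta_c$finite) next
    lag <- equilibrium_lag(eta_c$value, p$dem, p$gamma_f, p$arch,
                           p$B_f, p$B_m)
    # the pivot identity of the derivation: lag load exactly cancels r_max*T
    expect_equal(abs(lag), sqrt(2 * p$dem$r_max * p$dem$T / p$gamma_f),
                 tolerance = 1e-12)
  }
})

test_that("units compose: per-year demography with day-scaled genetics gives
           a rate in degrees C per year", {
  # halve the generation time at fixed r_max: eta_c scales by sqrt(2)/1 * 2
  # through the 1/T inside the square root and the per-year optimum shift
  a <- eta_critical_reference(demography(0.5, 1), ref_gamma, 6, -5)$value
  b <- eta_critical_reference(demography(0.5, 4), ref_gamma, 6, -5)$value
  expect_equal(a / b, 2, tolerance = 1e-12)
})
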
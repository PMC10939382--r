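# Shared fixtures: the standard evaluation parameter set used throughout the
# package docs (r_max = 0.5, T = 2, gamma = 0.005, G_f = 6, B_f = -5) and a
# generator of randomized-but-reproducible parameter sets for property tests.

ref_dem <- function() demography(r_max = 0.5, T = 2)
ref_gamma <- 0.005
ref_G_f <- 6
ref_B_f <- -5

ref_landscape <- function(B_m = -5) {
  fitness_landscape(gamma_f = ref_gamma, B_f = ref_B_f, B_m = B_m)
}

# Random parameter sets kept inside the comfortably-converging region of the
# recursion (moderate correlations and curvatures).
random_param_sets <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    G_f <- runif(1, 2, 12)
    G_m <- runif(1, 1, 6)
    rho <- runif(1, -0.8, 0.8)
    psi <- runif(1, -1.2, 2)
    B_f <- runif(1, -8, -2)
    B_m <- runif(1, -8, -2)
    list(
      dem = demography(r_max = runif(1, 0.1, 0.8), T = runif(1, 1, 4)),
      gamma_f = runif(1, 0.003, 0.01),
      arch = genetic_architecture(G_f = G_f, G_m = G_m, rho = rho, psi = psi),
      B_f = B_f, B_m = B_m)
  })
}

landscape_of <- function(p) {
  fitness_landscape(gamma_f = p$gamma_f, B_f = p$B_f, B_m = p$B_m)
}
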
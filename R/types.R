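# Domain types: parameter bundles with validated invariants.  All are plain
# S3 lists; derived quantities (rho, xi) are computed on demand, never stored.

.check_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                       finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

#' Genetic architecture of female lay-date and the male partner trait
#'
#' Bundles the additive genetic (co)variance components and the social
#' plasticity slope that define the genotype-phenotype map of the model: the
#' female lay-date carries direct additive variance `G_f`, the male trait
#' carries additive variance `G_m`, the two may share architecture through the
#' cross-sex additive covariance `G_fm`, and the female responds plastically
#' to the expressed male trait with linear reaction-norm slope `psi`
#' (the interaction coefficient of trait-based indirect-genetic-effect
#' models).
#'
#' The cross-sex genetic correlation `rho = G_fm / sqrt(G_f * G_m)` and the
#' cross-sex genetic regression `xi = G_fm / G_m` are derived quantities;
#' compute them with [cross_sex_correlation()] and [cross_sex_regression()].
#' Either `G_fm` or `rho` may be supplied (not both); the constructor
#' normalizes to `G_fm` so that the bound `|G_fm| <= sqrt(G_f * G_m)` has a
#' single source of truth.
#'
#' @param G_f Additive genetic variance of female lay-date (days^2), > 0.
#' @param G_m Additive genetic variance of the male trait (days^2), > 0.
#' @param G_fm Cross-sex additive genetic covariance (days^2);
#'   `|G_fm| <= sqrt(G_f * G_m)`.  Default 0.
#' @param rho Alternative to `G_fm`: the cross-sex genetic correlation in
#'   `[-1, 1]`.
#' @param psi Social plasticity: slope of female lay-date on the male trait
#'   value (days per day, dimensionless).  Default 0.
#'
#' @return An object of class `"genetic_architecture"`: a list with elements
#'   `G_f`, `G_m`, `G_fm`, `psi`.
#' @examples
#' genetic_architecture(G_f = 6, G_m = 1.57, rho = 0.7, psi = 0.64)
#' @export
genetic_architecture <- function(G_f, G_m, G_fm = NULL, rho = NULL, psi = 0) {
  .check_num(G_f, "G_f", positive = TRUE)
  .check_num(G_m, "G_m", positive = TRUE)
  .check_num(psi, "psi")
  if (!is.null(G_fm) && !is.null(rho))
    stop("supply either `G_fm` or `rho`, not both", call. = FALSE)
  if (is.null(G_fm)) {
    if (is.null(rho)) {
      G_fm <- 0
    } else {
      .check_num(rho, "rho")
      if (abs(rho) > 1)
        stop(sprintf("`rho` must lie in [-1, 1] (got %g)", rho),
             call. = FALSE)
      G_fm <- rho * sqrt(G_f * G_m)
    }
  } else {
    .check_num(G_fm, "G_fm")
    if (abs(G_fm) > sqrt(G_f * G_m) * (1 + 1e-12))
      stop(sprintf(
        "`G_fm` (%g) exceeds sqrt(G_f * G_m) = %g: implied |correlation| > 1",
        G_fm, sqrt(G_f * G_m)), call. = FALSE)
  }
  structure(list(G_f = G_f, G_m = G_m, G_fm = G_fm, psi = psi),
            class = "genetic_architecture")
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat("Genetic architecture (days^2):\n")
  cat(sprintf("  G_f = %g, G_m = %g, G_fm = %g (rho = %.4g)\n",
              x$G_f, x$G_m, x$G_fm, cross_sex_correlation(x)))
  cat(sprintf("  social plasticity psi = %g\n", x$psi))
  invisible(x)
}

#' Cross-sex genetic correlation of an architecture
#'
#' @param arch A [genetic_architecture()].
#' @return `rho = G_fm / sqrt(G_f * G_m)`, dimensionless.
#' @export
cross_sex_correlation <- function(arch) {
  stopifnot(inherits(arch, "genetic_architecture"))
  arch$G_fm / sqrt(arch$G_f * arch$G_m)
}

#' Sex-specific fitness landscape
#'
#' Quadratic (stabilizing) fitness functions for the female lay-date and the
#' male trait, each with an optimum that advances linearly with temperature.
#' `B_f` and `B_m` are the environmental sensitivities of the sex-specific
#' optima (days per degree C); under spring warming at rate `eta` (degrees
#' C/year) the optima advance by `B_j * eta` days per year.
#'
#' The focal scenario has both optima shifting in the same direction
#' (`B_f * B_m > 0`, typically both negative: warming advances both optima).
#' Opposing shifts are a valid generalization of the model, so a differing
#' sign pattern only triggers a warning.
#'
#' @param gamma_f Curvature of stabilizing selection on lay-date (1/days^2),
#'   > 0.
#' @param B_f Sensitivity of the optimum lay-date to temperature (days/deg C).
#' @param B_m Sensitivity of the male-trait optimum (days/deg C).
#' @param gamma_m Curvature of stabilizing selection on the male trait;
#'   defaults to `gamma_f`.
#' @param theta_f0,theta_m0 Initial optima (days; day-of-year scale).
#'
#' @return An object of class `"fitness_landscape"`.
#' @examples
#' fitness_landscape(gamma_f = 0.005, B_f = -5, B_m = -5)
#' @export
fitness_landscape <- function(gamma_f, B_f, B_m, gamma_m = gamma_f,
                              theta_f0 = 0, theta_m0 = 0) {
  .check_num(gamma_f, "gamma_f", positive = TRUE)
  .check_num(gamma_m, "gamma_m", positive = TRUE)
  .check_num(B_f, "B_f")
  .check_num(B_m, "B_m")
  .check_num(theta_f0, "theta_f0")
  .check_num(theta_m0, "theta_m0")
  if (B_f * B_m < 0)
    warning("B_f and B_m have opposing signs: sex-specific optima shift in ",
            "opposite directions (a generalization of the focal scenario)",
            call. = FALSE)
  structure(list(gamma_f = gamma_f, gamma_m = gamma_m, B_f = B_f, B_m = B_m,
                 theta_f0 = theta_f0, theta_m0 = theta_m0),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("Fitness landscape:\n")
  cat(sprintf("  gamma_f = %g, gamma_m = %g (1/days^2)\n", x$gamma_f,
              x$gamma_m))
  cat(sprintf("  B_f = %g, B_m = %g (days/deg C); theta0 = (%g, %g)\n",
              x$B_f, x$B_m, x$theta_f0, x$theta_m0))
  invisible(x)
}

#' Demographic parameters
#'
#' Intrinsic growth rate and generation time.  The ratio `r_max / T` captures
#' the pace of life: "fast" species (high `r_max`, short `T`) tolerate faster
#' environmental change than "slow" species.
#'
#' @param r_max Intrinsic (maximum) population growth rate, per year, > 0.
#' @param T Generation time in years, > 0.  One simulator step spans one
#'   generation, i.e. `T` years.
#' @return An object of class `"demography"`.
#' @examples
#' demography(r_max = 0.5, T = 2)
#' @export
demography <- function(r_max, T) {
  .check_num(r_max, "r_max", positive = TRUE)
  .check_num(T, "T", positive = TRUE)
  structure(list(r_max = r_max, T = T), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("Demography: r_max = %g /year, T = %g years\n", x$r_max, x$T))
  invisible(x)
}

#' Critical rate of environmental change
#'
#' Container for a critical rate eta_c (degrees C per year).  `finite = FALSE`
#' marks the degenerate case where the tracking denominator of the model
#' vanishes and tolerance to environmental change is unbounded; `value` is
#' then `Inf`.  Grid and Monte Carlo callers must handle the non-finite case
#' explicitly, which is why it is flagged rather than raised as an error.
#'
#' @param value eta_c in degrees C/year; `Inf` allowed when `finite = FALSE`.
#' @param finite Logical flag; `FALSE` means unbounded tolerance.
#' @return An object of class `"critical_rate"`.
#' @export
critical_rate <- function(value, finite = is.finite(value)) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value))
    stop("`value` must be a single number (possibly Inf)", call. = FALSE)
  if (finite && value < 0)
    stop("a finite critical rate must be >= 0", call. = FALSE)
  structure(list(value = value, finite = isTRUE(finite)),
            class = "critical_rate")
}

#' @export
print.critical_rate <- function(x, ...) {
  if (x$finite)
    cat(sprintf("Critical rate of environmental change: %g deg C/year\n",
                x$value))
  else
    cat("Critical rate of environmental change: unbounded",
        "(tracking denominator is zero)\n")
  invisible(x)
}
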
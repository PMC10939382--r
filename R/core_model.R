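# Closed-form model quantities: critical rates of environmental change,
# responses to selection, optimal social plasticity, adaptive ranges, and
# equilibrium lags.

# Vectorized numeric kernel shared by the scalar wrappers, the psi-curve /
# grid evaluators, and the Monte Carlo propagation.  `rho2` is the squared
# cross-sex genetic correlation; `denom` is B_f - (psi + xi) * B_m.
# Returns Inf where the tracking denominator vanishes (unbounded tolerance)
# and 0 where rho2 == 1 (no sex-independent genetic variance left).
.eta_c_value <- function(r_max, T, gamma_f, G_f, rho2, denom) {
  pre <- 0.5 * sqrt(2 * r_max * gamma_f / T)
  out <- pre * G_f * (1 - rho2) / abs(denom)  # recycles to the longest input
  out[rep_len(denom == 0, length(out))] <- Inf
  out[rep_len(rho2 >= 1, length(out))] <- 0
  out
}

#' Back-calculate social plasticity from variance components
#'
#' Under the simplifying assumption that all male effects on lay-date act
#' through a single male trait, the social plasticity slope is the regression
#' of the direct-indirect genetic covariance on the indirect genetic
#' variance, `psi = G_fi / G_i`.  This is how published variance-partitioning
#' (animal model) estimates are converted to the trait-based interaction
#' coefficient used throughout the package.
#'
#' @param G_fi Direct-indirect additive genetic covariance (days^2).
#' @param G_i Indirect additive genetic variance (days^2), > 0.
#' @return The social plasticity slope (dimensionless).
#' @examples
#' psi_from_components(G_fi = 1.011, G_i = 1.57)  # great tit, ~0.64
#' @export
psi_from_components <- function(G_fi, G_i) {
  if (!is.numeric(G_i) || any(!is.finite(G_i)) || any(G_i <= 0))
    stop("`G_i` must be positive and finite: the indirect genetic variance ",
         "must exceed zero to back-calculate psi", call. = FALSE)
  if (!is.numeric(G_fi) || any(!is.finite(G_fi)))
    stop("`G_fi` must be finite", call. = FALSE)
  G_fi / G_i
}

#' Cross-sex genetic regression coefficient
#'
#' `xi = G_fm / G_m = rho * sqrt(G_f / G_m)`: the expected change in female
#' breeding value per unit change in male breeding value.  It enters the
#' tracking denominator of the full model exactly like the social plasticity
#' slope, which is what makes the two processes directly comparable.
#'
#' @param rho Cross-sex genetic correlation, in `[-1, 1]`.
#' @param G_f Additive genetic variance of female lay-date (days^2), > 0.
#' @param G_m Additive genetic variance of the male trait (days^2), > 0.
#' @return `xi` (dimensionless).
#' @export
cross_sex_regression <- function(rho, G_f, G_m) {
  if (any(abs(rho) > 1))
    stop(sprintf("`rho` must lie in [-1, 1] (got %g)", rho[which.max(abs(rho))]),
         call. = FALSE)
  if (any(G_f <= 0) || any(G_m <= 0))
    stop("`G_f` and `G_m` must be > 0", call. = FALSE)
  rho * sqrt(G_f / G_m)
}

#' Critical rate of environmental change, reference scenario
#'
#' The fastest sustained rate of temperature change a population can tolerate
#' when lay-date evolves as a sex-limited female trait with no male effects:
#'
#' \deqn{\eta_c = \frac{1}{2}\sqrt{\frac{2 r_{max} \gamma_f}{T}}
#'       \frac{G_f}{|B_f|}.}
#'
#' Faster-moving optima (larger `|B_f|`) require faster microevolution and
#' lower the critical rate; more genetic variance and a faster pace of life
#' (`r_max / T`) raise it.
#'
#' @param dem A [demography()].
#' @param gamma_f Stabilizing-selection curvature on lay-date (1/days^2).
#' @param G_f Additive genetic variance of lay-date (days^2).
#' @param B_f Sensitivity of the optimum lay-date to temperature
#'   (days/deg C).  `B_f = 0` yields an unbounded (non-finite) critical rate:
#'   an optimum insensitive to temperature never accrues a lag.
#' @return A [critical_rate()] in degrees C/year.
#' @examples
#' eta_critical_reference(demography(0.5, 2), gamma_f = 0.005,
#'                        G_f = 6, B_f = -5)  # 0.03 deg C/year
#' @export
eta_critical_reference <- function(dem, gamma_f, G_f, B_f) {
  stopifnot(inherits(dem, "demography"))
  .check_num(gamma_f, "gamma_f", positive = TRUE)
  .check_num(G_f, "G_f", positive = TRUE)
  .check_num(B_f, "B_f")
  v <- .eta_c_value(dem$r_max, dem$T, gamma_f, G_f, rho2 = 0, denom = B_f)
  critical_rate(v)
}

#' Critical rate with indirect genetic effects (uncorrelated traits)
#'
#' Extends the reference model with female social plasticity `psi` to a
#' genetically independent male trait whose optimum shifts at `B_m` days per
#' degree C.  The tracking denominator becomes `|B_f - psi * B_m|`: partner
#' effects shrink the realized mismatch whenever `psi * B_m` moves lay-date
#' in the direction the optimum is going.
#'
#' @inheritParams eta_critical_reference
#' @param psi Social plasticity slope (dimensionless).
#' @param B_m Sensitivity of the male-trait optimum (days/deg C).
#' @return A [critical_rate()].  Non-finite when `B_f - psi * B_m = 0`: the
#'   population then tracks the shifting optimum entirely through the
#'   indirect genetic effect.
#' @examples
#' eta_critical_ige(demography(0.5, 2), 0.005, G_f = 6, B_f = -5,
#'                  psi = 0.64, B_m = -5)
#' @export
eta_critical_ige <- function(dem, gamma_f, G_f, B_f, psi, B_m) {
  stopifnot(inherits(dem, "demography"))
  .check_num(gamma_f, "gamma_f", positive = TRUE)
  .check_num(G_f, "G_f", positive = TRUE)
  .check_num(B_f, "B_f"); .check_num(psi, "psi"); .check_num(B_m, "B_m")
  v <- .eta_c_value(dem$r_max, dem$T, gamma_f, G_f, rho2 = 0,
                    denom = B_f - psi * B_m)
  critical_rate(v)
}

#' Critical rate with indirect genetic effects and cross-sex correlation
#'
#' The full model: lay-date is socially plastic (slope `psi`) and genetically
#' correlated (covariance `G_fm`) with the male trait.  With
#' `rho = G_fm / sqrt(G_f G_m)` and `xi = G_fm / G_m`,
#'
#' \deqn{\eta_c = \frac{1}{2}\sqrt{\frac{2 \gamma_f r_{max}}{T}}
#'   \frac{G_f (1 - \rho^2)}{|B_f - (\psi + \xi) B_m|}.}
#'
#' The correlation acts twice: it erodes sex-independent genetic variance in
#' the numerator, and it adds indirect selection `xi * B_m` to the tracking
#' denominator alongside the plastic term `psi * B_m`.
#'
#' @inheritParams eta_critical_reference
#' @param arch A [genetic_architecture()] carrying `G_f`, `G_m`, `G_fm`,
#'   `psi`.
#' @param B_m Sensitivity of the male-trait optimum (days/deg C).
#' @return A [critical_rate()].  Non-finite when the denominator vanishes;
#'   zero (with a warning) when `|rho| = 1`, since no sex-independent
#'   genetic variance remains.
#' @examples
#' arch <- genetic_architecture(G_f = 6, G_m = 1.57, rho = 0.7, psi = 0.64)
#' eta_critical_full(demography(0.5, 2), 0.005, arch, B_f = -5, B_m = -5)
#' @export
eta_critical_full <- function(dem, gamma_f, arch, B_f, B_m) {
  stopifnot(inherits(dem, "demography"), inherits(arch, "genetic_architecture"))
  .check_num(gamma_f, "gamma_f", positive = TRUE)
  .check_num(B_f, "B_f"); .check_num(B_m, "B_m")
  rho2 <- arch$G_fm^2 / (arch$G_f * arch$G_m)
  xi <- arch$G_fm / arch$G_m
  if (rho2 >= 1) {
    warning("|rho| = 1: no sex-independent genetic variance; ",
            "critical rate is zero", call. = FALSE)
    return(critical_rate(0))
  }
  v <- .eta_c_value(dem$r_max, dem$T, gamma_f, arch$G_f, rho2,
                    denom = B_f - (arch$psi + xi) * B_m)
  critical_rate(v)
}

#' Per-generation response to selection in both sexes
#'
#' The multivariate Lande response for the interacting pair of traits.  The
#' male trait responds to direct and indirect selection,
#' \deqn{\Delta\bar z_m = \tfrac{1}{2}(G_m \beta_m + G_{fm} \beta_f),}
#' and the female lay-date responds to direct selection, to indirect
#' selection through the cross-sex covariance, and plastically to the
#' evolving male trait:
#' \deqn{\Delta\bar z_f = \tfrac{1}{2}(G_f \beta_f + G_{fm} \beta_m)
#'       + \psi \Delta\bar z_m.}
#' The factor 1/2 arises because selection on each trait acts in one sex
#' only.
#'
#' @param arch A [genetic_architecture()].
#' @param beta_f,beta_m Directional selection gradients on the female and
#'   male traits (1/days).
#' @return Named numeric vector `c(dz_f = ..., dz_m = ...)` in days per
#'   generation.
#' @export
response_to_selection <- function(arch, beta_f, beta_m) {
  stopifnot(inherits(arch, "genetic_architecture"))
  dz_m <- 0.5 * (arch$G_m * beta_m + arch$G_fm * beta_f)
  dz_f <- 0.5 * (arch$G_f * beta_f + arch$G_fm * beta_m) + arch$psi * dz_m
  c(dz_f = dz_f, dz_m = dz_m)
}

#' Optimal social plasticity
#'
#' The plasticity slope that maximizes the critical rate of environmental
#' change: `psi_opt = B_f / B_m - xi`.  At this value the tracking
#' denominator `B_f - (psi + xi) B_m` vanishes and the population follows the
#' shifting optimum entirely through male effects (the critical rate is
#' unbounded there).  With uncorrelated traits (`xi = 0`) the optimum is the
#' ratio of the environmental sensitivities of the sex-specific optima.
#'
#' @param B_f,B_m Environmental sensitivities of the optima (days/deg C);
#'   `B_m` must be non-zero.
#' @param xi Cross-sex genetic regression (default 0).
#' @return `psi_opt` (dimensionless).
#' @export
psi_optimal <- function(B_f, B_m, xi = 0) {
  if (any(B_m == 0))
    stop("`B_m` = 0: the male optimum does not move, so no degree of ",
         "social plasticity is optimal", call. = FALSE)
  B_f / B_m - xi
}

#' Range of social plasticity that aids persistence
#'
#' The open interval of `psi` over which the full-model critical rate exceeds
#' the reference (no-male-effects) critical rate on the same inputs.  It is
#' obtained by solving
#' `|B_f - (psi + xi) B_m| < (1 - rho^2) |B_f|`
#' for `psi`; with `rho = xi = 0` this reduces to the interval
#' `(0, 2 B_f / B_m)`.  Outside the interval, male effects leave the average
#' lay-date lagging too far behind (below the lower endpoint) or trailing too
#' far ahead of (above the upper endpoint) its optimum.
#'
#' @param B_f,B_m Environmental sensitivities (days/deg C); `B_m` non-zero.
#' @param rho Cross-sex genetic correlation, `|rho| < 1`.
#' @param xi Cross-sex genetic regression.
#' @return Numeric vector `c(lower, upper)`, ascending.
#' @export
psi_adaptive_range <- function(B_f, B_m, rho = 0, xi = 0) {
  if (B_m == 0)
    stop("`B_m` = 0: male effects cannot alter tracking", call. = FALSE)
  if (abs(rho) >= 1)
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  half_width <- (1 - rho^2) * abs(B_f)
  ends <- sort(c((B_f - half_width) / B_m, (B_f + half_width) / B_m)) - xi
  names(ends) <- c("lower", "upper")
  ends
}

#' Lag load
#'
#' Reduction in log mean population fitness from the mismatch (lag) between
#' the average lay-date and its optimum: `(gamma_f / 2) * lag^2`.  Quadratic,
#' hence symmetric in the sign of the lag.
#'
#' @param gamma_f Stabilizing-selection curvature (1/days^2).
#' @param lag Mismatch `zbar_f - theta_f` in days.
#' @return Dimensionless load (per generation).
#' @export
lag_load <- function(gamma_f, lag) {
  if (any(gamma_f <= 0)) stop("`gamma_f` must be > 0", call. = FALSE)
  (gamma_f / 2) * lag^2
}

#' Equilibrium lag under sustained environmental change
#'
#' Once both traits track their moving optima at a constant rate, the female
#' lag settles at
#' \deqn{\bar z_f - \theta_f = \frac{-2 \eta T (B_f - (\psi + \xi) B_m)}
#'       {\gamma_f G_f (1 - \rho^2)},}
#' the fixed point of the generational recursion.  Its sign follows the
#' convention lag = `zbar_f - theta_f`, so with `B_f < 0` (warming advances
#' the optimum) a positive lag means breeding later than optimal.  At
#' `eta = eta_c` from [eta_critical_full()] the magnitude equals
#' `sqrt(2 r_max T / gamma_f)`, the lag at which the lag load exactly
#' cancels `r_max T`.
#'
#' @param eta Rate of environmental change (deg C/year), >= 0.
#' @inheritParams eta_critical_full
#' @return Signed equilibrium lag in days.
#' @export
equilibrium_lag <- function(eta, dem, gamma_f, arch, B_f, B_m) {
  stopifnot(inherits(dem, "demography"), inherits(arch, "genetic_architecture"))
  .check_num(eta, "eta", nonneg = TRUE)
  .check_num(gamma_f, "gamma_f", positive = TRUE)
  rho2 <- arch$G_fm^2 / (arch$G_f * arch$G_m)
  if (rho2 >= 1)
    stop("|rho| = 1: the equilibrium lag is undefined (no sex-independent ",
         "genetic variance)", call. = FALSE)
  xi <- arch$G_fm / arch$G_m
  -2 * eta * dem$T * (B_f - (arch$psi + xi) * B_m) /
    (gamma_f * arch$G_f * (1 - rho2))
}
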
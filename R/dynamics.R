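# Generation-by-generation recursion of trait means chasing moving optima.
# The simulator is deterministic (infinite-population mean dynamics) and
# serves as the independent check on the closed-form critical rates: the
# persistence/extinction boundary located by bisection must reproduce them.
#
# Year <-> generation bookkeeping: one step spans T years, so optima advance
# by B_j * eta * T days per generation and per-generation log growth is
# r_max * T minus the lag load.  Extinction is declared when equilibrium log
# growth is negative (the population can no longer replace itself).

#' Population state at one generation
#'
#' @param generation Generation counter (0 = initial state).
#' @param zbar_f,zbar_m Trait means (days).
#' @param theta_f,theta_m Optima (days).
#' @param log_mean_fitness_gen Per-generation log population growth
#'   (dimensionless); `r_max * T` minus the lag load.
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(generation, zbar_f, zbar_m, theta_f, theta_m,
                             log_mean_fitness_gen = NA_real_) {
  structure(list(generation = as.integer(generation),
                 zbar_f = zbar_f, zbar_m = zbar_m,
                 theta_f = theta_f, theta_m = theta_m,
                 log_mean_fitness_gen = log_mean_fitness_gen),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf(
    "Generation %d: zbar = (%.4g, %.4g), theta = (%.4g, %.4g), lnW = %.4g\n",
    x$generation, x$zbar_f, x$zbar_m, x$theta_f, x$theta_m,
    x$log_mean_fitness_gen))
  invisible(x)
}

#' Directional selection gradient under stabilizing selection
#'
#' Linearized gradient on a quadratic fitness surface:
#' `beta = -gamma * (zbar - theta)`.  Zero at the optimum and restoring
#' toward it; the curvature `gamma` is used directly, with phenotypic
#' variance held constant and absorbed into the standing load.
#'
#' @param zbar Trait mean (days).
#' @param theta Optimum (days).
#' @param gamma Stabilizing-selection curvature (1/days^2), > 0.
#' @return Selection gradient in 1/days.
#' @export
selection_gradient <- function(zbar, theta, gamma) {
  if (any(gamma <= 0)) stop("`gamma` must be > 0", call. = FALSE)
  -gamma * (zbar - theta)
}

#' Advance the population by one generation
#'
#' Computes sex-specific selection gradients on the current (pre-update)
#' lags, advances both optima by `B_j * eta * T` days, updates the trait
#' means with [response_to_selection()], and evaluates per-generation log
#' growth `r_max * T - lag_load(gamma_f, zbar_f - theta_f)` at the new state.
#' Only the female lag enters population growth (female demographic
#' dominance).
#'
#' @param state A [population_state()].
#' @param arch A [genetic_architecture()].
#' @param landscape A [fitness_landscape()].
#' @param dem A [demography()].
#' @param eta Rate of environmental change (deg C/year), >= 0.
#' @return The next [population_state()].
#' @export
step_generation <- function(state, arch, landscape, dem, eta) {
  stopifnot(inherits(state, "population_state"))
  beta_f <- selection_gradient(state$zbar_f, state$theta_f, landscape$gamma_f)
  beta_m <- selection_gradient(state$zbar_m, state$theta_m, landscape$gamma_m)
  dz <- response_to_selection(arch, beta_f, beta_m)
  theta_f <- state$theta_f + landscape$B_f * eta * dem$T
  theta_m <- state$theta_m + landscape$B_m * eta * dem$T
  zbar_f <- state$zbar_f + dz[["dz_f"]]
  zbar_m <- state$zbar_m + dz[["dz_m"]]
  lnW <- dem$r_max * dem$T - lag_load(landscape$gamma_f, zbar_f - theta_f)
  population_state(state$generation + 1L, zbar_f, zbar_m, theta_f, theta_m,
                   lnW)
}

# Bare recursion on the two lags; no trajectory storage.  Returns the
# equilibrium female lag and whether successive lags converged.  Used by the
# bisection and by simulate_tracking's convergence bookkeeping.
.run_to_equilibrium <- function(arch, landscape, dem, eta,
                                lag_f0 = 0, lag_m0 = 0,
                                max_generations = 20000L,
                                equilibrium_tol = 1e-9) {
  shift_f <- landscape$B_f * eta * dem$T
  shift_m <- landscape$B_m * eta * dem$T
  lag_f <- lag_f0; lag_m <- lag_m0
  for (g in seq_len(max_generations)) {
    beta_f <- -landscape$gamma_f * lag_f
    beta_m <- -landscape$gamma_m * lag_m
    dz_m <- 0.5 * (arch$G_m * beta_m + arch$G_fm * beta_f)
    dz_f <- 0.5 * (arch$G_f * beta_f + arch$G_fm * beta_m) + arch$psi * dz_m
    new_f <- lag_f + dz_f - shift_f
    new_m <- lag_m + dz_m - shift_m
    conv <- abs(new_f - lag_f) < equilibrium_tol &&
      abs(new_m - lag_m) < equilibrium_tol
    lag_f <- new_f; lag_m <- new_m
    if (conv)
      return(list(lag_f = lag_f, lag_m = lag_m, generations = g,
                  converged = TRUE))
  }
  list(lag_f = lag_f, lag_m = lag_m, generations = max_generations,
       converged = FALSE)
}

#' Simulate adaptive tracking of moving optima
#'
#' Iterates [step_generation()] from an initially adapted population (trait
#' means at their optima, unless `initial` overrides this) under a constant
#' rate of temperature change.  Equilibrium is declared when the lags of both
#' sexes change by less than `equilibrium_tol` days between successive
#' generations; the population is flagged extinct when equilibrium log
#' growth is negative.  Non-convergence within `max_generations` is reported
#' via the `equilibrium_reached` attribute, never silently truncated.
#'
#' @inheritParams step_generation
#' @param initial Optional starting [population_state()]; defaults to the
#'   adapted state `zbar = theta = theta0` from the landscape.
#' @param max_generations Iteration cap, >= 1.
#' @param equilibrium_tol Convergence tolerance on successive lags (days).
#' @return A data frame of class `"rescue_trajectory"` with columns
#'   `generation`, `zbar_f`, `zbar_m`, `theta_f`, `theta_m`, `lag_f`,
#'   `lag_m`, `log_mean_fitness_gen`, and attributes `equilibrium_reached`
#'   (logical) and `extinct` (logical; `NA` if equilibrium was not reached).
#' @examples
#' arch <- genetic_architecture(G_f = 6, G_m = 6)
#' land <- fitness_landscape(0.005, B_f = -5, B_m = -5)
#' traj <- simulate_tracking(arch, land, demography(0.5, 2), eta = 0.02)
#' attr(traj, "extinct")
#' @export
simulate_tracking <- function(arch, landscape, dem, eta, initial = NULL,
                              max_generations = 20000L,
                              equilibrium_tol = 1e-9) {
  stopifnot(inherits(arch, "genetic_architecture"),
            inherits(landscape, "fitness_landscape"),
            inherits(dem, "demography"))
  .check_num(eta, "eta", nonneg = TRUE)
  if (max_generations < 1) stop("`max_generations` must be >= 1",
                                call. = FALSE)
  if (is.null(initial))
    initial <- population_state(0L, landscape$theta_f0, landscape$theta_m0,
                                landscape$theta_f0, landscape$theta_m0)
  state <- initial
  state$log_mean_fitness_gen <- dem$r_max * dem$T -
    lag_load(landscape$gamma_f, state$zbar_f - state$theta_f)

  out <- matrix(NA_real_, nrow = max_generations + 1L, ncol = 8L)
  colnames(out) <- c("generation", "zbar_f", "zbar_m", "theta_f", "theta_m",
                     "lag_f", "lag_m", "log_mean_fitness_gen")
  record <- function(i, s) out[i, ] <<- c(
    s$generation, s$zbar_f, s$zbar_m, s$theta_f, s$theta_m,
    s$zbar_f - s$theta_f, s$zbar_m - s$theta_m, s$log_mean_fitness_gen)
  record(1L, state)

  equilibrium <- FALSE
  n <- 1L
  for (g in seq_len(max_generations)) {
    prev_lag_f <- state$zbar_f - state$theta_f
    prev_lag_m <- state$zbar_m - state$theta_m
    state <- step_generation(state, arch, landscape, dem, eta)
    n <- n + 1L
    record(n, state)
    if (abs((state$zbar_f - state$theta_f) - prev_lag_f) < equilibrium_tol &&
        abs((state$zbar_m - state$theta_m) - prev_lag_m) < equilibrium_tol) {
      equilibrium <- TRUE
      break
    }
  }
  traj <- as.data.frame(out[seq_len(n), , drop = FALSE])
  traj$generation <- as.integer(traj$generation)
  structure(traj,
            class = c("rescue_trajectory", "data.frame"),
            equilibrium_reached = equilibrium,
            extinct = if (equilibrium)
              traj$log_mean_fitness_gen[n] < 0 else NA)
}

#' @export
print.rescue_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Tracking trajectory: %d generations; equilibrium %s\n",
              n - 1L,
              if (isTRUE(attr(x, "equilibrium_reached"))) "reached"
              else "NOT reached"))
  ext <- attr(x, "extinct")
  if (!is.na(ext))
    cat(sprintf("  final lag_f = %.6g days, lnW = %.6g => %s\n",
                x$lag_f[n], x$log_mean_fitness_gen[n],
                if (ext) "extinct" else "persists"))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param traj A `"rescue_trajectory"` from [simulate_tracking()].
#' @param path Output file path.
#' @param meta Optional named list echoed as `# key: value` header comments.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, meta = list()) {
  stopifnot(inherits(traj, "rescue_trajectory"))
  meta <- c(meta, list(equilibrium_reached = attr(traj, "equilibrium_reached"),
                       extinct = attr(traj, "extinct")))
  write_rescue_csv(as.data.frame(traj), path, meta = meta)
}

#' Critical rate of environmental change by simulation
#'
#' Independent, simulation-based estimate of the critical rate: bisection on
#' the rate of environmental change over the persistence/extinction boundary
#' of the generational recursion.  For each candidate rate the recursion is
#' run to its equilibrium lag and the sign of equilibrium log growth
#' (`r_max * T` minus the lag load) decides which half of the bracket is
#' kept.  Because the recursion never evaluates the closed-form critical
#' rates, agreement with [eta_critical_reference()], [eta_critical_ige()],
#' and [eta_critical_full()] validates their derivation.
#'
#' @inheritParams simulate_tracking
#' @param bracket Length-2 numeric: rates (deg C/year) straddling the
#'   boundary, i.e. the lower endpoint persists and the upper goes extinct.
#' @param tol Relative tolerance on the estimate (default `1e-6`).
#' @return The estimated critical rate (deg C/year), as a plain number.
#' @export
critical_rate_by_simulation <- function(arch, landscape, dem,
                                        bracket = c(0, 1), tol = 1e-6,
                                        max_generations = 100000L,
                                        equilibrium_tol = 1e-10) {
  stopifnot(length(bracket) == 2L, bracket[1] >= 0, bracket[2] > bracket[1])
  lnW_at <- function(eta) {
    eq <- .run_to_equilibrium(arch, landscape, dem, eta,
                              max_generations = max_generations,
                              equilibrium_tol = equilibrium_tol)
    if (!eq$converged)
      stop(sprintf(
        "recursion did not reach equilibrium within %d generations at eta = %g",
        max_generations, eta), call. = FALSE)
    dem$r_max * dem$T - lag_load(landscape$gamma_f, eq$lag_f)
  }
  lo <- bracket[1]; hi <- bracket[2]
  lnW_lo <- lnW_at(lo); lnW_hi <- lnW_at(hi)
  if (lnW_lo < 0 || lnW_hi >= 0)
    stop(sprintf(paste0(
      "bracket does not straddle the extinction boundary: ",
      "lnW(%g) = %.6g (%s), lnW(%g) = %.6g (%s)"),
      lo, lnW_lo, if (lnW_lo >= 0) "persists" else "extinct",
      hi, lnW_hi, if (lnW_hi >= 0) "persists" else "extinct"),
      call. = FALSE)
  while ((hi - lo) > tol * max(hi, .Machine$double.eps)) {
    mid <- (lo + hi) / 2
    if (lnW_at(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
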
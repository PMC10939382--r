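# Monte Carlo propagation of published parameter-estimate uncertainty into
# densities of the critical rate across scenario grids.

#' Parameter estimate with standard error
#'
#' @param mean Point estimate.
#' @param se Standard error; `se = 0` means the parameter is treated as fixed.
#' @return An object of class `"parameter_estimate"`.
#' @export
parameter_estimate <- function(mean, se = 0) {
  .check_num(mean, "mean")
  .check_num(se, "se", nonneg = TRUE)
  structure(list(mean = mean, se = se), class = "parameter_estimate")
}

.as_estimate <- function(x, name) {
  if (inherits(x, "parameter_estimate")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(parameter_estimate(x))
  stop(sprintf("`%s` must be a parameter_estimate or a single number", name),
       call. = FALSE)
}

#' Published quantitative-genetic and demographic estimates for one species
#'
#' Variance components from animal-model studies (`G_f`: direct additive
#' variance of lay-date; `G_i`: indirect additive variance attributable to
#' the male partner; `G_fi`: direct-indirect covariance) together with the
#' intrinsic growth rate and generation time.  Social plasticity is
#' back-calculated as `psi = G_fi / G_i` (see [psi_from_components()]).
#'
#' @param name Species label.
#' @param r_max Intrinsic growth rate (per year); published without an SE,
#'   hence a plain number.
#' @param T Generation time in years; a [parameter_estimate()] or number.
#' @param G_f,G_i,G_fi Variance components (days^2); [parameter_estimate()]s
#'   or numbers.
#' @return An object of class `"species_estimates"`.
#' @export
species_estimates <- function(name, r_max, T, G_f, G_i, G_fi) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_num(r_max, "r_max", positive = TRUE)
  T <- .as_estimate(T, "T"); G_f <- .as_estimate(G_f, "G_f")
  G_i <- .as_estimate(G_i, "G_i"); G_fi <- .as_estimate(G_fi, "G_fi")
  if (G_f$mean <= 0) stop("`G_f` point estimate must be > 0", call. = FALSE)
  if (G_i$mean <= 0) stop("`G_i` point estimate must be > 0", call. = FALSE)
  if (T$mean <= 0) stop("`T` point estimate must be > 0", call. = FALSE)
  structure(list(name = name, r_max = r_max, T = T, G_f = G_f, G_i = G_i,
                 G_fi = G_fi),
            class = "species_estimates")
}

#' @export
print.species_estimates <- function(x, ...) {
  fmt <- function(pe) if (pe$se > 0) sprintf("%g +/- %g", pe$mean, pe$se)
    else sprintf("%g", pe$mean)
  cat(sprintf("%s: r_max = %g, T = %s, G_f = %s, G_i = %s, G_fi = %s",
              x$name, x$r_max, fmt(x$T), fmt(x$G_f), fmt(x$G_i),
              fmt(x$G_fi)),
      sprintf("(psi = %.3g)\n", x$G_fi$mean / x$G_i$mean))
  invisible(x)
}

#' Path to the packaged species table
#'
#' CSV of published estimates (point estimate and SE) for common gull,
#' great tit, and song sparrow.
#'
#' @return File path of the installed CSV.
#' @export
species_estimates_path <- function() {
  system.file("extdata", "species_estimates.csv", package = "evorescue",
              mustWork = TRUE)
}

#' Read a species table
#'
#' Expects a CSV with header `species, r_max, T_mean, T_se, Gf_mean, Gf_se,
#' Gi_mean, Gi_se, Gfi_mean, Gfi_se`.  Lines starting with `#` are ignored.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Named list of [species_estimates()], keyed by species label.
#' @export
read_species_table <- function(path = species_estimates_path()) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "r_max", "T_mean", "T_se", "Gf_mean", "Gf_se",
            "Gi_mean", "Gi_se", "Gfi_mean", "Gfi_se")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("species table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    species_estimates(
      name = df$species[i], r_max = df$r_max[i],
      T = parameter_estimate(df$T_mean[i], df$T_se[i]),
      G_f = parameter_estimate(df$Gf_mean[i], df$Gf_se[i]),
      G_i = parameter_estimate(df$Gi_mean[i], df$Gi_se[i]),
      G_fi = parameter_estimate(df$Gfi_mean[i], df$Gfi_se[i]))
  })
  names(out) <- df$species
  out
}

# Draw n values from one estimate; se = 0 collapses to the point estimate.
.draw <- function(pe, n) {
  if (pe$se == 0) rep(pe$mean, n) else stats::rnorm(n, pe$mean, pe$se)
}

# Redraw entries of x failing `bad(x)` until none do; `gen(k)` supplies k
# fresh draws.  Errors after max_rejections redraw sweeps.
.redraw <- function(x, bad, gen, max_rejections = 1e5, what = "parameter") {
  tries <- 0L
  idx <- which(bad(x))
  while (length(idx) > 0) {
    tries <- tries + 1L
    if (tries > max_rejections)
      stop(sprintf(
        "more than %g consecutive rejected draws for %s: degenerate estimate set",
        max_rejections, what), call. = FALSE)
    x[idx] <- gen(length(idx))
    idx <- idx[bad(x[idx])]
  }
  x
}

#' Sample concrete parameter sets from published estimates
#'
#' Draws each uncertain parameter independently from a normal distribution
#' with its point estimate and SE (parameters with `se = 0` stay fixed).
#' Draws are rejected and repeated until `G_f` and `G_i` exceed `1e-6` days^2
#' and `|G_fi| <= sqrt(G_f * G_i)` (the implied direct-indirect correlation
#' must lie in `[-1, 1]`); generation time is likewise kept positive.  When
#' the covariance is published without an SE it cannot be redrawn, so
#' admissibility is enforced by resampling the variance pair instead.  The
#' social plasticity slope `psi = G_fi / G_i` is returned alongside the raw
#' draws.
#'
#' @param est A [species_estimates()].
#' @param n Number of parameter sets to draw.
#' @param seed Optional integer seed for reproducibility; when supplied, two
#'   calls with the same seed return identical draws.
#' @param max_rejections Cap on consecutive rejected redraws before a
#'   degenerate estimate set is reported as an error.
#' @return Data frame with `n` rows and columns `r_max`, `T`, `G_f`, `G_i`,
#'   `G_fi`, `psi`.
#' @export
sample_parameter_set <- function(est, n = 1, seed = NULL,
                                 max_rejections = 1e5) {
  stopifnot(inherits(est, "species_estimates"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  eps <- 1e-6
  T_ <- .redraw(.draw(est$T, n), function(x) x <= eps,
                function(k) stats::rnorm(k, est$T$mean, est$T$se),
                max_rejections, "T")
  G_f <- .redraw(.draw(est$G_f, n), function(x) x <= eps,
                 function(k) stats::rnorm(k, est$G_f$mean, est$G_f$se),
                 max_rejections, "G_f")
  G_i <- .redraw(.draw(est$G_i, n), function(x) x <= eps,
                 function(k) stats::rnorm(k, est$G_i$mean, est$G_i$se),
                 max_rejections, "G_i")
  G_fi <- .draw(est$G_fi, n)
  tries <- 0L
  idx <- which(abs(G_fi) > sqrt(G_f * G_i))
  while (length(idx) > 0) {
    tries <- tries + 1L
    if (tries > max_rejections)
      stop(sprintf(
        "more than %g consecutive rejected draws for G_fi: degenerate estimate set",
        max_rejections), call. = FALSE)
    if (est$G_fi$se > 0) {
      G_fi[idx] <- stats::rnorm(length(idx), est$G_fi$mean, est$G_fi$se)
    } else {
      # the covariance is published without an SE and cannot move: enforce
      # admissibility by resampling the variance pair instead
      G_f[idx] <- .redraw(stats::rnorm(length(idx), est$G_f$mean, est$G_f$se),
                          function(x) x <= eps,
                          function(k) stats::rnorm(k, est$G_f$mean,
                                                   est$G_f$se),
                          max_rejections, "G_f")
      G_i[idx] <- .redraw(stats::rnorm(length(idx), est$G_i$mean, est$G_i$se),
                          function(x) x <= eps,
                          function(k) stats::rnorm(k, est$G_i$mean,
                                                   est$G_i$se),
                          max_rejections, "G_i")
    }
    idx <- idx[abs(G_fi[idx]) > sqrt(G_f[idx] * G_i[idx])]
  }
  data.frame(r_max = rep(est$r_max, n), T = T_, G_f = G_f, G_i = G_i,
             G_fi = G_fi, psi = G_fi / G_i)
}

#' Scenario grid for critical-rate evaluation
#'
#' Defines the cells over which critical rates are evaluated: levels of the
#' cross-sex genetic correlation (imposed per scenario, not sampled) crossed
#' with offsets of the male optimum's environmental sensitivity relative to
#' the female's, `offset = B_m - B_f`.  Positive offsets make the male
#' optimum less sensitive than the optimum lay-date (with `B_f < 0`), and
#' vice versa.
#'
#' @param rho_levels Correlation levels, each in `[-1, 1]`.
#' @param sensitivity_offsets `B_m - B_f` values (days/deg C).  Default
#'   `seq(-5, 5, by = 0.1)`.
#' @param B_f Sensitivity of the optimum lay-date (days/deg C); default -5.
#' @param gamma_f Stabilizing-selection curvature (1/days^2); default 0.005.
#' @return An object of class `"scenario_grid"`.
#' @export
scenario_grid <- function(rho_levels = 0,
                          sensitivity_offsets = seq(-5, 5, by = 0.1),
                          B_f = -5, gamma_f = 0.005) {
  if (any(abs(rho_levels) > 1))
    stop("all `rho_levels` must lie in [-1, 1]", call. = FALSE)
  .check_num(B_f, "B_f")
  .check_num(gamma_f, "gamma_f", positive = TRUE)
  if (length(sensitivity_offsets) < 1)
    stop("`sensitivity_offsets` must be non-empty", call. = FALSE)
  structure(list(rho_levels = sort(rho_levels),
                 sensitivity_offsets = sort(sensitivity_offsets),
                 B_f = B_f, gamma_f = gamma_f),
            class = "scenario_grid")
}

# G_m under the two identification conventions for the male-trait variance.
# "Gi": G_m equals the printed indirect variance (the back-calculation
# psi = G_fi / G_i closes under this convention).  "Gi_over_psi2": the
# indirect variance is psi^2 * G_m, so G_m = G_i / psi^2 (requires psi != 0).
.male_variance <- function(G_i, psi, convention = c("Gi", "Gi_over_psi2")) {
  convention <- match.arg(convention)
  if (convention == "Gi") return(G_i)
  if (any(psi == 0))
    stop("convention \"Gi_over_psi2\" requires psi != 0", call. = FALSE)
  G_i / psi^2
}

#' Monte Carlo density of the critical rate over a scenario grid
#'
#' For each sampled parameter set and each `(rho, offset)` cell, evaluates
#' the full-model critical rate with the male-trait variance identified with
#' the indirect genetic variance (`G_m := G_i`; see `gm_convention`),
#' `xi = rho * sqrt(G_f / G_m)` recomputed per draw, and
#' `B_m = B_f + offset`.  Non-finite critical rates (vanishing tracking
#' denominator) are retained in the table as `Inf` and counted in the
#' `n_nonfinite` attribute, never dropped silently.
#'
#' @param est A [species_estimates()].
#' @param grid A [scenario_grid()].
#' @param n_samples Number of Monte Carlo draws (default 50000).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   tables.
#' @param gm_convention Identification of the male-trait variance: `"Gi"`
#'   (default) or `"Gi_over_psi2"`.
#' @return Data frame with columns `species`, `rho`, `offset`, `sample`,
#'   `eta_c` (deg C/year), ordered by `(rho, offset, sample)` ascending, with
#'   attribute `n_nonfinite`.
#' @export
eta_c_density <- function(est, grid, n_samples = 50000, seed = NULL,
                          gm_convention = c("Gi", "Gi_over_psi2")) {
  stopifnot(inherits(est, "species_estimates"),
            inherits(grid, "scenario_grid"), n_samples >= 1)
  gm_convention <- match.arg(gm_convention)
  draws <- sample_parameter_set(est, n = n_samples, seed = seed)
  G_m <- .male_variance(draws$G_i, draws$psi, gm_convention)

  cells <- expand.grid(offset = grid$sensitivity_offsets,
                       rho = grid$rho_levels,
                       KEEP.OUT.ATTRS = FALSE)[, c("rho", "offset")]
  n_cells <- nrow(cells)
  rho <- rep(cells$rho, each = n_samples)
  offset <- rep(cells$offset, each = n_samples)
  r_max <- rep.int(draws$r_max, n_cells)
  T_ <- rep.int(draws$T, n_cells)
  G_f <- rep.int(draws$G_f, n_cells)
  G_m_rep <- rep.int(G_m, n_cells)
  psi <- rep.int(draws$psi, n_cells)

  xi <- rho * sqrt(G_f / G_m_rep)
  B_m <- grid$B_f + offset
  denom <- grid$B_f - (psi + xi) * B_m
  eta_c <- .eta_c_value(r_max, T_, grid$gamma_f, G_f, rho^2, denom)

  out <- data.frame(species = est$name, rho = rho, offset = offset,
                    sample = rep.int(seq_len(n_samples), n_cells),
                    eta_c = eta_c)
  attr(out, "n_nonfinite") <- sum(!is.finite(eta_c))
  out
}

#' Sensitivity offset of the male optimum that maximizes the critical rate
#'
#' The critical rate is maximized where the tracking denominator
#' `B_f - (psi + xi) B_m` vanishes; solving for `B_m` and expressing the
#' answer relative to `B_f` gives `offset = B_f / (psi + xi) - B_f`.
#' Evaluated at the species' point estimates with `psi = G_fi / G_i`.
#'
#' @param est A [species_estimates()].
#' @param rho Imposed cross-sex genetic correlation (default 0).
#' @param B_f Sensitivity of the optimum lay-date (days/deg C); default -5.
#' @param gm_convention Identification of the male-trait variance, as in
#'   [eta_c_density()].
#' @return The offset `B_m - B_f` in days/deg C, with attribute `finite`;
#'   `Inf` (flagged `finite = FALSE`) when `psi + xi = 0` and no finite male
#'   sensitivity maximizes the rate.
#' @export
optimal_offset <- function(est, rho = 0, B_f = -5,
                           gm_convention = c("Gi", "Gi_over_psi2")) {
  stopifnot(inherits(est, "species_estimates"))
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  .check_num(B_f, "B_f")
  psi <- est$G_fi$mean / est$G_i$mean
  G_m <- .male_variance(est$G_i$mean, psi, match.arg(gm_convention))
  xi <- rho * sqrt(est$G_f$mean / G_m)
  s <- psi + xi
  if (s == 0) {
    warning("psi + xi = 0: no finite male sensitivity maximizes the ",
            "critical rate", call. = FALSE)
    return(structure(Inf, finite = FALSE))
  }
  structure(B_f / s - B_f, finite = TRUE)
}
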
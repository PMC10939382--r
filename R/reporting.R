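# Tabular outputs behind the figures: critical-rate curves over the social
# plasticity slope (with optimum and adaptive-range annotations) and
# cross-product scenario grids, plus CSV round-trip helpers.

#' Critical rate as a function of social plasticity
#'
#' Evaluates the full-model critical rate pointwise over a grid of social
#' plasticity values at fixed genetic and demographic parameters, and
#' annotates the curve with the optimal plasticity ([psi_optimal()]), the
#' endpoints of the range over which male effects raise the critical rate
#' ([psi_adaptive_range()]), and the reference (no-male-effects) critical
#' rate that the curve is compared against.  On the open interval between
#' the endpoints the curve lies above the reference value; outside it, below
#' (the point at the optimum is non-finite).
#'
#' @param dem A [demography()].
#' @param gamma_f Stabilizing-selection curvature on lay-date (1/days^2).
#' @param G_f,G_m Additive genetic variances (days^2).
#' @param rho Cross-sex genetic correlation, `|rho| < 1`.
#' @param B_f,B_m Environmental sensitivities of the optima (days/deg C).
#' @param psi_grid Ascending, non-empty grid of plasticity values.
#' @return An object of class `"psi_curve"`: list with `table` (data frame
#'   `psi`, `eta_c`), `psi_opt`, `range_endpoints`, `reference_eta_c`, and
#'   the evaluation parameters in `params`.
#' @examples
#' psi_curve(demography(0.5, 2), 0.005, G_f = 6, G_m = 2, rho = 0,
#'           B_f = -5, B_m = -5, psi_grid = seq(-1, 3, by = 0.5))
#' @export
psi_curve <- function(dem, gamma_f, G_f, G_m, rho, B_f, B_m, psi_grid) {
  stopifnot(inherits(dem, "demography"))
  .check_num(gamma_f, "gamma_f", positive = TRUE)
  .check_num(G_f, "G_f", positive = TRUE)
  .check_num(G_m, "G_m", positive = TRUE)
  .check_num(rho, "rho"); .check_num(B_f, "B_f"); .check_num(B_m, "B_m")
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  if (length(psi_grid) < 1 || is.unsorted(psi_grid, strictly = TRUE))
    stop("`psi_grid` must be non-empty and strictly ascending", call. = FALSE)

  xi <- cross_sex_regression(rho, G_f, G_m)
  eta_c <- .eta_c_value(dem$r_max, dem$T, gamma_f, G_f, rho^2,
                        denom = B_f - (psi_grid + xi) * B_m)
  ref <- eta_critical_reference(dem, gamma_f, G_f, B_f)$value
  structure(list(
    table = data.frame(psi = psi_grid, eta_c = eta_c),
    psi_opt = psi_optimal(B_f, B_m, xi),
    range_endpoints = psi_adaptive_range(B_f, B_m, rho, xi),
    reference_eta_c = ref,
    params = list(r_max = dem$r_max, T = dem$T, gamma_f = gamma_f,
                  G_f = G_f, G_m = G_m, rho = rho, B_f = B_f, B_m = B_m)),
    class = "psi_curve")
}

#' @export
print.psi_curve <- function(x, ...) {
  cat(sprintf(
    "psi-curve over [%g, %g] (%d points): reference eta_c = %.4g deg C/yr\n",
    min(x$table$psi), max(x$table$psi), nrow(x$table), x$reference_eta_c))
  cat(sprintf("  psi_opt = %.4g; male effects raise eta_c on (%.4g, %.4g)\n",
              x$psi_opt, x$range_endpoints[["lower"]],
              x$range_endpoints[["upper"]]))
  invisible(x)
}

#' Cross-product evaluation of the critical rate over scenario grids
#'
#' Evaluates the full-model critical rate on the cross product of correlation
#' levels, sensitivity offsets (`B_m - B_f`), and social plasticity values,
#' at fixed variances and demography.  Rows are ordered by `(rho, offset,
#' psi)` ascending; non-finite rates appear as `Inf`.
#'
#' @inheritParams psi_curve
#' @param psi_values Plasticity values to evaluate.
#' @param grid A [scenario_grid()] supplying `rho_levels`,
#'   `sensitivity_offsets`, `B_f`, and `gamma_f`.
#' @return Data frame with columns `rho`, `offset`, `psi`, `eta_c`.
#' @export
grid_evaluate <- function(dem, G_f, G_m, psi_values, grid) {
  stopifnot(inherits(dem, "demography"), inherits(grid, "scenario_grid"))
  .check_num(G_f, "G_f", positive = TRUE)
  .check_num(G_m, "G_m", positive = TRUE)
  if (length(psi_values) < 1) stop("`psi_values` must be non-empty",
                                   call. = FALSE)
  cells <- expand.grid(psi = sort(psi_values),
                       offset = grid$sensitivity_offsets,
                       rho = grid$rho_levels,
                       KEEP.OUT.ATTRS = FALSE)[, c("rho", "offset", "psi")]
  xi <- cross_sex_regression(cells$rho, G_f, G_m)
  B_m <- grid$B_f + cells$offset
  eta_c <- .eta_c_value(dem$r_max, dem$T, grid$gamma_f, G_f, cells$rho^2,
                        denom = grid$B_f - (cells$psi + xi) * B_m)
  cells$eta_c <- eta_c
  rownames(cells) <- NULL
  cells
}

#' Write a table to CSV with a provenance header
#'
#' Writes `# key: value` comment lines followed by the table.  Numeric values
#' are serialized at full double precision so the table round-trips
#' losslessly through [read_rescue_csv()]; non-finite critical rates are
#' written as the explicit sentinel `inf` (distinguishing unbounded values
#' from missing ones).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named list written as header comments.
#' @return `path`, invisibly.
#' @export
write_rescue_csv <- function(df, path, meta = list()) {
  stopifnot(is.data.frame(df))
  ser <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- formatC(col, digits = 17, format = "g")
      out[is.infinite(col) & col > 0] <- "inf"
      out[is.infinite(col) & col < 0] <- "-inf"
      trimws(out)
    } else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) ser <- matrix(ser, nrow = 1L,
                                    dimnames = list(NULL, names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
               con)
  writeLines(paste(names(df), collapse = ","), con)
  utils::write.table(ser, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_rescue_csv()]
#'
#' Restores `inf`/`-inf` sentinels to `Inf`/`-Inf` and returns the header
#' comments in the `meta` attribute.
#'
#' @param path CSV path.
#' @return Data frame with attribute `meta` (named character vector).
#' @export
read_rescue_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- character(0)
  if (length(hdr) > 0) {
    kv <- sub("^#\\s*", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- stats::setNames(vals, keys)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  for (j in seq_along(df)) {
    x <- df[[j]]
    y <- suppressWarnings(as.numeric(ifelse(x == "inf", "Inf",
                                            ifelse(x == "-inf", "-Inf", x))))
    if (!anyNA(y)) df[[j]] <- y
  }
  attr(df, "meta") <- meta
  df
}
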
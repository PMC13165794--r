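# Seat-mat module: 4x4 piezoresistive array geometry, calibration
# (conductance -> pressure, 6th-order polynomial), voltage -> force via the
# reference-resistor divider, force-weighted centre of pressure, and COP
# agreement metrics.

#' Seat-mat geometry
#'
#' The mat is a 300 x 350 mm sheet carrying a 4 x 4 array of piezoresistive
#' cells of 50 x 65 mm separated by 20 mm gaps. Cell centroids are therefore
#' at x in {-105, -35, +35, +105} mm (pitch 70 mm) and y in
#' {-127.5, -42.5, +42.5, +127.5} mm (pitch 85 mm), relative to the mat
#' centre; +x points right, +y forward. Sensors are numbered row-major from
#' the rear-left cell: sensor k sits at column `(k-1) %% 4` and row
#' `(k-1) %/% 4`.
#'
#' @return Object of class `mat_geometry` with `centroids` (16 x 2 matrix,
#'   mm), `cell_area_m2` (3.25e-3), `n_rows`, `n_cols`.
#' @export
mat_geometry <- function() {
  xc <- c(-105, -35, 35, 105)
  yc <- c(-127.5, -42.5, 42.5, 127.5)
  centroids <- cbind(
    x = rep(xc, times = 4),
    y = rep(yc, each = 4)
  )
  structure(
    list(centroids = centroids, cell_area_m2 = 0.050 * 0.065,
         n_rows = 4L, n_cols = 4L,
         col_x = xc, row_y = yc),
    class = "mat_geometry"
  )
}

#' Fit a sensor calibration curve (conductance to pressure)
#'
#' Each piezoresistive cell is calibrated by repeated loading/unloading
#' cycles between 200 Pa and 0.33 MPa; the per-cycle peak pressure and peak
#' conductance pairs are fitted with a 6th-order least-squares polynomial
#' mapping conductance to pressure. Conductance is scaled to [0, 1] before
#' fitting to keep the Vandermonde system well conditioned; the scale is
#' stored in the curve.
#'
#' @param pressure_pa Per-cycle peak pressures (Pa).
#' @param conductance_s Per-cycle peak conductances (S), same length.
#' @param degree Polynomial degree (default 6).
#' @return Object of class `calibration_curve` with `coef` (degree+1
#'   coefficients in increasing powers of scaled conductance), `g_scale`,
#'   `valid_range` (Pa) and `g_range` (S).
#' @export
fit_calibration <- function(pressure_pa, conductance_s, degree = 6L) {
  stopifnot(length(pressure_pa) == length(conductance_s))
  n <- length(pressure_pa)
  if (n < 8L) stop("underdetermined fit: need at least 8 calibration cycles")
  g_scale <- max(abs(conductance_s))
  if (!(g_scale > 0)) stop("all conductances are zero")
  u <- conductance_s / g_scale
  X <- outer(u, 0:degree, `^`)
  fit <- stats::lm.fit(X, pressure_pa)
  structure(
    list(coef = unname(fit$coefficients), g_scale = g_scale,
         valid_range = range(pressure_pa), g_range = range(conductance_s),
         degree = degree),
    class = "calibration_curve"
  )
}

#' Evaluate a calibration curve
#'
#' @param curve A `calibration_curve`.
#' @param conductance_s Conductances (S).
#' @return Pressures (Pa), not yet clipped to the valid range.
#' @export
predict_pressure <- function(curve, conductance_s) {
  u <- conductance_s / curve$g_scale
  drop(outer(u, 0:curve$degree, `^`) %*% curve$coef)
}

#' Convert divider voltages to cell forces
#'
#' Each cell's piezoresistive element is in series with a reference resistor
#' `r_ref` (70 ohm); the recorded voltage is the drop across the reference
#' resistor, so the sensor conductance is
#' `G = v / (r_ref * (v_supply - v))`. Pressure is the calibration
#' polynomial evaluated at `G`, clipped to the calibrated valid range, and
#' force is pressure times the nominal cell area.
#'
#' @param v Voltages (V); a vector (one sample, 16 cells) or matrix
#'   (samples x cells).
#' @param curves A single `calibration_curve` or a list of 16 curves
#'   (one per cell).
#' @param r_ref Reference resistance (ohm), default 70.
#' @param v_supply Supply voltage (V), default 3.3.
#' @param cell_area_m2 Nominal cell area (m^2), default 50 x 65 mm.
#' @return Forces in newtons, same shape as `v`.
#' @export
voltage_to_force <- function(v, curves, r_ref = 70, v_supply = 3.3,
                             cell_area_m2 = 0.050 * 0.065) {
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (any(vm < 0)) stop("negative voltages")
  if (any(vm >= v_supply)) stop("divider saturated: v >= v_supply")
  curve_list <- if (inherits(curves, "calibration_curve")) {
    rep(list(curves), ncol(vm))
  } else {
    curves
  }
  if (length(curve_list) != ncol(vm)) {
    stop("need one calibration curve per channel")
  }
  out <- matrix(NA_real_, nrow(vm), ncol(vm))
  for (j in seq_len(ncol(vm))) {
    g <- vm[, j] / (r_ref * (v_supply - vm[, j]))
    p <- predict_pressure(curve_list[[j]], g)
    rng <- curve_list[[j]]$valid_range
    p <- pmin(pmax(p, rng[1L]), rng[2L])
    out[, j] <- p * cell_area_m2
  }
  if (is.matrix(v)) out else drop(out)
}

#' Force-weighted centre of pressure
#'
#' The COP is the weighted average of the cell centroid coordinates, weighted
#' by the force on each cell: `copx = sum(F_i x_i) / sum(F_i)` and likewise
#' for y. Samples with zero total force have an undefined COP and are
#' returned as NA (flagged gaps, not errors).
#'
#' @param forces Forces in N; vector of 16 (one sample) or matrix
#'   (samples x 16). Must be non-negative.
#' @param geometry A [mat_geometry()].
#' @return Data.frame with `copx` (mm), `copy` (mm), `total` (N).
#' @examples
#' g <- mat_geometry()
#' f <- rep(1, 16)
#' cop(f, g)  # (0, 0), symmetric load
#' @export
cop <- function(forces, geometry = mat_geometry()) {
  fm <- if (is.matrix(forces)) forces else matrix(forces, nrow = 1L)
  if (ncol(fm) != nrow(geometry$centroids)) {
    stop("expected ", nrow(geometry$centroids), " force channels")
  }
  if (any(fm < 0)) stop("forces must be non-negative")
  tot <- rowSums(fm)
  cx <- drop(fm %*% geometry$centroids[, "x"]) / tot
  cy <- drop(fm %*% geometry$centroids[, "y"]) / tot
  cx[tot == 0] <- NA_real_
  cy[tot == 0] <- NA_real_
  data.frame(copx = cx, copy = cy, total = tot)
}

#' Agreement metrics between two COP series
#'
#' Quantifies agreement between one COP series and a reference (e.g., seat
#' mat vs force plate) per axis: ordinary least-squares slope and intercept
#' of `a` on `b` (ideally 1 and 0), Pearson R^2 and Spearman rank R^2.
#'
#' @param a,b Numeric vectors (same axis, time-aligned, equal length).
#' @return List with `slope`, `intercept`, `pearson_r2`, `spearman_r2`, `n`.
#' @export
cop_agreement <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 10L) stop("need at least 10 paired samples")
  slope <- stats::cov(a, b) / stats::var(b)
  intercept <- mean(a) - slope * mean(b)
  list(slope = slope, intercept = intercept,
       pearson_r2 = stats::cor(a, b)^2,
       spearman_r2 = stats::cor(a, b, method = "spearman")^2,
       n = length(a))
}

#' COP series from a seat-mat voltage recording
#'
#' Runs [voltage_to_force()] and [cop()] over a mat recording and flags
#' low-load samples (standing phases, strikes) as gaps.
#'
#' @param mat Data.frame with timestamp column (any name) and channels
#'   `v01`..`v16`.
#' @param curves List of 16 `calibration_curve`s (or one shared curve).
#' @param t_master Optional replacement timestamps (e.g., after clock
#'   mapping); defaults to the first column of `mat`.
#' @param min_force Total force (N) below which the sample is flagged as a
#'   gap (default 50).
#' @param ... Passed to [voltage_to_force()].
#' @return Data.frame of class `cop_series` with `t`, `copx`, `copy`,
#'   `total`; gap samples carry NA COP.
#' @export
cop_series <- function(mat, curves, t_master = NULL, min_force = 50, ...) {
  vcols <- grep("^v[0-9]+$", names(mat), value = TRUE)
  stopifnot(length(vcols) == 16L)
  vm <- as.matrix(mat[, vcols])
  f <- voltage_to_force(vm, curves, ...)
  cc <- cop(f, mat_geometry())
  low <- cc$total < min_force
  cc$copx[low] <- NA_real_
  cc$copy[low] <- NA_real_
  tt <- if (is.null(t_master)) mat[[1L]] else t_master
  out <- data.frame(t = tt, copx = cc$copx, copy = cc$copy, total = cc$total)
  class(out) <- c("cop_series", "data.frame")
  out
}
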
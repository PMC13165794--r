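# GPS track handling: micro-degree fixes to local metres, path distance,
# crude speed, and time alignment to the IMU clock.

# printed conversion scale: 10 micro-degrees latitude = 1.11 m
UDEG10_TO_M_LAT <- 1.11

#' Convert a micro-degree GPS track to a local metric path
#'
#' Uses the flat-earth scale of the study region: 10 micro-degrees of
#' latitude correspond to 1.11 m in the north (y) direction and 10
#' micro-degrees of longitude to 1.11 m times the cosine of the latitude
#' (about 0.88 m at 37.8 degrees south). The longitude scale uses a single
#' fixed cosine at the track's mean latitude (error < 0.01% over an 800 m
#' course). The origin is placed at `ref_point`, by default the first fix.
#'
#' @param t Timestamps (s), strictly increasing (nominally 1 Hz).
#' @param lat_udeg,lon_udeg Latitude/longitude in micro-degrees.
#' @param ref_point Optional `c(lat_udeg, lon_udeg)` origin; defaults to the
#'   first fix.
#' @return A data.frame of class `local_path` with columns `t`, `x` (m east),
#'   `y` (m north), `dist` (cumulative path distance, m). The conversion
#'   parameters are attached as attributes `ref_point` and `cos_lat` so the
#'   transform is invertible.
#' @export
microdeg_to_metres <- function(t, lat_udeg, lon_udeg, ref_point = NULL) {
  n <- length(t)
  if (n == 0L) stop("empty track")
  stopifnot(length(lat_udeg) == n, length(lon_udeg) == n)
  if (is.null(ref_point)) ref_point <- c(lat_udeg[1L], lon_udeg[1L])
  cos_lat <- cos(mean(lat_udeg) * 1e-6 * pi / 180)
  y <- (lat_udeg - ref_point[1L]) / 10 * UDEG10_TO_M_LAT
  x <- (lon_udeg - ref_point[2L]) / 10 * UDEG10_TO_M_LAT * cos_lat
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  out <- data.frame(t = t, x = x, y = y, dist = c(0, cumsum(seg)))
  attr(out, "ref_point") <- ref_point
  attr(out, "cos_lat") <- cos_lat
  class(out) <- c("local_path", "data.frame")
  out
}

#' Convert a local metric path back to micro-degrees
#'
#' Inverse of [microdeg_to_metres()] given the same reference point and
#' cosine factor; used by the simulator and for round-trip checks.
#'
#' @param x,y Local coordinates (m east/north).
#' @param ref_point `c(lat_udeg, lon_udeg)` origin.
#' @param cos_lat Cosine of the reference latitude.
#' @return List with `lat_udeg`, `lon_udeg`.
#' @export
metres_to_microdeg <- function(x, y, ref_point, cos_lat) {
  list(lat_udeg = ref_point[1L] + y / UDEG10_TO_M_LAT * 10,
       lon_udeg = ref_point[2L] + x / (UDEG10_TO_M_LAT * cos_lat) * 10)
}

#' Total path distance of a local path
#'
#' Sum of Euclidean segment lengths of the x,y polyline.
#'
#' @param path A `local_path` (or any data.frame with `x`, `y`).
#' @return Total distance in metres.
#' @export
path_distance <- function(path) {
  if (nrow(path) < 2L) stop("need at least 2 points")
  sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
}

#' Crude speed from a 1 Hz GPS path
#'
#' Differentiates the x and y coordinates with respect to time and returns
#' the resultant magnitude. The first sample is 0 (no preceding fix).
#'
#' @param path A `local_path`.
#' @return Numeric vector of speeds (m/s), same length as the path.
#' @export
gps_speed <- function(path) {
  n <- nrow(path)
  if (n < 2L) return(rep(0, n))
  dt <- diff(path$t)
  sp <- sqrt(diff(path$x)^2 + diff(path$y)^2) / dt
  c(0, sp)
}

#' Align a GPS speed series to an IMU speed series
#'
#' The GPS clock is aligned to the IMU clock using the initial speed increase
#' from standstill and the final decrease to standstill: the IMU speed is
#' averaged to 1 Hz and the integer-second offset minimising the summed
#' squared difference over the two ramp windows is returned. The returned
#' offset `o` is the lag of the IMU series: `gps_v[i]` matches
#' `imu_v_1hz[i + o]`.
#'
#' @param gps_t,gps_v GPS timestamps (s, 1 Hz) and speed (m/s).
#' @param imu_t,imu_v IMU timestamps (s) and frame speed (m/s).
#' @param max_offset Largest offset magnitude searched, in seconds
#'   (default 30).
#' @param standstill Speed below which the chair counts as stationary
#'   (default 0.1 m/s).
#' @param ramp_s Half-width of the ramp windows (default 15 s).
#' @return Integer offset in seconds.
#' @export
align_gps_to_imu <- function(gps_t, gps_v, imu_t, imu_v, max_offset = 30L,
                             standstill = 0.1, ramp_s = 15L) {
  # average IMU speed into 1 s bins on the absolute time axis
  sec <- floor(imu_t)
  s0 <- min(sec)
  imu1 <- as.numeric(tapply(imu_v, factor(sec, levels = s0:max(sec)), mean))
  imu1[is.na(imu1)] <- 0
  gsec <- round(gps_t)
  # moment correction for folded GPS noise: at standstill the observed
  # squared speed is pure noise power, E[v_obs^2] = 2 sigma^2, which also
  # inflates the moving samples as v_obs^2 ~ v^2 + 2 sigma^2
  thr0 <- max(standstill, 0.5 * stats::quantile(gps_v, 0.9, names = FALSE))
  low <- gps_v[gps_v < thr0]
  if (length(low) > 5L) gps_v <- sqrt(pmax(gps_v^2 - mean(low^2), 0))
  # light moving-average smoothing of both 1 Hz series stabilises the match
  # against the remaining noise without biasing the offset
  ma5 <- function(v) {
    s <- as.numeric(stats::filter(v, rep(0.2, 5), sides = 2))
    ifelse(is.na(s), v, s)
  }
  imu1 <- ma5(imu1)
  gps_v <- ma5(gps_v)
  find_ramps <- function(v) {
    # adaptive threshold: folded GPS noise keeps the standstill speed
    # slightly above zero, so scale with the series amplitude and require
    # the crossing to be sustained for 5 s
    thr <- max(standstill, 0.5 * stats::quantile(v, 0.9, names = FALSE))
    sus <- as.numeric(stats::filter(v >= thr, rep(1, 5), sides = 1))
    onset <- which(sus == 5)
    if (length(onset) == 0L || !any(v < thr)) return(NULL)
    c(max(1L, onset[1L] - 4L), onset[length(onset)])
  }
  ramp_i <- find_ramps(imu1)
  ramp_g <- find_ramps(gps_v)
  if (is.null(ramp_i) || is.null(ramp_g)) stop("no standstill ramps")
  win <- sort(unique(c(
    pmax(1L, ramp_g[1L] - ramp_s):(ramp_g[1L] + ramp_s),
    pmax(1L, ramp_g[2L] - ramp_s):(ramp_g[2L] + ramp_s)
  )))
  win <- win[win >= 1L & win <= length(gps_v)]
  offs <- seq.int(-max_offset, max_offset)
  # windowed correlation rather than raw SSE: the magnitude of a noisy
  # velocity vector is biased high near standstill, which an additive-
  # invariant criterion tolerates
  score <- vapply(offs, function(o) {
    # the gps speed at second T is the backward difference over (T-1, T],
    # so it matches the imu bin covering [T-1+o, T+o)
    j <- gsec[win] + o - s0
    ok <- j >= 1L & j <= length(imu1)
    if (sum(ok) < 5L) return(-Inf)
    a <- gps_v[win[ok]]
    b <- imu1[j[ok]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1L))
  offs[which.max(score)]
}

#' Lateral deviation of a path from a reference at a given northing
#'
#' Finds where each path crosses the horizontal line `y = at_y` (linear
#' interpolation in y along the path, first crossing in travel order) and
#' returns the absolute difference of the interpolated x positions. Used to
#' quantify GPS multipath excursions against the cohort-average path.
#'
#' @param path,reference `local_path` data.frames.
#' @param at_y Northing (m) at which to compare.
#' @return Absolute lateral deviation in metres.
#' @export
deviation_from_reference <- function(path, reference, at_y) {
  x_at <- function(p) {
    y <- p$y
    x <- p$x
    s <- (y[-length(y)] - at_y) * (y[-1L] - at_y)
    hit <- which(s <= 0 & (y[-1L] != y[-length(y)]))
    if (length(hit) == 0L) {
      exact <- which(y == at_y)
      if (length(exact) > 0L) return(x[exact[1L]])
      stop(sprintf("path does not cross y = %g", at_y))
    }
    i <- hit[1L]
    w <- (at_y - y[i]) / (y[i + 1L] - y[i])
    x[i] + w * (x[i + 1L] - x[i])
  }
  abs(x_at(path) - x_at(reference))
}
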
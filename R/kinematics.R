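#' Frame kinematics from left/right wheel angular velocity
#'
#' Converts the two wheel-hub gyroscope streams into frame speed,
#' acceleration, yaw rate, turning radius and cumulative distance using the
#' cambered differential-drive model. With camber angle `theta` the effective
#' rolling radius is `r_eff = r * cos(theta)` and the ground-contact track
#' width is `w_g = w + 2 r * sin(theta)` (cambered wheels contact the ground
#' wider apart than the hubs). With wheel rates in rad/s:
#' \deqn{v = r_{eff} (\omega_L + \omega_R) / 2}
#' \deqn{\dot\psi = r_{eff} (\omega_R - \omega_L) / w_g}
#' Positive yaw rate is counter-clockwise seen from above. The turning radius
#' `v / |yaw|` is reported only where `|yaw| >= yaw_threshold` (NA on
#' straights to avoid division blow-up). Acceleration is the central
#' difference of a moving-average-smoothed copy of `v` (the reported `v`
#' itself is not smoothed); distance is the trapezoidal integral of `v`.
#'
#' @param t Timestamps (s), strictly increasing; shared by both streams.
#' @param omega_left_dps,omega_right_dps Wheel angular velocities in degrees
#'   per second (forward motion positive for both wheels).
#' @param geometry A [wheelchair_geometry()].
#' @param smooth_s Moving-average window (s) applied to `v` before
#'   differentiating for acceleration (default 0.5).
#' @param yaw_threshold Yaw rate magnitude (rad/s) below which the turning
#'   radius is undefined (default 1e-3).
#' @param omega_range Gyroscope full-scale range in degrees/s (default 2000);
#'   values beyond it are clipped with a warning.
#' @return A data.frame of class `frame_kinematics` with columns
#'   `t`, `v`, `a`, `yaw_rate`, `turn_radius`, `dist`.
#' @examples
#' g <- wheelchair_geometry()
#' k <- frame_kinematics(seq(0, 1, 0.01), rep(100, 101), rep(100, 101), g)
#' k$v[1]  # 0.305 * cos(3.2 deg) * 100 * pi/180 = 0.5315 m/s
#' @export
frame_kinematics <- function(t, omega_left_dps, omega_right_dps, geometry,
                             smooth_s = 0.5, yaw_threshold = 1e-3,
                             omega_range = 2000) {
  stopifnot(inherits(geometry, "wheelchair_geometry"))
  n <- length(t)
  if (length(omega_left_dps) != n || length(omega_right_dps) != n) {
    stop("mismatched timestamps: gyro streams must share the time base")
  }
  if (n < 2L) stop("need at least 2 samples")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  clip <- function(w) {
    if (any(abs(w) > omega_range)) {
      warning(sprintf("angular velocity beyond +/-%g deg/s clipped", omega_range))
      w <- pmin(pmax(w, -omega_range), omega_range)
    }
    w
  }
  wl <- clip(omega_left_dps) * pi / 180
  wr <- clip(omega_right_dps) * pi / 180
  v <- geometry$r_eff * (wl + wr) / 2
  yaw <- geometry$r_eff * (wr - wl) / geometry$w_ground
  radius <- ifelse(abs(yaw) >= yaw_threshold, abs(v) / abs(yaw), NA_real_)
  dt <- diff(t)
  # trapezoidal cumulative distance
  dist <- c(0, cumsum((v[-1L] + v[-n]) / 2 * dt))
  # acceleration: central difference of smoothed v
  med_dt <- stats::median(dt)
  k <- max(1L, round(smooth_s / med_dt))
  if (k %% 2L == 0L) k <- k + 1L
  vs <- if (k > 1L && n > k) {
    as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  } else {
    v
  }
  # fall back to raw v at the ends where the window is incomplete
  vs[is.na(vs)] <- v[is.na(vs)]
  a <- numeric(n)
  a[2:(n - 1L)] <- (vs[3:n] - vs[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  a[1L] <- (vs[2L] - vs[1L]) / (t[2L] - t[1L])
  a[n] <- (vs[n] - vs[n - 1L]) / (t[n] - t[n - 1L])
  out <- data.frame(t = t, v = v, a = a, yaw_rate = yaw,
                    turn_radius = radius, dist = dist)
  class(out) <- c("frame_kinematics", "data.frame")
  out
}

#' Distance calibration from a reference roll-out
#'
#' The gyroscopes are calibrated by repeatedly rolling the chair over a known
#' reference distance; the integrated distance slightly overestimates the
#' true one (the study's roll-out over 300 m overestimated by 0.4 m, 0.133%),
#' and the instantaneous velocity is overestimated by the same percentage.
#'
#' @param computed Integrated (computed) distance in metres.
#' @param reference True reference distance in metres.
#' @return List of class `distance_calibration` with `correction_factor`
#'   (`reference / computed`), `overestimate_percent`
#'   (`100 * (computed - reference) / reference`), and the two inputs.
#' @examples
#' calibrate_distance(300.4, 300)$overestimate_percent  # 0.1333
#' @export
calibrate_distance <- function(computed, reference) {
  if (!(computed > 0) || !(reference > 0)) {
    stop("computed and reference distances must be positive")
  }
  structure(
    list(correction_factor = reference / computed,
         overestimate_percent = 100 * (computed - reference) / reference,
         computed_distance = computed, reference_distance = reference),
    class = "distance_calibration"
  )
}

#' Apply a distance calibration to frame kinematics
#'
#' Scales `v`, `a` and `dist` by the correction factor; yaw rate and turning
#' geometry are unchanged (the calibration corrects rolling radius, which
#' cancels in the yaw ratio only to first order, but the study applies it to
#' the translational quantities).
#'
#' @param kin A `frame_kinematics` data.frame.
#' @param cal A `distance_calibration` (or a bare numeric factor).
#' @return The rescaled `frame_kinematics`.
#' @export
apply_correction <- function(kin, cal) {
  f <- if (inherits(cal, "distance_calibration")) cal$correction_factor else as.numeric(cal)
  if (!(f > 0)) stop("correction factor must be positive")
  kin$v <- kin$v * f
  kin$a <- kin$a * f
  kin$dist <- kin$dist * f
  kin
}
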
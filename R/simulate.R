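# Synthetic-run generator: complete sensor recordings with known ground
# truth, possessing the statistical structure of the 13-section urban course
# (per-section speed/COP means and SDs, route-compliance mixing, clock
# distortion, trigger pentads, piezoresistive sensor response, GPS noise).

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 65537) %% 2147483629)
}

#' Participant profile for the simulator
#'
#' Encodes where a participant sits on the route-driven vs individualistic
#' spectrum: `compliance_lambda` is the weight of the course-driven speed/COP
#' component (1 = fully route-driven, 0 = fully individual), `speed_scale`
#' a multiplicative speed factor, and `cop_offset_x` a constant lateral COP
#' shift for off-centre sitters (mm, negative = left).
#'
#' @param participant_id Identifier string.
#' @param compliance_lambda Course weight in `[0, 1]`.
#' @param speed_scale Positive speed multiplier.
#' @param cop_offset_x Lateral COP offset (mm).
#' @param noise_seed Integer stream id separating participants' noise.
#' @return Object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id = "P1", compliance_lambda = 0.5,
                                speed_scale = 1, cop_offset_x = 0,
                                noise_seed = 1L) {
  if (!(compliance_lambda >= 0 && compliance_lambda <= 1)) {
    stop("compliance_lambda must be in [0, 1]")
  }
  if (!(speed_scale > 0)) stop("speed_scale must be > 0")
  structure(
    list(participant_id = participant_id,
         compliance_lambda = compliance_lambda,
         speed_scale = speed_scale, cop_offset_x = cop_offset_x,
         noise_seed = as.integer(noise_seed)),
    class = "participant_profile"
  )
}

#' Default seven-participant cohort
#'
#' Compliance weights span the route-driven vs individualistic spectrum
#' observed in the study (one strongly individual participant, one strongly
#' route-driven); speed scales reproduce the spread of the participants'
#' median speeds around the cohort mean; one participant sits off-centre
#' (the largest leftward offset representable inside the sensor-centroid
#' hull of the 4x4 array).
#'
#' @return Named list of seven [participant_profile()]s.
#' @export
make_cohort_profiles <- function() {
  lambda <- c(0.2, 0.5, 0.5, 0.5, 0.9, 0.8, 0.5)
  scale <- c(1.01, 1.16, 0.90, 0.90, 0.90, 0.83, 1.01)
  offx <- c(0, -80, 0, 0, 0, 0, 0)
  out <- lapply(1:7, function(i) {
    participant_profile(paste0("P", i), lambda[i], scale[i], offx[i],
                        noise_seed = i)
  })
  names(out) <- paste0("P", 1:7)
  out
}

#' Clock distortion applied to the seat-mat (slave) clock
#'
#' The mat's real-time clock runs at a different rate than the IMU clock:
#' master time relates to slave time as `t_m = skew * t_s + offset`.
#' `jitter_sd` adds Gaussian timing noise to the trigger strikes as recorded
#' on the slave side (the strikes themselves, not the sample clock).
#'
#' @param skew Slave-to-master rate ratio (> 0), default 1.
#' @param offset Offset in seconds, default 0.
#' @param jitter_sd Trigger timing jitter SD (s), default 0.
#' @return Object of class `clock_distortion`.
#' @export
clock_distortion <- function(skew = 1, offset = 0, jitter_sd = 0) {
  if (!(skew > 0)) stop("skew must be > 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(skew = skew, offset = offset, jitter_sd = jitter_sd),
            class = "clock_distortion")
}

#' Simulator options
#'
#' Bundles the tunable constants of the generator. Defaults are the study
#' conditions; see the methods vignette for the rationale of each value.
#'
#' @param dt Sample interval (s), 100 Hz.
#' @param standstill_s Standing phase before/after the run (s).
#' @param noise_scale Master multiplier for all stochastic components
#'   (0 = noise-free).
#' @param share_frac Fraction of within-section *variance* shared across
#'   participants via the course micro-profile (default 0.95).
#' @param phi_time AR(1) coefficient of the individual processes at 100 Hz.
#' @param phi_dist AR(1) coefficient of the distance-domain fields at
#'   `field_res` spacing.
#' @param field_res Distance resolution of the micro-profile fields (m).
#' @param xi_sd_v,xi_sd_cop Stationary SDs of the individual AR(1) processes
#'   (m/s, mm).
#' @param course_seed Seed of the shared course micro-profile (same for all
#'   participants of a cohort).
#' @param mat_seed Seed of the per-cell sensor response laws; fixed by
#'   default because the response spread belongs to the physical mat, not
#'   to a run.
#' @param v_floor Minimum ground-truth speed while moving (m/s).
#' @param turn_duration Duration of a 90-degree yaw pulse (s).
#' @param total_force Seated load on the mat (N).
#' @param base_force Preload per cell (N) keeping unloaded cells inside the
#'   calibrated range.
#' @param v_supply,r_ref Divider supply (V) and reference resistance (ohm).
#' @param voltage_noise_sd Electronic noise on mat voltages (V).
#' @param gps_sigma GPS noise SD per axis (m).
#' @param gps_noise_phi 1 Hz autocorrelation of the GPS position noise
#'   (receiver filtering makes consecutive fix errors strongly correlated).
#' @param gps_multipath Either `NULL` or
#'   `list(offset = c(dx, dy), window = c(d1, d2))`: constant position offset
#'   applied while the true distance is inside the window (multipath
#'   emulation).
#' @param ref_lat_udeg,ref_lon_udeg GPS reference point (micro-degrees;
#'   default Melbourne suburb).
#' @param corner_radius Turn arc radius of the true path (m).
#' @param trigger_spacing Spacing of strikes within a pentad (s).
#' @param max_duration Safety cap on simulated motion time (s).
#' @return List of class `sim_options`.
#' @export
sim_options <- function(dt = 0.01, standstill_s = 12, noise_scale = 1,
                        share_frac = 0.95, phi_time = 0.98, phi_dist = 0.3,
                        field_res = 0.25, xi_sd_v = 0.31, xi_sd_cop = 6,
                        course_seed = 20260424, mat_seed = 7041,
                        v_floor = 0.1,
                        turn_duration = 2.5, total_force = 600,
                        base_force = 1, v_supply = 3.3, r_ref = 70,
                        voltage_noise_sd = 5e-4, gps_sigma = 2,
                        gps_noise_phi = 0.99, gps_multipath = NULL,
                        ref_lat_udeg = -37822000, ref_lon_udeg = 145035000,
                        corner_radius = 1.5, trigger_spacing = 0.5,
                        max_duration = 3600) {
  structure(as.list(environment()), class = "sim_options")
}

# standardised AR(1) series (stationary variance 1, stationary start)
ar1_series <- function(n, phi, seed) {
  set.seed(seed)
  z0 <- stats::rnorm(1L)
  if (n == 1L) return(z0)
  innov <- stats::rnorm(n - 1L, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(c(z0, innov), phi, method = "recursive"))
}

# per-sensor quadratic conductance->pressure laws:
# P = p1 * G + p2 * G^2 (within the 6th-order calibration model class)
sensor_laws <- function(seed, n = 16L) {
  set.seed(derive_seed(seed, 901L))
  p_max <- 0.33e6
  g_max <- 0.005
  spread <- 1 + stats::runif(n, -0.05, 0.05)
  lapply(seq_len(n), function(i) {
    p1 <- 0.8 * p_max / g_max * spread[i]
    p2 <- 0.2 * p_max / g_max^2
    list(p1 = p1, p2 = p2, p_range = c(200, p_max))
  })
}

# inverse of the quadratic sensor law: conductance carrying pressure P
law_conductance <- function(law, pressure_pa) {
  p <- pmax(pressure_pa, 0)
  (-law$p1 + sqrt(law$p1^2 + 4 * law$p2 * p)) / (2 * law$p2)
}

#' Simulate bench calibration cycles for one sensor
#'
#' Emulates the loading/unloading bench calibration: `n_cycles` peak
#' pressures spread between 200 Pa and 0.33 MPa with the matching peak
#' conductances from the cell's response law, optionally with relative
#' measurement noise.
#'
#' @param law One element of the run's `meta$sensor_laws`.
#' @param n_cycles Number of cycles (default 20).
#' @param seed RNG seed.
#' @param noise_frac Relative noise on the conductances (default 0).
#' @return Data.frame with `pressure_pa`, `conductance_s`.
#' @export
simulate_calibration_cycles <- function(law, n_cycles = 20L, seed = 1L,
                                        noise_frac = 0) {
  set.seed(seed)
  p <- exp(seq(log(law$p_range[1L]), log(law$p_range[2L]), length.out = n_cycles))
  g <- law_conductance(law, p)
  if (noise_frac > 0) g <- g * (1 + stats::rnorm(n_cycles, sd = noise_frac))
  data.frame(pressure_pa = p, conductance_s = g)
}

# heading profile of the true path: 90-degree arcs of radius R at each turn
# boundary, straight in between; parameterised by arc length so the path
# length equals the course length exactly
course_path_xy <- function(course, corner_radius = 1.5, res = 0.25,
                           heading0 = pi) {
  L <- course$total_length
  d <- seq(0, L, by = res)
  if (d[length(d)] < L) d <- c(d, L)
  h <- rep(heading0, length(d))
  turns <- course$sections[course$sections$turn_in != "none", ]
  a <- pi * corner_radius / 4  # half arc length of a 90-degree turn
  if (nrow(turns) > 0L) {
    for (k in seq_len(nrow(turns))) {
      D <- turns$start_distance[k]
      sgn <- if (turns$turn_in[k] == "right") -1 else 1
      frac <- pmin(pmax((d - (D - a)) / (2 * a), 0), 1)
      h <- h + sgn * (pi / 2) * frac
    }
  }
  dx <- cos(h)
  dy <- sin(h)
  n <- length(d)
  x <- c(0, cumsum((dx[-1L] + dx[-n]) / 2 * diff(d)))
  y <- c(0, cumsum((dy[-1L] + dy[-n]) / 2 * diff(d)))
  list(d = d, x = x, y = y)
}

#' Simulate a complete instrumented-wheelchair run
#'
#' Generates a full synthetic recording with known ground truth: wheel
#' gyroscope streams obtained by inverting the cambered differential-drive
#' model, a 16-channel seat-mat voltage recording on a distorted slave
#' clock, a 1 Hz micro-degree GPS track, trigger-spike pentads at start and
#' end, and the per-sample ground truth (speed, distance, COP, section).
#'
#' Ground-truth speed at distance `d` is
#' `speed_scale * (lambda * (mu_v(sec) + shared(d)) +
#' (1-lambda) * (v_bar + xi(t)) + eta(d))`, floored at `v_floor`, where
#' `shared` is the course micro-profile common to all participants (same
#' `course_seed`), `xi` the individual AR(1) process and `eta` the unshared
#' residual; `shared` and `eta` carry the per-section SDs of the course
#' table split `share_frac` / `1 - share_frac` by variance. COPx/COPy follow
#' the same structure around the per-section COP means. Mat cell forces are
#' allocated with a per-axis two-cell (bilinear) interpolation around the
#' planted COP plus a uniform preload, so the force-weighted centroid equals
#' the planted COP exactly.
#'
#' @param course A `course_definition`.
#' @param profile A [participant_profile()].
#' @param geometry A [wheelchair_geometry()].
#' @param distortion A [clock_distortion()].
#' @param seed Integer seed; all randomness derives from it and the
#'   profile's `noise_seed`.
#' @param opts A [sim_options()].
#' @param signals `"full"` for all sensor streams or `"truth"` for the
#'   ground-truth record only (fast path for statistical experiments).
#' @return Object of class `raw_run`: list with data.frames `gyro`
#'   (`t_s`, `omega_left_dps`, `omega_right_dps`, `accel_trigger`), `mat`
#'   (`t_slave_s`, `v01`..`v16`), `gps` (`t_s`, `lat_udeg`, `lon_udeg`),
#'   `truth` (`t_s`, `v_mps`, `dist_m`, `copx_mm`, `copy_mm`, `section`) and
#'   `meta`.
#' @export
simulate_run <- function(course, profile, geometry = wheelchair_geometry(),
                         distortion = clock_distortion(), seed = 1L,
                         opts = sim_options(), signals = c("full", "truth")) {
  signals <- match.arg(signals)
  stopifnot(inherits(course, "course_definition"),
            inherits(profile, "participant_profile"),
            inherits(distortion, "clock_distortion"))
  dt <- opts$dt
  L <- course$total_length
  sec_tab <- course$sections
  bnd <- course$boundaries
  lam <- profile$compliance_lambda
  oml <- 1 - lam
  scl <- profile$speed_scale
  nsc <- opts$noise_scale
  share_sd <- sqrt(opts$share_frac)
  unsh_sd <- sqrt(1 - opts$share_frac)
  v_bar <- sum(sec_tab$length * sec_tab$v_mean) / L
  x_bar <- sum(sec_tab$length * sec_tab$copx_mean) / L
  y_bar <- sum(sec_tab$length * sec_tab$copy_mean) / L

  # distance-domain fields (0.25 m resolution): shared course micro-profile
  # (one seed for the whole cohort) and per-participant unshared residuals
  n_field <- ceiling(L / opts$field_res) + 2L
  field <- function(s) {
    if (nsc == 0) rep(0, n_field) else ar1_series(n_field, opts$phi_dist, s)
  }
  zsh_v <- field(derive_seed(opts$course_seed, 11L))
  zsh_x <- field(derive_seed(opts$course_seed, 12L))
  zsh_y <- field(derive_seed(opts$course_seed, 13L))
  pseed <- derive_seed(seed, 1000L + profile$noise_seed)
  zun_v <- field(derive_seed(pseed, 21L))
  zun_x <- field(derive_seed(pseed, 22L))
  zun_y <- field(derive_seed(pseed, 23L))

  # individual AR(1) processes in time (grown on demand)
  n_guess <- ceiling(1.6 * L / (scl * max(opts$v_floor, 0.5 * v_bar)) / dt)
  xi_v <- if (nsc == 0 || oml == 0) rep(0, n_guess) else
    ar1_series(n_guess, opts$phi_time, derive_seed(pseed, 31L))

  # per-section coefficients of the speed model
  A <- scl * lam * sec_tab$v_mean
  B <- scl * lam * nsc * share_sd * sec_tab$v_sd
  C <- scl * oml * v_bar
  Dc <- scl * oml * nsc * opts$xi_sd_v
  E <- scl * nsc * unsh_sd * sec_tab$v_sd

  inv_res <- 1 / opts$field_res
  n_max <- ceiling(opts$max_duration / dt)
  v <- numeric(n_guess)
  d <- numeric(n_guess)
  sec <- integer(n_guess)
  s <- 1L
  di <- 0
  i <- 0L
  while (di < L && i < n_max) {
    i <- i + 1L
    if (i > length(v)) {  # extend buffers
      grow <- length(v)
      v <- c(v, numeric(grow))
      d <- c(d, numeric(grow))
      sec <- c(sec, integer(grow))
      xi_v <- c(xi_v, if (nsc == 0 || oml == 0) numeric(grow) else
        ar1_series(grow, opts$phi_time, derive_seed(pseed, 31L + i)))
    }
    while (s < course$n_sections && di >= bnd[s + 1L]) s <- s + 1L
    fi <- floor(di * inv_res) + 1L
    vi <- A[s] + B[s] * zsh_v[fi] + C + Dc * xi_v[i] + E[s] * zun_v[fi]
    if (vi < opts$v_floor) vi <- opts$v_floor
    v[i] <- vi
    di <- di + vi * dt
    d[i] <- di
    sec[i] <- s
  }
  n_mot <- i
  v <- v[seq_len(n_mot)]
  sec <- sec[seq_len(n_mot)]

  # standstill padding: standing phases before and after the run
  n_pad <- round(opts$standstill_s / dt)
  v_all <- c(numeric(n_pad), v, numeric(n_pad))
  n <- length(v_all)
  t <- (seq_len(n) - 1L) * dt
  # trapezoidal cumulative distance (identical scheme to the pipeline)
  dist_all <- c(0, cumsum((v_all[-1L] + v_all[-n]) / 2 * dt))
  sec_all <- c(rep(1L, n_pad), sec, rep(course$n_sections, n_pad))
  moving <- c(rep(FALSE, n_pad), rep(TRUE, n_mot), rep(FALSE, n_pad))

  # planted COP (defined while seated and moving; NA while standing)
  fi_all <- pmin(floor(pmin(dist_all, L - 1e-9) * inv_res) + 1L, n_field)
  xi_x <- if (nsc == 0 || oml == 0) numeric(n) else
    ar1_series(n, opts$phi_time, derive_seed(pseed, 32L))
  xi_y <- if (nsc == 0 || oml == 0) numeric(n) else
    ar1_series(n, opts$phi_time, derive_seed(pseed, 33L))
  plant_cop <- function(mu, sdv, zsh, zun, xbar, xi, offset) {
    offset + lam * (mu[sec_all] + nsc * share_sd * sdv[sec_all] * zsh[fi_all]) +
      oml * (xbar + nsc * opts$xi_sd_cop * xi) +
      nsc * unsh_sd * sdv[sec_all] * zun[fi_all]
  }
  copx <- plant_cop(sec_tab$copx_mean, sec_tab$copx_sd, zsh_x, zun_x,
                    x_bar, xi_x, profile$cop_offset_x)
  copy_ <- plant_cop(sec_tab$copy_mean, sec_tab$copy_sd, zsh_y, zun_y,
                     y_bar, xi_y, 0)
  # keep the planted COP strictly inside the sensor-centroid hull
  copx <- pmin(pmax(copx, -100), 100)
  copy_ <- pmin(pmax(copy_, -122), 122)
  copx[!moving] <- NA_real_
  copy_[!moving] <- NA_real_

  # yaw pulses: half-sine 90-degree turns centred on the turn boundaries
  yaw <- numeric(n)
  turns <- sec_tab[sec_tab$turn_in != "none", ]
  t_move0 <- n_pad * dt
  for (k in seq_len(nrow(turns))) {
    Dk <- turns$start_distance[k]
    if (Dk <= 0) next
    idx <- which(dist_all >= Dk)[1L]
    if (is.na(idx)) next
    tc <- t[idx]
    Tt <- opts$turn_duration
    Aamp <- pi^2 / (4 * Tt)
    sgn <- if (turns$turn_in[k] == "right") -1 else 1
    win <- which(t >= tc - Tt / 2 & t <= tc + Tt / 2)
    yaw[win] <- yaw[win] + sgn * Aamp * sin(pi * (t[win] - (tc - Tt / 2)) / Tt)
  }

  truth <- data.frame(t_s = t, v_mps = v_all, dist_m = dist_all,
                      copx_mm = copx, copy_mm = copy_, section = sec_all)
  section_means <- sec_tab[, c("index", "v_mean", "v_sd", "copx_mean",
                               "copx_sd", "copy_mean", "copy_sd")]
  meta <- list(profile = profile, distortion = distortion,
               geometry = geometry, course = course, opts = opts,
               seed = seed, section_means = section_means,
               n_motion = n_mot, t_motion = c(t_move0, t_move0 + n_mot * dt))

  if (signals == "truth") {
    return(structure(list(gyro = NULL, mat = NULL, gps = NULL,
                          truth = truth, meta = meta), class = "raw_run"))
  }

  ## --- gyroscope streams (inverse kinematic model) + trigger channel ---
  wl <- (v_all - yaw * geometry$w_ground / 2) / geometry$r_eff * 180 / pi
  wr <- (v_all + yaw * geometry$w_ground / 2) / geometry$r_eff * 180 / pi
  set.seed(derive_seed(pseed, 41L))
  accel <- stats::rnorm(n, sd = 0.02 * nsc)
  t_stop <- t[n_pad + n_mot]
  trig_master <- c(2 + opts$trigger_spacing * (0:4),
                   t_stop + 2 + opts$trigger_spacing * (0:4))
  amp_pattern <- rep(c(0.85, 0.95, 1.25, 1.0, 0.9), 2)
  amp_base <- 10 * max(stats::quantile(abs(accel), 0.99), 1)
  trig_idx <- pmin(pmax(round(trig_master / dt) + 1L, 1L), n)
  accel[trig_idx] <- accel[trig_idx] + amp_base * amp_pattern
  trig_master_actual <- t[trig_idx]
  gyro <- data.frame(t_s = t, omega_left_dps = wl, omega_right_dps = wr,
                     accel_trigger = accel)

  ## --- seat mat on the distorted slave clock ---
  t_s_end <- (t[n] - distortion$offset) / distortion$skew
  t_s_start <- (t[1L] - distortion$offset) / distortion$skew
  t_slave <- seq(ceiling(t_s_start / dt) * dt, t_s_end, by = dt)
  t_mat_master <- distortion$skew * t_slave + distortion$offset
  # planted COP and seating state at the mat's master times
  cx_m <- stats::approx(t, ifelse(moving, copx, 0), xout = t_mat_master, rule = 2)$y
  cy_m <- stats::approx(t, ifelse(moving, copy_, 0), xout = t_mat_master, rule = 2)$y
  seated <- stats::approx(t, as.numeric(moving), xout = t_mat_master, rule = 2)$y > 0.5
  geom_mat <- mat_geometry()
  laws <- sensor_laws(opts$mat_seed)
  forces <- matrix(0, length(t_slave), 16L)
  if (any(seated)) {
    f_rem <- opts$total_force - 16 * opts$base_force
    # bilinear two-cell-per-axis allocation hitting the planted COP exactly
    xt <- cx_m * opts$total_force / f_rem
    yt <- cy_m * opts$total_force / f_rem
    xt <- pmin(pmax(xt, geom_mat$col_x[1L] + 0.5), geom_mat$col_x[4L] - 0.5)
    yt <- pmin(pmax(yt, geom_mat$row_y[1L] + 0.5), geom_mat$row_y[4L] - 0.5)
    jc <- pmin(pmax(findInterval(xt, geom_mat$col_x), 1L), 3L)
    jr <- pmin(pmax(findInterval(yt, geom_mat$row_y), 1L), 3L)
    wxc <- (xt - geom_mat$col_x[jc]) / diff(geom_mat$col_x)[jc]
    wyr <- (yt - geom_mat$row_y[jr]) / diff(geom_mat$row_y)[jr]
    idx <- function(row, col) (row - 1L) * 4L + col
    sel <- which(seated)
    add <- function(row, col, w) {
      ii <- cbind(sel, idx(row, col)[sel])
      forces[ii] <<- forces[ii] + f_rem * w[sel]
    }
    add(jr, jc, (1 - wxc) * (1 - wyr))
    add(jr, jc + 1L, wxc * (1 - wyr))
    add(jr + 1L, jc, (1 - wxc) * wyr)
    add(jr + 1L, jc + 1L, wxc * wyr)
    forces[seated, ] <- forces[seated, ] + opts$base_force
  }
  # piezoresistive response + divider
  volts <- matrix(0, length(t_slave), 16L)
  area <- geom_mat$cell_area_m2
  for (j in 1:16) {
    g <- law_conductance(laws[[j]], forces[, j] / area)
    volts[, j] <- opts$v_supply * opts$r_ref * g / (1 + opts$r_ref * g)
  }
  if (nsc > 0 && opts$voltage_noise_sd > 0) {
    set.seed(derive_seed(pseed, 42L))
    volts <- volts + matrix(stats::rnorm(length(volts),
                                         sd = opts$voltage_noise_sd * nsc),
                            nrow(volts))
    volts <- pmax(volts, 0)
  }
  # trigger strikes on the mat (slave side, optional timing jitter)
  set.seed(derive_seed(pseed, 43L))
  jit <- if (distortion$jitter_sd > 0) {
    stats::rnorm(length(trig_master), sd = distortion$jitter_sd)
  } else {
    rep(0, length(trig_master))
  }
  trig_slave <- (trig_master_actual - distortion$offset) / distortion$skew + jit
  trig_sidx <- pmin(pmax(round((trig_slave - t_slave[1L]) / dt) + 1L, 1L),
                    length(t_slave))
  ch_p99 <- apply(abs(volts), 2, stats::quantile, probs = 0.99)
  spike_amp <- 10 * pmax(ch_p99, 0.05)
  for (k in seq_along(trig_sidx)) {
    volts[trig_sidx[k], ] <- volts[trig_sidx[k], ] + spike_amp * amp_pattern[k]
  }
  volts <- pmin(volts, 0.99 * opts$v_supply)
  mat <- data.frame(t_slave_s = t_slave, volts)
  names(mat) <- c("t_slave_s", sprintf("v%02d", 1:16))

  ## --- GPS track (1 Hz, micro-degrees) ---
  pathxy <- course_path_xy(course, opts$corner_radius)
  t_gps <- seq(0, floor(t[n]), by = 1)
  d_gps <- stats::approx(t, dist_all, xout = t_gps, rule = 2)$y
  px <- stats::approx(pathxy$d, pathxy$x, xout = pmin(d_gps, L), rule = 2)$y
  py <- stats::approx(pathxy$d, pathxy$y, xout = pmin(d_gps, L), rule = 2)$y
  if (!is.null(opts$gps_multipath)) {
    mp <- opts$gps_multipath
    inwin <- d_gps >= mp$window[1L] & d_gps <= mp$window[2L]
    px[inwin] <- px[inwin] + mp$offset[1L]
    py[inwin] <- py[inwin] + mp$offset[2L]
  }
  if (opts$gps_sigma > 0) {
    px <- px + opts$gps_sigma *
      ar1_series(length(px), opts$gps_noise_phi, derive_seed(pseed, 44L))
    py <- py + opts$gps_sigma *
      ar1_series(length(py), opts$gps_noise_phi, derive_seed(pseed, 45L))
  }
  cos_lat <- cos(opts$ref_lat_udeg * 1e-6 * pi / 180)
  ll <- metres_to_microdeg(px, py, c(opts$ref_lat_udeg, opts$ref_lon_udeg),
                           cos_lat)
  gps <- data.frame(t_s = t_gps, lat_udeg = ll$lat_udeg, lon_udeg = ll$lon_udeg)

  meta$sensor_laws <- laws
  meta$trigger_master <- trig_master_actual
  meta$trigger_slave <- t_slave[trig_sidx]
  # exact strike times on the slave clock before sampling quantisation
  # (the recorded mat spikes snap to the nearest 100 Hz slave sample)
  meta$trigger_slave_exact <- (trig_master_actual - distortion$offset) /
    distortion$skew + jit
  meta$gps_ref <- c(opts$ref_lat_udeg, opts$ref_lon_udeg)
  meta$path <- pathxy
  structure(list(gyro = gyro, mat = mat, gps = gps, truth = truth,
                 meta = meta), class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf("Synthetic run: %s, %.0f m in %.0f s (%d samples%s)\n",
              x$meta$profile$participant_id,
              max(x$truth$dist_m), max(x$truth$t_s), nrow(x$truth),
              if (is.null(x$gyro)) ", truth only" else ""))
  invisible(x)
}
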
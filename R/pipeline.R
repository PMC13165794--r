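# End-to-end orchestration: sync -> kinematics -> gps -> cop -> distance
# alignment -> per-run report; cohort-level effect networks and compliance.

#' Fit per-cell calibration curves for a simulated run
#'
#' Regenerates the bench calibration cycles from the run's sensor response
#' laws and fits the 6th-order conductance-to-pressure polynomial per cell.
#'
#' @param run A simulated `raw_run` (with `meta$sensor_laws`).
#' @param n_cycles Cycles per cell (default 20).
#' @param noise_frac Relative conductance noise in the bench data
#'   (default 0).
#' @param seed RNG seed for the bench noise.
#' @return List of 16 `calibration_curve`s.
#' @export
fit_run_calibration <- function(run, n_cycles = 20L, noise_frac = 0,
                                seed = 99L) {
  laws <- run$meta$sensor_laws
  if (is.null(laws)) stop("run carries no sensor laws (not a simulated full run)")
  fit_law_curves(laws, n_cycles, noise_frac, seed)
}

fit_law_curves <- function(laws, n_cycles = 20L, noise_frac = 0, seed = 99L) {
  lapply(seq_along(laws), function(j) {
    cyc <- simulate_calibration_cycles(laws[[j]], n_cycles,
                                       seed = derive_seed(seed, j),
                                       noise_frac = noise_frac)
    fit_calibration(cyc$pressure_pa, cyc$conductance_s)
  })
}

#' Bench calibration curves of the simulated mat
#'
#' The 16 cell response laws are a property of the physical mat (fixed by
#' `mat_seed` in [sim_options()]); this regenerates the bench cycles and
#' fits the calibration polynomial per cell without needing a simulated
#' run, e.g. when processing recordings read back from disk.
#'
#' @param opts A [sim_options()] (only `mat_seed` is used).
#' @param n_cycles,noise_frac,seed Bench-cycle settings as in
#'   [fit_run_calibration()].
#' @return List of 16 `calibration_curve`s.
#' @export
mat_calibration_curves <- function(opts = sim_options(), n_cycles = 20L,
                                   noise_frac = 0, seed = 99L) {
  fit_law_curves(sensor_laws(opts$mat_seed), n_cycles, noise_frac, seed)
}

#' Process one run through the full sensing pipeline
#'
#' Stages, in order: trigger-spike clock synchronisation (mat to IMU clock),
#' frame kinematics from the wheel gyroscopes (with optional distance
#' calibration), GPS conversion to local metres, seat-mat COP, and
#' distance-domain alignment with section assignment.
#'
#' @param run A `raw_run` (simulated or read from disk).
#' @param course A `course_definition`.
#' @param geometry A [wheelchair_geometry()].
#' @param curves List of 16 calibration curves; when `NULL` and the run is a
#'   simulated full run, noise-free bench curves are fitted via
#'   [fit_run_calibration()].
#' @param calibration Distance-correction factor or `distance_calibration`
#'   (default 1: none).
#' @param grid_step Distance grid spacing (m), default 1.
#' @param cop_smooth_m COP moving-average window (m), default 4; 0 disables.
#' @param min_force Seated-load threshold for COP gaps (N), default 50.
#' @param v_supply,r_ref Divider constants for [voltage_to_force()].
#' @return List of class `run_report`: `sync`, `kin`, `cop`, `gps_path`,
#'   `aligned`, `sections`, and scalar summaries `total_distance`,
#'   `duration`, `mean_speed`.
#' @export
process_run <- function(run, course, geometry = wheelchair_geometry(),
                        curves = NULL, calibration = 1, grid_step = 1,
                        cop_smooth_m = 4, min_force = 50,
                        v_supply = 3.3, r_ref = 70) {
  stopifnot(inherits(run, "raw_run"))
  if (is.null(run$gyro)) stop("run has no gyro stream (truth-only simulation)")
  if (is.null(run$mat)) stop("seat_mat stage: mat recording missing")
  sync <- sync_run(run$gyro, run$mat)
  kin <- frame_kinematics(run$gyro$t_s, run$gyro$omega_left_dps,
                          run$gyro$omega_right_dps, geometry)
  kin <- apply_correction(kin, calibration)
  if (is.null(curves)) {
    curves <- if (!is.null(run$meta$sensor_laws)) {
      fit_run_calibration(run)
    } else {
      mat_calibration_curves()
    }
  }
  cops <- cop_series(run$mat, curves, t_master = sync$t_mat_master,
                     min_force = min_force, v_supply = v_supply, r_ref = r_ref)
  gps_path <- if (!is.null(run$gps)) {
    microdeg_to_metres(run$gps$t_s, run$gps$lat_udeg, run$gps$lon_udeg)
  } else {
    NULL
  }
  aligned <- align_run(kin, cops, course, grid_step = grid_step,
                       cop_smooth_m = cop_smooth_m)
  moving <- kin$v > 0.05
  dur <- if (any(moving)) diff(range(kin$t[moving])) else diff(range(kin$t))
  total <- max(kin$dist)
  structure(
    list(sync = sync, kin = kin, cop = cops, gps_path = gps_path,
         aligned = aligned, sections = section_summary(aligned),
         total_distance = total, duration = dur,
         mean_speed = total / dur),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: %.1f m in %.0f s (mean %.2f m/s); sync SD %.3g s\n",
              x$total_distance, x$duration, x$mean_speed, x$sync$residual_sd))
  invisible(x)
}

#' Cohort report: average profiles, effect networks, compliance
#'
#' Combines processed runs into the cohort-level outputs: per-distance mean
#' and SD profiles for speed and COP, the Cohen's d effect-size network per
#' parameter (edges where the participant-averaged d is at least `d_floor`),
#' and the route-compliance report (pairwise R^2, medians, ranks, Kendall's
#' W).
#'
#' @param reports Named list of `run_report`s (or bare `aligned_run`s).
#' @param alpha Tukey significance level (default 0.05).
#' @param d_floor,d_cap Effect-size thresholds for the network (0.8, 2).
#' @param parameters Parameters analysed (default v, copx, copy).
#' @return List of class `cohort_report`: `profiles` (per-distance mean/SD),
#'   `networks`, `comparisons`, `compliance`.
#' @export
cohort_report <- function(reports, alpha = 0.05, d_floor = 0.8, d_cap = 2,
                          parameters = c("v", "copx", "copy")) {
  if (length(reports) < 2L) stop("need at least 2 runs for a cohort report")
  aligned <- lapply(reports, function(r) {
    if (inherits(r, "run_report")) r$aligned else r
  })
  len <- vapply(aligned, nrow, integer(1L))
  if (length(unique(len)) != 1L) {
    n_min <- min(len)
    aligned <- lapply(aligned, function(a) a[seq_len(n_min), , drop = FALSE])
  }
  grid <- aligned[[1L]]$dist
  for (a in aligned) {
    if (max(abs(a$dist - grid)) > 1e-9) stop("grids differ across runs")
  }
  profiles <- list(dist = grid)
  for (p in parameters) {
    m <- vapply(aligned, function(a) a[[p]], numeric(length(grid)))
    profiles[[paste0(p, "_mean")]] <- rowMeans(m)
    profiles[[paste0(p, "_sd")]] <- apply(m, 1, stats::sd)
  }
  comparisons <- lapply(parameters, function(p) {
    lapply(aligned, compare_sections, parameter = p, alpha = alpha)
  })
  names(comparisons) <- parameters
  networks <- lapply(comparisons, effect_network, d_floor = d_floor,
                     d_cap = d_cap)
  structure(
    list(profiles = as.data.frame(profiles), networks = networks,
         comparisons = comparisons,
         compliance = if (length(aligned) >= 3L) {
           compliance_report(aligned, parameters)
         }),
    class = "cohort_report"
  )
}

#' Simulate and analyse a full cohort
#'
#' Convenience end-to-end driver: simulates one run per profile on the same
#' course (sharing the course micro-profile), processes each through the
#' sensing pipeline and assembles the cohort report.
#'
#' @param course A `course_definition`.
#' @param profiles List of [participant_profile()]s (default
#'   [make_cohort_profiles()]).
#' @param seed Master seed.
#' @param geometry,distortion,opts Passed to [simulate_run()].
#' @param ... Passed to [process_run()].
#' @return List with `runs` (raw), `reports` (per-run), `cohort`.
#' @export
run_pipeline <- function(course = build_course(),
                         profiles = make_cohort_profiles(), seed = 1L,
                         geometry = wheelchair_geometry(),
                         distortion = clock_distortion(1.01, 5),
                         opts = sim_options(), ...) {
  runs <- lapply(seq_along(profiles), function(i) {
    simulate_run(course, profiles[[i]], geometry, distortion,
                 seed = derive_seed(seed, i), opts = opts)
  })
  names(runs) <- names(profiles)
  reports <- lapply(runs, process_run, course = course, geometry = geometry, ...)
  list(runs = runs, reports = reports, cohort = cohort_report(reports))
}

#' Distance-aligned ground-truth runs for statistical experiments
#'
#' Fast path used by the planted-effect and compliance-recovery experiments:
#' simulates truth-only runs for a set of profiles and aligns the
#' ground-truth speed/COP onto the distance grid directly (no sensor
#' encoding), which exercises the alignment and statistics stages on known
#' signal structure.
#'
#' @param course A `course_definition`.
#' @param profiles List of [participant_profile()]s.
#' @param seed Master seed.
#' @param opts A [sim_options()].
#' @param grid_step Grid spacing (m).
#' @param cop_smooth_m COP smoothing window (m), default 4.
#' @return Named list of `aligned_run`s.
#' @export
simulate_aligned_cohort <- function(course, profiles, seed = 1L,
                                    opts = sim_options(), grid_step = 1,
                                    cop_smooth_m = 4) {
  out <- lapply(seq_along(profiles), function(i) {
    run <- simulate_run(course, profiles[[i]], distortion = clock_distortion(),
                        seed = derive_seed(seed, i), opts = opts,
                        signals = "truth")
    tr <- run$truth
    kin <- data.frame(t = tr$t_s, v = tr$v_mps, dist = tr$dist_m)
    cops <- data.frame(t = tr$t_s, copx = tr$copx_mm, copy = tr$copy_mm)
    align_run(kin, cops, course, grid_step = grid_step,
              cop_smooth_m = cop_smooth_m)
  })
  names(out) <- vapply(profiles, function(p) p$participant_id, character(1L))
  out
}
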
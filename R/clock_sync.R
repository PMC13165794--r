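#' Detect trigger-spike pentads in a sensor channel
#'
#' The synchronisation protocol has the participant strike both wheels five
#' times while standing, at the beginning and again at the end of the
#' recording. The strikes appear as short, high-amplitude spikes in the wheel
#' accelerometer channel and in the seat-mat channels. This function finds
#' the spikes by robust thresholding (median + `threshold_sd` MADs),
#' de-bounces detections closer than `min_separation` (keeping the
#' largest-amplitude sample of each burst) and splits them into a start and
#' an end pentad using the first/last `window_s` seconds of the recording.
#'
#' @param t Numeric vector of timestamps (s), strictly increasing.
#' @param x Numeric vector of channel values, same length as `t`.
#' @param threshold_sd Detection threshold in robust SDs above the median
#'   (default 6).
#' @param min_separation Minimum spacing between distinct spikes in seconds
#'   (default 0.2); closer detections are merged.
#' @param window_s Length of the start/end windows assumed to contain the
#'   pentads (default 60 s).
#' @param expected Expected number of spikes per pentad (default 5). Only
#'   used for a warning; detection does not force the count.
#' @return A list with elements `start` and `end`, each a list with `times`
#'   (spike timestamps), `amplitudes`, `anchor` (timestamp of the
#'   maximum-amplitude spike, the representative anchor of the pentad) and
#'   `pentad` (`"start"`/`"end"`).
#' @export
detect_triggers <- function(t, x, threshold_sd = 6, min_separation = 0.2,
                            window_s = 60, expected = 5L) {
  stopifnot(length(t) == length(x), length(t) > 1L)
  med <- stats::median(x)
  rsd <- stats::mad(x)
  if (rsd == 0) rsd <- stats::sd(x)
  if (!is.finite(rsd) || rsd == 0) stop("pentad not found: channel is constant")
  thr <- med + threshold_sd * rsd
  idx <- which(x > thr)
  if (length(idx) == 0L) stop("pentad not found: no samples above threshold")
  # de-bounce: group detections separated by < min_separation, keep the peak
  grp <- cumsum(c(TRUE, diff(t[idx]) >= min_separation))
  peak_idx <- vapply(split(idx, grp), function(ii) ii[which.max(x[ii])], integer(1L))
  peak_t <- t[peak_idx]
  peak_a <- x[peak_idx]

  t0 <- t[1L]
  t1 <- t[length(t)]
  in_start <- peak_t <= t0 + window_s
  in_end <- peak_t >= t1 - window_s
  make_pentad <- function(keep, label) {
    if (sum(keep) < 2L) {
      stop(sprintf("pentad not found: fewer than 2 spikes in the %s window", label))
    }
    tt <- peak_t[keep]
    aa <- peak_a[keep]
    if (sum(keep) != expected) {
      warning(sprintf("%s pentad has %d spikes (expected %d)",
                      label, sum(keep), expected))
    }
    list(times = tt, amplitudes = aa, anchor = tt[which.max(aa)], pentad = label)
  }
  list(start = make_pentad(in_start, "start"), end = make_pentad(in_end, "end"))
}

#' Fit the linear slave-to-master clock map from two anchor pairs
#'
#' The seat-mat (slave) clock and the IMU (master) clock run at different
#' rates and with an offset. Assuming a linear clock model, the slave
#' timestamp `t_s` maps to the master time scale as
#' `t_sm = m * t_s + delta_tB + b`, where the skew is the ratio of anchor
#' spans `m = (t_Bm - t_Em) / (t_Bs - t_Es)`, `delta_tB = t_Bm - t_Bs` is the
#' start-anchor differential, and the intercept `b = t_Bm - delta_tB - m * t_Bs`
#' is chosen so that both anchor pairs map exactly (two-point interpolation).
#'
#' @param t_Bm,t_Bs Master/slave timestamps of the selected start-pentad
#'   anchor spike (s).
#' @param t_Em,t_Es Master/slave timestamps of the selected end-pentad anchor
#'   spike (s).
#' @return An object of class `clock_map` with fields `skew_m`,
#'   `delta_tB`, `intercept_b` and `anchors`.
#' @examples
#' m <- fit_clock_map(0, 5, 600, 611)
#' m$skew_m                       # 600/606
#' apply_clock_map(m, c(5, 611))  # 0, 600
#' @export
fit_clock_map <- function(t_Bm, t_Bs, t_Em, t_Es) {
  stopifnot(is.numeric(t_Bm), is.numeric(t_Bs), is.numeric(t_Em), is.numeric(t_Es))
  if (t_Bs == t_Es) stop("degenerate anchors: coincident slave timestamps")
  if (!(t_Bm < t_Em)) stop("master anchors must be ordered: t_Bm < t_Em")
  m <- (t_Bm - t_Em) / (t_Bs - t_Es)
  if (!(m > 0)) stop("fitted skew is not positive; anchor pairing is inconsistent")
  delta_tB <- t_Bm - t_Bs
  b <- t_Bm - delta_tB - m * t_Bs
  structure(
    list(skew_m = m, delta_tB = delta_tB, intercept_b = b,
         anchors = c(t_Bm = t_Bm, t_Bs = t_Bs, t_Em = t_Em, t_Es = t_Es)),
    class = "clock_map"
  )
}

#' Apply a fitted clock map to slave timestamps
#'
#' Affine, order-preserving conversion of slave-clock timestamps to the
#' master time scale; the two anchor pairs reproduce exactly.
#'
#' @param map A `clock_map` from [fit_clock_map()].
#' @param t_s Numeric vector of slave timestamps (s).
#' @return Numeric vector of master timestamps (s).
#' @export
apply_clock_map <- function(map, t_s) {
  stopifnot(inherits(map, "clock_map"))
  map$skew_m * t_s + map$delta_tB + map$intercept_b
}

#' Invert a clock map (master to slave)
#'
#' Used by the simulator to distort timestamps in a way the fit recovers.
#'
#' @param map A `clock_map`.
#' @param t_m Master timestamps (s).
#' @return Slave timestamps (s).
#' @export
invert_clock_map <- function(map, t_m) {
  stopifnot(inherits(map, "clock_map"))
  (t_m - map$delta_tB - map$intercept_b) / map$skew_m
}

#' @export
print.clock_map <- function(x, ...) {
  cat(sprintf("Clock map: t_m = %.9g * t_s + %.6g s (delta_tB %.6g, b %.6g)\n",
              x$skew_m, x$delta_tB + x$intercept_b, x$delta_tB, x$intercept_b))
  invisible(x)
}

#' Synchronisation residual SD over all trigger spikes
#'
#' The clock map is fitted on one anchor spike per pentad; the remaining
#' spikes provide an error estimate. Given master-time spikes paired with
#' their mapped slave-time counterparts, returns the standard deviation of
#' the pairwise differences (master minus mapped slave).
#'
#' @param master Numeric vector of master-clock spike times (s).
#' @param mapped_slave Numeric vector of the corresponding slave spike times
#'   after [apply_clock_map()], same length.
#' @param n_anchors Number of anchor pairs included in the vectors (default
#'   2). At least 2 non-anchor pairs are required.
#' @return List with `sd` (s), `residuals` (s), `n`.
#' @export
sync_residuals <- function(master, mapped_slave, n_anchors = 2L) {
  stopifnot(length(master) == length(mapped_slave))
  if (length(master) - n_anchors < 2L) {
    stop("need at least 2 spike pairs beyond the anchors")
  }
  r <- master - mapped_slave
  list(sd = stats::sd(r), residuals = r, n = length(r))
}

#' Synchronise a simulated/recorded run's seat mat to the IMU clock
#'
#' Convenience wrapper running the full synchronisation stage on a run:
#' detects the trigger pentads in the wheel accelerometer (master) and in the
#' summed mat channels (slave), fits the clock map on the maximum-amplitude
#' anchor spike of each pentad, and reports the residual SD over all paired
#' spikes.
#'
#' @param gyro Data.frame with columns `t_s` and `accel_trigger`.
#' @param mat Data.frame with column `t_slave_s` and the 16 voltage channels
#'   `v01`..`v16`.
#' @param threshold_sd,min_separation,window_s Passed to [detect_triggers()].
#' @return List with `map` (a `clock_map`), `residual_sd` (s), `master_spikes`,
#'   `slave_spikes_mapped`, and `t_mat_master` (all mat timestamps mapped to
#'   the master clock).
#' @export
sync_run <- function(gyro, mat, threshold_sd = 6, min_separation = 0.2,
                     window_s = 60) {
  vcols <- grep("^v[0-9]+$", names(mat), value = TRUE)
  mat_sum <- rowSums(mat[, vcols, drop = FALSE])
  # strikes are single-sample impulses; detecting on the absolute first
  # difference removes the seated-load baseline and its slow drift, and
  # keeps the noise floor of the threshold estimate well defined
  mat_impulse <- c(0, abs(diff(mat_sum)))
  prune <- function(p, k = 5L) {
    if (length(p$times) <= k) return(p)
    keep <- order(p$amplitudes, decreasing = TRUE)[seq_len(k)]
    keep <- sort(keep)
    p$times <- p$times[keep]
    p$amplitudes <- p$amplitudes[keep]
    p$anchor <- p$times[which.max(p$amplitudes)]
    p
  }
  trig_m <- detect_triggers(gyro$t_s, gyro$accel_trigger,
                            threshold_sd = threshold_sd,
                            min_separation = min_separation, window_s = window_s)
  trig_s <- suppressWarnings(
    detect_triggers(mat$t_slave_s, mat_impulse,
                    threshold_sd = threshold_sd,
                    min_separation = min_separation, window_s = window_s)
  )
  trig_m$start <- prune(trig_m$start)
  trig_m$end <- prune(trig_m$end)
  trig_s$start <- prune(trig_s$start)
  trig_s$end <- prune(trig_s$end)
  map <- fit_clock_map(trig_m$start$anchor, trig_s$start$anchor,
                       trig_m$end$anchor, trig_s$end$anchor)
  ms <- c(trig_m$start$times, trig_m$end$times)
  ss <- apply_clock_map(map, c(trig_s$start$times, trig_s$end$times))
  res <- if (length(ms) == length(ss) && length(ms) >= 4L) {
    sync_residuals(sort(ms), sort(ss))
  } else {
    list(sd = NA_real_, residuals = numeric(0), n = 0L)
  }
  list(map = map, residual_sd = res$sd, master_spikes = ms,
       slave_spikes_mapped = ss,
       t_mat_master = apply_clock_map(map, mat$t_slave_s))
}
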
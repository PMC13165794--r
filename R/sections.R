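# Distance-domain alignment ("synchorisation"), section segmentation, and
# per-section statistics: one-way ANOVA, Tukey HSD, Cohen's d, and the
# effect-size network across participants.

#' Resample a timestamped series onto a uniform distance grid
#'
#' The study compares signals by *location* rather than by time
#' ("synchorisation": alignment to space). Given a series sampled in time and
#' the cumulative distance as a function of time, the series is linearly
#' interpolated onto a uniform distance grid. The grid uses bin centres:
#' d_k = (k - 1/2) * step for k = 1..floor(L/step), so grid points sit
#' mid-way between integer-metre section boundaries rather than on them.
#' Standstill samples (no distance progress) are collapsed to a single
#' support point. COP channels are optionally smoothed with a moving average
#' over `smooth_m` metres after resampling.
#'
#' @param t Timestamps of the value series (s).
#' @param value Series values.
#' @param dist_t Timestamps of the distance series (s).
#' @param dist Cumulative distance (m), non-decreasing.
#' @param grid_step Grid spacing (m), default 1.
#' @param smooth_m Moving-average window in metres applied after resampling
#'   (default 0: none). Use 4 for COP channels.
#' @param max_dist Optional cap for the grid (m); defaults to the final
#'   distance.
#' @return Data.frame with `dist` (grid) and `value`.
#' @export
synchorise <- function(t, value, dist_t, dist, grid_step = 1, smooth_m = 0,
                       max_dist = NULL) {
  stopifnot(length(t) == length(value), length(dist_t) == length(dist))
  if (any(diff(dist) < -1e-9)) stop("distance must be non-decreasing")
  # distance at the value series' timestamps
  d_at <- stats::approx(dist_t, dist, xout = t, rule = 2)$y
  # drop standstill: keep samples strictly advancing in distance
  keep <- c(TRUE, diff(cummax(d_at)) > 0)
  d_at <- d_at[keep]
  val <- value[keep]
  ok <- is.finite(val)
  d_at <- d_at[ok]
  val <- val[ok]
  if (length(d_at) < 2L) stop("not enough moving samples to resample")
  L <- if (is.null(max_dist)) max(d_at) else max_dist
  n_bins <- floor(L / grid_step + 1e-9)
  if (n_bins < 1L) stop("course shorter than one grid step")
  grid <- (seq_len(n_bins) - 0.5) * grid_step
  v <- stats::approx(d_at, val, xout = grid, rule = 2, ties = "ordered")$y
  if (smooth_m > 0) {
    k <- max(1L, round(smooth_m / grid_step))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L) {
      sm <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
      v <- ifelse(is.na(sm), v, sm)
    }
  }
  data.frame(dist = grid, value = v)
}

#' Assign course sections to distances
#'
#' Sections are half-open intervals `[start, start + length)`; the final
#' boundary is closed so the course end belongs to the last section.
#' Distances beyond the course end (plus `tolerance`) are flagged NA.
#'
#' @param dist Distances (m).
#' @param course A `course_definition` (or a numeric boundary vector).
#' @param tolerance Overflow tolerance beyond the final boundary (m),
#'   default 0.5.
#' @return Integer vector of section indices (NA for overflow samples).
#' @examples
#' crs <- build_course()
#' assign_sections(c(0, 500, 789), crs)  # 1, 8, 13
#' @export
assign_sections <- function(dist, course, tolerance = 0.5) {
  b <- if (inherits(course, "course_definition")) course$boundaries else as.numeric(course)
  n_sec <- length(b) - 1L
  idx <- findInterval(dist, b, rightmost.closed = TRUE)
  idx[idx < 1L] <- NA_integer_
  over <- dist > b[length(b)] + tolerance
  idx[idx > n_sec] <- n_sec
  idx[over] <- NA_integer_
  as.integer(idx)
}

#' Build a distance-aligned run from speed and COP series
#'
#' Convenience assembly of the `aligned_run` used by the section statistics:
#' speed, COPx and COPy on a common distance grid with section labels.
#'
#' @param kin A `frame_kinematics` data.frame (`t`, `v`, `dist`).
#' @param cop A `cop_series` data.frame (`t`, `copx`, `copy`) on the master
#'   clock (may be NULL to align speed only).
#' @param course A `course_definition`.
#' @param grid_step Grid spacing (m), default 1.
#' @param cop_smooth_m COP moving-average window (m), default 4 (set 0 to
#'   disable).
#' @return Data.frame of class `aligned_run`: `dist`, `v`, `copx`, `copy`,
#'   `section`.
#' @export
align_run <- function(kin, cop, course, grid_step = 1, cop_smooth_m = 4) {
  L <- min(course$total_length, max(kin$dist))
  va <- synchorise(kin$t, kin$v, kin$t, kin$dist, grid_step, 0, max_dist = L)
  out <- data.frame(dist = va$dist, v = va$value)
  if (!is.null(cop)) {
    xa <- synchorise(cop$t, cop$copx, kin$t, kin$dist, grid_step, cop_smooth_m, max_dist = L)
    ya <- synchorise(cop$t, cop$copy, kin$t, kin$dist, grid_step, cop_smooth_m, max_dist = L)
    out$copx <- xa$value
    out$copy <- ya$value
  } else {
    out$copx <- NA_real_
    out$copy <- NA_real_
  }
  out$section <- assign_sections(out$dist, course)
  class(out) <- c("aligned_run", "data.frame")
  out
}

#' Per-section mean and SD of speed and COP
#'
#' @param run An `aligned_run`.
#' @return Data.frame with `section`, `n`, and mean/SD columns for `v`,
#'   `copx`, `copy`.
#' @export
section_summary <- function(run) {
  secs <- sort(unique(run$section[!is.na(run$section)]))
  n_expected <- max(secs)
  missing_secs <- setdiff(seq_len(n_expected), secs)
  if (length(missing_secs) > 0L) {
    stop("empty section(s): ", paste(missing_secs, collapse = ", "))
  }
  agg <- function(v, f) vapply(secs, function(s) f(v[run$section == s]), numeric(1L))
  data.frame(
    section = secs,
    n = vapply(secs, function(s) sum(run$section == s, na.rm = TRUE), numeric(1L)),
    v_mean = agg(run$v, mean), v_sd = agg(run$v, stats::sd),
    copx_mean = agg(run$copx, function(z) mean(z, na.rm = TRUE)),
    copx_sd = agg(run$copx, function(z) stats::sd(z, na.rm = TRUE)),
    copy_mean = agg(run$copy, function(z) mean(z, na.rm = TRUE)),
    copy_sd = agg(run$copy, function(z) stats::sd(z, na.rm = TRUE))
  )
}

#' Cohen's d with pooled standard deviation
#'
#' `d = |m1 - m2| / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Returns `Inf` when the pooled SD is zero but the means differ, and 0 when
#' both are degenerate and equal.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return Unsigned effect size.
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  delta <- abs(m1 - m2)
  ifelse(sp == 0, ifelse(delta == 0, 0, Inf), delta / sp)
}

#' Compare all section pairs for one parameter
#'
#' Runs a one-way ANOVA of the parameter across the 13 sections, the Tukey
#' HSD post-hoc test over all 78 section pairs, and Cohen's d (pooled SD) for
#' every pair. The comparisons are per participant (N-of-1) and descriptive:
#' consecutive samples of one trial are serially correlated, so the p-values
#' are not population-level inferences.
#'
#' @param run An `aligned_run`.
#' @param parameter One of `"v"`, `"copx"`, `"copy"`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return List of class `section_comparison` with `anova_F`, `anova_p`, and
#'   `pairs` (data.frame: `i`, `j`, `diff`, `tukey_p`, `cohens_d`,
#'   `significant`).
#' @export
compare_sections <- function(run, parameter = c("v", "copx", "copy"),
                             alpha = 0.05) {
  parameter <- match.arg(parameter)
  ok <- !is.na(run$section) & is.finite(run[[parameter]])
  value <- run[[parameter]][ok]
  sec <- factor(run$section[ok], levels = sort(unique(run$section[ok])))
  counts <- table(sec)
  if (any(counts < 2L)) {
    stop("need at least 2 samples per section; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  fit <- stats::aov(value ~ sec)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$sec
  # pair labels are "j-i" with j > i in factor order
  lab <- strsplit(rownames(tk), "-", fixed = TRUE)
  i <- as.integer(vapply(lab, `[`, "", 2L))
  j <- as.integer(vapply(lab, `[`, "", 1L))
  gm <- tapply(value, sec, mean)
  gs <- tapply(value, sec, stats::sd)
  gn <- tapply(value, sec, length)
  key_i <- as.character(i)
  key_j <- as.character(j)
  d <- cohens_d(gm[key_i], gs[key_i], gn[key_i], gm[key_j], gs[key_j], gn[key_j])
  pairs <- data.frame(
    i = pmin(i, j), j = pmax(i, j),
    diff = unname(tk[, "diff"]),
    tukey_p = unname(tk[, "p adj"]),
    cohens_d = unname(d)
  )
  pairs$significant <- pairs$tukey_p < alpha
  pairs <- pairs[order(pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  structure(
    list(parameter = parameter,
         anova_F = an[["F value"]][1L], anova_p = an[["Pr(>F)"]][1L],
         pairs = pairs, alpha = alpha),
    class = "section_comparison"
  )
}

#' Effect-size network across participants
#'
#' Builds the radial-network edge list: for every section pair the Cohen's d
#' values are averaged across participants, and two sections are connected
#' only if the average effect size is at least `d_floor` (0.8, a large
#' effect) and the pair is significant (Tukey p < alpha) for a majority of
#' participants. Line weight maps mean d linearly from `d_floor` (thinnest,
#' 0) to `d_cap` (thickest, 1; 2.0 is a huge effect).
#'
#' @param comparisons List of `section_comparison` objects (one per
#'   participant) for the same parameter.
#' @param d_floor Minimum average effect size for an edge (default 0.8).
#' @param d_cap Effect size mapped to weight 1 (default 2).
#' @param require_significant Require Tukey significance in more than half of
#'   the participants (default TRUE).
#' @return Data.frame with `i`, `j`, `mean_d`, `prop_significant`, `edge`,
#'   `weight` for all pairs; edges are the rows with `edge == TRUE`.
#' @export
effect_network <- function(comparisons, d_floor = 0.8, d_cap = 2,
                           require_significant = TRUE) {
  stopifnot(length(comparisons) >= 1L, d_cap > d_floor)
  key <- function(p) paste(p$i, p$j, sep = "-")
  ref <- comparisons[[1L]]$pairs
  ref_key <- key(ref)
  dmat <- matrix(NA_real_, nrow(ref), length(comparisons))
  smat <- matrix(NA, nrow(ref), length(comparisons))
  for (k in seq_along(comparisons)) {
    p <- comparisons[[k]]$pairs
    if (!identical(key(p), ref_key)) stop("inconsistent pair sets across participants")
    dmat[, k] <- p$cohens_d
    smat[, k] <- p$significant
  }
  mean_d <- rowMeans(dmat)
  prop_sig <- rowMeans(smat)
  edge <- mean_d >= d_floor
  if (require_significant) edge <- edge & prop_sig > 0.5
  weight <- pmin(pmax((mean_d - d_floor) / (d_cap - d_floor), 0), 1)
  weight[!edge] <- NA_real_
  data.frame(i = ref$i, j = ref$j, mean_d = mean_d,
             prop_significant = prop_sig, edge = edge, weight = weight)
}
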
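test_that("profile and distortion constructors validate their inputs", {
  expect_error(participant_profile(compliance_lambda = 1.2), "lambda")
  expect_error(participant_profile(speed_scale = 0), "speed_scale")
  expect_error(clock_distortion(skew = 0), "skew")
  p <- make_cohort_profiles()
  expect_length(p, 7L)
  expect_equal(p$P5$compliance_lambda, 0.9)
})

test_that("noise-free lambda=1 truth has exact section means and full length", {
  crs <- mini_course()
  run <- simulate_run(crs, prof(lambda = 1), seed = 3, opts = quiet_opts(),
                      signals = "truth")
  tr <- run$truth
  expect_gte(max(tr$dist_m), crs$total_length)
  expect_lt(max(tr$dist_m), crs$total_length * 1.001)
  mov <- tr$v_mps > 0
  for (s in 1:3) {
    sel <- mov & tr$section == s & tr$dist_m > crs$boundaries[s] &
      tr$dist_m < crs$boundaries[s + 1]
    expect_equal(mean(tr$v_mps[sel]), crs$sections$v_mean[s], tolerance = 1e-9)
    expect_equal(mean(tr$copx_mm[sel]), crs$sections$copx_mean[s], tolerance = 1e-9)
  }
})

test_that("ground-truth distance covers the course for any lambda and seed", {
  crs <- mini_course()
  for (lam in c(0, 0.4, 1)) {
    for (s in 1:3) {
      run <- simulate_run(crs, prof(lambda = lam, ns = s), seed = 100 + s,
                          signals = "truth")
      expect_lt(abs(max(run$truth$dist_m) - crs$total_length) /
                  crs$total_length, 0.001)
    }
  }
})

test_that("planted COP is recovered exactly from the allocated cell forces", {
  # the bilinear two-cell allocation is oracle-equivalent to cop()
  crs <- mini_course()
  run <- simulate_run(crs, prof(lambda = 1, offx = -20), seed = 9,
                      opts = quiet_opts())
  curves <- fit_run_calibration(run)
  cs <- cop_series(run$mat, curves)
  seated <- !is.na(cs$copx) & cs$total > 500
  truth_x <- approx(run$truth$t_s, run$truth$copx_mm,
                    xout = run$mat$t_slave_s * run$meta$distortion$skew +
                      run$meta$distortion$offset, rule = 2)$y
  err <- abs(cs$copx[seated] - truth_x[seated])
  # exclude strike samples (spikes overwrite the voltages)
  expect_lt(median(err, na.rm = TRUE), 1e-6)
})

test_that("independent participants (lambda = 0) decorrelate", {
  crs <- build_course()
  r2s <- vapply(1:6, function(s) {
    al <- simulate_aligned_cohort(
      crs, list(prof("A", 0, ns = 1), prof("B", 0, ns = 2)),
      seed = 4000 + s, opts = sim_options(share_frac = 0.95))
    pairwise_r2(list(a = al[[1]]$v, b = al[[2]]$v))[1, 2]
  }, numeric(1))
  expect_lt(max(r2s), 0.1)
})

test_that("median pairwise R2 increases with the compliance weight", {
  crs <- build_course()
  lam <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  acc <- matrix(0, 5, 5)
  n_seeds <- 8
  for (s in 1:n_seeds) {
    profs <- lapply(1:5, function(i) prof(paste0("L", i), lam[i], ns = i))
    al <- simulate_aligned_cohort(crs, profs, seed = 5000 + s)
    acc <- acc + pairwise_r2(lapply(al, function(a) a$v))
  }
  acc <- acc / n_seeds
  pairs <- which(upper.tri(acc), arr.ind = TRUE)
  minlam <- pmin(lam[pairs[, 1]], lam[pairs[, 2]])
  rho <- cor(minlam, acc[pairs], method = "spearman")
  expect_gt(rho, 0)
})

test_that("runs round-trip through CSV files losslessly", {
  crs <- mini_course()
  run <- simulate_run(crs, prof(lambda = 0.7), seed = 12)
  dir <- withr::local_tempdir()
  write_run(run, dir)
  expect_error(write_run(run, dir), "exist")
  back <- read_run(dir)
  expect_identical(back$gyro$omega_left_dps, run$gyro$omega_left_dps)
  expect_identical(back$mat$v05, run$mat$v05)
  expect_identical(back$gps$lat_udeg, run$gps$lat_udeg)
  expect_identical(back$truth$dist_m, run$truth$dist_m)
  # writing the same text again is byte-identical
  dir2 <- withr::local_tempdir()
  write_run(back, dir2)
  expect_identical(readLines(file.path(dir, "gyro.csv")),
                   readLines(file.path(dir2, "gyro.csv")))
})

test_that("a 600 s recording writes 60000 gyro rows plus a header", {
  t <- seq(0, 599.99, 0.01)
  run <- structure(list(
    gyro = data.frame(t_s = t, omega_left_dps = 0, omega_right_dps = 0,
                      accel_trigger = 0),
    mat = NULL, gps = NULL,
    truth = data.frame(t_s = t, v_mps = 0, dist_m = 0, copx_mm = 0,
                       copy_mm = 0, section = 1L),
    meta = NULL), class = "raw_run")
  dir <- withr::local_tempdir()
  write_run(run, dir)
  expect_length(readLines(file.path(dir, "gyro.csv")), 60001L)
  empty <- structure(list(gyro = NULL, mat = NULL, gps = NULL,
                          truth = data.frame(), meta = NULL),
                     class = "raw_run")
  expect_error(write_run(empty, dir, overwrite = TRUE), "no samples")
})

test_that("gyro streams stay inside the instrument range", {
  crs <- build_course()
  run <- simulate_run(crs, prof(lambda = 0.5, scale = 1.16, ns = 2), seed = 31)
  expect_lt(max(abs(c(run$gyro$omega_left_dps, run$gyro$omega_right_dps))),
            2000)
  # two pentads of five strikes in the trigger channel
  tr <- detect_triggers(run$gyro$t_s, run$gyro$accel_trigger)
  expect_length(tr$start$times, 5L)
  expect_length(tr$end$times, 5L)
  expect_equal(tr$start$times, run$meta$trigger_master[1:5], tolerance = 0.011)
})
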
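test_that("mat geometry places centroids on the 70/85 mm pitch", {
  g <- mat_geometry()
  expect_equal(g$col_x, c(-105, -35, 35, 105))
  expect_equal(g$row_y, c(-127.5, -42.5, 42.5, 127.5))
  expect_equal(nrow(g$centroids), 16L)
  expect_equal(g$cell_area_m2, 3.25e-3)
})

test_that("calibration fit interpolates its own model class", {
  set.seed(8)
  g <- seq(1e-4, 5e-3, length.out = 20)
  p <- drop(outer(g / max(g), 0:6, `^`) %*% c(200, 1e5, 5e4, 0, 2e4, 0, 0))
  curve <- fit_calibration(p, g)
  expect_lt(max(abs(predict_pressure(curve, g) - p) / p), 1e-8)
  expect_error(fit_calibration(p[1:3], g[1:3]), "underdetermined")
})

test_that("simulator sensor law round-trips through fit and divider", {
  laws <- wheelmetrics:::sensor_laws(5)
  cyc <- simulate_calibration_cycles(laws[[1]], 20, seed = 2)
  curve <- fit_calibration(cyc$pressure_pa, cyc$conductance_s)
  # forces -> pressure -> conductance -> voltage -> decode
  f_true <- seq(5, 500, length.out = 40)
  p_true <- f_true / 3.25e-3
  gg <- wheelmetrics:::law_conductance(laws[[1]], p_true)
  v <- 3.3 * 70 * gg / (1 + 70 * gg)
  f_rec <- voltage_to_force(matrix(v, ncol = 1), list(curve))
  rel <- (f_rec - f_true) / f_true
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("divider edge cases follow the contract", {
  laws <- wheelmetrics:::sensor_laws(5)
  cyc <- simulate_calibration_cycles(laws[[1]], 20, seed = 2)
  curve <- fit_calibration(cyc$pressure_pa, cyc$conductance_s)
  # v = 0 -> conductance 0 -> force clipped to the lower calibration bound
  f0 <- voltage_to_force(matrix(0, 1, 1), list(curve))
  expect_equal(drop(f0), curve$valid_range[1] * 3.25e-3, tolerance = 1e-6)
  expect_error(voltage_to_force(matrix(3.3, 1, 1), list(curve)), "saturated")
})

test_that("cop is the hand-computed weighted centroid", {
  g <- mat_geometry()
  expect_equal(unlist(cop(rep(1, 16), g)[1, 1:2]), c(copx = 0, copy = 0))
  # single loaded sensor: COP at its centroid (-105, 127.5) = sensor 13
  f <- rep(0, 16)
  f[13] <- 5
  expect_equal(unlist(cop(f, g)[1, 1:2]), c(copx = -105, copy = 127.5))
  # two-cell example: 2 N at (-35, -42.5) [sensor 6], 1 N at (35, -42.5) [7]
  f2 <- rep(0, 16)
  f2[6] <- 2
  f2[7] <- 1
  r <- cop(f2, g)
  expect_equal(r$copx, (2 * (-35) + 1 * 35) / 3, tolerance = 1e-12)
  expect_equal(r$copx, -11.667, tolerance = 1e-3)
  expect_equal(r$copy, -42.5)
  # all-zero frame is a flagged gap, not an error
  z <- cop(rep(0, 16), g)
  expect_true(is.na(z$copx) && is.na(z$copy))
})

test_that("cop equals a brute-force loop and obeys invariances", {
  g <- mat_geometry()
  brute <- function(f) {
    sx <- 0; sy <- 0; st <- 0
    for (i in 1:16) {
      sx <- sx + f[i] * g$centroids[i, "x"]
      sy <- sy + f[i] * g$centroids[i, "y"]
      st <- st + f[i]
    }
    c(sx / st, sy / st)
  }
  set.seed(99)
  for (k in 1:1000) {
    f <- runif(16, 0, 100)
    r <- cop(f, g)
    b <- brute(f)
    expect_lt(abs(r$copx - b[1]), 1e-12)
    expect_lt(abs(r$copy - b[2]), 1e-12)
    # force-scale invariance
    r2 <- cop(3.7 * f, g)
    expect_lt(abs(r2$copx - r$copx), 1e-12)
    expect_lt(abs(r2$copy - r$copy), 1e-12)
  }
  # translation covariance: shifting all centroids shifts the COP exactly
  g2 <- g
  g2$centroids[, "x"] <- g2$centroids[, "x"] + 12.5
  g2$centroids[, "y"] <- g2$centroids[, "y"] - 7.25
  f <- runif(16, 0, 10)
  r <- cop(f, g)
  r2 <- cop(f, g2)
  expect_equal(r2$copx, r$copx + 12.5, tolerance = 1e-12)
  expect_equal(r2$copy, r$copy - 7.25, tolerance = 1e-12)
})

test_that("two-support load shift matches the ischial-spacing arithmetic", {
  # equal load on two supports d apart; shifting the COP laterally by
  # delta transfers a fraction delta/d of the total load
  shift_fraction <- function(d, delta) {
    w <- 0.5 + delta / d  # load share on the approached support
    w - 0.5
  }
  expect_equal(100 * shift_fraction(134.9, 10), 7.43, tolerance = 0.03)
  expect_equal(100 * shift_fraction(116.5, 10), 8.57, tolerance = 0.03)
})

test_that("cop agreement metrics follow the regression contract", {
  set.seed(31)
  a <- rnorm(200)
  r <- cop_agreement(a, a)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$pearson_r2, 1)
  expect_equal(r$spearman_r2, 1)
  # b = 2a + 3: regressing a on b halves the slope, R^2 stays 1
  b <- 2 * a + 3
  r2 <- cop_agreement(a, b)
  expect_equal(r2$slope, 0.5, tolerance = 1e-12)
  expect_equal(r2$pearson_r2, 1, tolerance = 1e-12)
  # independent noise degrades Pearson R^2 monotonically
  r2s <- vapply(c(0.2, 1, 3), function(s) {
    set.seed(42)
    cop_agreement(a + rnorm(200, 0, s), a)$pearson_r2
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))
  expect_error(cop_agreement(a[1:5], a[1:5]), "at least 10")
})
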
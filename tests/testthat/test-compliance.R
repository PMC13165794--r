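test_that("pairwise R2 matrix is symmetric with unit diagonal", {
  set.seed(3)
  profs <- list(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  r2 <- pairwise_r2(profs)
  expect_equal(r2, t(r2))
  expect_equal(unname(diag(r2)), rep(1, 3))
  expect_true(all(r2 >= 0 & r2 <= 1, na.rm = TRUE))
  # affine invariance: b = a + constant -> R^2 = 1
  r2b <- pairwise_r2(list(a = profs$a, b = profs$a + 5))
  expect_equal(r2b["a", "b"], 1, tolerance = 1e-12)
  # constant series: flagged NA, not an error
  r2c <- pairwise_r2(list(a = profs$a, b = rep(2, 300)))
  expect_true(is.na(r2c["a", "b"]))
})

test_that("participant medians use type-7 quartiles (hand-checked)", {
  # {0.1..0.6}: median 0.35; Q1 = 0.225, Q3 = 0.475 -> IQR 0.25
  r2 <- matrix(NA, 7, 7)
  diag(r2) <- 1
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  r2[1, 2:7] <- r2[2:7, 1] <- vals
  r2[2:7, 2:7][is.na(r2[2:7, 2:7])] <- 0.3
  diag(r2) <- 1
  pm <- participant_medians(r2)
  expect_equal(pm$median[1], 0.35)
  expect_equal(pm$iqr[1], 0.25)
  # identical values -> IQR 0
  r2e <- matrix(0.4, 4, 4)
  diag(r2e) <- 1
  expect_equal(participant_medians(r2e)$iqr, rep(0, 4))
})

test_that("outlier rule flags the low straggler and nothing else", {
  # mirrors the study's most individualistic participant:
  # Q1 = 0.445, IQR = 0.035, fence = 0.3925 -> 0.31 is flagged
  v <- c(0.44, 0.45, 0.46, 0.47, 0.49, 0.50, 0.31)
  fl <- outlier_flags(v)
  expect_equal(which(fl), 7L)
  expect_false(any(outlier_flags(rep(0.4, 5))))
  # brute-force check of the rule on monotone spreads without a gap
  for (s in 1:20) {
    set.seed(900 + s)
    x <- sort(runif(7, 0.3, 0.5))
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    expect_equal(outlier_flags(x), x < q[1] - 1.5 * (q[2] - q[1]))
  }
})

test_that("rank table reproduces the printed cohort ranking", {
  # medians of the three parameters for the seven participants
  med <- cbind(
    v = c(0.307, 0.469, 0.463, 0.437, 0.499, 0.497, 0.490),
    copx = c(0.334, 0.226, 0.273, 0.287, 0.425, 0.406, 0.109),
    copy = c(0.141, 0.170, 0.013, 0.063, 0.235, 0.205, 0.194))
  rownames(med) <- paste0("P", 1:7)
  rt <- rank_table(med)
  expect_equal(unname(rt$ranks[, "v"]), c(1, 4, 3, 2, 7, 6, 5))
  expect_equal(unname(rt$ranks[, "copx"]), c(5, 2, 3, 4, 7, 6, 1))
  expect_equal(unname(rt$ranks[, "copy"]), c(3, 4, 1, 2, 7, 6, 5))
  expect_equal(unname(rt$rank_sums), c(9, 10, 7, 8, 21, 18, 11))
  # rank sums total m * n (n + 1) / 2
  expect_equal(sum(rt$rank_sums), 3 * 7 * 8 / 2)
  # identical columns of distinct values -> rank sum = 3 x column rank
  same <- cbind(a = 1:5, b = 1:5, c = 1:5)
  expect_equal(unname(rank_table(same)$rank_sums), 3 * (1:5))
  # reversing a column reverses its ranks
  rev1 <- rank_table(cbind(a = 1:5))$ranks[, 1]
  rev2 <- rank_table(cbind(a = 5:1))$ranks[, 1]
  expect_equal(unname(rev2), rev(unname(rev1)))
})

test_that("Kendall's W matches hand-computed values and its algebraic twin", {
  ranks <- cbind(
    v = c(1, 4, 3, 2, 7, 6, 5),
    copx = c(5, 2, 3, 4, 7, 6, 1),
    copy = c(3, 4, 1, 2, 7, 6, 5))
  kw <- kendalls_w(ranks)
  # S = 172, denominator 3^2 * (343 - 7) = 3024
  expect_equal(kw$S, 172)
  expect_equal(kw$W, 12 * 172 / 3024, tolerance = 1e-12)
  expect_equal(kw$W, 0.683, tolerance = 1e-3)
  expect_equal(kw$chi2, 3 * 6 * kw$W, tolerance = 1e-12)
  # algebraically equivalent form via sum of squared rank sums
  n <- nrow(ranks)
  m <- ncol(ranks)
  W2 <- (12 * sum(rowSums(ranks)^2) - 3 * m^2 * n * (n + 1)^2) /
    (m^2 * (n^3 - n))
  expect_lt(abs(kw$W - W2), 1e-12)
  # identical rankings -> W = 1; exactly reversed pair -> W = 0
  expect_equal(kendalls_w(cbind(1:6, 1:6))$W, 1)
  expect_equal(kendalls_w(cbind(1:6, 6:1))$W, 0)
  expect_error(kendalls_w(matrix(1, 1, 3)), "at least 2")
})

test_that("W is invariant under relabelling of items and judges", {
  set.seed(14)
  for (k in 1:10) {
    r <- replicate(4, sample(1:8))
    w0 <- kendalls_w(r)$W
    perm_items <- sample(1:8)
    perm_judges <- sample(1:4)
    expect_equal(kendalls_w(r[perm_items, perm_judges])$W, w0,
                 tolerance = 1e-12)
  }
})

test_that("tie-corrected W stays in [0, 1] with tied ranks", {
  r <- cbind(c(1, 2.5, 2.5, 4), c(1.5, 1.5, 3, 4))
  kw <- kendalls_w(r)
  expect_true(kw$W >= 0 && kw$W <= 1)
})

test_that("Friedman wrapper agrees with base behaviour and a sign test", {
  # identical columns: all within-block ranks tie, statistic at its minimum
  x <- matrix(rep(1:10, 3), ncol = 3)
  f <- friedman_test(x)
  expect_equal(f$chi2, 0)
  expect_gt(f$p, 0.99)
  # strongly ordered columns separate clearly
  set.seed(15)
  y <- cbind(rnorm(20), rnorm(20) + 2, rnorm(20) + 4)
  expect_lt(friedman_test(y)$p, 0.01)
  # two conditions reduce to sign-test behaviour (exact binomial oracle;
  # the chi-squared approximation has no continuity correction, so allow
  # the usual exact-vs-asymptotic gap)
  set.seed(16)
  for (k in 1:5) {
    z <- cbind(rnorm(40), rnorm(40, 0.8))
    pf <- friedman_test(z)$p
    wins <- sum(z[, 2] > z[, 1])
    ps <- stats::binom.test(wins, 40)$p.value
    expect_lt(abs(pf - ps), 0.1)
  }
})
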
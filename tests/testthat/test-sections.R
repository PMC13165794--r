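test_that("synchorise resamples onto the bin-centre distance grid", {
  # constant 1 m/s over 789 m on a 1 m grid -> 789 identical samples
  t <- seq(0, 789, 1)
  al <- synchorise(t, rep(2.5, length(t)), t, t, grid_step = 1)
  expect_equal(nrow(al), 789L)
  expect_equal(al$dist[1], 0.5)
  expect_true(all(al$value == 2.5))
  expect_error(synchorise(1:10, 1:10, 1:10, 10:1), "non-decreasing")
})

test_that("standstill samples are dropped before resampling", {
  t <- seq(0, 100, 0.5)
  d <- pmax(t - 20, 0)           # stationary for 20 s, then 1 m/s
  v <- ifelse(t <= 20, 0, 1.5)
  al <- synchorise(t, v, t, d, grid_step = 1)
  expect_true(all(al$value[al$dist > 1] == 1.5))
})

test_that("section assignment uses half-open intervals, closed at the end", {
  crs <- build_course()
  expect_equal(assign_sections(500, crs), 8L)   # 481 <= 500 < 521
  expect_equal(assign_sections(0, crs), 1L)
  expect_equal(assign_sections(789, crs), 13L)  # closed final boundary
  expect_equal(assign_sections(47, crs), 2L)
  expect_true(is.na(assign_sections(795, crs)))
  # sections partition the grid
  grid <- seq(0.5, 788.5, 1)
  sec <- assign_sections(grid, crs)
  expect_equal(as.integer(table(sec)), crs$sections$length)
  expect_equal(sum(table(sec)), length(grid))
})

test_that("section summary recovers means and flags empty sections", {
  crs <- mini_course()
  grid <- seq(0.5, 99.5, 1)
  run <- data.frame(dist = grid, v = rep(c(1, 2, 3), times = c(30, 40, 30)),
                    copx = 0, copy = 0,
                    section = assign_sections(grid, crs))
  ss <- section_summary(run)
  expect_equal(ss$v_mean, c(1, 2, 3))
  expect_equal(ss$v_sd, c(0, 0, 0))
  bad <- run[run$section != 2, ]
  expect_error(section_summary(bad), "empty section")
})

test_that("cohens d matches direct arithmetic and flags degeneracy", {
  expect_equal(cohens_d(0, 1, 100, 1, 1, 100), 1)
  expect_equal(cohens_d(3, 0.5, 10, 3, 0.5, 10), 0)
  expect_true(is.infinite(cohens_d(0, 0, 10, 1, 0, 10)))
  # Monte-Carlo: planted unit effect recovers d ~ 1
  set.seed(12)
  d <- replicate(20, {
    a <- rnorm(100, 0, 1)
    b <- rnorm(100, 1, 1)
    cohens_d(mean(a), sd(a), 100, mean(b), sd(b), 100)
  })
  expect_true(all(abs(d - 1) < 0.45))
  expect_lt(abs(mean(d) - 1), 0.15)
})

test_that("ANOVA p-values are uniform under the null across sections", {
  # all 13 sections drawn from one distribution
  pvals <- vapply(1:400, function(s) {
    set.seed(5000 + s)
    run <- data.frame(v = rnorm(13 * 20),
                      section = rep(1:13, each = 20))
    run$copx <- 0
    run$copy <- 0
    run$dist <- seq_len(nrow(run))
    compare_sections(run, "v")$anova_p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("compare_sections produces all 78 pairs with sane effect sizes", {
  set.seed(77)
  run <- data.frame(v = rnorm(13 * 30, mean = rep(c(1, 1.5), length.out = 13 * 30)),
                    section = rep(1:13, each = 30))
  run$v <- rnorm(13 * 30, mean = rep(seq(1, 2.2, length.out = 13), each = 30), sd = 0.3)
  run$copx <- run$copy <- 0
  run$dist <- seq_len(nrow(run))
  cmp <- compare_sections(run, "v")
  expect_equal(nrow(cmp$pairs), 78L)
  expect_true(all(cmp$pairs$cohens_d >= 0))
  expect_true(all(cmp$pairs$tukey_p >= 0 & cmp$pairs$tukey_p <= 1))
  expect_lt(cmp$anova_p, 1e-6)
  # widely separated sections carry a larger effect than neighbours
  d_far <- cmp$pairs$cohens_d[cmp$pairs$i == 1 & cmp$pairs$j == 13]
  d_near <- cmp$pairs$cohens_d[cmp$pairs$i == 1 & cmp$pairs$j == 2]
  expect_gt(d_far, d_near)
})

test_that("effect network applies the averaged-d edge rule and weights", {
  mkcmp <- function(dvals, p = 1e-6) {
    pairs <- data.frame(i = 1, j = 2, diff = 1, tukey_p = p,
                        cohens_d = dvals, significant = p < 0.05)
    structure(list(parameter = "v", anova_F = 1, anova_p = 0,
                   pairs = pairs, alpha = 0.05),
              class = "section_comparison")
  }
  # all participants d = 0.5 -> no edge
  net <- effect_network(list(mkcmp(0.5), mkcmp(0.5)))
  expect_false(net$edge[1])
  # all d = 2.5 -> edge at the weight cap
  net2 <- effect_network(list(mkcmp(2.5), mkcmp(2.5)))
  expect_true(net2$edge[1])
  expect_equal(net2$weight[1], 1)
  # boundary: {0.6, 1.0} averages to exactly 0.8 -> edge with weight 0
  net3 <- effect_network(list(mkcmp(0.6), mkcmp(1.0)))
  expect_true(net3$edge[1])
  expect_equal(net3$weight[1], 0)
  # significance gate: large d but non-significant everywhere -> no edge
  net4 <- effect_network(list(mkcmp(2.5, p = 0.5), mkcmp(2.5, p = 0.5)))
  expect_false(net4$edge[1])
  expect_error(effect_network(list(mkcmp(1), {
    x <- mkcmp(1)
    x$pairs$j <- 3
    x
  })), "inconsistent")
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(13)
  mk <- function() {
    pairs <- expand.grid(i = 1:5, j = 1:5)
    pairs <- pairs[pairs$i < pairs$j, ]
    pairs$diff <- 1
    pairs$tukey_p <- 1e-6
    pairs$cohens_d <- runif(nrow(pairs), 0, 3)
    pairs$significant <- TRUE
    structure(list(parameter = "v", anova_F = 1, anova_p = 0,
                   pairs = pairs, alpha = 0.05),
              class = "section_comparison")
  }
  cmps <- list(mk(), mk(), mk())
  counts <- vapply(seq(0.2, 2.8, 0.2), function(thr) {
    sum(effect_network(cmps, d_floor = thr, d_cap = thr + 1.2)$edge)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
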
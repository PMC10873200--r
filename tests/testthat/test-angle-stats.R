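test_that("relative histograms use fixed 3-degree bins summing to 100", {
  h <- relative_histogram(rep(45.5, 17))
  expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  expect_identical(sum(h$percent > 0), 1L)          # one occupied bin
  expect_equal(h$bin_edges[which(h$percent > 0) + c(0, 1)], c(45, 48))
  set.seed(21)
  u <- runif(60000, 0, 180)
  hu <- relative_histogram(u)
  occ <- hu$percent[hu$percent > 0]
  expect_equal(length(occ), 60L)
  expect_lt(max(abs(occ - 100 / 60)), 0.3)
  expect_equal(sum(hu$percent), 100, tolerance = 1e-9)
})

test_that("box statistics follow the type-7 quantile and 1.5 IQR rules", {
  b <- box_stats(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$Q1, 25.75)
  expect_equal(b$Q3, 75.25)
  expect_identical(length(b$outliers), 0L)
  expect_true(b$min <= b$whisker_low && b$whisker_low <= b$Q1)
  expect_true(b$Q3 <= b$whisker_high && b$whisker_high <= b$max)
  b1 <- box_stats(42)
  expect_true(all(unlist(b1[c("mean", "min", "max", "Q1", "median", "Q3",
                              "whisker_low", "whisker_high")]) == 42))
  set.seed(22)
  sym <- c(x <- rnorm(5000, 70, 10), 140 - x)  # exactly symmetric about 70
  bs <- box_stats(sym)
  expect_equal(bs$mean, bs$median, tolerance = 1e-9)
  # outliers are exactly the points beyond the whiskers
  out <- sym[sym < bs$whisker_low | sym > bs$whisker_high]
  expect_equal(sort(bs$outliers), sort(out))
})

test_that("Welch test reproduces the printed bulk-rate comparison", {
  # nanoengine vs nicked variant: n=40, 1.00 +/- 0.12 vs n=14, 2.12 +/- 0.69
  w <- welch_from_summary(40, 1.00, 0.12, 14, 2.12, 0.69)
  expect_lt(abs(w$p - 3.9e-5) / 3.9e-5, 0.25)
  expect_lt(abs(abs(w$t) - 6.0415), 1e-3)
  expect_lt(abs(w$df - 13.276), 1e-2)
})

test_that("extreme tails are evaluated on the log scale without underflow", {
  # TEM angle populations, n in the thousands: p ~ 3e-57 and 8e-64
  w1 <- welch_from_summary(5135, 64.13, 20.04, 3266, 56.51, 21.79)
  expect_lt(abs(w1$log10_p - log10(3e-57)), 0.5)
  w2 <- welch_from_summary(1074, 64.09, 17.32, 1190, 51.37, 17.38)
  expect_lt(abs(w2$log10_p - log10(8e-64)), 0.5)
  # frozen arbitrary-precision reference for t = 16.116, df = 6523
  lp <- stats::pt(16.116, 6523, lower.tail = FALSE, log.p = TRUE) + log(2)
  expect_lt(abs(lp / log(10) - (-56.60331)), 0.1)
  expect_lt(abs(w1$log10_p - (-56.59691)), 0.01)
})

test_that("summary-statistics route equals the raw-sample route", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(30 + i, 60, 15); y <- rnorm(50 - i, 55, 20)
    a <- welch_t_test(x, y)
    b <- welch_from_summary(length(x), mean(x), sd(x),
                            length(y), mean(y), sd(y))
    expect_equal(a$t, b$t, tolerance = 1e-12)
    expect_equal(a$df, b$df, tolerance = 1e-12)
    # cross-check against the stock implementation
    ref <- t.test(x, y)
    expect_equal(a$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(a$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(a$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("p decreases monotonically with |t| and handles degenerate input", {
  ts <- seq(0.5, 30, by = 0.5)
  ps <- vapply(ts, function(t) {
    welch_from_summary(20, t * sqrt(2 / 20), 1, 20, 0, 1)$log10_p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  ident <- welch_from_summary(10, 5, 2, 10, 5, 2)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_equal(welch_from_summary(5, 3, 0, 5, 3, 0)$p, 1)  # zero variance
  expect_error(welch_from_summary(1, 0, 1, 10, 0, 1), "n >= 2")
})

test_that("KS comparison matches a permutation oracle at n = 10", {
  set.seed(24)
  x <- rnorm(10, 60, 15); y <- rnorm(10, 50, 15)
  ks <- ks_compare(x, y)
  # permutation oracle: D under random relabellings
  pooled <- c(x, y)
  dstat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(v) - ecdf(b)(v)))
  }
  nperm <- 4000
  dd <- replicate(nperm, {
    ix <- sample(20, 10)
    dstat(pooled[ix], pooled[-ix])
  })
  p_perm <- mean(dd >= ks$D - 1e-12)
  mc_se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(ks$p - p_perm), 4 * mc_se + 0.02)
  # degenerate cases
  z <- rnorm(10)
  same <- ks_compare(z, z)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_compare(1:10, 101:110)$D, 1)
})

test_that("skew-normal TEM sampler respects range and symmetry", {
  s <- sample_tem_angles(70, 15, skew = 0, n = 4000, seed = 25)
  expect_identical(length(s$angles), 4000L)
  expect_true(all(s$angles >= 0 & s$angles <= 180))
  se <- sd(s$angles) / sqrt(4000)
  expect_lt(abs(mean(s$angles) - 70), 3 * se)
  expect_identical(length(sample_tem_angles(70, 15, -3, 0, seed = 1)$angles),
                   0L)
  # negative skew shifts mass below the location parameter
  sk <- sample_tem_angles(70, 20, skew = -4, n = 4000, seed = 26)
  expect_lt(mean(sk$angles), 70)
  # two samples drawn at the printed TEM summaries give a Welch p of the
  # printed order of magnitude
  a <- sample_tem_angles(64.13, 20.04, 0, 5135, seed = 27)
  b <- sample_tem_angles(56.51, 21.79, 0, 3266, seed = 28)
  w <- welch_t_test(a, b)
  expect_lt(w$log10_p, -40)
  expect_gt(w$log10_p, -80)
})

test_that("angles outside the physical range are rejected", {
  expect_error(angle_sample(c(10, 190)), "within")
  expect_error(angle_sample(c(-1, 20)), "within")
})
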
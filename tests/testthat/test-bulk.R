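test_that("beacon calibration fits the standards line", {
  pts <- data.frame(rna_amount = c(0, 50, 100, 200, 400),
                    fluorescence = 100 + 12 * c(0, 50, 100, 200, 400))
  cal <- calibrate_mb(pts)
  expect_equal(cal$slope, 12, tolerance = 1e-12)
  expect_equal(cal$intercept, 100, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)
  # duplicate amounts with differing readings: fit proceeds
  dup <- data.frame(rna_amount = c(0, 0, 100, 100),
                    fluorescence = c(98, 102, 1299, 1301))
  expect_equal(calibrate_mb(dup)$slope, 12, tolerance = 1e-9)
  # a non-positive slope is a calibration failure
  bad <- data.frame(rna_amount = c(0, 100), fluorescence = c(500, 400))
  expect_error(calibrate_mb(bad), "positive")
  expect_error(calibrate_mb(data.frame(rna_amount = 1, fluorescence = 2)),
               "distinct")
})

test_that("linear-phase detection lands inside the growth ramp", {
  sim <- simulate_mb_fluorescence(2.3, 10, lag = 15, saturation_time = 150,
                                  duration = 210, noise_sd = 0, seed = 41)
  win <- find_linear_phase(sim$trace)
  expect_gte(win$window[1], 15)
  expect_lte(win$window[2], 150)
  expect_gt(win$r_squared, 0.999)
  # globally linear trace: the earliest window wins the tie-break
  lin <- structure(data.frame(time_min = 0:100,
                              fluorescence = 5 + 3 * (0:100)),
                   class = c("bulk_trace", "data.frame"))
  expect_equal(find_linear_phase(lin)$window[1], 0)
  # flat noise never reaches the R^2 floor
  set.seed(42)
  flat <- structure(data.frame(time_min = 0:100,
                               fluorescence = rnorm(101)),
                    class = c("bulk_trace", "data.frame"))
  expect_error(find_linear_phase(flat), "R\\^2")
})

test_that("the bulk pipeline recovers the generating per-engine rate", {
  sim <- simulate_mb_fluorescence(2.3, 10, noise_sd = 0.01, seed = 43)
  cal <- calibrate_mb(sim$calibration)
  win <- find_linear_phase(sim$trace)
  est <- absolute_rate(sim$trace, win$window, cal, 10)
  expect_lt(abs(est$calibrated_rate - 2.3) / 2.3, 0.1)
  # noise-free, no lag, no plateau: slope recovered exactly
  clean <- simulate_mb_fluorescence(1.7, 10, lag = 0, saturation_time = Inf,
                                    duration = 100, noise_sd = 0, seed = 44)
  cal2 <- calibrate_mb(clean$calibration)
  est2 <- absolute_rate(clean$trace, NULL, cal2, 10)
  expect_equal(est2$calibrated_rate, 1.7, tolerance = 1e-9)
})

test_that("rate estimates are offset-invariant and gain-linear", {
  sim <- simulate_mb_fluorescence(2.0, 10, noise_sd = 0, seed = 45)
  cal <- calibrate_mb(sim$calibration)
  win <- find_linear_phase(sim$trace)
  base <- absolute_rate(sim$trace, win$window, cal, 10)$calibrated_rate
  shifted <- sim$trace; shifted$fluorescence <- shifted$fluorescence + 5000
  expect_equal(absolute_rate(shifted, win$window, cal, 10)$calibrated_rate,
               base, tolerance = 1e-9)
  gained <- sim$trace; gained$fluorescence <- gained$fluorescence * 3
  expect_equal(absolute_rate(gained, win$window, cal, 10)$calibrated_rate,
               3 * base, tolerance = 1e-9)
})

test_that("relative rates normalise to the reference mean and keep signs", {
  est <- data.frame(
    condition = c(rep("engine", 4), rep("nicked", 3), rep("nts", 2)),
    rate = c(2.2, 2.4, 2.3, 2.3, 4.8, 4.9, 4.9, -0.1, -0.2))
  rel <- relative_rates(est, "engine")
  expect_equal(rel$mean_relative[rel$condition == "engine"], 1)
  expect_equal(rel$mean_relative[rel$condition == "nicked"],
               mean(c(4.8, 4.9, 4.9)) / 2.3, tolerance = 1e-9)
  # negative control rates stay negative (photobleaching drift)
  expect_lt(rel$mean_relative[rel$condition == "nts"], 0)
  expect_error(relative_rates(est, "absent"), "not present")
})

test_that("nicked-versus-engine ratio survives the full round trip", {
  rate_of <- function(rate, seed) {
    sim <- simulate_mb_fluorescence(rate, 10, noise_sd = 0.01, seed = seed)
    cal <- calibrate_mb(sim$calibration)
    win <- find_linear_phase(sim$trace)
    absolute_rate(sim$trace, win$window, cal, 10)$calibrated_rate
  }
  r1 <- rate_of(2.3, 46)
  r2 <- rate_of(2.3 * 2.12, 47)   # nicked template doubles the rate
  expect_lt(abs(r2 / r1 - 2.12) / 2.12, 0.1)
})
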
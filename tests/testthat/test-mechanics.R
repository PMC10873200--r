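perfect_cloud <- function(angle, n = 10, L = 100) {
  a <- angle / 2 * pi / 180
  s <- seq(0.1, 1, length.out = n) * L
  data.frame(frame = 1L, arm_label = rep(c("A", "B"), each = n),
             x = c(s * cos(a), s * cos(a)),
             y = c(s * sin(a), -s * sin(a)),
             z = 0)
}

test_that("arm-axis fit recovers exact apertures on perfect clouds", {
  expect_equal(fit_arm_axes(perfect_cloud(90))$angle_deg, 90, tolerance = 1e-9)
  for (th in c(20, 58.4, 120, 179))
    expect_equal(fit_arm_axes(perfect_cloud(th))$angle_deg, th,
                 tolerance = 1e-6)
  # collinear arms: hinge-outward convention gives 180 degrees
  expect_equal(fit_arm_axes(perfect_cloud(180))$angle_deg, 180,
               tolerance = 1e-6)
  expect_equal(unname(sqrt(sum(fit_arm_axes(perfect_cloud(90))$dir_a^2))), 1)
  bad <- perfect_cloud(90); bad$x <- 1; bad$y <- 2; bad$z <- 3
  expect_error(fit_arm_axes(bad), "degenerate")
})

test_that("noisy point clouds recover the angle within a degree", {
  at <- simulate_angle_trajectory(1e9, 58.4, 5, 100, seed = 31)  # stiff
  pc <- simulate_arm_point_clouds(at, arm_length = 100, points_per_arm = 50,
                                  noise_sd = 2, seed = 32)
  tr <- angle_trace(pc)
  err <- abs(tr$angles - attr(pc, "true_angles"))
  expect_lt(mean(err), 1)
  expect_lt(max(err), 3)
})

test_that("the aperture angle is invariant under rigid transformations", {
  pc <- perfect_cloud(58.4, n = 12)
  base <- fit_arm_axes(pc)$angle_deg
  set.seed(33)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rz %*% Rx
    shift <- runif(3, -50, 50)
    m <- as.matrix(pc[, c("x", "y", "z")]) %*% t(R)
    pc2 <- pc
    pc2$x <- m[, 1] + shift[1]; pc2$y <- m[, 2] + shift[2]
    pc2$z <- m[, 3] + shift[3]
    expect_equal(fit_arm_axes(pc2, hinge = shift)$angle_deg, base,
                 tolerance = 1e-9)
  }
})

test_that("equipartition recovers the generating spring constant", {
  # unit case: angular variance of ~1 rad^2 gives k ~ 1 kBT/rad^2
  tr <- structure(list(times = 1:1000,
                       angles = 70 + (180 / pi) * rep(c(-1, 1), 500),
                       temperature = 298, applied_torque = 0),
                  class = "angle_trajectory")
  v <- var(tr$angles * pi / 180)
  est <- spring_constant(tr)
  expect_equal(est$k_kbt, 1 / v, tolerance = 1e-12)
  expect_equal(est$k_kbt, 1, tolerance = 2e-3)
  # OU trajectory at k = 50: recovered within 5% on 1e5 frames
  at <- simulate_angle_trajectory(50, 70, 5, 1e5, seed = 34)
  k <- spring_constant(at)
  expect_lt(abs(k$k_kbt - 50), 2.5)
  expect_equal(k$k_pn_nm, k$k_kbt * 4.114, tolerance = 1e-9)
  expect_lt(abs(k$theta0_deg - 70), 1)
})

test_that("spring-constant error shrinks as the trajectory grows", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    at <- simulate_angle_trajectory(50, 70, 5, n, seed = 35)
    abs(spring_constant(at)$k_kbt - 50)
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3] / 50, 0.05)
})

test_that("applied torque shifts the OU equilibrium as k * delta", {
  delta <- 20 * pi / 180   # 20 degrees in radians
  at <- simulate_angle_trajectory(50, 70, 5, 2e4, torque = -50 * delta,
                                  seed = 36)
  expect_lt(abs(mean(at$angles) - 50), 1)
  # stiff limit: essentially constant at theta0
  stiff <- simulate_angle_trajectory(1e12, 70, 5, 1000, seed = 37)
  expect_lt(max(abs(stiff$angles - 70)), 1e-3)
})

test_that("rates are OLS slopes and normalisation preserves sign", {
  ramp <- structure(list(times = seq(0, 60, by = 1),
                         angles = seq(90, 30, length.out = 61),
                         temperature = 298, applied_torque = 0),
                    class = "angle_trajectory")
  expect_equal(open_close_rate(ramp), -1, tolerance = 1e-12)
  flat <- ramp; flat$angles <- rep(45, 61)
  expect_equal(open_close_rate(flat), 0, tolerance = 1e-12)
  expect_equal(open_close_rate(ramp, window = c(10, 30)), -1,
               tolerance = 1e-12)
  # reference replicates {-1, -1}: normalised median stays -1 (closing)
  expect_equal(median(normalize_rates(c(-1, -1), c(-1, -1))), -1)
  set.seed(38)
  ref <- -runif(6, 0.5, 1.5)
  expect_equal(abs(mean(normalize_rates(ref, ref))), 1, tolerance = 1e-12)
})
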
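test_that("proximity ratio arithmetic and clamping", {
  tr <- list(donor = rep(3000, 5), acceptor = rep(1000, 5),
             frame_interval = 0.1)
  expect_equal(compute_fret(tr)$efficiency, rep(0.25, 5))
  tr2 <- list(donor = c(500, 500), acceptor = c(500, 500),
              frame_interval = 0.1)
  expect_equal(compute_fret(tr2)$efficiency, c(0.5, 0.5))
  # negative donor overshoot clamps to [0, 1]; zero total undefined
  tr3 <- list(donor = c(-100, 0), acceptor = c(300, 0), frame_interval = 1)
  e <- compute_fret(tr3)$efficiency
  expect_equal(e[1], 1)
  expect_true(is.na(e[2]))
  expect_error(compute_fret(list(donor = numeric(0), acceptor = numeric(0))),
               "empty")
})

test_that("rendered open-state mean efficiency recovers the generator level", {
  p <- quiet_params(noise_sd = 0.05, E_low = 0.25)
  traj <- simulate_state_trajectory(p, 0, 1000, seed = 5)  # stalled open
  fl <- render_fluorescence(traj, p, seed = 6)
  e <- compute_fret(fl)$efficiency
  expect_equal(length(e), 10000L)
  expect_lt(abs(mean(e) - 0.25), 0.01)
})

test_that("donor and acceptor conserve total intensity before bleaching", {
  p <- quiet_params()
  traj <- simulate_state_trajectory(p, 1, 100, seed = 8)
  fl <- render_fluorescence(traj, p, seed = 9)
  expect_equal(fl$donor + fl$acceptor, rep(p$total_intensity, length(fl$donor)),
               tolerance = 1e-12)
})

test_that("Foerster conversion: midpoint, frozen value, inverse pair", {
  expect_equal(fret_to_distance(0.5, 54), 54)
  # R = R0 (1/E - 1)^(1/6) at E = 0.25, R0 = 54: 54 * 3^(1/6)
  expect_equal(fret_to_distance(0.25, 54), 64.86, tolerance = 1e-3)
  ee <- seq(0.05, 0.95, by = 0.05)
  expect_equal(distance_to_fret(fret_to_distance(ee, 54), 54), ee,
               tolerance = 1e-9)
  rr <- seq(20, 120, by = 5)
  expect_equal(fret_to_distance(distance_to_fret(rr, 54), 54), rr,
               tolerance = 1e-9)
  # strictly decreasing in E
  expect_true(all(diff(fret_to_distance(ee, 54)) < 0))
  expect_error(fret_to_distance(1, 54), "inside")
  expect_error(fret_to_distance(0, 54), "inside")
})

test_that("photobleach steps are found at the injected frame", {
  tr <- inject_acceptor_bleach(static_trace(E = 0.25, noise = 0.05, seed = 2),
                               700)
  pb <- detect_photobleach(tr)
  expect_lte(abs(pb$acceptor_bleach_frame - 700), 2)
  expect_identical(pb$n_steps_acceptor, 1L)
  # a constant noisy trace has no bleach
  pb0 <- detect_photobleach(static_trace(E = 0.25, noise = 0.05, seed = 3))
  expect_true(is.na(pb0$acceptor_bleach_frame))
  expect_identical(pb0$n_steps_acceptor, 0L)
  expect_true(is.na(pb0$donor_bleach_frame))
})

test_that("a two-step acceptor cascade is counted and rejected by QC", {
  tr <- static_trace(E = 0.25, noise = 0.03, seed = 4)
  # aggregate-like: half the acceptor dies at 400, the rest at 700
  tr$acceptor[400:1000] <- tr$acceptor[400:1000] - 125
  tr$donor[400:1000] <- tr$donor[400:1000] + 125
  tr <- inject_acceptor_bleach(tr, 700)
  pb <- detect_photobleach(tr)
  expect_identical(pb$n_steps_acceptor, 2L)
  expect_false(qc_trace(tr)$accepted)
  expect_true("acceptor_bleach_steps" %in% qc_trace(tr)$reasons)
})

test_that("QC applies the frame-count, SNR and single-bleach criteria", {
  # 99 usable frames -> rejected with reason min_frames
  short <- static_trace(E = 0.25, noise = 0.02, n = 120, seed = 5)
  short <- inject_acceptor_bleach(short, 100)
  qc <- qc_trace(short)
  expect_false(qc$accepted)
  expect_true("min_frames" %in% qc$reasons)
  # noise-free trace with one clean bleach: infinite SNR, accepted
  clean <- inject_acceptor_bleach(static_trace(E = 0.25, noise = 0, seed = 6),
                                  700)
  qc2 <- qc_trace(clean)
  expect_identical(qc2$snr, Inf)
  expect_true(qc2$accepted)
  expect_identical(qc2$reasons, character(0))
  # heavy noise pushes SNR below 1.5 -> rejected
  noisy <- inject_acceptor_bleach(
    static_trace(E = 0.25, noise = 0.7, seed = 7), 700)
  qc3 <- qc_trace(noisy)
  expect_lt(qc3$snr, 1.5)
  expect_true("snr" %in% qc3$reasons)
})

test_that("donor bleach collapses both channels and is classified as donor", {
  tr <- static_trace(E = 0.25, noise = 0.05, seed = 8)
  tr$acceptor[600:1000] <- tr$acceptor[600:1000] - 250
  tr$donor[600:1000] <- tr$donor[600:1000] - 750
  pb <- detect_photobleach(tr)
  expect_lte(abs(pb$donor_bleach_frame - 600), 3)
  expect_identical(pb$n_steps_acceptor, 0L)
})
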
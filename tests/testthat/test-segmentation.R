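# thresholds placed just off the generating FRET levels so that linear
# transition ramps are recovered at (nearly) their full extent
tight <- function(fret) segment_cycles(fret, low_exit = 0.25,
                                       high_enter = 0.65,
                                       high_exit = 0.65, low_enter = 0.25)

test_that("noise-free round trip recovers the generating dwell times", {
  p <- quiet_params()
  traj <- simulate_state_trajectory(p, 1, 400, seed = 71)
  seg <- tight(compute_fret(render_fluorescence(traj, p, seed = 72)))
  truth <- state_dwells(traj)
  truth <- truth[-c(1, nrow(truth)), ]              # censored edges
  comp <- seg$components[!seg$components$censored, ]
  expect_equal(nrow(comp), nrow(truth))
  map <- c(OPEN = "O", CLOSING = "tC", CLOSED = "C", OPENING = "tO")
  expect_identical(unname(map[truth$state]), comp$component)
  # recovered durations match generating segment times to ~2 frames
  err <- abs(comp$duration_s - truth$duration)
  expect_lt(stats::median(err), 0.15)
  expect_lt(max(err), 0.35)
})

test_that("component durations partition the analysed span exactly", {
  for (s in 1:5) {
    p <- engine_params(noise_sd = 0.12, bleach_rate_donor = 0,
                       bleach_rate_acceptor = 0)
    traj <- simulate_state_trajectory(p, 1, 150, seed = 80 + s)
    fr <- compute_fret(render_fluorescence(traj, p, seed = 90 + s))
    seg <- segment_cycles(fr)
    span <- (length(fr$efficiency) - seg$first_frame + 1L) *
      fr$frame_interval
    expect_equal(sum(seg$components$duration_s), span, tolerance = 1e-9)
  }
})

test_that("a static low-FRET trace yields one censored open dwell, no cycles", {
  fr <- compute_fret(static_trace(E = 0.2, noise = 0.02, seed = 12))
  seg <- segment_cycles(fr)
  expect_identical(nrow(seg$components), 1L)
  expect_identical(seg$components$component, "O")
  expect_true(seg$components$censored)
  expect_identical(nrow(seg$cycles), 0L)
})

test_that("segmentation is idempotent on its own reconstruction", {
  p <- quiet_params()
  traj <- simulate_state_trajectory(p, 1, 300, seed = 73)
  fr <- compute_fret(render_fluorescence(traj, p, seed = 74))
  seg1 <- segment_cycles(fr)
  # rebuild an idealised efficiency trace from the segmentation
  lev <- c(O = 0.2, C = 0.7)
  e <- numeric(length(seg1$frame_component))
  comp <- seg1$components
  for (i in seq_len(nrow(comp))) {
    ix <- (comp$start_frame[i]:comp$end_frame[i]) - seg1$first_frame + 1L
    e[ix] <- switch(comp$component[i],
      O = 0.2, C = 0.7,
      tC = seq(0.2, 0.7, length.out = length(ix)),
      tO = seq(0.7, 0.2, length.out = length(ix)))
  }
  fr2 <- structure(list(times = fr$times, efficiency = e,
                        frame_interval = fr$frame_interval,
                        bleach_frame = NA, trace_id = "recon"),
                   class = "fret_trace")
  seg2 <- segment_cycles(fr2)
  expect_identical(seg2$components$component, seg1$components$component)
  expect_true(all(abs(seg2$components$start_frame -
                      seg1$components$start_frame) <= 1))
})

test_that("raising NTP shortens tau_O and tau_t-C but not tau_C or tau_t-O", {
  s1 <- summarize_cycles(segmented_ensemble(1, 12, 220, seed0 = 700), "1")
  s5 <- summarize_cycles(segmented_ensemble(5, 12, 220, seed0 = 800), "5")
  a <- s1$summary; b <- s5$summary
  expect_gt(a$mean_tau_o_s, b$mean_tau_o_s)
  expect_gt(a$mean_tau_tc_s, b$mean_tau_tc_s)
  # directionally consistent with 9.5 -> 5.1 s and 1.3 -> 0.7 s
  expect_gt(a$mean_tau_o_s / b$mean_tau_o_s, 1.3)
  expect_gt(a$mean_tau_tc_s / b$mean_tau_tc_s, 1.2)
  # NTP-independent stages agree within ensemble noise
  expect_lt(abs(a$mean_tau_c_s - b$mean_tau_c_s) / a$mean_tau_c_s, 0.2)
  expect_lt(abs(a$mean_tau_to_s - b$mean_tau_to_s) / a$mean_tau_to_s, 0.25)
})

test_that("threshold ordering is validated", {
  fr <- compute_fret(static_trace(E = 0.2, n = 50, seed = 1))
  expect_error(segment_cycles(fr, low_exit = 0.6, high_enter = 0.5),
               "low_exit < high_enter")
  expect_error(segment_cycles(fr, low_exit = 1.2), "inside")
})
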
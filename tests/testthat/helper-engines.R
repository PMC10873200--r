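# Shared fixture builders: everything is generated in code at test time.

quiet_params <- function(...) {
  args <- utils::modifyList(
    list(noise_sd = 0, bleach_rate_donor = 0, bleach_rate_acceptor = 0),
    list(...))
  do.call(engine_params, args)
}

# static single-state trace at a fixed proximity ratio
static_trace <- function(E = 0.25, n = 1000, noise = 0, I = 1000, seed = 1,
                         frame_interval = 0.1) {
  set.seed(seed)
  a <- rep(E * I, n) + stats::rnorm(n, 0, noise * I)
  d <- rep((1 - E) * I, n) + stats::rnorm(n, 0, noise * I)
  structure(list(trace_id = "static", frame_interval = frame_interval,
                 donor = d, acceptor = a),
            class = "fluorescence_trace")
}

# inject an instantaneous acceptor bleach (acceptor drops to background,
# donor recovers the transferred intensity; noise retained)
inject_acceptor_bleach <- function(trace, frame) {
  n <- length(trace$acceptor)
  ix <- frame:n
  level <- mean(trace$acceptor[ix])
  trace$donor[ix] <- trace$donor[ix] + level
  trace$acceptor[ix] <- trace$acceptor[ix] - level
  trace
}

# ensemble of segmented traces at one NTP concentration
segmented_ensemble <- function(conc, n_traces, duration, params = NULL,
                               seed0 = 0) {
  if (is.null(params)) params <- engine_params(
    noise_sd = 0.1, bleach_rate_donor = 0, bleach_rate_acceptor = 0)
  lapply(seq_len(n_traces), function(i) {
    traj <- simulate_state_trajectory(params, conc, duration,
                                      seed = seed0 + i)
    segment_cycles(compute_fret(
      render_fluorescence(traj, params, seed = seed0 + 100000L + i)))
  })
}
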
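#!/usr/bin/env Rscript
# Stage 1: generate the synthetic smFRET ensembles used by the later
# stages — 1 mM and 5 mM NTP conditions plus a 0.1 mM ensemble with
# abortive excursions — and write them as tidy CSV under results/.

suppressPackageStartupMessages(library(nanopulse))
seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

p <- engine_params(noise_sd = 0.1, bleach_rate_donor = 0,
                   bleach_rate_acceptor = 0)
message("Engine parameters (open dwell 9.5 s at 1 mM, 5.1 s at 5 mM):")
print(p)

for (conc in c(1, 5)) {
  traces <- lapply(1:40, function(i) {
    traj <- simulate_state_trajectory(p, conc, 220, seed = seed + conc * 1000L + i)
    render_fluorescence(traj, p, seed = seed + conc * 1000L + 500L + i,
                        trace_id = sprintf("ntp%g_%03d", conc, i))
  })
  f <- file.path(out, sprintf("traces_%gmM.csv", conc))
  write_traces_csv(traces, f)
  message(sprintf("wrote %s (%d traces x 220 s)", f, length(traces)))
}

pa <- engine_params(noise_sd = 1 / (3 * sqrt(2)), abort_rate = 0.13,
                    bleach_rate_donor = 0, bleach_rate_acceptor = 0)
ab_traces <- lapply(1:50, function(i) {
  traj <- simulate_state_trajectory(pa, 0.1, 30, seed = seed + 9000L + i)
  render_fluorescence(traj, pa, seed = seed + 9500L + i,
                      trace_id = sprintf("ntp0.1_%03d", i))
})
f <- file.path(out, "traces_0.1mM_abortive.csv")
write_traces_csv(ab_traces, f)
message(sprintf("wrote %s (long open dwells, Poisson aborts at 0.13/s)", f))
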
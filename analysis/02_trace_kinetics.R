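#!/usr/bin/env Rscript
# Stage 2: segment the simulated smFRET ensembles into four-phase cycles,
# fit dwell (double-exponential) and transition (gamma) distributions per
# NTP condition, and detect abortive excursions in the 0.1 mM ensemble.
# Expects the CSVs from 01_simulate_traces.R under results/.

suppressPackageStartupMessages(library(nanopulse))
out <- "results"

all_segs <- list(); conds <- character(0)
for (conc in c(1, 5)) {
  traces <- read_traces_csv(file.path(out, sprintf("traces_%gmM.csv", conc)))
  segs <- lapply(traces, function(tr) segment_cycles(compute_fret(tr)))
  write_segments_csv(segs, file.path(out, sprintf("segments_%gmM.csv", conc)))
  all_segs <- c(all_segs, segs)
  conds <- c(conds, rep(sprintf("%g mM", conc), length(segs)))
}

cs <- summarize_cycles(all_segs, conds)
print(cs)
write.csv(cs$summary, file.path(out, "cycle_stats.csv"), row.names = FALSE)

dt <- dwell_table(all_segs, conds)
dt <- dt[!dt$censored, ]
fits <- lapply(split(dt, dt$condition), function(g) {
  lapply(c(O = "O", tC = "tC", C = "C", tO = "tO"), function(comp) {
    d <- g$duration_s[g$component == comp & g$duration_s > 0]
    if (length(d) < 10) return(NULL)
    if (comp %in% c("O", "C")) {
      f <- fit_double_exponential(d)
      list(model = "double_exponential", A1 = f$A1, tau1 = f$tau1,
           A2 = f$A2, tau2 = f$tau2, weighted_mean = f$weighted_mean, n = f$n)
    } else {
      f <- fit_gamma(d)
      list(model = "gamma", shape = f$shape, rate = f$rate, mean = f$mean,
           n = f$n)
    }
  })
})
jsonlite::write_json(fits, file.path(out, "kinetics_fits.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
for (cond in names(fits)) {
  f <- fits[[cond]]
  message(sprintf("%s: tau_O %.2f s, tau_t-C %.2f s, tau_C %.2f s, tau_t-O %.2f s",
                  cond, f$O$weighted_mean, f$tC$mean, f$C$weighted_mean,
                  f$tO$mean))
}
message(sprintf("elongation-rate bounds from tau_t-C at 1 mM: %.1f-%.1f nt/s",
                estimate_elongation_rate(89, 110, fits[["1 mM"]]$tC$mean)[1],
                estimate_elongation_rate(89, 110, fits[["1 mM"]]$tC$mean)[2]))

# abortive excursions in the low-NTP ensemble
ab_traces <- read_traces_csv(file.path(out, "traces_0.1mM_abortive.csv"))
ev <- 0L; open_s <- 0
for (tr in ab_traces) {
  ab <- detect_abortive_events(compute_fret(tr))
  ev <- ev + ab$n_events; open_s <- open_s + ab$open_time_s
}
message(sprintf("abortive events: %d over %.0f s open time -> %.3f /s",
                ev, open_s, ev / open_s))
write.csv(data.frame(n_events = ev, open_time_s = open_s,
                     rate_per_s = ev / open_s),
          file.path(out, "abortive_rate.csv"), row.names = FALSE)
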
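# nanopulse

Quantitative analysis of a chemically fuelled, pulsating DNA-origami
**leaf-spring nanoengine** — an origami device whose two stiff arms,
joined by a compliant hinge, are pulled closed by an anchored T7 RNA
polymerase transcribing a tethered template and reopened by the spring
when the polymerase releases. The package is aimed at single-molecule
biophysicists who want a reproducible, scriptable version of the
analyses such devices require, with seeded synthetic-data generators
standing in for every wet-lab and coarse-grained-simulation input.

## What it computes

- **smFRET trace analysis** — proximity-ratio FRET efficiency
  (E = A/(A+D)), quality control (SNR > 1.5, ≥ 100 frames, single-step
  acceptor bleaching), photobleach step detection, and a deterministic
  dual-threshold hysteresis segmentation of each pulsation into the four
  components τ_O (open dwell), τ_t-C (closing transition), τ_C (closed
  dwell), τ_t-O (opening transition), plus detection of abortive
  transcription excursions to the intermediate FRET level.
- **Dwell-time kinetics** — maximum-likelihood double-exponential
  mixture fits of dwell times, summarised by the amplitude-weighted
  average A₁τ₁ + A₂τ₂; gamma fits (Δt)^(N−1) e^(−kΔt) of transition
  times; cycle statistics; elongation-rate bounds from τ_t-C.
- **Fuel dependence** — a saturation law τ(c) = τ∞(1 + K/c) calibrated
  exactly through two measured dwell means (9.5 s at 1 mM → 5.1 s at
  5 mM NTP), with stalling at zero fuel.
- **Angle-distribution statistics** — 3°-bin relative histograms, box
  statistics (type-7 quantiles, 1.5 IQR whiskers), two-tailed Welch
  t-tests (from raw samples *or* printed summary statistics, with
  log-scale tail evaluation accurate down to p ~ 1e-300) and two-sample
  Kolmogorov–Smirnov comparisons.
- **Mechanics** — total-least-squares arm-axis fits on labelled point
  clouds, per-frame aperture angles, equipartition torsional spring
  constants k = 1/var(θ) (k_BT rad⁻², converted to pN nm rad⁻²), and
  opening/closing rates normalised to a reference design.
- **Bulk transcription** — molecular-beacon calibration, automatic
  linear-growth-phase detection, absolute rates in
  transcripts min⁻¹ engine⁻¹ and relative-rate tables.
- **Synthetic data** — seeded generators for all of the above:
  stochastic four-state engine cycles with Poisson abortive excursions
  and photobleaching, rendered donor/acceptor traces,
  Ornstein–Uhlenbeck angle fluctuations, arm point clouds, skew-normal
  TEM-like angle samples, and beacon fluorescence time courses.

## Worked example

Simulate an ensemble at 1 mM NTP, segment it, and fit the kinetics:

```r
library(nanopulse)

p <- engine_params(noise_sd = 0.1, bleach_rate_donor = 0,
                   bleach_rate_acceptor = 0)
segs <- lapply(1:40, function(i) {
  traj <- simulate_state_trajectory(p, ntp_schedule = 1, duration = 220,
                                    seed = 1000 + i)
  segment_cycles(compute_fret(render_fluorescence(traj, p, seed = 1500 + i)))
})
summarize_cycles(segs, "1 mM")
```

```
 condition n_molecules n_cycles mean_tau_cycle_s sd_tau_cycle_s mean_tau_o_s
      1 mM          40      453         16.70442      10.824147     9.139956
 mean_tau_tc_s mean_tau_c_s mean_tau_to_s
     1.0909492     5.598896     0.8746137
```

The mean cycle time (16.7 s here) and the component means recover the
generating kinetics (open dwell 9.5 s, closing 1.3 s); at 5 mM the same
pipeline yields ~12.1 s cycles with τ_O → 5.0 s while τ_C and τ_t-O are
unchanged — the signature of fuel acting on initiation and elongation
only. Welch comparisons recomputed from reported group summaries:

```r
welch_from_summary(40, 1.00, 0.12, 14, 2.12, 0.69)$p      # 3.80e-05
welch_from_summary(5135, 64.13, 20.04, 3266, 56.51, 21.79)$p  # 2.53e-57
```

The repository's `analysis/` directory holds five numbered driver
scripts (simulation → trace kinetics → angle statistics → mechanics →
bulk rates) that run the full workflow and write tables under
`results/`:

```sh
Rscript analysis/01_simulate_traces.R
Rscript analysis/02_trace_kinetics.R   # ... through 05_bulk_rates.R
```

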
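---
title: "Models and methods behind the nanopulse pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the nanopulse pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopulse)
```

# The system

A leaf-spring nanoengine is a DNA-origami device: two stiff arms joined
by a compliant hinge, with a T7 RNA polymerase anchored to one arm and a
transcribable double-stranded template tethered between the arms.
Transcription reels the template in and pulls the arms closed against
the spring; when the polymerase terminates and releases, the stored
elastic energy reopens the device. With donor and acceptor dyes on the
two arms, the pulsation is visible as repeated transitions of the FRET
efficiency between a low open-state level (E around 0.2) and a high
closed-state level (E around 0.7), with occasional brief excursions to
an intermediate level (around 0.4) when initiation aborts before
entering elongation.

`nanopulse` implements the quantitative analysis of this machine as a
reproducible pipeline over synthetic data: a seeded generator for every
input the analysis consumes, and the estimators that turn those inputs
into kinetic, statistical and mechanical summaries.

# The cycle model and its parameterisation

Each pulsation is decomposed into four stages with their own time
constants: the open dwell tau_O (waiting for initiation), the closing
transition tau_t-C (active transcription), the closed dwell tau_C
(termination), and the opening transition tau_t-O (spring relaxation).

The generator draws open dwells from an exponential distribution and
transition times from gamma distributions (default shape 4), matching
the distribution families used to fit the measured dwell and transition
times: a single rate-limiting step for initiation, several sequential
sub-steps for the mechanically complex transitions. Closed dwells are
exponential.

**NTP dependence.** The only quantitative statement available about fuel
dependence is a pair of dwell means per stage (9.5 s at 1 mM vs 5.1 s at
5 mM for tau_O; 1.3 s vs 0.7 s for tau_t-C). We adopt a single-substrate
saturation law

$$\tau(c) = \tau_\infty\,(1 + K/c),$$

which stalls as c goes to 0 and saturates at high fuel, and calibrate
(tau_inf, K) exactly through the two printed points
(`calibrate_saturation()`): tau_inf = 4.0 s, K = 1.375 mM for the open
dwell; tau_inf = 0.55 s, K = 1.36 mM for the closing transition. The law
is a modelling choice, not an asserted mechanism; K is calibrated, never
taken from literature.

**Closed dwell and opening transition.** These stages are
NTP-independent (termination and spring relaxation). The printed
component means do not quite add up to the printed cycle means at both
concentrations simultaneously (9.5 + 1.3 leaves 7.6 s of cycle at 1 mM
but 5.1 + 0.7 leaves 6.1 s at 5 mM, while the two NTP-independent stages
should contribute equally). The defaults tau_C = 5.9 s and tau_t-O =
1.0 s were chosen once to place both simulated cycle means inside the
printed 18.4 +/- 2 s and 11.9 +/- 2 s bands under exact
NTP-independence; this is the package's resolution of that arithmetic
tension and is not revisited per analysis.

**Abortive excursions** are modelled as a Poisson process active only in
the open state with fuel present, producing rectangular excursions to
the intermediate FRET level with exponentially distributed durations
(mean 0.5 s). Only their frequency is constrained by measurement
(0.13 per second of open time at 0.1 mM); the duration scale is a
modelling choice on the order of the observed blips.

**Stalling.** At 0 mM the machine freezes in whatever state it occupies,
including partially completed transitions. Internally each stage
consumes a unit-mean "work" clock at a speed equal to the reciprocal of
the stage's mean duration at the prevailing concentration, so fuel
switches rescale the remaining stage time and a switch to zero freezes
it. This reproduces the fuel-switch experiments: static, then dynamic,
then halted in either state.

**Rendering.** Per frame (default 0.1 s, matching the 100-ms camera
interval), acceptor = E x I and donor = (1 - E) x I with E constant in
dwell states and ramping linearly in completed work across transitions
(the observed transitions are gradual and monotone; no finer model is
justified by the data). Gaussian noise is added per channel as a
fraction of the total intensity (default 0.15, which reproduces the
printed width of the open-state FRET histogram). Photobleaching is
single-step and exponential in time per dye; after acceptor bleach the
donor recovers the transferred intensity, after donor bleach both
channels fall to background. Bleaching truncates analysis downstream; it
is not modelled kinetically.

# Trace analysis

**Efficiency** is the uncorrected proximity ratio A / (A + D), clamped
to [0, 1]; no gamma or cross-talk correction is applied because no
correction factors are available. Frames with non-positive total
intensity are undefined and excluded.

**Quality control** follows the trace-selection rules used for the
measured data: at least 100 usable frames, signal-to-noise ratio above
1.5 (mean pre-bleach total intensity minus post-bleach baseline, over
the detrended noise SD), and exactly one acceptor bleach step.
Step detection compares window means on either side of each frame
against five times the noise SD of the median-filtered channel. Because
FRET transitions also step the acceptor channel, a candidate step only
counts as bleaching if it is irreversible and leaves the proximity
ratio at background rather than at the open-state level — this is the
reproducible replacement for what is visually obvious to a human
scorer.

**Segmentation.** The measured traces were segmented by visual
inspection; this package defines a deterministic equivalent. A 3-frame
median filter is followed by dual-threshold hysteresis: a low phase ends
only when E reaches `high_enter` (default 0.55) and a high phase only
when E falls to `low_enter` (default 0.35) — midway between the two
state levels, robust to their printed SDs — so abortive excursions never
split an open dwell. Phases shorter than 3 frames are merged. Each phase
junction is then refined into dwell + transition: the transition extent
is measured between the threshold crossings and extrapolated linearly
out to each phase's own median level, so a linear ramp is recovered at
its full duration rather than only its inter-threshold middle. Every
analysed frame belongs to exactly one component; the partition is exact
by construction. Leading and trailing dwells are censored and excluded
from fits, matching the per-trace visual analysis (no survival
correction is attempted).

**Abortive-event detection** looks for runs inside the intermediate
band (default [0.30, 0.55]) within open dwells that return to the open
level. At realistic noise the per-frame efficiency noise is comparable
to the 0.2 separation between the open and abortive levels, so any
detector must trade missed short events against noise-induced runs. The
detector therefore adapts its median-filter width and minimum run
length to the estimated per-frame noise (from the differenced
open-state efficiency); the tier boundaries were calibrated on
synthetic traces so that the recovered event rate stays approximately
unbiased from noise-free rendering up to a total-intensity SNR of 3.
Consequences worth knowing: individual event boundaries are unreliable
at high noise even though the rate is well estimated, and events much
shorter than two frames are never recoverable.

**Dwell-time fits.** Open and closed dwells are fitted with a
two-component exponential mixture by direct maximum likelihood (five
dispersed, seeded restarts; components ordered tau1 <= tau2), summarised
by the amplitude-weighted average A1 tau1 + A2 tau2. If the mixture
fails to improve the log-likelihood by more than 2 units over a single
exponential, the fit collapses to the one-component MLE — this keeps the
weighted mean equal to the sample mean in the single-exponential regime
instead of reporting an arbitrary split. Transition times are fitted
with a gamma distribution by MLE; the shape is continuous because
nothing constrains it to integers.

# Angle-distribution statistics

TEM-like angle samples are compared with the conventions used for the
measured populations: relative histograms in fixed 3-degree bins
(percentages of total), box statistics with type-7 quantiles and
1.5 IQR whiskers clipped to the data (the quantile convention is
declared here because none was stated and Q1/Q3 feed whisker
placement), a two-tailed heteroscedastic (Welch) t-test, and a
two-sample Kolmogorov-Smirnov test. The Welch p-value is evaluated
through the log survival function of the t distribution: the measured
comparisons sit at p around 1e-57 to 1e-64, where a naive CDF
underflows. The summary-statistics interface (`welch_from_summary()`)
is the primary route because the reported group summaries are the only
recoverable input for the wet-lab comparisons; it is algebraically
identical to the raw-sample route. Angles outside [0, 180] degrees are
rejected as errors, not wrapped. The synthetic TEM sampler draws from a
skew-normal (truncated by rejection to the physical range), which
captures the long acute-angle tail that transcription produces.

# Mechanics

Arm axes are fitted to labelled point clouds by total least squares
(principal axis via SVD) rather than coordinate regression, which would
be biased for steeply oriented arms; directions are oriented outward
from the hinge, and the aperture is the angle between the outward
directions (never its supplement). The torsional spring constant comes
from the equipartition theorem, k = 1 / var(theta) with theta in
radians (radians are required for k_B T consistency and are used
throughout), reported in k_B T per rad^2 and converted to pN nm per
rad^2 with k_B T = 4.114 pN nm at 298 K. Equilibrium angle fluctuations
are generated as an exact-discretisation Ornstein-Uhlenbeck process
whose stationary variance is 1/k by construction; this is the
round-trip used to validate the estimator at k = 10, 50 and 200 k_B T
per rad^2.

Opening/closing rates are OLS slopes of angle versus time over a
configurable window (default the full driven segment; no regression
window was specified for the measured traces). Because coarse-grained
simulation time has no real-time correspondence, rates are only
reported relative to the mean rate of the reference design, signs
preserved (closing negative).

# Bulk transcription rates

Beacon fluorescence is calibrated against standards of known RNA amount
by least squares (the slope must be positive). The "linear growth
phase" is operationalised as the sliding window (default 20% of the
trace) with the largest slope among windows achieving R^2 >= 0.98, ties
broken earliest; per-trace windows are used since nothing indicates a
shared window across wells. The absolute rate is slope / calibration
slope / engine amount, in transcripts per minute per engine; negative
rates (photobleaching drift in template-free controls) are reported
as-is, never clipped. Rate estimates are exactly invariant to
fluorescence offset and linear in gain.

Two reported bulk calibrations coexist (one new transcript every
12 +/- 5 s at 2 mM, versus 2.3 +/- 0.8 transcripts per minute); the
package does not reconcile them. The generator default (2.3 per minute)
follows the per-minute estimate; the other is available by setting the
generating rate to 5.

# What the synthetic data do and do not establish

The generators reproduce the statistical structure the analyses assume:
two-state pulsing with finite ramps, NTP-dependent dwell means, Poisson
aborts, single-step bleaching, harmonic angle fluctuations, skewed
angle populations, and lag/linear/plateau beacon curves. They do not
emulate instrument-specific artefacts — cross-talk and gamma factors,
baseline drift, blinking, stage drift, non-Gaussian camera noise, or
polymerase heterogeneity between molecules. Passing round-trip tests
therefore demonstrates that the estimators are correct and unbiased
under the stated model, not that the model captures every property of
the measured data.

# Problem sizes and numerical choices

The shipped analyses and tests use ensembles of 35-50 traces of
200-300 s (a few hundred cycles per condition), 1e5-frame OU
trajectories for equipartition checks, and 1,000-dwell samples for
distribution fits; these sizes put the Monte-Carlo error of each
recovered quantity comfortably inside its assessment band. Mixture
fitting uses Nelder-Mead on (logit A, log tau1, log tau2) with five
seeded restarts; gamma fitting uses the standard MLE with analytic
moment-based initialisation. Degenerate inputs fail loudly: fewer than
10 uncensored dwells, zero angular variance, non-positive calibration
slopes, out-of-order segmentation thresholds and unknown pipeline
configuration keys are all errors, not warnings.

# Known limitations

- Censored dwells are dropped, not survival-corrected; with short
  traces this biases dwell means slightly low.
- Dual-threshold segmentation assigns a few frames of each ramp to the
  neighbouring dwells when transitions are much faster than the frame
  interval; at the studied frame rate this is a sub-frame effect.
- The abortive-event detector estimates rates, not event boundaries, at
  high noise (see above).
- The heat-map representation assigns one cell per trace per time bin
  (its median efficiency), so very fast switching within a bin
  registers at an intermediate level.
- The saturation law is exactly identified by two points; its
  extrapolation below 0.1 mM fuel is untested by construction.
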
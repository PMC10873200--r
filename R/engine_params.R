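#' Nanoengine cycle parameters
#'
#' Bundles every parameter of the pulsating leaf-spring nanoengine cycle:
#' stage dwell-time laws, FRET levels of the open/closed/abortive states,
#' NTP saturation constants, camera and noise settings, and photobleaching
#' rates. Defaults are calibrated so that the open dwell interpolates
#' 9.5 s at 1 mM NTP and 5.1 s at 5 mM, and the closing transition
#' interpolates 1.3 s and 0.7 s at the same concentrations.
#'
#' The open dwell and the closing-transition mean both follow the
#' single-substrate saturation law \eqn{\tau(c) = \tau_\infty (1 + K/c)}
#' (see [dwell_mean_at_ntp()]). The closed dwell and the opening transition
#' are NTP-independent: the closed dwell is set by polymerase termination
#' and the opening transition by the spring relaxation of the origami.
#'
#' @param tau_open_sat Saturated (high-NTP limit) open dwell, seconds.
#' @param K_ntp Half-saturation constant for the open dwell, mM.
#' @param tau_tc_sat Saturated closing-transition time, seconds.
#' @param K_tc Half-saturation constant for the closing transition, mM.
#' @param tau_closed Mean closed dwell, seconds (NTP-independent).
#' @param tau_to Mean opening-transition time, seconds (NTP-independent).
#' @param transition_shape Gamma shape of both transition-time
#'   distributions (continuous, >= 1).
#' @param E_low,E_high,E_abort FRET efficiencies of the open state, the
#'   closed state and the abortive intermediate; must satisfy
#'   `0 <= E_low < E_abort < E_high <= 1`.
#' @param abort_rate Poisson rate of abortive excursions, events per second
#'   of open-state time (active only in the open state and only at
#'   non-zero NTP).
#' @param abort_duration Mean duration of an abortive excursion, seconds
#'   (exponentially distributed).
#' @param frame_interval Camera frame interval, seconds.
#' @param noise_sd Per-channel additive Gaussian noise, as a fraction of
#'   `total_intensity`.
#' @param bleach_rate_donor,bleach_rate_acceptor Photobleaching rates of
#'   the two dyes, per second (0 disables bleaching).
#' @param total_intensity Total (donor + acceptor) emission intensity,
#'   arbitrary units.
#'
#' @return An object of class `engine_params` (a validated list).
#' @examples
#' p <- engine_params()
#' dwell_mean_at_ntp(p$tau_open_sat, p$K_ntp, 1)  # 9.5 s
#' @export
engine_params <- function(tau_open_sat = 4.0,
                          K_ntp = 1.375,
                          tau_tc_sat = 0.55,
                          K_tc = 15 / 11,
                          tau_closed = 5.9,
                          tau_to = 1.0,
                          transition_shape = 4,
                          E_low = 0.2,
                          E_high = 0.7,
                          E_abort = 0.4,
                          abort_rate = 0,
                          abort_duration = 0.5,
                          frame_interval = 0.1,
                          noise_sd = 0.15,
                          bleach_rate_donor = 0.001,
                          bleach_rate_acceptor = 0.002,
                          total_intensity = 1000) {
  p <- list(
    tau_open_sat = tau_open_sat, K_ntp = K_ntp,
    tau_tc_sat = tau_tc_sat, K_tc = K_tc,
    tau_closed = tau_closed, tau_to = tau_to,
    transition_shape = transition_shape,
    E_low = E_low, E_high = E_high, E_abort = E_abort,
    abort_rate = abort_rate, abort_duration = abort_duration,
    frame_interval = frame_interval, noise_sd = noise_sd,
    bleach_rate_donor = bleach_rate_donor,
    bleach_rate_acceptor = bleach_rate_acceptor,
    total_intensity = total_intensity
  )
  class(p) <- "engine_params"
  validate_engine_params(p)
}

validate_engine_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("tau_open_sat", "K_ntp", "tau_tc_sat", "K_tc", "tau_closed",
              "tau_to", "transition_shape", "abort_duration",
              "frame_interval", "total_intensity")) {
    if (!num1(p[[f]]) || p[[f]] <= 0)
      stop("engine_params: '", f, "' must be a single positive number",
           call. = FALSE)
  }
  for (f in c("abort_rate", "noise_sd", "bleach_rate_donor",
              "bleach_rate_acceptor")) {
    if (!num1(p[[f]]) || p[[f]] < 0)
      stop("engine_params: '", f, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (!(p$E_low >= 0 && p$E_low < p$E_abort && p$E_abort < p$E_high &&
        p$E_high <= 1))
    stop("engine_params: FRET levels must satisfy 0 <= E_low < E_abort < E_high <= 1",
         call. = FALSE)
  if (p$transition_shape < 1)
    stop("engine_params: 'transition_shape' must be >= 1", call. = FALSE)
  p
}

#' @export
print.engine_params <- function(x, ...) {
  cat("Nanoengine cycle parameters\n")
  cat(sprintf("  open dwell:  tau_sat = %.3g s, K = %.3g mM (9.5 s at 1 mM -> %.3g s)\n",
              x$tau_open_sat, x$K_ntp,
              dwell_mean_at_ntp(x$tau_open_sat, x$K_ntp, 1)))
  cat(sprintf("  closing:     tau_sat = %.3g s, K = %.3g mM, gamma shape %.3g\n",
              x$tau_tc_sat, x$K_tc, x$transition_shape))
  cat(sprintf("  closed dwell %.3g s; opening %.3g s\n", x$tau_closed, x$tau_to))
  cat(sprintf("  FRET levels: open %.2f, abort %.2f, closed %.2f\n",
              x$E_low, x$E_abort, x$E_high))
  cat(sprintf("  abort rate %.3g /s (mean %.3g s); frame %.3g s; noise %.3g\n",
              x$abort_rate, x$abort_duration, x$frame_interval, x$noise_sd))
  invisible(x)
}

#' Mean dwell time at a given NTP concentration
#'
#' Single-substrate saturation law \eqn{\tau(c) = \tau_\infty (1 + K/c)}:
#' the dwell diverges as fuel is exhausted (the engine stalls at 0 mM) and
#' approaches `tau_sat` at saturating NTP.
#'
#' @param tau_sat Saturated dwell time, seconds.
#' @param K Half-saturation constant, mM.
#' @param conc NTP concentration, mM (vectorised; 0 returns `Inf`).
#' @return Mean dwell in seconds, same length as `conc`.
#' @seealso [calibrate_saturation()] to fit `(tau_sat, K)` from two
#'   measured dwell means.
#' @examples
#' dwell_mean_at_ntp(4, 1.375, c(1, 5))  # 9.5, 5.1
#' @export
dwell_mean_at_ntp <- function(tau_sat, K, conc) {
  if (!is.numeric(tau_sat) || tau_sat <= 0 || !is.numeric(K) || K <= 0)
    stop("dwell_mean_at_ntp: 'tau_sat' and 'K' must be positive", call. = FALSE)
  if (any(conc < 0)) stop("dwell_mean_at_ntp: 'conc' must be >= 0", call. = FALSE)
  ifelse(conc == 0, Inf, tau_sat * (1 + K / conc))
}

#' Calibrate the saturation law from two dwell measurements
#'
#' Solves \eqn{\tau_i = a (1 + K/c_i)} exactly for `(a, K)` given two
#' (concentration, dwell) pairs, e.g. the measured open dwells 9.5 s at
#' 1 mM and 5.1 s at 5 mM.
#'
#' @param point1,point2 Numeric pairs `c(conc_mM, dwell_s)` at two distinct
#'   positive concentrations; the dwell must decrease with concentration.
#' @return List with elements `tau_sat` and `K`; both inputs round-trip
#'   exactly through [dwell_mean_at_ntp()].
#' @examples
#' calibrate_saturation(c(1, 9.5), c(5, 5.1))  # tau_sat 4, K 1.375
#' @export
calibrate_saturation <- function(point1, point2) {
  stopifnot(length(point1) == 2, length(point2) == 2)
  c1 <- point1[1]; t1 <- point1[2]
  c2 <- point2[1]; t2 <- point2[2]
  if (c1 <= 0 || c2 <= 0 || c1 == c2)
    stop("calibrate_saturation: need two distinct positive concentrations",
         call. = FALSE)
  if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- t1; t1 <- t2; t2 <- tmp }
  if (t1 <= t2)
    stop("calibrate_saturation: dwell must strictly decrease with concentration; ",
         "no saturation law fits (", t1, " s at ", c1, " mM vs ",
         t2, " s at ", c2, " mM)", call. = FALSE)
  # linear system in (a, b = a*K):  t = a + b/c
  b <- (t1 - t2) / (1 / c1 - 1 / c2)
  a <- t1 - b / c1
  if (a <= 0)
    stop("calibrate_saturation: implied saturated dwell is non-positive; ",
         "the pair is inconsistent with a saturation law", call. = FALSE)
  list(tau_sat = a, K = b / a)
}
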
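#' Render a donor/acceptor fluorescence trace from a state trajectory
#'
#' Converts a simulated state trajectory into per-frame Cy3/Cy5
#' intensities the way a TIRF camera would see them: per frame the
#' acceptor emits `E * I_total` and the donor `(1 - E) * I_total`, with
#' the FRET level constant within dwell states, ramping linearly across
#' transitions, and sitting at the intermediate level during abortive
#' excursions. Additive Gaussian noise (`noise_sd * I_total` per
#' channel) is applied. Photobleaching is single-step: after an
#' exponentially distributed acceptor bleach time the acceptor falls to
#' baseline and the donor recovers to the full intensity (FRET lost);
#' after donor bleach both channels fall to baseline.
#'
#' @param traj A `state_trajectory` from [simulate_state_trajectory()].
#' @param params An [engine_params()] object (camera/noise/bleach
#'   settings; defaults to the trajectory's own parameters).
#' @param seed Optional integer seed.
#' @param trace_id Identifier stored with the trace.
#' @return An object of class `fluorescence_trace`: list with
#'   `trace_id`, `frame_interval`, `donor`, `acceptor` and a `truth`
#'   attribute carrying generator bookkeeping (bleach frames and the
#'   noise-free FRET level per frame).
#' @examples
#' p <- engine_params(noise_sd = 0, bleach_rate_donor = 0, bleach_rate_acceptor = 0)
#' traj <- simulate_state_trajectory(p, 1, 50, seed = 2)
#' tr <- render_fluorescence(traj, seed = 3)
#' @export
render_fluorescence <- function(traj, params = traj$params, seed = NULL,
                                trace_id = "trace1") {
  stopifnot(inherits(traj, "state_trajectory"))
  validate_engine_params(params)
  if (!is.null(seed)) set.seed(seed)
  dt <- params$frame_interval
  n <- floor(traj$duration / dt)
  if (n < 1L) stop("render_fluorescence: duration shorter than one frame",
                   call. = FALSE)
  tm <- (seq_len(n) - 0.5) * dt  # frame midpoints

  seg <- traj$segments
  idx <- findInterval(tm, seg$t_start)
  idx[idx < 1L] <- 1L
  span <- seg$t_end[idx] - seg$t_start[idx]
  frac <- ifelse(span > 0, (tm - seg$t_start[idx]) / span, 0)
  e_true <- seg$e_start[idx] + frac * (seg$e_end[idx] - seg$e_start[idx])

  I <- params$total_intensity
  t_bleach_a <- if (params$bleach_rate_acceptor > 0)
    stats::rexp(1, params$bleach_rate_acceptor) else Inf
  t_bleach_d <- if (params$bleach_rate_donor > 0)
    stats::rexp(1, params$bleach_rate_donor) else Inf

  acceptor <- e_true * I
  donor <- (1 - e_true) * I
  a_bleached <- tm >= t_bleach_a
  acceptor[a_bleached] <- 0
  donor[a_bleached] <- I
  d_bleached <- tm >= t_bleach_d
  acceptor[d_bleached] <- 0
  donor[d_bleached] <- 0
  if (params$noise_sd > 0) {
    acceptor <- acceptor + stats::rnorm(n, 0, params$noise_sd * I)
    donor <- donor + stats::rnorm(n, 0, params$noise_sd * I)
  }

  frame_of <- function(tb) if (is.finite(tb) && tb < n * dt)
    findInterval(tb, (seq_len(n) - 1) * dt) else NA_integer_
  structure(list(trace_id = trace_id, frame_interval = dt,
                 donor = donor, acceptor = acceptor),
            truth = list(e_true = e_true,
                         acceptor_bleach_frame = frame_of(t_bleach_a),
                         donor_bleach_frame = frame_of(t_bleach_d)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("smFRET fluorescence trace '%s': %d frames at %.3g s/frame\n",
              x$trace_id, length(x$donor), x$frame_interval))
  invisible(x)
}
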
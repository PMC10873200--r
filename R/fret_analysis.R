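#' Compute a FRET efficiency trace from donor/acceptor intensities
#'
#' Uses the uncorrected proximity ratio
#' \eqn{E_t = A_t / (A_t + D_t)}, clamped to \[0, 1\]. No gamma or
#' cross-talk correction is applied. Frames with non-positive total
#' intensity are undefined (`NA`) and excluded downstream. If
#' `truncate_at_bleach` is `TRUE` the efficiency is only defined up to
#' the first detected photobleach.
#'
#' @param trace A `fluorescence_trace` (or list with `donor`,
#'   `acceptor`, `frame_interval`).
#' @param truncate_at_bleach Blank frames after the first detected
#'   photobleach event (requires >= 20 frames; default `FALSE`).
#' @return A `fret_trace`: list with `times` (s), `efficiency`,
#'   `frame_interval`, `bleach_frame` (`NA` if none/undetected) and
#'   `trace_id`.
#' @examples
#' tr <- list(donor = rep(3000, 5), acceptor = rep(1000, 5), frame_interval = 0.1)
#' compute_fret(tr)$efficiency  # all 0.25
#' @export
compute_fret <- function(trace, truncate_at_bleach = FALSE) {
  d <- trace$donor; a <- trace$acceptor
  if (length(d) == 0L || length(a) == 0L)
    stop("compute_fret: empty trace", call. = FALSE)
  if (length(d) != length(a))
    stop("compute_fret: donor and acceptor differ in length", call. = FALSE)
  tot <- d + a
  e <- ifelse(tot > 0, pmin(1, pmax(0, a / tot)), NA_real_)
  dt <- if (!is.null(trace$frame_interval)) trace$frame_interval else 1
  bleach <- NA_integer_
  if (truncate_at_bleach && length(d) >= 20L) {
    pb <- detect_photobleach(trace)
    bleach <- min(pb$acceptor_bleach_frame, pb$donor_bleach_frame,
                  na.rm = TRUE)
    if (!is.finite(bleach)) bleach <- NA_integer_
    if (!is.na(bleach) && bleach < length(e)) e[(bleach + 1L):length(e)] <- NA
  }
  structure(list(times = (seq_along(e) - 0.5) * dt, efficiency = e,
                 frame_interval = dt, bleach_frame = bleach,
                 trace_id = trace$trace_id),
            class = "fret_trace")
}

# Downward step detection in one channel: compare window means either
# side of each frame; a step qualifies when it exceeds 5x the noise SD
# of the median-filtered channel (frame noise reduced by the filter).
detect_steps_down <- function(x, w = 7L, k_sigma = 5) {
  n <- length(x)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (sigma == 0) sigma <- .Machine$double.eps
  sigma_f <- 1.25 * sigma / sqrt(2 * w - 1)  # SD after median filtering
  cs <- cumsum(c(0, x))
  i <- seq.int(w + 1L, n - w)
  after <- (cs[i + w + 1L] - cs[i + 1L]) / w
  before <- (cs[i + 1L] - cs[i - w + 1L]) / w
  step <- after - before
  cand <- i[step < -k_sigma * sigma_f]
  if (length(cand) == 0L)
    return(list(frames = integer(0), n_steps = 0L, sigma = sigma))
  # cluster candidates closer than the window into single events
  grp <- cumsum(c(TRUE, diff(cand) > w))
  frames <- vapply(split(seq_along(cand), grp), function(ix) {
    cand[ix][which.min(step[match(cand[ix], i)])]
  }, integer(1))
  list(frames = unname(frames), n_steps = length(frames), sigma = sigma)
}

#' Detect photobleaching steps in a fluorescence trace
#'
#' Scans each channel for abrupt downward intensity steps exceeding
#' five times the local noise standard deviation (estimated from
#' frame-to-frame differences). A candidate step only counts as a
#' bleach if it is irreversible (the channel never recovers afterwards)
#' and lands at background — this separates bleaching from FRET
#' transitions, which also step the acceptor down but land at the
#' open-state level and recur. Donor bleaching is detected on the total
#' intensity, which collapses when the donor dies. Single-step acceptor
#' bleaching is a trace-selection criterion; multiple qualifying
#' acceptor steps indicate aggregates and fail QC.
#'
#' @param trace A `fluorescence_trace` with >= 20 frames.
#' @param window Half-window (frames) for the before/after step
#'   contrast.
#' @return List with `acceptor_bleach_frame`, `donor_bleach_frame`
#'   (`NA` when absent), `n_steps_acceptor`, `n_steps_donor`.
#' @export
detect_photobleach <- function(trace, window = 5L) {
  n <- length(trace$donor)
  if (n < 20L)
    stop("detect_photobleach: need at least 20 frames", call. = FALSE)
  tot <- trace$donor + trace$acceptor
  i_tot <- stats::median(tot)
  w <- window

  qualify <- function(x, frames, sigma) {
    # bleaching is an irreversible cascade ending at background; FRET
    # transitions also step the acceptor down but either recover (the
    # next cycle) or leave the channel at the open-state level
    if (length(frames) == 0L) return(integer(0))
    f <- stats::runmed(x, 2L * (w %/% 2L) + 1L)
    sigma_f <- 1.25 * sigma / sqrt(2 * w - 1)
    irr <- frames[vapply(frames, function(fr) {
      before <- mean(x[seq.int(max(fr - w + 1L, 1L), fr)])
      after <- mean(x[seq.int(min(fr + 1L, n), min(fr + w, n))])
      aft <- seq.int(min(fr + w, n), n)
      # never recovers halfway (with a noise floor on the test level)
      max(f[aft]) < max((before + after) / 2, after + 4 * sigma_f)
    }, logical(1))]
    if (length(irr) == 0L) return(integer(0))
    tail_level <- stats::median(x[seq.int(min(max(irr) + w, n), n)])
    if (tail_level >= 0.15 * i_tot) return(integer(0))
    irr
  }

  st <- detect_steps_down(tot, w = w)
  donor_frames <- qualify(tot, st$frames, st$sigma)
  sa <- detect_steps_down(trace$acceptor, w = w)
  acc_frames <- qualify(trace$acceptor, sa$frames, sa$sigma)
  # a FRET transition into a terminal open dwell also steps the acceptor
  # down irreversibly, but leaves the proximity ratio at the open-state
  # level; after a true acceptor bleach the ratio sits at background
  if (length(acc_frames)) {
    nxt <- pmin(c(acc_frames[-1L], n), acc_frames + 10L * w)
    keep <- vapply(seq_along(acc_frames), function(k) {
      seg <- seq.int(min(acc_frames[k] + w, n), nxt[k])
      stats::median(trace$acceptor[seg] / pmax(tot[seg], 1e-12)) < 0.15
    }, logical(1))
    acc_frames <- acc_frames[keep]
  }
  # steps caused by the donor dying are not acceptor bleaches
  acc_frames <- acc_frames[vapply(acc_frames, function(f)
    !any(abs(donor_frames - f) <= w), logical(1))]
  list(acceptor_bleach_frame = if (length(acc_frames)) acc_frames[1L] else NA_integer_,
       donor_bleach_frame = if (length(donor_frames)) donor_frames[1L] else NA_integer_,
       n_steps_acceptor = length(acc_frames),
       n_steps_donor = length(donor_frames))
}

#' Quality-control a single-molecule trace
#'
#' Applies the trace-selection criteria used for smFRET analysis:
#' at least `min_frames` frames of usable signal before the first
#' bleach, a signal-to-noise ratio above `min_snr`, and exactly one
#' acceptor bleaching step. SNR is computed as (mean pre-bleach total
#' intensity minus post-bleach baseline) divided by the standard
#' deviation of the detrended noise.
#'
#' @param trace A `fluorescence_trace`.
#' @param min_snr Minimum SNR (default 1.5).
#' @param min_frames Minimum usable frames (default 100).
#' @param require_single_bleach Require exactly one acceptor bleach step
#'   (default `TRUE`).
#' @return A `qc_report`: list with `snr`, `n_frames`,
#'   `single_step_acceptor_bleach`, `accepted` and `reasons` (character
#'   vector of failed criteria, empty when accepted).
#' @export
qc_trace <- function(trace, min_snr = 1.5, min_frames = 100,
                     require_single_bleach = TRUE) {
  n_total <- length(trace$donor)
  pb <- if (n_total >= 20L) detect_photobleach(trace) else
    list(acceptor_bleach_frame = NA_integer_, donor_bleach_frame = NA_integer_,
         n_steps_acceptor = 0L, n_steps_donor = 0L)
  first_bleach <- suppressWarnings(
    min(pb$acceptor_bleach_frame, pb$donor_bleach_frame, na.rm = TRUE))
  n_frames <- if (is.finite(first_bleach)) first_bleach else n_total

  tot <- trace$donor + trace$acceptor
  pre <- tot[seq_len(max(n_frames, 2L))]
  baseline <- if (!is.na(pb$donor_bleach_frame) &&
                  pb$donor_bleach_frame < n_total)
    stats::median(tot[(pb$donor_bleach_frame + 2L):n_total]) else 0
  noise_sd <- stats::mad(diff(pre)) / sqrt(2)
  snr <- if (noise_sd > 0) (mean(pre) - baseline) / noise_sd else Inf

  single <- pb$n_steps_acceptor == 1L
  reasons <- character(0)
  if (n_frames < min_frames) reasons <- c(reasons, "min_frames")
  if (!(snr > min_snr)) reasons <- c(reasons, "snr")
  if (require_single_bleach && !single)
    reasons <- c(reasons, "acceptor_bleach_steps")
  structure(list(snr = snr, n_frames = n_frames,
                 single_step_acceptor_bleach = single,
                 accepted = length(reasons) == 0L, reasons = reasons),
            class = "qc_report")
}

#' Convert between FRET efficiency and inter-dye distance
#'
#' Standard Foerster relation \eqn{E = 1 / (1 + (R/R_0)^6)} and its
#' inverse \eqn{R = R_0 (1/E - 1)^{1/6}}, with `R0` the distance at
#' which half the donor excitations transfer (about 54 A for Cy3/Cy5).
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R Inter-dye distance, same units as `R0`.
#' @param R0 Foerster distance (default 54 A).
#' @return Distance (or efficiency), vectorised.
#' @examples
#' fret_to_distance(0.5, 54)  # 54
#' @export
fret_to_distance <- function(E, R0 = 54) {
  if (any(E <= 0 | E >= 1))
    stop("fret_to_distance: E must lie strictly inside (0, 1)", call. = FALSE)
  if (any(R0 <= 0)) stop("R0 must be > 0", call. = FALSE)
  R0 * (1 / E - 1)^(1 / 6)
}

#' @rdname fret_to_distance
#' @export
distance_to_fret <- function(R, R0 = 54) {
  if (any(R <= 0) || any(R0 <= 0))
    stop("distance_to_fret: R and R0 must be > 0", call. = FALSE)
  1 / (1 + (R / R0)^6)
}

#' Cumulative state-occupancy heat map of a trace ensemble
#'
#' Bins every trace's FRET level in time and efficiency, aligned at a
#' declared event (e.g. the moment of NTP addition), and counts one
#' molecule per (time-bin, efficiency-bin) cell using the trace's median
#' efficiency within the time bin. Column sums therefore equal the
#' number of traces still alive (unbleached, with defined frames) in
#' each time bin.
#'
#' @param fret_traces List of `fret_trace` objects.
#' @param e_breaks Efficiency bin breaks (default 20 bins over \[0, 1\]).
#' @param time_breaks Time bin breaks in seconds (default 30 bins over
#'   the ensemble span).
#' @param align_times Per-trace alignment offsets subtracted from each
#'   trace's times (scalar or vector, default 0).
#' @return Matrix of counts, rows = efficiency bins, columns = time
#'   bins, with informative dimnames.
#' @export
state_occupancy_heatmap <- function(fret_traces, e_breaks = seq(0, 1, 0.05),
                                    time_breaks = NULL, align_times = 0) {
  stopifnot(length(fret_traces) >= 1L)
  align_times <- rep_len(align_times, length(fret_traces))
  all_t <- unlist(lapply(seq_along(fret_traces), function(i)
    fret_traces[[i]]$times - align_times[i]))
  if (is.null(time_breaks))
    time_breaks <- seq(min(all_t), max(all_t), length.out = 31L)
  nb_e <- length(e_breaks) - 1L; nb_t <- length(time_breaks) - 1L
  counts <- matrix(0L, nrow = nb_e, ncol = nb_t,
                   dimnames = list(
                     efficiency = sprintf("[%.2f,%.2f)", e_breaks[-length(e_breaks)],
                                          e_breaks[-1]),
                     time = sprintf("[%.1f,%.1f)", time_breaks[-length(time_breaks)],
                                    time_breaks[-1])))
  for (i in seq_along(fret_traces)) {
    ft <- fret_traces[[i]]
    ok <- !is.na(ft$efficiency)
    tb <- findInterval(ft$times[ok] - align_times[i], time_breaks,
                       rightmost.closed = TRUE)
    e <- ft$efficiency[ok]
    for (b in unique(tb[tb >= 1L & tb <= nb_t])) {
      med <- stats::median(e[tb == b])
      eb <- min(max(findInterval(med, e_breaks, rightmost.closed = TRUE), 1L),
                nb_e)
      counts[eb, b] <- counts[eb, b] + 1L
    }
  }
  counts
}
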
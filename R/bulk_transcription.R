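#' Calibrate molecular-beacon fluorescence against known RNA amounts
#'
#' Least-squares line through (RNA amount, fluorescence) standards; the
#' slope converts fluorescence to RNA amount for rate extraction.
#'
#' @param standard_points data.frame with columns `rna_amount` and
#'   `fluorescence` (>= 2 distinct amounts).
#' @return An `mb_calibration`: list with `slope` (fluorescence per
#'   amount, must be > 0), `intercept`, `r_squared`, `residuals`.
#' @export
calibrate_mb <- function(standard_points) {
  s <- as.data.frame(standard_points)
  if (!all(c("rna_amount", "fluorescence") %in% names(s)))
    stop("calibrate_mb: need columns 'rna_amount' and 'fluorescence'",
         call. = FALSE)
  if (length(unique(s$rna_amount)) < 2L)
    stop("calibrate_mb: need at least 2 distinct RNA amounts", call. = FALSE)
  fit <- stats::lm(fluorescence ~ rna_amount, data = s)
  slope <- unname(stats::coef(fit)[2L])
  if (!(slope > 0))
    stop("calibrate_mb: calibration slope must be positive (got ",
         signif(slope, 3), ")", call. = FALSE)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 residuals = stats::residuals(fit)),
            class = "mb_calibration")
}

#' Locate the linear growth phase of a fluorescence time course
#'
#' Slides a window of `window_fraction` of the trace length and
#' returns the window with the largest positive slope among windows
#' whose linear fit achieves `R^2 >= r2_min`; ties are broken by the
#' earliest window. This operationalises "linear fit during the linear
#' growth phase" reproducibly.
#'
#' @param trace A `bulk_trace` (data.frame `time_min`,
#'   `fluorescence`).
#' @param window_fraction Window length as a fraction of the trace
#'   (default 0.2).
#' @param r2_min Minimum R^2 for a window to qualify (default 0.98).
#' @return List with `window` (`c(t_start, t_end)` minutes), `slope`
#'   (a.u. per minute), `r_squared`.
#' @export
find_linear_phase <- function(trace, window_fraction = 0.2, r2_min = 0.98) {
  t <- trace$time_min; y <- trace$fluorescence
  n <- length(t)
  w <- max(3L, round(window_fraction * n))
  if (w > n) stop("find_linear_phase: window longer than trace", call. = FALSE)
  best_slope <- -Inf; best <- NULL; best_r2_any <- -Inf
  for (i in seq_len(n - w + 1L)) {
    ti <- t[i:(i + w - 1L)]; yi <- y[i:(i + w - 1L)]
    sxx <- sum((ti - mean(ti))^2)
    sxy <- sum((ti - mean(ti)) * (yi - mean(yi)))
    syy <- sum((yi - mean(yi))^2)
    slope <- sxy / sxx
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
    best_r2_any <- max(best_r2_any, r2)
    if (r2 >= r2_min && slope > best_slope + 1e-12) {
      best_slope <- slope
      best <- list(window = c(ti[1L], ti[w]), slope = slope, r_squared = r2)
    }
  }
  if (is.null(best))
    stop("find_linear_phase: no window reached R^2 >= ", r2_min,
         " (best achieved: ", signif(best_r2_any, 4), ")", call. = FALSE)
  best
}

#' Absolute transcription rate from a calibrated fluorescence slope
#'
#' Converts the linear-phase fluorescence slope to transcripts per
#' minute per engine: slope / calibration slope gives RNA amount per
#' minute, divided by the engine amount (same amount units as the
#' calibration standards, e.g. nM). Negative slopes (e.g. slow
#' photobleaching in template-free controls) are reported as-is.
#'
#' @param trace A `bulk_trace`.
#' @param window `c(t_start, t_end)` minutes (e.g. from
#'   [find_linear_phase()]); `NULL` uses the whole trace.
#' @param calibration An `mb_calibration`.
#' @param engine_conc Engine amount (same units as the calibration's
#'   `rna_amount`).
#' @return A `rate_estimate`: list with `slope` (a.u./min), `window`,
#'   `r_squared`, `calibrated_rate` (transcripts min^-1 engine^-1).
#' @export
absolute_rate <- function(trace, window = NULL, calibration, engine_conc) {
  if (engine_conc <= 0) stop("absolute_rate: 'engine_conc' must be > 0",
                             call. = FALSE)
  t <- trace$time_min; y <- trace$fluorescence
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1L] & t <= window[2L]
  if (sum(keep) < 2L) stop("absolute_rate: window too narrow", call. = FALSE)
  fit <- stats::lm(y[keep] ~ t[keep])
  slope <- unname(stats::coef(fit)[2L])
  structure(list(slope = slope, window = window,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 calibrated_rate = slope / calibration$slope / engine_conc),
            class = "rate_estimate")
}

#' Relative transcription rates versus a reference condition
#'
#' Divides each condition's mean rate by the reference condition's mean
#' rate and reports the per-condition statistics used in the bulk
#' comparisons (n, mean relative rate, sd, min, max, median).
#'
#' @param estimates data.frame with columns `condition` and `rate`
#'   (one row per replicate).
#' @param reference_label Condition to normalise against.
#' @return data.frame with columns `condition`, `n`, `mean_relative`,
#'   `sd`, `min`, `max`, `median`.
#' @export
relative_rates <- function(estimates, reference_label) {
  e <- as.data.frame(estimates)
  if (!all(c("condition", "rate") %in% names(e)))
    stop("relative_rates: need columns 'condition' and 'rate'", call. = FALSE)
  if (!reference_label %in% e$condition)
    stop("relative_rates: reference condition '", reference_label,
         "' not present", call. = FALSE)
  ref_mean <- mean(e$rate[e$condition == reference_label])
  if (ref_mean == 0) stop("relative_rates: reference mean rate is zero",
                          call. = FALSE)
  rel <- e$rate / ref_mean
  out <- do.call(rbind, lapply(split(seq_len(nrow(e)), e$condition),
                               function(ix) {
    data.frame(condition = e$condition[ix[1L]], n = length(ix),
               mean_relative = mean(rel[ix]), sd = stats::sd(rel[ix]),
               min = min(rel[ix]), max = max(rel[ix]),
               median = stats::median(rel[ix]))
  }))
  rownames(out) <- NULL
  out[order(match(out$condition, unique(e$condition))), , drop = FALSE]
}
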
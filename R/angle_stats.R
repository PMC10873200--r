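#' Relative histogram of aperture angles
#'
#' Bins angles into fixed-width bins starting at 0 degrees and reports
#' each bin's count as a percentage of the total, the convention used
#' for angle populations measured from micrographs (3-degree bins).
#'
#' @param sample An `angle_sample` or numeric vector of angles
#'   (degrees).
#' @param bin_width Bin width in degrees (default 3).
#' @return List with `bin_edges` (length one more than the number of
#'   bins) and `percent` (summing to 100).
#' @export
relative_histogram <- function(sample, bin_width = 3) {
  a <- if (inherits(sample, "angle_sample")) sample$angles else as.numeric(sample)
  if (length(a) == 0L) stop("relative_histogram: empty sample", call. = FALSE)
  if (bin_width <= 0) stop("'bin_width' must be > 0", call. = FALSE)
  edges <- seq(0, bin_width * ceiling(max(a, bin_width) / bin_width + 1e-12),
               by = bin_width)
  if (max(a) >= edges[length(edges)]) edges <- c(edges, edges[length(edges)] + bin_width)
  counts <- tabulate(findInterval(a, edges), nbins = length(edges) - 1L)
  list(bin_edges = edges, percent = 100 * counts / length(a))
}

#' Box-plot statistics of an angle sample
#'
#' Quartiles use linear interpolation between order statistics
#' (type-7); whiskers extend at most 1.5 IQR beyond the quartiles and
#' are clipped to the most extreme data point inside that fence; points
#' beyond the whiskers are outliers.
#'
#' @param sample An `angle_sample` or numeric vector.
#' @return A `box_stats` list: `n`, `mean`, `sd`, `min`, `max`, `Q1`,
#'   `median`, `Q3`, `whisker_low`, `whisker_high`, `outliers`.
#' @examples
#' box_stats(1:100)[c("median", "Q1", "Q3")]
#' @export
box_stats <- function(sample) {
  x <- if (inherits(sample, "angle_sample")) sample$angles else as.numeric(sample)
  if (length(x) < 1L) stop("box_stats: empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  wl <- min(inside); wh <- max(inside)
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x),
                 min = min(x), max = max(x), Q1 = q[1L], median = q[2L],
                 Q3 = q[3L], whisker_low = wl, whisker_high = wh,
                 outliers = x[x < wl | x > wh]),
            class = "box_stats")
}

#' Welch's heteroscedastic two-sample t-test
#'
#' Two-tailed Welch test, either from raw samples or directly from
#' printed summary statistics (n, mean, sd per group). The p-value is
#' evaluated on the log scale of the t survival function, so extreme
#' tails (down to ~1e-300) are computed accurately instead of
#' underflowing.
#'
#' @param sample1,sample2 Numeric vectors (raw-sample interface;
#'   `angle_sample` objects accepted).
#' @return List with `t`, `df`, `p`, and `log10_p` (accurate even when
#'   `p` underflows).
#' @examples
#' welch_from_summary(40, 1.00, 0.12, 14, 2.12, 0.69)$p  # ~3.9e-5
#' @export
welch_t_test <- function(sample1, sample2) {
  x <- if (inherits(sample1, "angle_sample")) sample1$angles else as.numeric(sample1)
  y <- if (inherits(sample2, "angle_sample")) sample2$angles else as.numeric(sample2)
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t_test: need at least 2 observations per group", call. = FALSE)
  welch_from_summary(length(x), mean(x), stats::sd(x),
                     length(y), mean(y), stats::sd(y))
}

#' @param n1,m1,s1,n2,m2,s2 Group sizes, means and standard deviations
#'   (summary-statistics interface).
#' @rdname welch_t_test
#' @export
welch_from_summary <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2L || n2 < 2L)
    stop("welch_from_summary: need n >= 2 per group", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    # zero variance in both groups: equal means give p = 1 by convention
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1, log10_p = 0))
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0,
                log10_p = -Inf))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  log_p <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE) + log(2)
  list(t = t, df = df, p = exp(log_p), log10_p = log_p / log(10))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] (two-tailed) returning the
#' statistic and p-value in a fixed shape; used to compare angle
#' distributions between design variants.
#'
#' @param sample1,sample2 Numeric vectors or `angle_sample` objects.
#' @return List with `D` and `p`.
#' @export
ks_compare <- function(sample1, sample2) {
  x <- if (inherits(sample1, "angle_sample")) sample1$angles else as.numeric(sample1)
  y <- if (inherits(sample2, "angle_sample")) sample2$angles else as.numeric(sample2)
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}
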
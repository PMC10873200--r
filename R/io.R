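#' Read and write the pipeline's tidy CSV formats
#'
#' Fluorescence traces are stored long-format with columns `trace_id`,
#' `frame`, `time_s`, `donor`, `acceptor`; angle samples with
#' `sample_id`, `angle_deg`; point clouds with `frame`, `arm_label`,
#' `x`, `y`, `z`; bulk traces with `time_min`, `fluorescence`;
#' calibration tables with `rna_amount`, `fluorescence`.
#'
#' @param traces List of `fluorescence_trace` objects.
#' @param path Output/input file path.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    n <- length(tr$donor)
    data.frame(trace_id = tr$trace_id, frame = seq_len(n),
               time_s = (seq_len(n) - 0.5) * tr$frame_interval,
               donor = tr$donor, acceptor = tr$acceptor)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("trace_id", "frame", "time_s", "donor", "acceptor")
  if (!all(need %in% names(d)))
    stop("read_traces_csv: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  lapply(split(d, d$trace_id), function(g) {
    g <- g[order(g$frame), ]
    dt <- if (nrow(g) > 1L) stats::median(diff(g$time_s)) else 1
    structure(list(trace_id = as.character(g$trace_id[1L]),
                   frame_interval = dt, donor = g$donor,
                   acceptor = g$acceptor),
              class = "fluorescence_trace")
  })
}

#' @param sample An `angle_sample` (or data.frame `sample_id`,
#'   `angle_deg` on read).
#' @rdname trace_io
#' @export
write_angles_csv <- function(sample, path) {
  samples <- if (inherits(sample, "angle_sample")) list(sample) else sample
  rows <- lapply(samples, function(s)
    data.frame(sample_id = s$label, angle_deg = s$angles))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_angles_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("sample_id", "angle_deg") %in% names(d)))
    stop("read_angles_csv: need columns 'sample_id', 'angle_deg'",
         call. = FALSE)
  lapply(split(d, d$sample_id), function(g)
    angle_sample(g$angle_deg, label = as.character(g$sample_id[1L])))
}

#' @param segments_list List of `cycle_segments` objects.
#' @rdname trace_io
#' @export
write_segments_csv <- function(segments_list, path) {
  rows <- lapply(segments_list, function(s) {
    if (nrow(s$cycles) == 0L) return(NULL)
    cbind(trace_id = if (!is.null(s$trace_id)) s$trace_id else NA, s$cycles)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
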
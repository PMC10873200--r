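#' Default pipeline configuration
#'
#' Returns the versioned default configuration for [run_pipeline()]:
#' a demo-scale end-to-end run (small trace counts so it completes in
#' minutes on one CPU). All values can be overridden via the `config`
#' argument of [run_pipeline()] or a YAML file with the same structure.
#'
#' @return Nested named list of per-stage parameter blocks.
#' @export
default_pipeline_config <- function() {
  list(
    version = "1",
    seed = 1L,
    stages = c("traces", "kinetics", "angles", "mechanics", "bulk"),
    traces = list(n_traces = 20L, duration_s = 150, ntp_mM = c(1, 5),
                  noise_sd = 0.1, abort_rate = 0),
    kinetics = list(min_dwells = 10L),
    angles = list(n = 500L, mode_no_tx = 70, mode_tx = 58, spread = 22,
                  skew = -2, bin_width = 3),
    mechanics = list(k_spring = 50, theta0 = 70, n_frames = 20000L,
                     relaxation_frames = 5, n_pull_replicates = 4L,
                     points_per_arm = 25L, cloud_noise = 2),
    bulk = list(rate = 2.3, engine_conc = 10, duration_min = 210,
                sampling_min = 0.5, noise_sd = 0.01)
  )
}

validate_config <- function(config) {
  def <- default_pipeline_config()
  check_keys <- function(x, ref, path) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop("run_pipeline: unknown configuration key",
           if (length(unknown) > 1) "s", " ",
           paste0("'", path, unknown, "'", collapse = ", "), call. = FALSE)
  }
  check_keys(config, def, "")
  for (blk in intersect(names(config), names(def)))
    if (is.list(def[[blk]]) && is.list(config[[blk]]))
      check_keys(config[[blk]], def[[blk]], paste0(blk, "$"))
  merged <- utils::modifyList(def, config)
  bad <- setdiff(merged$stages, def$stages)
  if (length(bad))
    stop("run_pipeline: unknown stage(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  merged
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order — trace
#' simulation and segmentation, dwell-time kinetics, angle-distribution
#' statistics, mechanics (spring constant and opening rates), and the
#' bulk transcription-rate pipeline — writing tidy CSV/JSON outputs and
#' a manifest (inputs, seed, package version, per-file MD5 checksums)
#' to `out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config Named list (see [default_pipeline_config()]) or path
#'   to a YAML file with the same structure. Unknown keys are rejected.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("nanopulse_run"),
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_run0 <- Sys.time()
  files <- character(0)
  add <- function(f) files <<- c(files, f)
  seed <- as.integer(cfg$seed)
  fits_per_cond <- NULL

  if (any(c("traces", "kinetics") %in% cfg$stages)) {
    say("[traces] simulating %d traces x %d NTP conditions",
        cfg$traces$n_traces, length(cfg$traces$ntp_mM))
    p <- engine_params(noise_sd = cfg$traces$noise_sd,
                       abort_rate = cfg$traces$abort_rate,
                       bleach_rate_donor = 0, bleach_rate_acceptor = 0)
    seg_all <- list(); cond_all <- character(0); traces_all <- list()
    for (ci in seq_along(cfg$traces$ntp_mM)) {
      conc <- cfg$traces$ntp_mM[ci]
      for (i in seq_len(cfg$traces$n_traces)) {
        s <- seed + ci * 10000L + i
        traj <- simulate_state_trajectory(p, conc, cfg$traces$duration_s,
                                          seed = s)
        tr <- render_fluorescence(traj, p, seed = s + 500000L,
                                  trace_id = sprintf("ntp%g_%03d", conc, i))
        traces_all[[length(traces_all) + 1L]] <- tr
        seg_all[[length(seg_all) + 1L]] <- segment_cycles(compute_fret(tr))
        cond_all <- c(cond_all, sprintf("%g mM", conc))
      }
    }
    f <- file.path(out_dir, "traces.csv"); write_traces_csv(traces_all, f); add(f)
    f <- file.path(out_dir, "segments.csv"); write_segments_csv(seg_all, f); add(f)
    stats_tab <- summarize_cycles(seg_all, cond_all)
    f <- file.path(out_dir, "cycle_stats.csv")
    utils::write.csv(stats_tab$summary, f, row.names = FALSE); add(f)

    if ("kinetics" %in% cfg$stages) {
      say("[kinetics] fitting dwell and transition distributions")
      dt <- dwell_table(seg_all, cond_all)
      dt <- dt[!dt$censored, ]
      fits_per_cond <- lapply(split(dt, dt$condition), function(g) {
        res <- list()
        for (comp in c("O", "tC", "C", "tO")) {
          d <- g$duration_s[g$component == comp & g$duration_s > 0]
          if (length(d) < cfg$kinetics$min_dwells) next
          res[[comp]] <- if (comp %in% c("O", "C")) {
            ft <- fit_double_exponential(d)
            list(model = "double_exponential", A1 = ft$A1, tau1 = ft$tau1,
                 A2 = ft$A2, tau2 = ft$tau2, mean = ft$weighted_mean,
                 n = ft$n)
          } else {
            ft <- fit_gamma(d)
            list(model = "gamma", shape = ft$shape, rate = ft$rate,
                 mean = ft$mean, n = ft$n)
          }
        }
        res
      })
      f <- file.path(out_dir, "kinetics_fits.json")
      jsonlite::write_json(fits_per_cond, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE); add(f)
    }
  }

  if ("angles" %in% cfg$stages) {
    say("[angles] angle-distribution statistics")
    a <- cfg$angles
    s1 <- sample_tem_angles(a$mode_no_tx, a$spread, a$skew, a$n,
                            seed = seed + 1L, label = "no_transcription")
    s2 <- sample_tem_angles(a$mode_tx, a$spread, a$skew, a$n,
                            seed = seed + 2L, label = "transcription")
    f <- file.path(out_dir, "angles.csv")
    write_angles_csv(list(s1, s2), f); add(f)
    report <- list(
      histogram = lapply(list(no_transcription = s1, transcription = s2),
                         relative_histogram, bin_width = a$bin_width),
      box = lapply(list(no_transcription = s1, transcription = s2),
                   function(s) unclass(box_stats(s))),
      welch = welch_t_test(s1, s2),
      ks = ks_compare(s1, s2))
    f <- file.path(out_dir, "angle_report.json")
    jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE); add(f)
  }

  if ("mechanics" %in% cfg$stages) {
    say("[mechanics] equilibrium fluctuations and opening rates")
    m <- cfg$mechanics
    eq <- simulate_angle_trajectory(m$k_spring, m$theta0,
                                    m$relaxation_frames, m$n_frames,
                                    seed = seed + 11L)
    spring <- spring_constant(eq)
    # short pulled/relaxation replicates: closing ramp + thermal noise
    slopes <- vapply(seq_len(m$n_pull_replicates), function(i) {
      tr <- simulate_angle_trajectory(m$k_spring, m$theta0,
                                      m$relaxation_frames, 500L,
                                      torque = -m$k_spring * (30 * pi / 180),
                                      seed = seed + 100L + i)
      ramp <- seq(0, -30, length.out = 500L)  # deterministic closing drive
      tr$angles <- m$theta0 + ramp + (tr$angles - mean(tr$angles))
      open_close_rate(tr)
    }, numeric(1))
    rel <- normalize_rates(slopes, slopes)
    out <- list(spring = unclass(spring), slopes = slopes,
                normalized_slopes = rel)
    f <- file.path(out_dir, "mechanics.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE); add(f)
  }

  if ("bulk" %in% cfg$stages) {
    say("[bulk] molecular-beacon rate extraction")
    b <- cfg$bulk
    sim <- simulate_mb_fluorescence(b$rate, b$engine_conc,
                                    duration = b$duration_min,
                                    sampling = b$sampling_min,
                                    noise_sd = b$noise_sd, seed = seed + 21L)
    calib <- calibrate_mb(sim$calibration)
    win <- find_linear_phase(sim$trace)
    est <- absolute_rate(sim$trace, win$window, calib, b$engine_conc)
    f <- file.path(out_dir, "bulk_trace.csv")
    utils::write.csv(sim$trace, f, row.names = FALSE); add(f)
    f <- file.path(out_dir, "bulk_rate.json")
    jsonlite::write_json(list(window = est$window, slope = est$slope,
                              r_squared = est$r_squared,
                              calibrated_rate = est$calibrated_rate),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(f)
  }

  manifest <- list(
    package = "nanopulse",
    version = as.character(utils::packageVersion("nanopulse")),
    seed = seed, stages = cfg$stages, config = cfg,
    elapsed_s = as.numeric(difftime(Sys.time(), t_run0, units = "secs")),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %d output files in %s", length(files), out_dir)
  invisible(manifest)
}
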
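#' Simulate the open/close state trajectory of a nanoengine
#'
#' Kinetic Monte-Carlo simulation of the four-stage pulsation cycle
#' OPEN -> CLOSING -> CLOSED -> OPENING -> OPEN. Open dwells are
#' exponential with mean given by the NTP saturation law; closing and
#' opening transitions are gamma-distributed (shape
#' `params$transition_shape`); closed dwells are exponential. Abortive
#' excursions (brief visits to an intermediate FRET level while the
#' engine is open) are inserted as a Poisson process at
#' `params$abort_rate`, active only in the open state and only when fuel
#' is present. At 0 mM NTP the engine stalls: whatever state it is in
#' persists, including partially completed transitions, until fuel
#' returns.
#'
#' Internally each stage consumes a unit-mean random "work" clock at a
#' speed equal to the reciprocal of the stage's mean duration at the
#' prevailing NTP concentration, so concentration switches mid-stage
#' rescale the remaining time and a switch to 0 mM freezes it.
#'
#' @param params An [engine_params()] object.
#' @param ntp_schedule Either a single concentration in mM, or a
#'   data.frame with columns `time` (s, first row at 0) and `conc` (mM)
#'   defining a stepwise-constant concentration.
#' @param duration Total simulated time, seconds.
#' @param seed Optional integer seed for reproducibility.
#' @param initial_state State at time 0 (default `"OPEN"`).
#' @return An object of class `state_trajectory`: a list with
#'   `segments` (data.frame `state`, `t_start`, `t_end`, `e_start`,
#'   `e_end` — the FRET level at each segment end, with transitions
#'   ramping linearly in completed work), `duration`, `ntp_schedule`,
#'   `params` and `n_aborts`.
#' @examples
#' p <- engine_params()
#' traj <- simulate_state_trajectory(p, ntp_schedule = 1, duration = 100, seed = 1)
#' head(traj$segments)
#' @export
simulate_state_trajectory <- function(params, ntp_schedule, duration,
                                      seed = NULL, initial_state = "OPEN") {
  validate_engine_params(params)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("simulate_state_trajectory: 'duration' must be a positive number",
         call. = FALSE)
  sched <- normalize_ntp_schedule(ntp_schedule)
  states <- c("OPEN", "CLOSING", "CLOSED", "OPENING")
  if (!initial_state %in% states)
    stop("simulate_state_trajectory: unknown initial state '", initial_state,
         "'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  N <- params$transition_shape
  stage_mean <- function(state, conc) {
    if (conc <= 0) return(Inf)
    switch(state,
      OPEN    = dwell_mean_at_ntp(params$tau_open_sat, params$K_ntp, conc),
      CLOSING = dwell_mean_at_ntp(params$tau_tc_sat, params$K_tc, conc),
      CLOSED  = params$tau_closed,
      OPENING = params$tau_to)
  }
  draw_work <- function(state) {
    # unit-mean work requirement for the stage
    if (state %in% c("CLOSING", "OPENING")) stats::rgamma(1, shape = N, rate = N)
    else stats::rexp(1, rate = 1)
  }
  next_state <- function(state) states[match(state, states) %% 4L + 1L]
  # FRET level as a function of stage progress p in [0, 1]
  e_at <- function(state, p) {
    switch(state,
      OPEN    = params$E_low,
      CLOSED  = params$E_high,
      CLOSING = params$E_low + p * (params$E_high - params$E_low),
      OPENING = params$E_high - p * (params$E_high - params$E_low),
      ABORT   = params$E_abort)
  }

  seg_state <- character(); seg_t0 <- seg_t1 <- seg_e0 <- seg_e1 <- numeric()
  emit <- function(state, t0, t1, e0, e1) {
    if (t1 > t0) {
      seg_state[length(seg_state) + 1L] <<- state
      seg_t0[length(seg_t0) + 1L] <<- t0
      seg_t1[length(seg_t1) + 1L] <<- t1
      seg_e0[length(seg_e0) + 1L] <<- e0
      seg_e1[length(seg_e1) + 1L] <<- e1
    }
  }

  t <- 0
  state <- initial_state
  work_total <- draw_work(state)
  work_rem <- work_total
  isched <- 1L
  n_aborts <- 0L

  while (t < duration) {
    conc <- sched$conc[isched]
    t_sched <- if (isched < nrow(sched)) sched$time[isched + 1L] else Inf
    m <- stage_mean(state, conc)
    v <- if (is.finite(m)) 1 / m else 0
    dt_complete <- if (v > 0) work_rem / v else Inf
    dt_abort <- if (state == "OPEN" && conc > 0 && params$abort_rate > 0)
      stats::rexp(1, params$abort_rate) else Inf
    dt_sched <- t_sched - t
    dt_end <- duration - t
    dt <- min(dt_complete, dt_abort, dt_sched, dt_end)

    p0 <- 1 - work_rem / work_total
    work_rem <- work_rem - v * dt
    p1 <- 1 - work_rem / work_total
    emit(state, t, t + dt, e_at(state, p0), e_at(state, p1))
    t <- t + dt

    if (dt == dt_end) break
    if (dt == dt_complete) {
      state <- next_state(state)
      work_total <- draw_work(state)
      work_rem <- work_total
    } else if (dt == dt_abort) {
      n_aborts <- n_aborts + 1L
      d <- min(stats::rexp(1, 1 / params$abort_duration), duration - t)
      emit("ABORT", t, t + d, params$E_abort, params$E_abort)
      t <- t + d
      while (isched < nrow(sched) && sched$time[isched + 1L] <= t)
        isched <- isched + 1L
    } else {
      isched <- isched + 1L
    }
  }

  structure(list(
    segments = data.frame(state = seg_state, t_start = seg_t0, t_end = seg_t1,
                          e_start = seg_e0, e_end = seg_e1,
                          stringsAsFactors = FALSE),
    duration = duration, ntp_schedule = sched, params = params,
    n_aborts = n_aborts
  ), class = "state_trajectory")
}

normalize_ntp_schedule <- function(ntp_schedule) {
  if (is.numeric(ntp_schedule) && length(ntp_schedule) == 1L) {
    if (ntp_schedule < 0) stop("NTP concentration must be >= 0", call. = FALSE)
    return(data.frame(time = 0, conc = ntp_schedule))
  }
  s <- as.data.frame(ntp_schedule)
  if (!all(c("time", "conc") %in% names(s)))
    stop("ntp_schedule needs columns 'time' and 'conc'", call. = FALSE)
  if (nrow(s) < 1L || s$time[1] > 0)
    stop("ntp_schedule must start at time 0", call. = FALSE)
  if (is.unsorted(s$time, strictly = TRUE))
    stop("ntp_schedule times must be strictly increasing", call. = FALSE)
  if (any(s$conc < 0)) stop("NTP concentrations must be >= 0", call. = FALSE)
  s[, c("time", "conc")]
}

#' Merge a trajectory's fine-grained segments into state dwells
#'
#' Contiguous segments in the same state (split internally at
#' concentration switches or abortive interruptions) are merged into
#' single dwells. With `collapse_aborts = TRUE` abortive excursions and
#' the open time around them are folded into one OPEN dwell, matching
#' how open dwell times are read off experimental traces.
#'
#' @param traj A `state_trajectory`.
#' @param collapse_aborts Fold ABORT excursions into the surrounding
#'   OPEN dwell (default `TRUE`).
#' @return data.frame with columns `state`, `t_start`, `t_end`,
#'   `duration`.
#' @export
state_dwells <- function(traj, collapse_aborts = TRUE) {
  seg <- traj$segments
  st <- seg$state
  if (collapse_aborts) st[st == "ABORT"] <- "OPEN"
  run <- cumsum(c(TRUE, st[-1] != st[-length(st)]))
  out <- data.frame(
    state = st[!duplicated(run)],
    t_start = tapply(seg$t_start, run, min),
    t_end = tapply(seg$t_end, run, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$duration <- out$t_end - out$t_start
  out
}

#' @export
print.state_trajectory <- function(x, ...) {
  dw <- state_dwells(x)
  cat(sprintf("Nanoengine state trajectory: %.1f s, %d dwells, %d abortive events\n",
              x$duration, nrow(dw), x$n_aborts))
  print(table(dw$state))
  invisible(x)
}
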
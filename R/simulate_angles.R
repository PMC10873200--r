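#' Simulate thermal hinge-angle fluctuations (Ornstein-Uhlenbeck)
#'
#' Discretized Ornstein-Uhlenbeck process for the aperture angle of a
#' torsional spring in a thermal bath. The stationary variance follows
#' the equipartition theorem: `1/k_spring` rad^2 for a spring constant
#' expressed in units of k_B*T per rad^2. A constant applied torque
#' shifts the equilibrium aperture by `torque / k_spring` radians
#' (negative torque closes the hinge).
#'
#' Uses the exact OU transition density, so any step size is unbiased:
#' theta[t+1] = mu + phi (theta[t] - mu) + sigma sqrt(1 - phi^2) eps,
#' with phi = exp(-1/relaxation_time) per frame and sigma the stationary
#' standard deviation.
#'
#' @param k_spring Torsional spring constant, k_B*T per rad^2 (> 0).
#' @param theta0 Equilibrium aperture angle, degrees.
#' @param relaxation_time Autocorrelation time in frames.
#' @param n_frames Number of frames to generate.
#' @param dt Time per frame (arbitrary simulation units; stored only).
#' @param torque Constant applied torque, k_B*T per rad (default 0).
#' @param temperature Bath temperature in kelvin (metadata; spring
#'   constants in k_B*T units are temperature-free).
#' @param seed Optional integer seed.
#' @return An `angle_trajectory`: list with `times`, `angles` (degrees),
#'   `temperature` and `applied_torque`.
#' @examples
#' at <- simulate_angle_trajectory(50, 70, 10, 1e4, seed = 1)
#' 1 / stats::var(at$angles * pi / 180)  # ~ 50
#' @export
simulate_angle_trajectory <- function(k_spring, theta0 = 70,
                                      relaxation_time = 10, n_frames = 1000,
                                      dt = 1, torque = 0, temperature = 298,
                                      seed = NULL) {
  if (!is.numeric(k_spring) || k_spring <= 0)
    stop("simulate_angle_trajectory: 'k_spring' must be > 0", call. = FALSE)
  if (n_frames < 1) stop("'n_frames' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  deg <- 180 / pi
  mu <- theta0 + torque / k_spring * deg
  sigma <- sqrt(1 / k_spring) * deg
  phi <- exp(-1 / relaxation_time)
  eps <- stats::rnorm(n_frames)
  ang <- numeric(n_frames)
  ang[1] <- mu + sigma * eps[1]
  innov_sd <- sigma * sqrt(1 - phi^2)
  for (i in seq_len(n_frames - 1L))
    ang[i + 1L] <- mu + phi * (ang[i] - mu) + innov_sd * eps[i + 1L]
  structure(list(times = (seq_len(n_frames) - 1) * dt, angles = ang,
                 temperature = temperature, applied_torque = torque),
            class = "angle_trajectory")
}

#' Generate labelled arm point clouds from an angle trajectory
#'
#' For each frame, places two straight arms meeting at the hinge
#' (origin) in the xy-plane, opened symmetrically about the x-axis at
#' the frame's aperture angle, samples `points_per_arm` points evenly
#' along each arm and adds isotropic Gaussian scatter. Stands in for
#' coarse-grained structural snapshots whose arms are to be recovered by
#' line fitting.
#'
#' @param traj An `angle_trajectory`.
#' @param arm_length Arm length (same units as `noise_sd`).
#' @param points_per_arm Points per arm per frame (>= 2).
#' @param noise_sd Isotropic Gaussian scatter of each point.
#' @param seed Optional integer seed.
#' @return A `point_cloud_series`: data.frame with columns `frame`,
#'   `arm_label` (`"A"`/`"B"`), `x`, `y`, `z`, plus attributes
#'   `true_angles` and `hinge` (the origin).
#' @export
simulate_arm_point_clouds <- function(traj, arm_length = 100,
                                      points_per_arm = 20, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(inherits(traj, "angle_trajectory"))
  if (points_per_arm < 2) stop("'points_per_arm' must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nf <- length(traj$angles)
  s <- seq(0.05, 1, length.out = points_per_arm) * arm_length
  half <- traj$angles / 2 * pi / 180
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    a <- half[i]
    pa <- cbind(x = s * cos(a), y = s * sin(a), z = 0)
    pb <- cbind(x = s * cos(a), y = -s * sin(a), z = 0)
    m <- rbind(pa, pb)
    if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                      ncol = 3)
    rows[[i]] <- data.frame(frame = i,
                            arm_label = rep(c("A", "B"),
                                            each = points_per_arm),
                            x = m[, 1], y = m[, 2], z = m[, 3])
  }
  out <- do.call(rbind, rows)
  attr(out, "true_angles") <- traj$angles
  attr(out, "hinge") <- c(0, 0, 0)
  class(out) <- c("point_cloud_series", "data.frame")
  out
}

#' Sample TEM-like aperture angles from a skewed distribution
#'
#' Draws from a skew-normal distribution (direct-parameterisation
#' location `mode`, scale `spread`, shape `skew`), truncated by
#' rejection to the physical aperture range \[0, 180\] degrees. Emulates
#' the skewed angle populations measured from negative-stain
#' micrographs, where transcription shifts mass toward acute angles.
#'
#' @param mode Location parameter, degrees.
#' @param spread Scale parameter, degrees (> 0).
#' @param skew Shape parameter (0 = symmetric normal; negative skews
#'   toward small angles).
#' @param n Number of angles to draw (0 gives an empty sample).
#' @param seed Optional integer seed.
#' @param label Sample label stored as metadata.
#' @return An `angle_sample`: list with `label` and `angles` (degrees).
#' @export
sample_tem_angles <- function(mode, spread, skew = 0, n, seed = NULL,
                              label = "sample") {
  if (spread <= 0) stop("'spread' must be > 0", call. = FALSE)
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  delta <- skew / sqrt(1 + skew^2)
  angles <- numeric(0)
  while (length(angles) < n) {
    m <- max(16L, 2L * (n - length(angles)))
    u0 <- stats::rnorm(m); u1 <- stats::rnorm(m)
    z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
    x <- mode + spread * z
    angles <- c(angles, x[x >= 0 & x <= 180])
  }
  angle_sample(angles[seq_len(n)], label = label)
}

#' Construct an angle sample
#'
#' @param angles Numeric vector of aperture angles, degrees in \[0, 180\]
#'   (values outside the range are rejected, not wrapped).
#' @param label Sample label.
#' @param condition,micrographs Optional source metadata.
#' @return An `angle_sample` object.
#' @export
angle_sample <- function(angles, label = "sample", condition = NULL,
                         micrographs = NULL) {
  angles <- as.numeric(angles)
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 180))
    stop("angle_sample: angles must be finite and within [0, 180] degrees",
         call. = FALSE)
  structure(list(label = label, angles = angles, condition = condition,
                 micrographs = micrographs), class = "angle_sample")
}
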
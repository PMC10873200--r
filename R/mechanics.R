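#' Fit arm axes to a labelled point cloud
#'
#' Fits a straight line through each labelled arm of one structural
#' snapshot by total least squares (the principal axis of the point
#' set), which is unbiased at any arm orientation, and orients each
#' direction vector to point away from the hinge.
#'
#' @param points data.frame with columns `arm_label` (`"A"`/`"B"`),
#'   `x`, `y`, `z` for a single frame.
#' @param hinge Hinge position, numeric length-3 (default origin).
#' @return An `arm_fit`: list with unit vectors `dir_a`, `dir_b`,
#'   `hinge`, `residual_rms` and `angle_deg` (aperture between the
#'   outward arm directions, in \[0, 180\]).
#' @export
fit_arm_axes <- function(points, hinge = c(0, 0, 0)) {
  fit_one <- function(m) {
    if (nrow(m) < 2L) stop("fit_arm_axes: need >= 2 points per arm",
                           call. = FALSE)
    ctr <- colMeans(m)
    cm <- sweep(m, 2L, ctr)
    if (all(abs(cm) < 1e-12))
      stop("fit_arm_axes: degenerate (all-coincident) arm point cloud",
           call. = FALSE)
    sv <- svd(cm)
    v <- sv$v[, 1L]
    # orient away from the hinge
    if (sum(v * (ctr - hinge)) < 0) v <- -v
    resid <- cm - (cm %*% v) %*% t(v)
    list(dir = v, rms = sqrt(mean(rowSums(resid^2))))
  }
  ma <- as.matrix(points[points$arm_label == "A", c("x", "y", "z")])
  mb <- as.matrix(points[points$arm_label == "B", c("x", "y", "z")])
  fa <- fit_one(ma); fb <- fit_one(mb)
  cosang <- max(-1, min(1, sum(fa$dir * fb$dir)))
  structure(list(dir_a = fa$dir, dir_b = fb$dir, hinge = hinge,
                 residual_rms = sqrt((fa$rms^2 + fb$rms^2) / 2),
                 angle_deg = acos(cosang) * 180 / pi),
            class = "arm_fit")
}

#' Aperture-angle trace from a point-cloud series
#'
#' Applies [fit_arm_axes()] framewise and returns the per-frame
#' aperture angle between the outward arm directions.
#'
#' @param cloud_series A `point_cloud_series` (data.frame with `frame`,
#'   `arm_label`, `x`, `y`, `z`).
#' @param hinge Hinge position (default origin).
#' @param dt Time per frame (arbitrary units, default 1).
#' @return An `angle_trajectory`.
#' @export
angle_trace <- function(cloud_series, hinge = c(0, 0, 0), dt = 1) {
  frames <- sort(unique(cloud_series$frame))
  ang <- vapply(frames, function(fr) {
    fit_arm_axes(cloud_series[cloud_series$frame == fr, , drop = FALSE],
                 hinge = hinge)$angle_deg
  }, numeric(1))
  structure(list(times = (frames - min(frames)) * dt, angles = ang,
                 temperature = 298, applied_torque = 0),
            class = "angle_trajectory")
}

#' Torsional spring constant by equipartition
#'
#' For an equilibrium (torque-free) angle trajectory in a harmonic
#' hinge potential, the equipartition theorem
#' \eqn{\frac{1}{2} k \langle(\theta - \theta_0)^2\rangle = \frac{1}{2} k_B T}
#' gives the spring constant as the reciprocal of the angular variance
#' in radians squared, in units of k_B*T per rad^2. The conversion to
#' pN nm per rad^2 uses k_B*T = 4.114 pN nm at 298 K (scaled to the
#' stated temperature).
#'
#' @param traj An `angle_trajectory` (equilibrium; >= 100 frames).
#' @param temperature Temperature in kelvin (default the trajectory's).
#' @return A `spring_estimate`: list with `k_kbt` (k_B*T rad^-2),
#'   `k_pn_nm` (pN nm rad^-2), `theta0_deg`, `variance_rad2`,
#'   `n_frames`, `temperature`.
#' @export
spring_constant <- function(traj, temperature = traj$temperature) {
  stopifnot(inherits(traj, "angle_trajectory"))
  if (length(traj$angles) < 100L)
    stop("spring_constant: need >= 100 frames", call. = FALSE)
  if (!is.null(traj$applied_torque) && any(traj$applied_torque != 0))
    stop("spring_constant: equilibrium (zero-torque) trajectory required",
         call. = FALSE)
  th <- traj$angles * pi / 180
  v <- stats::var(th)
  if (v == 0) stop("spring_constant: zero angular variance", call. = FALSE)
  kbt_pn_nm <- 4.114 * temperature / 298
  structure(list(k_kbt = 1 / v, k_pn_nm = kbt_pn_nm / v,
                 theta0_deg = mean(traj$angles), variance_rad2 = v,
                 n_frames = length(th), temperature = temperature),
            class = "spring_estimate")
}

#' @export
print.spring_estimate <- function(x, ...) {
  cat(sprintf("Equipartition spring constant: %.2f kBT/rad^2 (%.2f pN nm/rad^2)\n",
              x$k_kbt, x$k_pn_nm))
  cat(sprintf("  theta0 = %.1f deg, var = %.4g rad^2, n = %d frames, T = %g K\n",
              x$theta0_deg, x$variance_rad2, x$n_frames, x$temperature))
  invisible(x)
}

#' Opening/closing rate of an angle trace
#'
#' Slope of the ordinary least-squares line of angle versus time over
#' the declared window (default the full trace). Closing gives a
#' negative slope, opening a positive one; signs are preserved.
#'
#' @param traj An `angle_trajectory`.
#' @param window Optional `c(t_start, t_end)` restricting the
#'   regression.
#' @return Slope in degrees per time unit.
#' @export
open_close_rate <- function(traj, window = NULL) {
  t <- traj$times; a <- traj$angles
  if (!is.null(window)) {
    keep <- t >= window[1L] & t <= window[2L]
    if (sum(keep) < 2L) stop("open_close_rate: window too narrow", call. = FALSE)
    t <- t[keep]; a <- a[keep]
  }
  unname(stats::coef(stats::lm(a ~ t))[2L])
}

#' Normalise opening/closing rates to a reference design
#'
#' Because coarse-grained simulation time has no direct real-time
#' correspondence, each replicate's slope is divided by the mean slope
#' of the reference design's replicates. Signs are preserved, so the
#' reference set normalised against itself has mean exactly 1 in
#' magnitude.
#'
#' @param rates Numeric vector of slopes (one per replicate).
#' @param reference_rates Slopes of the reference design's replicates.
#' @return Numeric vector of relative rates.
#' @export
normalize_rates <- function(rates, reference_rates) {
  mref <- mean(reference_rates)
  if (mref == 0) stop("normalize_rates: reference mean rate is zero",
                      call. = FALSE)
  rates / abs(mref)
}
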
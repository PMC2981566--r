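# Chair (sled) kinematics: trapezoidal stimulus generation and the geometric
# ideal eye velocity. Units throughout: cm, s, deg. Sign convention follows
# the right-hand rule: leftward positions and velocities are positive.

#' Standard gravity used to convert printed g-units, in cm/s^2
#' @export
G_CM_S2 <- 980.665

#' Stimulus protocol for one translation step
#'
#' Describes the trapezoidal velocity profile of the sled: constant
#' acceleration up to a peak speed, a constant-speed plateau, then constant
#' deceleration to rest. The defaults are the interaural translation protocol
#' used throughout the package: 0.26 g acceleration to 40 cm/s, 320 ms at
#' constant speed, 0.20 g deceleration, for a total displacement of 20 cm.
#'
#' @param a_accel acceleration magnitude, g-units.
#' @param v_peak peak speed, cm/s.
#' @param t_const duration of the constant-speed phase, seconds.
#' @param a_decel deceleration magnitude, g-units.
#' @param direction `"left"` or `"right"`. Leftward velocity is positive.
#' @param displacement_nominal nominal total displacement, cm (bookkeeping
#'   only; the realized displacement follows from the kinematic parameters).
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(a_accel = 0.26, v_peak = 40, t_const = 0.320,
                              a_decel = 0.20, direction = c("left", "right"),
                              displacement_nominal = 20) {
  direction <- match.arg(direction)
  vals <- c(a_accel = a_accel, v_peak = v_peak, t_const = t_const,
            a_decel = a_decel, displacement_nominal = displacement_nominal)
  if (anyNA(vals) || any(vals <= 0))
    stop("all stimulus protocol magnitudes must be strictly positive")
  structure(list(a_accel = a_accel, v_peak = v_peak, t_const = t_const,
                 a_decel = a_decel, direction = direction,
                 displacement_nominal = displacement_nominal),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "translation step: %.2f g -> %.1f cm/s, %.0f ms constant, %.2f g stop (%s)\n",
    x$a_accel, x$v_peak, 1000 * x$t_const, x$a_decel, x$direction))
  invisible(x)
}

#' Generate a trapezoidal chair trajectory
#'
#' Samples the three-phase velocity profile on a uniform grid (default 2 ms,
#' the chair signal's native sample period) and obtains position by
#' trapezoidal integration. A stationary lead-in and tail are included so
#' that downstream latency shifts and plant transients have support.
#'
#' @param protocol a [stimulus_protocol()].
#' @param dt sample period, seconds.
#' @param t_pre,t_post stationary padding before motion onset and after motion
#'   end, seconds.
#' @return a `chair_trajectory`: data frame with columns `time`, `x`
#'   (position, cm), `v` (velocity, cm/s), `a` (acceleration, cm/s^2), with
#'   the protocol and the motion onset/end times stored as attributes.
#' @examples
#' traj <- make_trapezoid_profile(stimulus_protocol())
#' abs(traj$x[nrow(traj)] - traj$x[1])  # ~20 cm displacement
#' @export
make_trapezoid_profile <- function(protocol, dt = 0.002,
                                   t_pre = 0.1, t_post = 0.5) {
  if (!inherits(protocol, "stimulus_protocol"))
    stop("protocol must be a stimulus_protocol")
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("dt must be a positive number")
  if (t_pre < 0 || t_post < 0) stop("padding must be non-negative")

  a1 <- protocol$a_accel * G_CM_S2
  a3 <- protocol$a_decel * G_CM_S2
  vp <- protocol$v_peak
  t1 <- vp / a1                      # acceleration-phase duration
  t2 <- t1 + protocol$t_const        # end of constant-speed phase
  t3 <- t2 + vp / a3                 # motion end
  sgn <- if (protocol$direction == "left") 1 else -1

  time <- seq(0, t_pre + t3 + t_post, by = dt)
  tm <- time - t_pre                 # time since motion onset
  v <- numeric(length(time))
  a <- numeric(length(time))
  ph1 <- tm >= 0 & tm < t1
  ph2 <- tm >= t1 & tm < t2
  ph3 <- tm >= t2 & tm < t3
  v[ph1] <- a1 * tm[ph1]
  v[ph2] <- vp
  v[ph3] <- vp - a3 * (tm[ph3] - t2)
  a[ph1] <- a1
  a[ph3] <- -a3
  v <- sgn * v
  a <- sgn * a
  x <- pracma::cumtrapz(time, v)[, 1]

  structure(data.frame(time = time, x = x, v = v, a = a),
            protocol = protocol,
            motion_onset = t_pre, motion_end = t_pre + t3,
            class = c("chair_trajectory", "data.frame"))
}

#' Motion onset / end times of a chair trajectory
#'
#' Taken from the generating protocol when available, otherwise detected as
#' the first/last sample with non-negligible speed.
#' @param traj a `chair_trajectory` (or any data frame with `time` and `v`).
#' @return named numeric vector `c(onset, end)`, seconds.
#' @export
motion_interval <- function(traj) {
  on <- attr(traj, "motion_onset"); en <- attr(traj, "motion_end")
  if (is.null(on) || is.null(en)) {
    i <- which(abs(traj$v) > 1e-9)
    if (!length(i)) return(c(onset = NA_real_, end = NA_real_))
    on <- traj$time[i[1]]; en <- traj$time[i[length(i)]]
  }
  c(onset = on, end = en)
}

#' Geometrically ideal eye velocity
#'
#' The eye angular velocity that keeps the fovea on a stationary target at
#' perpendicular distance `d` while the head translates along the interaural
#' axis: the time derivative of the gaze angle `atan(x_h / d)`,
#' `omega = d * v_h / (d^2 + x_h^2)`, converted to deg/s.
#'
#' @param traj a `chair_trajectory`.
#' @param d perpendicular eye-to-target distance, cm (> 0).
#' @return numeric vector of ideal eye velocity, deg/s, one value per sample.
#' @examples
#' traj <- make_trapezoid_profile(stimulus_protocol())
#' max(ideal_eye_velocity(traj, 70))  # ~32.7 deg/s at 70 cm
#' @export
ideal_eye_velocity <- function(traj, d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0)
    stop("target distance d must be a positive number")
  (180 / pi) * d * traj$v / (d^2 + traj$x^2)
}
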
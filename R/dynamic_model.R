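# The proposed tVOR block model: otolith dynamics feed a direct acceleration
# pathway (gain G_acc) in parallel with an acceleration-to-velocity integrator
# (gain G_i). The summed eye-velocity command is delayed, converted from
# linear to angular demand by the target geometry, and drives the common
# velocity-to-position neural integrator (NI) and the ocular plant. The model
# output is horizontal eye position; eye velocity is its derivative.

#' Parameter set for the dynamic tVOR model
#'
#' @param G_i gain of the integrated (acceleration-to-velocity) pathway,
#'   dimensionless, >= 0. At `G_i = 1` the sustained response matches the
#'   geometrically ideal eye velocity for small gaze angles.
#' @param G_acc gain of the direct acceleration pathway, seconds, >= 0
#'   (it maps cm/s^2 to a cm/s velocity command).
#' @param tau_delay response latency, seconds, in `[0, 0.075]`.
#' @param tvor_integrator_tc time constant of the tVOR integrator, seconds;
#'   `Inf` (the default) gives a pure integrator.
#' @param ni_tc time constant of the common velocity-to-position neural
#'   integrator, seconds (default 20).
#' @param otolith list with elements `k`, `T_lead`, `T_lag` for the
#'   first-order lead-lag otolith transfer function
#'   `k (1 + T_lead s) / (1 + T_lag s)`. With `T_lead == T_lag` (the default)
#'   the block is a pure gain.
#' @param plant_order `"third"` or `"first"`.
#' @param plant_tc plant time constants, seconds: three for the third-order
#'   plant (default 0.224, 0.013, 0.004) or one for the first-order plant
#'   (default 0.25). The plant has unity DC gain.
#' @param distance perpendicular target distance D, cm.
#' @return an object of class `tvor_parameters`.
#' @export
model_parameters <- function(G_i = 1, G_acc = 0.23, tau_delay = 0.031,
                             tvor_integrator_tc = Inf, ni_tc = 20,
                             otolith = list(k = 1, T_lead = 0.01, T_lag = 0.01),
                             plant_order = c("third", "first"),
                             plant_tc = NULL, distance = 70) {
  plant_order <- match.arg(plant_order)
  if (is.null(plant_tc))
    plant_tc <- if (plant_order == "third") c(0.224, 0.013, 0.004) else 0.25
  p <- structure(list(G_i = G_i, G_acc = G_acc, tau_delay = tau_delay,
                      tvor_integrator_tc = tvor_integrator_tc, ni_tc = ni_tc,
                      otolith = otolith, plant_order = plant_order,
                      plant_tc = plant_tc, distance = distance),
                 class = "tvor_parameters")
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  if (!is.numeric(p$G_i) || p$G_i < 0 || !is.numeric(p$G_acc) || p$G_acc < 0)
    stop("pathway gains must be non-negative")
  if (p$tau_delay < 0 || p$tau_delay > 0.075)
    stop("tau_delay must lie in [0, 0.075] s")
  tcs <- c(p$tvor_integrator_tc, p$ni_tc, p$otolith$T_lead, p$otolith$T_lag,
           p$plant_tc)
  if (any(!is.numeric(tcs)) || any(tcs <= 0))
    stop("all time constants must be strictly positive")
  n_tc <- if (p$plant_order == "third") 3L else 1L
  if (length(p$plant_tc) != n_tc)
    stop(sprintf("%s-order plant needs %d time constant(s)",
                 p$plant_order, n_tc))
  if (!is.numeric(p$distance) || p$distance <= 0)
    stop("target distance must be positive")
  invisible(p)
}

#' @export
print.tvor_parameters <- function(x, ...) {
  cat(sprintf(
    "tVOR model: G_i = %.4g, G_acc = %.4g s, delay = %.1f ms, D = %g cm\n",
    x$G_i, x$G_acc, 1000 * x$tau_delay, x$distance))
  cat(sprintf("  tVOR integrator tc = %s s, NI tc = %g s, %s-order plant\n",
              format(x$tvor_integrator_tc), x$ni_tc, x$plant_order))
  invisible(x)
}

#' Otolith transfer function block
#'
#' First-order lead-lag approximation of otolith afferent dynamics,
#' `k (1 + T_lead s) / (1 + T_lag s)`, applied to linear head acceleration.
#' The default configuration (`T_lead == T_lag`) reduces to a pure gain.
#' @param params a [model_parameters()] object.
#' @return an [lti_tf()].
#' @export
otolith_tf <- function(params) {
  o <- params$otolith
  if (o$T_lead <= 0 || o$T_lag <= 0)
    stop("otolith time constants must be strictly positive")
  lti_tf(o$k * c(o$T_lead, 1), c(o$T_lag, 1))
}

#' Ocular plant transfer function block
#'
#' Unity-DC-gain low-pass plant: a single lag for the first-order plant or a
#' cascade of three lags for the third-order plant.
#' @param params a [model_parameters()] object.
#' @return an [lti_tf()].
#' @export
plant_tf <- function(params) {
  validate_parameters(params)
  blocks <- lapply(params$plant_tc, function(tc) lti_tf(1, c(tc, 1)))
  do.call(lti_series, blocks)
}

# Block cascade of the full chain from (delayed) head acceleration in
# cm/s^2 to eye position in deg. The delay itself is applied to the input
# signal, not folded into the rational part. The blocks are kept separate
# so the simulation uses a well-scaled series state-space realization.
tvor_blocks <- function(params, output = c("position", "velocity")) {
  output <- match.arg(output)
  lam <- if (is.finite(params$tvor_integrator_tc))
    1 / params$tvor_integrator_tc else 0
  pathways <- lti_tf(c(params$G_acc, params$G_acc * lam + params$G_i),
                     c(1, lam))
  geometry <- (180 / pi) / params$distance
  # for the velocity output the differentiation is folded into the NI block
  # (s / (s + 1/tc), a proper block) so the simulation never has to
  # difference nearly-cancelling fast plant states
  ni <- lti_tf(if (output == "velocity") c(1, 0) else 1,
               c(1, 1 / params$ni_tc))
  c(list(otolith_tf(params), pathways, geometry, ni),
    lapply(params$plant_tc, function(tc) lti_tf(1, c(tc, 1))))
}

# Polynomial transfer function of the same chain (analysis only; the
# companion realization of the full product is too ill-conditioned to
# simulate stiff configurations).
tvor_position_tf <- function(params) {
  do.call(lti_series, tvor_blocks(params))
}

# Shift a sampled signal by a (possibly fractional-sample) delay using linear
# interpolation; the signal is taken to be at rest outside its support.
delay_signal <- function(time, y, tau) {
  stats::approx(time, y, xout = time - tau, yleft = 0, yright = 0,
                rule = 2, ties = "ordered")$y
}

#' Simulate the dynamic tVOR model for a chair trajectory
#'
#' Resamples head acceleration to the simulation grid, applies the response
#' latency as a fractional-sample shift of the input, and integrates the full
#' LTI chain with a zero-order-hold discretization at step `dt` (single
#' state-space realization for the whole chain). Intermediate signals
#' (post-otolith acceleration and the integrator-pathway velocity command)
#' are returned for diagnostics.
#'
#' @param params a [model_parameters()] object.
#' @param traj a `chair_trajectory`.
#' @param duration simulation length, seconds; defaults to the trajectory
#'   length and must not be shorter than it.
#' @param dt simulation step, seconds (default 1 ms, the eye sampling period).
#' @return a `tvor_simulation`: data frame with columns `time`,
#'   `eye_position` (deg), `eye_velocity` (deg/s), `otolith_output` (cm/s^2),
#'   `integrator_output` (cm/s), with `params` and the motion interval as
#'   attributes.
#' @examples
#' traj <- make_trapezoid_profile(stimulus_protocol())
#' sim <- simulate_tvor(model_parameters(), traj)
#' max(abs(sim$eye_velocity))
#' @export
simulate_tvor <- function(params, traj, duration = NULL, dt = 0.001) {
  validate_parameters(params)
  if (dt <= 0) stop("dt must be positive")
  t_end <- traj$time[nrow(traj)]
  if (is.null(duration)) duration <- t_end
  if (duration < t_end - 1e-12)
    stop("duration must not be shorter than the chair trajectory")

  time <- seq(0, duration, by = dt)
  acc <- stats::approx(traj$time, traj$a, xout = time, yleft = 0, yright = 0,
                       rule = 2, ties = "ordered")$y
  u <- delay_signal(time, acc, params$tau_delay)

  main <- cbind(
    lti_simulate_chain(tvor_blocks(params, "position"), u, dt),
    lti_simulate_chain(tvor_blocks(params, "velocity"), u, dt))

  oto <- otolith_tf(params)
  lam <- if (is.finite(params$tvor_integrator_tc))
    1 / params$tvor_integrator_tc else 0
  ipath <- lti_series(oto, lti_tf(params$G_i, c(1, lam)))
  aux <- cbind(lti_simulate(oto$den, list(oto$num), u, dt),
               lti_simulate(ipath$den, list(ipath$num), u, dt))

  structure(data.frame(time = time,
                       eye_position = main[, 1],
                       eye_velocity = main[, 2],
                       otolith_output = aux[, 1],
                       integrator_output = aux[, 2]),
            params = params,
            motion_onset = attr(traj, "motion_onset"),
            motion_end = attr(traj, "motion_end"),
            class = c("tvor_simulation", "data.frame"))
}

#' Eye position of a simulation at a fixed time after motion onset
#'
#' @param sim a `tvor_simulation`.
#' @param at time after motion onset, seconds (default 0.5).
#' @return eye position in deg at the requested time.
#' @export
final_eye_position <- function(sim, at = 0.5) {
  onset <- attr(sim, "motion_onset")
  if (is.null(onset)) onset <- 0
  stats::approx(sim$time, sim$eye_position, xout = onset + at,
                ties = "ordered")$y
}

#' Frequency response of the dynamic model by simulation
#'
#' For each frequency, simulates the model response to sinusoidal head motion
#' (unit-amplitude head velocity, so head acceleration amplitude is
#' `2 pi f`), discards the transient (three times the slowest finite time
#' constant), and fits a sine/cosine pair at the known frequency to the
#' steady-state eye velocity by least squares. Gain is the eye-velocity
#' amplitude in deg/s per cm/s of head velocity; phase (degrees) is relative
#' to head velocity, positive for phase lead.
#'
#' @param params a [model_parameters()] object.
#' @param freqs vector of positive frequencies, Hz.
#' @param normalize if `TRUE`, divide gains by the gain at 1 Hz (simulated
#'   additionally if 1 Hz is not among `freqs`), as is conventional when
#'   comparing responses measured at different effective distances.
#' @param n_cycles number of steady-state cycles used in the fit (>= 5).
#' @return data frame with columns `freq`, `gain`, `phase`.
#' @export
frequency_response <- function(params, freqs, normalize = FALSE,
                               n_cycles = 5) {
  validate_parameters(params)
  if (!length(freqs) || any(!is.finite(freqs)) || any(freqs <= 0))
    stop("frequencies must be positive")
  one <- function(f) {
    # keep >= 1000 samples per cycle, capped at the 1 ms eye-sampling grid
    dt <- min(0.001, 1 / (1000 * f))
    tcs <- c(params$ni_tc, params$plant_tc, params$otolith$T_lag)
    if (is.finite(params$tvor_integrator_tc))
      tcs <- c(tcs, params$tvor_integrator_tc)
    settle <- 4 * max(tcs)
    duration <- settle + n_cycles / f
    time <- seq(0, duration, by = dt)
    # head velocity sin(2 pi f t): its acceleration integrates to a
    # zero-mean sinusoid, so the pure integrator acquires no DC offset
    u <- 2 * pi * f * cos(2 * pi * f * time)       # head acceleration, cm/s^2
    ud <- delay_signal(time, u, params$tau_delay)
    vel <- lti_simulate_chain(tvor_blocks(params, "velocity"), ud, dt)[, 1]
    keep <- time >= settle
    co <- cos(2 * pi * f * time[keep]); si <- sin(2 * pi * f * time[keep])
    b <- stats::lm.fit(cbind(si, co, 1), vel[keep])$coefficients
    # response = A sin(wt + phi): A cos(phi) * sin + A sin(phi) * cos
    c(gain = sqrt(b[[1]]^2 + b[[2]]^2),
      phase = atan2(b[[2]], b[[1]]) * 180 / pi)
  }
  res <- t(vapply(freqs, one, c(gain = 0, phase = 0)))
  out <- data.frame(freq = freqs, gain = res[, 1], phase = res[, 2])
  if (normalize) {
    g1 <- if (any(abs(freqs - 1) < 1e-12)) out$gain[which.min(abs(freqs - 1))]
          else one(1)[["gain"]]
    out$gain <- out$gain / g1
  }
  out
}
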
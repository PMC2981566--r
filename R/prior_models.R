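# Step-response comparison with three previously published tVOR
# architectures, simulated on the same head-acceleration input with a common
# response latency (31 ms) and outputs scaled to matching peak eye
# velocities. Internal constants of the prior architectures live in their
# source publications; the defaults below are declared in one place
# (`prior_model_defaults`) and every comparative claim in the test suite is
# exercised under +/-20% variation of them.
#
#   telford       leaky tVOR integrator (tc 250 ms) in series with a
#                 high-pass stage (tc 50 ms), then the common
#                 velocity-to-position neural integrator; no plant.
#   green_galiana a single central integrator with a first-order ocular
#                 plant (tc 0.27 s) whose low-pass dynamics stand in for the
#                 second integration.
#   angelaki      green_galiana extended with first-order otolith afferent
#                 lead-lag dynamics (the semicircular-canal input of the
#                 published model is omitted: pure translation only).
#   proposed      the dynamic model of this package (see
#                 [model_parameters()]).

#' Default block constants of the comparison architectures
#' @export
prior_model_defaults <- list(
  telford = list(tvor_tc = 0.25, highpass_tc = 0.05, ni_tc = 20),
  green_galiana = list(ni_tc = 20, plant_tc = 0.27),
  angelaki = list(ni_tc = 20, plant_tc = 0.27,
                  oto_k = 1, oto_T_lead = 0.1, oto_T_lag = 0.016)
)

#' Specification of a comparison model
#'
#' @param model one of `"telford"`, `"green_galiana"`, `"angelaki"`,
#'   `"proposed"`.
#' @param delay common response latency, seconds (default 0.031, the value
#'   fitted for the proposed model).
#' @param scale output scale factor applied to position and velocity
#'   (comparisons later rescale to matched peak velocities).
#' @param constants named list overriding entries of
#'   [prior_model_defaults]; for `"proposed"`, a [model_parameters()]
#'   object may be supplied as `constants$params`.
#' @return a `prior_model_spec`.
#' @export
prior_model_spec <- function(model = c("telford", "green_galiana",
                                       "angelaki", "proposed"),
                             delay = 0.031, scale = 1, constants = list()) {
  model <- match.arg(model)
  base <- if (model == "proposed") list(params = model_parameters())
          else prior_model_defaults[[model]]
  structure(list(model = model, delay = delay, scale = scale,
                 constants = utils::modifyList(base, constants)),
            class = "prior_model_spec")
}

prior_blocks <- function(spec, output = c("position", "velocity")) {
  output <- match.arg(output)
  k <- spec$constants
  # every architecture routes through a velocity-to-position integrator;
  # the velocity output folds the differentiation into that block
  ni <- function(tc) lti_tf(if (output == "velocity") c(1, 0) else 1,
                            c(1, 1 / tc))
  leak <- function(tc) lti_tf(1, c(1, 1 / tc))
  lag <- function(tc) lti_tf(1, c(tc, 1))
  switch(spec$model,
    telford = list(leak(k$tvor_tc),   # leaky tVOR integrator, tc 250 ms
                   lti_tf(c(k$highpass_tc, 0), c(k$highpass_tc, 1)),
                   ni(k$ni_tc)),
    green_galiana = c(list(ni(k$ni_tc)), lapply(k$plant_tc, lag)),
    angelaki = c(list(lti_tf(k$oto_k * c(k$oto_T_lead, 1),
                             c(k$oto_T_lag, 1)),
                      ni(k$ni_tc)),
                 lapply(k$plant_tc, lag)),
    proposed = {
      p <- k$params
      p$tau_delay <- 0   # the common delay is applied to the input
      tvor_blocks(p, output)
    })
}

#' Simulate a comparison architecture on a chair trajectory
#'
#' @param spec a [prior_model_spec()].
#' @param traj a `chair_trajectory`; for step comparisons the simulation
#'   should extend at least 1.2 s beyond motion end.
#' @param duration simulation length, seconds (default: trajectory length).
#' @param dt simulation step, seconds.
#' @return a `tvor_simulation` data frame (`time`, `eye_position`,
#'   `eye_velocity`), in the model's native output scale times
#'   `spec$scale`.
#' @export
simulate_prior <- function(spec, traj, duration = NULL, dt = 0.001) {
  if (!inherits(spec, "prior_model_spec")) stop("unknown model specification")
  t_end <- traj$time[nrow(traj)]
  if (is.null(duration)) duration <- t_end
  if (duration < t_end - 1e-12)
    stop("duration must not be shorter than the chair trajectory")
  time <- seq(0, duration, by = dt)
  acc <- stats::approx(traj$time, traj$a, xout = time, yleft = 0,
                       yright = 0, rule = 2, ties = "ordered")$y
  u <- delay_signal(time, acc, spec$delay)
  out <- cbind(lti_simulate_chain(prior_blocks(spec, "position"), u, dt),
               lti_simulate_chain(prior_blocks(spec, "velocity"), u, dt))
  structure(data.frame(time = time,
                       eye_position = spec$scale * out[, 1],
                       eye_velocity = spec$scale * out[, 2]),
            model = spec$model,
            motion_onset = attr(traj, "motion_onset"),
            motion_end = attr(traj, "motion_end"),
            class = c("tvor_simulation", "data.frame"))
}

#' First- versus third-order plant substitution
#'
#' Simulates a single-integrator architecture (`green_galiana` or
#' `angelaki`) with its published first-order plant and with the
#' third-order plant, on the same input.
#'
#' @param spec a [prior_model_spec()] for `green_galiana` or `angelaki`.
#' @param traj a `chair_trajectory`.
#' @param third_tc third-order plant time constants, seconds.
#' @param ... passed to [simulate_prior()].
#' @return list with elements `first` and `third` (`tvor_simulation`s).
#' @export
plant_substitution <- function(spec, traj,
                               third_tc = c(0.224, 0.013, 0.004), ...) {
  if (!spec$model %in% c("green_galiana", "angelaki"))
    stop("plant substitution applies to green_galiana or angelaki")
  spec3 <- spec
  spec3$constants$plant_tc <- third_tc
  list(first = simulate_prior(spec, traj, ...),
       third = simulate_prior(spec3, traj, ...))
}

#' Step-response comparison table across architectures
#'
#' Simulates each model on the same trajectory (extended 1.2 s beyond
#' motion end), rescales every output so that peak eye-velocity magnitudes
#' match the first model in the list, and tabulates peak velocity, velocity
#' and position at motion end, and position 1.2 s later. When both the
#' Telford and Green/Galiana architectures are present, their rescaled
#' velocity traces' RMS difference relative to the common peak is attached
#' as attribute `"telford_gg_rms"`.
#'
#' @param specs list of [prior_model_spec()] objects (>= 1).
#' @param traj a `chair_trajectory`.
#' @param dt simulation step, seconds.
#' @return data frame, one row per model, with the comparison metrics and
#'   the simulations attached as attribute `"simulations"`.
#' @export
step_comparison <- function(specs, traj, dt = 0.001) {
  if (!length(specs)) stop("at least one model specification is required")
  mi <- motion_interval(traj)
  duration <- mi[["end"]] + 1.3
  sims <- lapply(specs, simulate_prior, traj = traj, duration = duration,
                 dt = dt)
  peaks <- vapply(sims, function(s) max(abs(s$eye_velocity)), 0)
  ref_peak <- peaks[1]
  sims <- Map(function(s, pk) {
    s$eye_position <- s$eye_position * ref_peak / pk
    s$eye_velocity <- s$eye_velocity * ref_peak / pk
    s
  }, sims, peaks)
  at <- function(s, col, t) stats::approx(s$time, s[[col]], xout = t,
                                          rule = 2, ties = "ordered")$y
  tab <- do.call(rbind, Map(function(spec, s) data.frame(
    model = spec$model,
    peak_velocity = max(abs(s$eye_velocity)),
    velocity_at_motion_end = at(s, "eye_velocity", mi[["end"]]),
    position_at_motion_end = at(s, "eye_position", mi[["end"]]),
    position_at_plus_1.2s = at(s, "eye_position", mi[["end"]] + 1.2)),
    specs, sims))
  rownames(tab) <- NULL
  models <- tab$model
  if (all(c("telford", "green_galiana") %in% models)) {
    vt <- sims[[which(models == "telford")[1]]]$eye_velocity
    vg <- sims[[which(models == "green_galiana")[1]]]$eye_velocity
    attr(tab, "telford_gg_rms") <- sqrt(mean((vt - vg)^2)) / ref_peak
  }
  attr(tab, "simulations") <- stats::setNames(sims, models)
  tab
}
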
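# Sensitivity analysis around a fitted optimum: each parameter is varied as
# a fractional change f in [-1, 1] (f = -1 sets a gain to zero, f = 1
# doubles it; the delay is varied additively over its bound range), and the
# effect on peak simulated eye velocity, final eye position (500 ms after
# motion onset), and the error function (percent of baseline) is recorded.
# In this context g_a refers to the direct-pathway gain G_acc and g_v to the
# integrated-pathway gain G_i, since the integrated pathway carries the
# velocity-proportional component of the response.

sens_param_map <- c(g_a = "G_acc", g_v = "G_i", delay = "tau_delay")

apply_fraction <- function(params, parameter, f) {
  if (parameter == "delay") {
    base <- params$tau_delay
    # additive variation spanning the bound range [0, 0.075], anchored so
    # f = 0 is the baseline: f < 0 moves toward 0, f > 0 toward the cap
    params$tau_delay <- if (f >= 0) base + f * (0.075 - base)
                        else base * (1 + f)
  } else {
    field <- sens_param_map[[parameter]]
    params[[field]] <- params[[field]] * (1 + f)
  }
  params
}

sens_metrics <- function(params, ref_traj, trials) {
  sim <- simulate_tvor(params, ref_traj, duration = max(ref_traj$time))
  c(peak = max(abs(sim$eye_velocity)),
    fp = final_eye_position(sim),
    err = sum(error_vector(params, trials)^2))
}

#' One-dimensional parameter sensitivity sweep
#'
#' @param params baseline [model_parameters()], normally a fitted optimum
#'   for `trials`.
#' @param parameter `"g_a"` (direct gain G_acc), `"g_v"` (integrator gain
#'   G_i) or `"delay"`.
#' @param fractions fractional changes in `[-1, 1]`.
#' @param trials reference trial series for the error function; its first
#'   trial's chair trajectory is the standard step used for the response
#'   metrics.
#' @return a `sensitivity_sweep` data frame: `fraction`,
#'   `peak_velocity_ratio`, `final_position_ratio`, `error_percent` (error
#'   as percent of baseline, 100 at `fraction = 0`).
#' @export
sweep_1d <- function(params, parameter = c("g_a", "g_v", "delay"),
                     fractions = seq(-1, 1, by = 0.1), trials) {
  parameter <- match.arg(parameter)
  if (any(fractions < -1 | fractions > 1))
    stop("fractions must lie in [-1, 1]")
  if (!length(trials)) stop("a reference trial series is required")
  ref <- trials[[1]]$chair
  base <- sens_metrics(params, ref, trials)
  rows <- lapply(fractions, function(f) {
    m <- sens_metrics(apply_fraction(params, parameter, f), ref, trials)
    data.frame(fraction = f,
               peak_velocity_ratio = m[["peak"]] / base[["peak"]],
               final_position_ratio = m[["fp"]] / base[["fp"]],
               error_percent = 100 * m[["err"]] / base[["err"]])
  })
  structure(do.call(rbind, rows), parameter = parameter,
            class = c("sensitivity_sweep", "data.frame"))
}

#' Two-dimensional error surface over the two pathway gains
#'
#' @param params baseline [model_parameters()], normally a fitted optimum.
#' @param ga_fractions,gv_fractions fractional-change grids in `[-1, 1]`
#'   for G_acc and G_i (default 41 points per axis).
#' @param trials reference trial series for the error function.
#' @return list with `ga_fractions`, `gv_fractions`, `error_percent`
#'   (matrix, rows = g_a, cols = g_v) and `baseline_is_minimum` (`TRUE`
#'   when the (0, 0) cell, if present, attains the grid minimum).
#' @export
sweep_2d <- function(params, ga_fractions = seq(-1, 1, length.out = 41),
                     gv_fractions = seq(-1, 1, length.out = 41), trials) {
  if (!length(ga_fractions) || !length(gv_fractions))
    stop("fraction grids must be non-empty")
  if (any(c(ga_fractions, gv_fractions) < -1) ||
      any(c(ga_fractions, gv_fractions) > 1))
    stop("fractions must lie in [-1, 1]")
  base_err <- sum(error_vector(params, trials)^2)
  err <- matrix(NA_real_, length(ga_fractions), length(gv_fractions))
  for (i in seq_along(ga_fractions)) {
    for (j in seq_along(gv_fractions)) {
      p <- apply_fraction(apply_fraction(params, "g_a", ga_fractions[i]),
                          "g_v", gv_fractions[j])
      err[i, j] <- 100 * sum(error_vector(p, trials)^2) / base_err
    }
  }
  i0 <- which(abs(ga_fractions) < 1e-12)
  j0 <- which(abs(gv_fractions) < 1e-12)
  base_min <- length(i0) == 1L && length(j0) == 1L &&
    all(err >= err[i0, j0] - 1e-9)
  list(ga_fractions = ga_fractions, gv_fractions = gv_fractions,
       error_percent = err, baseline_is_minimum = base_min)
}
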
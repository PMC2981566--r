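# Bounded nonlinear least-squares estimation of the dynamic model's three
# free parameters: the latency (time delay, bounded to [0, 75] ms) and the
# two pathway gains (bounded below at zero). The objective is the
# concatenated difference between measured and simulated eye velocity over
# the unmasked samples of the whole trial series; minimization uses a
# Levenberg-Marquardt algorithm with bound projection (minpack.lm), with
# a seeded multi-start to guard against local minima. The delay enters the
# simulation as a fractional-sample interpolation of the input, which keeps
# the objective smooth in the delay.

#' Residuals of the dynamic model against a trial series
#'
#' Simulates the model once per distinct stimulus (direction x distance) in
#' the series and returns the concatenated measured-minus-simulated eye
#' velocity over unmasked samples. Fully masked trials contribute no rows.
#' The simulation distance is taken from each trial's metadata.
#'
#' @param params a [model_parameters()] object.
#' @param trials list of `tvor_trial` objects with masks computed.
#' @return numeric residual vector, deg/s.
#' @export
error_vector <- function(params, trials) {
  if (!length(trials)) stop("at least one trial is required")
  keys <- vapply(trials, function(tr)
    paste(tr$meta$direction, tr$meta$distance, sep = "/"), "")
  sims <- list()
  res <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    key <- keys[i]
    if (is.null(sims[[key]])) {
      p <- params
      p$distance <- tr$meta$distance
      sims[[key]] <- simulate_tvor(p, tr$chair)
    }
    sim <- sims[[key]]
    keep <- !tr$eye$mask
    if (!any(keep)) next
    sv <- stats::approx(sim$time, sim$eye_velocity, xout = tr$eye$time[keep],
                        rule = 2, ties = "ordered")$y
    res[[length(res) + 1L]] <- tr$eye$velocity[keep] - sv
  }
  out <- unlist(res)
  if (!length(out)) stop("no unmasked samples available")
  out
}

free_par_names <- c("tau_delay", "G_acc", "G_i")

set_free_params <- function(params, p) {
  params$tau_delay <- p[1]
  params$G_acc <- p[2]
  params$G_i <- p[3]
  params
}

#' Fit the dynamic model's free parameters to a trial series
#'
#' Minimizes the sum of squared [error_vector()] residuals over
#' `(tau_delay, G_acc, G_i)` by bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm]), from `n_starts` seeded starting points (the
#' supplied/default initial value plus random perturbations). The best
#' converged start is returned; non-convergence is flagged, not thrown.
#'
#' @param trials list of masked `tvor_trial` objects.
#' @param params template [model_parameters()] supplying the fixed blocks
#'   (otolith, plant, integrator time constants).
#' @param init optional numeric vector `c(tau_delay, G_acc, G_i)`; defaults
#'   to `c(0.03, 0.1, 0.5)`.
#' @param lower,upper parameter bounds, same order as `init` (defaults:
#'   latency in `[0, 0.075]` s, gains positive and unbounded above).
#' @param n_starts number of optimization starts (default 5).
#' @param seed seed for the start perturbations.
#' @param max_iter maximum LM iterations per start.
#' @return a `tvor_model_fit`: list with fitted `params`, `residual_ss`,
#'   `converged`, `iterations`, `message`, and a `starts` data frame
#'   (initial points and attained objectives).
#' @export
optimize_parameters <- function(trials, params = model_parameters(),
                                init = NULL,
                                lower = c(0, 0, 0),
                                upper = c(0.075, Inf, Inf),
                                n_starts = 5, seed = 1, max_iter = 100) {
  if (is.null(init)) init <- c(0.03, 0.1, 0.5)
  if (any(init < lower) || any(init > upper)) stop("init outside bounds")

  starts <- with_local_seed(seed, {
    s <- list(init)
    while (length(s) < n_starts) {
      tau0 <- stats::runif(1, lower[1] + 0.005,
                           min(upper[1] - 0.005, 0.07))
      gains <- pmax(init[2:3], 0.05) * exp(stats::runif(2, -1, 1))
      s[[length(s) + 1L]] <- pmin(pmax(c(tau0, gains), lower), upper)
    }
    s
  })

  fn <- function(p) error_vector(set_free_params(params, p), trials)
  best <- NULL
  log_rows <- list()
  for (i in seq_along(starts)) {
    fit <- minpack.lm::nls.lm(
      par = starts[[i]], lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter))
    ss <- fit$deviance
    log_rows[[i]] <- data.frame(
      start = i, tau0 = starts[[i]][1], G_acc0 = starts[[i]][2],
      G_i0 = starts[[i]][3], objective = ss, info = fit$info)
    if (is.null(best) || ss < best$deviance) best <- fit
  }

  p <- as.numeric(best$par)
  structure(list(params = set_free_params(params, p),
                 tau_delay = p[1], G_acc = p[2], G_i = p[3],
                 residual_ss = best$deviance,
                 converged = best$info %in% 1:4,
                 iterations = best$niter,
                 message = best$message,
                 starts = do.call(rbind, log_rows)),
            class = "tvor_model_fit")
}

#' @export
print.tvor_model_fit <- function(x, ...) {
  cat(sprintf(
    "dynamic model fit: tau = %.1f ms, G_acc = %.4g, G_i = %.4g, rss = %.4g%s\n",
    1000 * x$tau_delay, x$G_acc, x$G_i, x$residual_ss,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Percent parameter change between epochs across matched conditions
#'
#' For matched pre- and post-lesion model fits, computes per-condition
#' percent changes of `G_i` and `G_acc`, their means with t-based 95%
#' confidence intervals, and p-values against zero change; the latency
#' difference (ms) is summarized the same way.
#'
#' @param pre_fits,post_fits named lists of `tvor_model_fit` objects with
#'   matching condition names.
#' @return list with `by_condition` and `summary` data frames.
#' @export
lesion_contrast <- function(pre_fits, post_fits) {
  if (is.null(names(pre_fits)) || is.null(names(post_fits)) ||
      !setequal(names(pre_fits), names(post_fits)) || !length(pre_fits))
    stop("pre and post fits must be non-empty named lists with matching conditions")
  conds <- names(pre_fits)
  by_cond <- data.frame(
    condition = conds,
    G_i_change = vapply(conds, function(k)
      100 * (post_fits[[k]]$G_i / pre_fits[[k]]$G_i - 1), 0),
    G_acc_change = vapply(conds, function(k)
      100 * (post_fits[[k]]$G_acc / pre_fits[[k]]$G_acc - 1), 0),
    tau_diff_ms = vapply(conds, function(k)
      1000 * (post_fits[[k]]$tau_delay - pre_fits[[k]]$tau_delay), 0),
    row.names = NULL)
  summarize <- function(x) {
    if (length(x) > 1 && stats::sd(x) > 0) {
      tt <- stats::t.test(x, mu = 0)
      data.frame(mean = mean(x), ci_lo = tt$conf.int[1],
                 ci_hi = tt$conf.int[2], p_value = tt$p.value)
    } else {
      data.frame(mean = mean(x), ci_lo = NA_real_, ci_hi = NA_real_,
                 p_value = if (all(x == 0)) 1 else NA_real_)
    }
  }
  summary <- rbind(
    cbind(quantity = "G_i_change_pct", summarize(by_cond$G_i_change)),
    cbind(quantity = "G_acc_change_pct", summarize(by_cond$G_acc_change)),
    cbind(quantity = "tau_diff_ms", summarize(by_cond$tau_diff_ms)))
  list(by_condition = by_cond, summary = summary)
}
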
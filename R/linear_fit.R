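# The two-parameter linear model: recorded eye velocity is regressed on a
# delayed linear combination of head velocity and head acceleration,
#   omega_fit(t) = g_v * v_h(t - dt) + g_a * a_h(t - dt),
# with the latency dt searched over a grid (10-80 ms in 2 ms steps, the
# chair signal's sample period) and, at each latency, g_v and g_a estimated
# by robust least-squares regression. The grid latency with the smallest
# squared residual wins; ties break toward the smallest latency.

#' Robust linear regression by iteratively reweighted least squares
#'
#' Huber-loss IRLS with the conventional 95%-efficiency tuning constant
#' (k = 1.345) and a MAD scale estimate, iterated until the relative
#' coefficient change falls below `tol`. On data with an exact linear
#' structure the scale collapses to zero and the exact least-squares
#' solution is returned.
#'
#' @param design numeric design matrix (no intercept is added).
#' @param response numeric response vector.
#' @param k Huber tuning constant.
#' @param tol relative convergence tolerance on the coefficients.
#' @param max_iter maximum IRLS iterations.
#' @return named numeric vector of coefficients.
#' @export
robust_regress <- function(design, response, k = 1.345, tol = 1e-8,
                           max_iter = 100) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  if (nrow(X) != length(y)) stop("design and response lengths differ")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  b <- stats::lm.fit(X, y)$coefficients
  yscale <- max(abs(y), 1)
  for (it in seq_len(max_iter)) {
    r <- y - X %*% b
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s <= 1e-12 * yscale) break
    w <- pmin(1, k * s / pmax(abs(r), 1e-300))
    b_new <- stats::lm.wfit(X, y, w = as.numeric(w))$coefficients
    delta <- max(abs(b_new - b)) / max(max(abs(b)), 1e-300)
    b <- b_new
    if (delta < tol) break
  }
  b
}

# Chair-derived regressors delayed by `delta` and resampled to the eye grid:
# the chair signal is shifted on its native grid, then linearly interpolated,
# which for a latency on the chair grid reproduces the shifted samples
# exactly. The chair is at rest outside its recorded support.
delayed_regressors <- function(chair, delta, eye_time) {
  shift <- function(y) stats::approx(chair$time + delta, y, xout = eye_time,
                                     yleft = y[1], yright = y[length(y)],
                                     ties = "ordered")$y
  cbind(v = shift(chair$v), a = shift(chair$a))
}

#' Fit eye velocity to delayed head velocity and acceleration
#'
#' Pools the unmasked eye-velocity samples of all supplied trials (which
#' should share condition metadata) and, for each candidate latency, fits
#' the two-term linear model by [robust_regress()]. Returns the latency
#' with the lowest squared residual error.
#'
#' @param trials list of `tvor_trial` objects with masks computed.
#' @param latency_grid candidate latencies, seconds (default 10-80 ms by
#'   2 ms).
#' @param regressors `"both"` (the model), or `"velocity"` /
#'   `"acceleration"` for the single-term control fits.
#' @param ... passed to [robust_regress()].
#' @return a `linear_fit_result`: list with `g_v` ((deg/s)/(cm/s)), `g_a`
#'   ((deg/s)/(cm/s^2)), `delta_t` (s), `residual_ss` ((deg/s)^2),
#'   `n_samples`, `regressors`, and the per-latency residual profile
#'   `grid_rss`.
#' @export
fit_linear_model <- function(trials, latency_grid = seq(0.010, 0.080, 0.002),
                             regressors = c("both", "velocity",
                                            "acceleration"), ...) {
  regressors <- match.arg(regressors)
  if (!length(trials)) stop("at least one trial is required")
  n_par <- if (regressors == "both") 2L else 1L
  pick <- switch(regressors, both = 1:2, velocity = 1L, acceleration = 2L)

  rss <- rep(NA_real_, length(latency_grid))
  fits <- vector("list", length(latency_grid))
  n_used <- 0L
  for (j in seq_along(latency_grid)) {
    Xs <- list(); ys <- list()
    for (tr in trials) {
      keep <- !tr$eye$mask
      X <- delayed_regressors(tr$chair, latency_grid[j], tr$eye$time)
      Xs[[length(Xs) + 1L]] <- X[keep, pick, drop = FALSE]
      ys[[length(ys) + 1L]] <- tr$eye$velocity[keep]
    }
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    if (j == 1L) {
      n_used <- length(y)
      if (n_used < 10L * n_par)
        stop("insufficient unmasked samples for the linear fit")
    }
    b <- if (all(abs(y) < 1e-300)) stats::setNames(rep(0, length(pick)),
                                                   colnames(X))
         else robust_regress(X, y, ...)
    rss[j] <- sum((y - X %*% b)^2)
    fits[[j]] <- b
  }
  best <- which.min(rss)   # first minimum = smallest latency on ties
  b <- fits[[best]]
  structure(list(g_v = if ("v" %in% names(b)) b[["v"]] else 0,
                 g_a = if ("a" %in% names(b)) b[["a"]] else 0,
                 delta_t = latency_grid[best],
                 residual_ss = rss[best],
                 n_samples = n_used,
                 regressors = regressors,
                 grid_rss = data.frame(delta_t = latency_grid, rss = rss)),
            class = "linear_fit_result")
}

#' @export
print.linear_fit_result <- function(x, ...) {
  cat(sprintf(
    "linear tVOR fit (%s): g_v = %.4g, g_a = %.4g, delta_t = %.0f ms, rss = %.4g (n = %d)\n",
    x$regressors, x$g_v, x$g_a, 1000 * x$delta_t, x$residual_ss, x$n_samples))
  invisible(x)
}

#' Post/pre parameter ratios across matched conditions
#'
#' For matched pre- and post-lesion fits (same eye x direction conditions),
#' computes the per-condition post/pre ratios of `g_v` and `g_a`, their
#' means, and one-sample t-tests of ratio = 1.
#'
#' @param pre,post named lists of `linear_fit_result` objects; names encode
#'   the condition and must match between epochs.
#' @return list with `ratios` (one row per condition) and `summary` (one
#'   row per parameter: mean ratio, 95% CI, p-value for ratio = 1).
#' @export
compare_epochs <- function(pre, post) {
  if (is.null(names(pre)) || is.null(names(post)) ||
      !setequal(names(pre), names(post)) || !length(pre))
    stop("pre and post must be non-empty named lists with matching conditions")
  conds <- names(pre)
  ratios <- data.frame(
    condition = conds,
    g_v_ratio = vapply(conds, function(k) post[[k]]$g_v / pre[[k]]$g_v, 0),
    g_a_ratio = vapply(conds, function(k) post[[k]]$g_a / pre[[k]]$g_a, 0),
    row.names = NULL)
  summarize <- function(r) {
    if (length(r) > 1 && stats::sd(r) > 0) {
      tt <- stats::t.test(r, mu = 1)
      data.frame(mean_ratio = mean(r), ci_lo = tt$conf.int[1],
                 ci_hi = tt$conf.int[2], p_value = tt$p.value)
    } else {
      data.frame(mean_ratio = mean(r), ci_lo = NA_real_, ci_hi = NA_real_,
                 p_value = if (all(r == 1)) 1 else NA_real_)
    }
  }
  summary <- rbind(cbind(parameter = "g_v", summarize(ratios$g_v_ratio)),
                   cbind(parameter = "g_a", summarize(ratios$g_a_ratio)))
  list(ratios = ratios, summary = summary)
}
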
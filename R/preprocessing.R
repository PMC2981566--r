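# Slow-phase extraction, trial synchronization, and summary velocity
# profiles. Quick phases and saccades are detected from eye acceleration and
# jerk thresholds and excluded from all downstream fits.

#' Detect quick phases and saccades in an eye trace
#'
#' Flags samples whose absolute eye acceleration exceeds
#' `accel_threshold` (strictly) or absolute jerk exceeds `jerk_threshold`
#' (strictly). Derivatives are computed by Savitzky-Golay local-polynomial
#' differentiation of the velocity trace, which avoids the noise
#' amplification of sample differencing at 1 kHz. Flagged runs are dilated
#' by `margin` on each side to exclude pre- and post-saccadic shoulders that
#' sit below the thresholds.
#'
#' @param eye eye-trace data frame with columns `time` and `velocity`
#'   (uniformly sampled), or a `tvor_trial`.
#' @param accel_threshold acceleration threshold, deg/s^2 (default 1400).
#' @param jerk_threshold jerk threshold, deg/s^3 (default 50000).
#' @param margin dilation margin, seconds, applied on each side (default
#'   10 ms).
#' @param sg_window Savitzky-Golay window length, seconds (default 15 ms).
#' @param sg_order local polynomial order (default 3).
#' @return logical vector, `TRUE` for excluded (fast-phase) samples.
#' @export
detect_fast_phases <- function(eye, accel_threshold = 1400,
                               jerk_threshold = 50000, margin = 0.010,
                               sg_window = 0.015, sg_order = 3) {
  if (inherits(eye, "tvor_trial")) eye <- eye$eye
  vel <- eye$velocity
  dt <- median(diff(eye$time))
  n_win <- round(sg_window / dt)
  if (n_win %% 2 == 0) n_win <- n_win + 1L
  if (length(vel) < n_win)
    stop("trace shorter than the differentiation window")
  acc <- signal::sgolayfilt(vel, p = sg_order, n = n_win, m = 1, ts = dt)
  jerk <- signal::sgolayfilt(vel, p = sg_order, n = n_win, m = 2, ts = dt)
  flag <- abs(acc) > accel_threshold | abs(jerk) > jerk_threshold
  dilate_mask(flag, round(margin / dt))
}

# Dilate a logical mask by m samples on each side (coverage-count trick).
dilate_mask <- function(flag, m) {
  n <- length(flag)
  if (m <= 0 || !any(flag)) return(flag)
  idx <- which(flag)
  starts <- pmax(idx - m, 1L)
  ends <- pmin(idx + m, n)
  inc <- tabulate(starts, nbins = n)
  dec <- tabulate(ends + 1L, nbins = n + 1L)[1:n]
  cumsum(inc - dec) > 0
}

#' Apply fast-phase detection to every trial of a session
#'
#' @param trials list of `tvor_trial` objects.
#' @param ... passed to [detect_fast_phases()].
#' @return the trials with their `eye$mask` columns filled in.
#' @export
mask_session <- function(trials, ...) {
  out <- lapply(trials, function(tr) {
    tr$eye$mask <- detect_fast_phases(tr$eye, ...)
    tr
  })
  attributes(out) <- attributes(trials)
  out
}

#' Synchronize trials on chair motion onset
#'
#' Shifts each trial's time axes so that `t = 0` falls on the first chair
#' sample whose speed reaches 1 cm/s (the synchronization threshold).
#' Trials whose chair speed never crosses the threshold are dropped with a
#' warning. The operation is idempotent.
#'
#' @param trials list of `tvor_trial` objects.
#' @param threshold chair speed threshold, cm/s.
#' @return the synchronized trials (possibly fewer than supplied).
#' @export
synchronize_trials <- function(trials, threshold = 1) {
  out <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    k <- which(abs(tr$chair$v) >= threshold)
    if (!length(k)) {
      warning(sprintf("trial %d rejected: chair speed never reaches %g cm/s",
                      i, threshold))
      next
    }
    t0 <- tr$chair$time[k[1]]
    tr$chair$time <- tr$chair$time - t0
    for (a in c("motion_onset", "motion_end"))
      if (!is.null(attr(tr$chair, a)))
        attr(tr$chair, a) <- attr(tr$chair, a) - t0
    tr$eye$time <- tr$eye$time - t0
    out[[length(out) + 1L]] <- tr
  }
  attributes(out) <- attributes(trials)[setdiff(names(attributes(trials)),
                                                "names")]
  out
}

#' Median velocity profile across trials
#'
#' Per-sample median and 25th/75th percentiles of slow-phase eye velocity
#' across synchronized trials, using unmasked samples only. Percentiles use
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param trials synchronized, masked `tvor_trial` list.
#' @param window time window `c(from, to)` relative to synchronization,
#'   seconds (default the first 400 ms).
#' @return a `velocity_profile` data frame: `time`, `median`, `p25`, `p75`,
#'   `n_trials`; samples with no unmasked contribution are `NA`.
#' @export
median_velocity_profile <- function(trials, window = c(0, 0.4)) {
  if (!length(trials)) stop("at least one trial is required")
  dt <- median(diff(trials[[1]]$eye$time))
  grid <- seq(window[1], window[2], by = dt)
  vals <- sapply(trials, function(tr) {
    v <- tr$eye$velocity
    v[tr$eye$mask] <- NA_real_
    idx <- round((grid - tr$eye$time[1]) / dt) + 1L
    ok <- idx >= 1L & idx <= length(v) &
      abs(tr$eye$time[pmax(pmin(idx, length(v)), 1L)] - grid) < dt / 2
    out <- rep(NA_real_, length(grid))
    out[ok] <- v[idx[ok]]
    out
  })
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(!is.na(vals))
  q <- t(apply(vals, 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  }))
  structure(data.frame(time = grid, median = q[, 2], p25 = q[, 1],
                       p75 = q[, 3], n_trials = n),
            class = c("velocity_profile", "data.frame"))
}
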
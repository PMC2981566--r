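# Synthetic trial generator. Stands in for the monkey recordings: slow-phase
# eye velocity from the forward dynamic model, plus band-limited measurement
# noise and injected quick phases, organized into sessions labelled by
# animal, eye, motion direction, viewing distance, target condition and
# epoch (pre/post lesion, i.e. two parameter regimes).

#' Noise and quick-phase specification for synthetic trials
#'
#' The recordings the generator emulates are not noise-characterized in any
#' deposited form, so this is deliberately simple: additive Gaussian velocity
#' noise low-pass filtered at `bandwidth` (default 20 Hz, below the band the
#' fast-phase detector differentiates, so slow-phase noise is not itself
#' classified as saccadic), rescaled after filtering so its standard
#' deviation equals `velocity_sd`; quick phases as raised-cosine
#' velocity pulses whose amplitude/duration ranges guarantee peak
#' accelerations above the slow-phase detection thresholds.
#'
#' @param velocity_sd standard deviation of velocity noise, deg/s (>= 0).
#' @param bandwidth noise low-pass corner, Hz.
#' @param qp_rate quick-phase rate, events per second (>= 0).
#' @param qp_amplitude quick-phase peak-velocity range, deg/s.
#' @param qp_duration quick-phase duration range, seconds.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(velocity_sd = 2, bandwidth = 20, qp_rate = 1,
                       qp_amplitude = c(20, 60), qp_duration = c(0.02, 0.04)) {
  if (velocity_sd < 0 || qp_rate < 0)
    stop("velocity_sd and qp_rate must be non-negative")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  structure(list(velocity_sd = velocity_sd, bandwidth = bandwidth,
                 qp_rate = qp_rate, qp_amplitude = sort(qp_amplitude),
                 qp_duration = sort(qp_duration)),
            class = "noise_spec")
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

band_limited_noise <- function(n, sd, bandwidth, dt) {
  e <- stats::rnorm(n)
  ny <- 0.5 / dt
  if (bandwidth < ny) {
    bf <- signal::butter(2, bandwidth / ny)
    e <- signal::filtfilt(bf, e)
  }
  s <- stats::sd(e)
  if (s > 0) e * (sd / s) else e
}

raised_cosine_pulse <- function(time, onset, duration, amplitude) {
  u <- (time - onset) / duration
  v <- numeric(length(time))
  inside <- u >= 0 & u <= 1
  v[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  v
}

#' Generate one synthetic translation trial
#'
#' Runs the forward dynamic model on the protocol's trapezoidal trajectory,
#' adds band-limited velocity noise, and injects quick phases at Poisson
#' times. Ground-truth parameters and quick-phase windows are stored in the
#' trial metadata so parameter-recovery tests can score themselves.
#' Deterministic for a given `seed`.
#'
#' @param params a [model_parameters()] object (its `distance` is the trial's
#'   viewing distance).
#' @param protocol a [stimulus_protocol()].
#' @param noise a [noise_spec()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param meta named list of condition metadata overrides (`animal`, `eye`,
#'   `target`, `epoch`).
#' @param dt eye sampling period, seconds (default 1 ms).
#' @return a `tvor_trial`: list with elements `chair` (`chair_trajectory`),
#'   `eye` (data frame `time`, `position`, `velocity`, `mask`) and `meta`.
#' @export
generate_trial <- function(params, protocol, noise = noise_spec(),
                           seed = NULL, meta = list(), dt = 0.001) {
  validate_parameters(params)
  if (!inherits(noise, "noise_spec")) stop("noise must be a noise_spec")
  with_local_seed(seed, {
    chair <- make_trapezoid_profile(protocol)
    sim <- simulate_tvor(params, chair, dt = dt)
    vel <- sim$eye_velocity
    n <- length(vel)

    if (noise$velocity_sd > 0)
      vel <- vel + band_limited_noise(n, noise$velocity_sd,
                                      noise$bandwidth, dt)

    qp <- data.frame(onset = numeric(0), duration = numeric(0),
                     amplitude = numeric(0))
    if (noise$qp_rate > 0) {
      span <- sim$time[n]
      k <- stats::rpois(1, noise$qp_rate * span)
      if (k > 0) {
        qp <- data.frame(
          onset = sort(stats::runif(k, 0, span - max(noise$qp_duration))),
          duration = stats::runif(k, noise$qp_duration[1],
                                  noise$qp_duration[2]),
          amplitude = stats::runif(k, noise$qp_amplitude[1],
                                   noise$qp_amplitude[2]) *
            sample(c(-1, 1), k, replace = TRUE))
        for (i in seq_len(k))
          vel <- vel + raised_cosine_pulse(sim$time, qp$onset[i],
                                           qp$duration[i], qp$amplitude[i])
      }
    }

    pos <- sim$eye_position +
      pracma::cumtrapz(sim$time, vel - sim$eye_velocity)[, 1]

    meta_full <- utils::modifyList(
      list(animal = "M1", eye = "L", direction = protocol$direction,
           distance = params$distance, target = "off", epoch = "pre"),
      meta)
    meta_full$ground_truth <- list(G_i = params$G_i, G_acc = params$G_acc,
                                   tau_delay = params$tau_delay)
    meta_full$quick_phases <- qp
    meta_full$seed <- seed

    structure(list(chair = chair,
                   eye = data.frame(time = sim$time, position = pos,
                                    velocity = vel,
                                    mask = rep(FALSE, n)),
                   meta = meta_full),
              class = "tvor_trial")
  })
}

#' @export
print.tvor_trial <- function(x, ...) {
  m <- x$meta
  cat(sprintf("tVOR trial: %s eye %s, %s, %g cm, target %s, epoch %s (%d samples)\n",
              m$animal, m$eye, m$direction, m$distance, m$target, m$epoch,
              nrow(x$eye)))
  invisible(x)
}

#' Post-lesion parameter surrogate
#'
#' Scales the pathway gains of a parameter set, emulating the effect of a
#' nodulus/uvula lesion: a large drop in the integrated-pathway gain with
#' the direct acceleration pathway largely spared.
#'
#' @param params a [model_parameters()] object (the pre-lesion regime).
#' @param gi_scale,gacc_scale multiplicative scalings of `G_i` and `G_acc`
#'   (defaults 0.38 and 0.87, i.e. 62% and 13% decreases).
#' @return the scaled `tvor_parameters`.
#' @export
lesion_params <- function(params, gi_scale = 0.38, gacc_scale = 0.87) {
  params$G_i <- params$G_i * gi_scale
  params$G_acc <- params$G_acc * gacc_scale
  validate_parameters(params)
  params
}

#' Generate a session of synthetic trials across conditions
#'
#' Emulates the experimental session structure: for each epoch, eye and
#' viewing distance, `n_trials` trials are generated with alternating
#' leftward/rightward motion. Each trial gets its own sub-seed drawn from
#' the session stream, recorded in the trial metadata, so the session is
#' reproducible as a whole and any trial individually.
#'
#' @param pre_params pre-lesion [model_parameters()].
#' @param post_params post-lesion parameters, or `NULL` to skip the post
#'   epoch (see [lesion_params()]).
#' @param n_trials trials per epoch x eye x distance x direction (>= 1).
#' @param distances viewing distances, cm.
#' @param eyes recorded eyes, subset of `c("L", "R")`.
#' @param protocol base [stimulus_protocol()]; its direction field is
#'   overridden by the alternation.
#' @param noise a [noise_spec()].
#' @param seed session seed.
#' @return a `tvor_session`: list of `tvor_trial` objects with a manifest
#'   data frame attached as attribute `"manifest"`.
#' @export
generate_session <- function(pre_params, post_params = NULL, n_trials = 4,
                             distances = c(27, 70), eyes = c("L", "R"),
                             protocol = stimulus_protocol(),
                             noise = noise_spec(), seed = 1) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (!length(distances) || !length(eyes))
    stop("condition lists must be non-empty")
  regimes <- list(pre = pre_params)
  if (!is.null(post_params)) regimes$post <- post_params
  with_local_seed(seed, {
    trials <- list()
    rows <- list()
    for (epoch in names(regimes)) {
      for (d in distances) {
        for (eye in eyes) {
          pars <- regimes[[epoch]]
          pars$distance <- d
          dirs <- rep(c("left", "right"), length.out = 2 * n_trials)
          for (i in seq_along(dirs)) {
            pr <- protocol
            pr$direction <- dirs[i]
            sub_seed <- sample.int(.Machine$integer.max, 1)
            tr <- generate_trial(pars, pr, noise, seed = sub_seed,
                                 meta = list(eye = eye, epoch = epoch))
            trials[[length(trials) + 1L]] <- tr
            rows[[length(rows) + 1L]] <- data.frame(
              index = length(trials), animal = tr$meta$animal, eye = eye,
              direction = dirs[i], distance = d, target = "off",
              epoch = epoch, seed = sub_seed,
              G_i = pars$G_i, G_acc = pars$G_acc,
              tau_delay = pars$tau_delay)
          }
        }
      }
    }
    structure(trials, manifest = do.call(rbind, rows),
              session_seed = seed, class = "tvor_session")
  })
}

#' Subset a session by condition metadata
#'
#' @param session a `tvor_session` (or plain list of trials).
#' @param ... named condition values to match against trial metadata, e.g.
#'   `epoch = "pre"`, `distance = 70`, `direction = "left"`, `eye = "L"`.
#' @return list of matching trials.
#' @export
session_subset <- function(session, ...) {
  want <- list(...)
  keep <- vapply(session, function(tr) {
    all(vapply(names(want), function(k)
      identical(as.character(tr$meta[[k]]), as.character(want[[k]])),
      logical(1)))
  }, logical(1))
  session[keep]
}
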
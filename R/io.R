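# Trial serialization and the end-to-end pipeline. Trials are stored as
# delimited text (schema-versioned) with a JSON sidecar: there is no
# standard interchange format for oculomotor time series, so the package
# uses a documented simple dialect. The eye trace occupies every row of the
# table; the chair signal, recorded on its own coarser grid, occupies the
# rows whose times coincide with chair samples and is NA elsewhere, making
# the round trip lossless for both grids.

TRIAL_SCHEMA_VERSION <- "1.0"

meta_vocab <- list(direction = c("left", "right"),
                   target = c("on", "off"),
                   epoch = c("pre", "post"),
                   eye = c("L", "R"))

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a trial to a delimited text file with a JSON sidecar
#'
#' @param trial a `tvor_trial`.
#' @param path output path for the table; the sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  eye <- trial$eye
  chair <- trial$chair
  dt <- median(diff(eye$time))
  idx <- round((chair$time - eye$time[1]) / dt) + 1L
  if (any(idx < 1L | idx > nrow(eye)) ||
      max(abs(eye$time[idx] - chair$time)) > dt / 2)
    stop("chair grid is not alignable with the eye grid")
  tab <- data.frame(t = fmt17(eye$time),
                    chair_x = "NA", chair_v = "NA", chair_a = "NA",
                    eye_pos = fmt17(eye$position),
                    eye_vel = fmt17(eye$velocity),
                    mask = as.integer(eye$mask),
                    stringsAsFactors = FALSE)
  tab$chair_x[idx] <- fmt17(chair$x)
  tab$chair_v[idx] <- fmt17(chair$v)
  tab$chair_a[idx] <- fmt17(chair$a)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- trial$meta
  side <- list(schema_version = TRIAL_SCHEMA_VERSION,
               meta = meta[setdiff(names(meta), "quick_phases")],
               quick_phases = meta$quick_phases,
               protocol = unclass(attr(chair, "protocol")),
               motion_onset = attr(chair, "motion_onset"),
               motion_end = attr(chair, "motion_end"))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", "", path) |> paste0(".json")

parse_fail <- function(path, field, why)
  stop(sprintf("malformed trial file %s: field '%s' %s", path, field, why))

# JSON round-trips may narrow doubles to integers; restore numeric fields.
as_protocol <- function(lst) {
  lst <- as.list(lst)
  for (f in c("a_accel", "v_peak", "t_const", "a_decel",
              "displacement_nominal"))
    if (!is.null(lst[[f]])) lst[[f]] <- as.numeric(lst[[f]])
  structure(lst, class = "stimulus_protocol")
}

#' Read a trial file back into a trial object
#'
#' @param path path of the table file.
#' @return a `tvor_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path) || !file.exists(sidecar_path(path)))
    stop("trial file or sidecar not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "numeric")
  need <- c("t", "chair_x", "chair_v", "chair_a", "eye_pos", "eye_vel",
            "mask")
  if (!all(need %in% names(tab)))
    parse_fail(path, setdiff(need, names(tab))[1], "is missing")
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(side$schema_version))
    parse_fail(path, "schema_version", "is missing")
  meta <- side$meta
  for (field in names(meta_vocab)) {
    v <- meta[[field]]
    if (!is.null(v) && !v %in% meta_vocab[[field]])
      parse_fail(path, field,
                 sprintf("has unknown value '%s' (allowed: %s)", v,
                         paste(meta_vocab[[field]], collapse = ", ")))
  }
  if (!is.null(side$quick_phases) && length(side$quick_phases))
    meta$quick_phases <- as.data.frame(side$quick_phases)
  ci <- !is.na(tab$chair_x)
  chair <- data.frame(time = tab$t[ci], x = tab$chair_x[ci],
                      v = tab$chair_v[ci], a = tab$chair_a[ci])
  proto <- side$protocol
  if (!is.null(proto))
    attr(chair, "protocol") <- as_protocol(proto)
  attr(chair, "motion_onset") <- side$motion_onset
  attr(chair, "motion_end") <- side$motion_end
  class(chair) <- c("chair_trajectory", "data.frame")
  structure(list(chair = chair,
                 eye = data.frame(time = tab$t, position = tab$eye_pos,
                                  velocity = tab$eye_vel,
                                  mask = as.logical(tab$mask)),
                 meta = meta),
            class = "tvor_trial")
}

#' Write a chair trajectory (or simulation) to a delimited text file
#'
#' @param x a `chair_trajectory` or `tvor_simulation` data frame.
#' @param path output path; a JSON sidecar with the protocol / motion
#'   interval is written next to it.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  tab <- as.data.frame(lapply(as.data.frame(x), fmt17))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(schema_version = TRIAL_SCHEMA_VERSION,
                            protocol = unclass(attr(x, "protocol")),
                            motion_onset = attr(x, "motion_onset"),
                            motion_end = attr(x, "motion_end")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-series file back into a data frame
#'
#' @param path table path.
#' @return data frame; chair trajectories regain their class and protocol.
#' @export
read_timeseries <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "numeric")
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(side$protocol))
      attr(tab, "protocol") <- as_protocol(side$protocol)
    attr(tab, "motion_onset") <- side$motion_onset
    attr(tab, "motion_end") <- side$motion_end
  }
  if (all(c("time", "x", "v", "a") %in% names(tab)))
    class(tab) <- c("chair_trajectory", "data.frame")
  tab
}

#' Write a session (trials plus manifest) to a directory
#'
#' @param session a `tvor_session`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- attr(session, "manifest")
  files <- sprintf("trial_%04d.tsv", seq_along(session))
  for (i in seq_along(session))
    write_trial(session[[i]], file.path(dir, files[i]))
  manifest$file <- files
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(schema_version = TRIAL_SCHEMA_VERSION,
                            session_seed = attr(session, "session_seed"),
                            trials = manifest),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory containing `manifest.json`.
#' @return a `tvor_session`.
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest.json not found in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  trials <- lapply(man$trials$file,
                   function(f) read_trial(file.path(dir, f)))
  for (f in man$trials$file)
    if (!file.exists(file.path(dir, f)))
      stop("manifest references missing trial file: ", f)
  structure(trials, manifest = man$trials,
            session_seed = man$session_seed, class = "tvor_session")
}

#' Default configuration for [run_pipeline()]
#'
#' @param seed session seed.
#' @param n_trials trials per condition cell.
#' @param distances viewing distances, cm.
#' @param eyes recorded eyes.
#' @return a configuration list.
#' @export
default_pipeline_config <- function(seed = 1, n_trials = 3,
                                    distances = 70, eyes = "L") {
  list(seed = seed, n_trials = n_trials, distances = distances,
       eyes = eyes,
       protocol = stimulus_protocol(),
       pre_params = model_parameters(),
       gi_scale = 0.38, gacc_scale = 0.87,
       noise = noise_spec(),
       fit_model = TRUE, sensitivity = TRUE, compare_models = TRUE,
       n_starts = 2)
}

pipeline_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  log(sprintf("stage %s: done", name))
  out
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes synthesis, preprocessing, the linear fit, the dynamic-model
#' fit and lesion contrast, a sensitivity sweep and the prior-model
#' comparison, writing all tables, the synthetic session and a run log to
#' `out_dir`. Rerunning with the same configuration reproduces identical
#' outputs.
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @param out_dir output directory.
#' @return list of result objects, invisibly; tables are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("tvor_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    writeLines(line, log_con); message(line)
  }
  log(sprintf("tvorsim %s, seed %d",
              as.character(utils::packageVersion("tvorsim")), config$seed))

  if (config$n_trials < 1)
    stop("pipeline stage 'synth' failed: zero trials configured",
         call. = FALSE)
  post_params <- lesion_params(config$pre_params, config$gi_scale,
                               config$gacc_scale)
  session <- pipeline_stage("synth", log,
    generate_session(config$pre_params, post_params,
                     n_trials = config$n_trials,
                     distances = config$distances, eyes = config$eyes,
                     protocol = config$protocol, noise = config$noise,
                     seed = config$seed))
  write_session(session, file.path(out_dir, "session"))

  session <- pipeline_stage("preprocess", log,
    synchronize_trials(mask_session(session)))
  prof <- median_velocity_profile(
    session_subset(session, epoch = "pre", direction = "left"))
  utils::write.table(prof, file.path(out_dir, "profile_pre_left.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  conds <- expand.grid(eye = config$eyes, distance = config$distances,
                       direction = c("left", "right"),
                       stringsAsFactors = FALSE)
  cond_name <- function(cc) paste(cc$eye, cc$distance, cc$direction,
                                  sep = "/")
  subset_cond <- function(epoch, cc)
    session_subset(session, epoch = epoch, eye = cc$eye,
                   distance = cc$distance, direction = cc$direction)

  lin <- pipeline_stage("fit-linear", log, {
    fits <- list(pre = list(), post = list())
    for (i in seq_len(nrow(conds))) {
      cc <- conds[i, ]
      for (ep in c("pre", "post"))
        fits[[ep]][[cond_name(cc)]] <- fit_linear_model(subset_cond(ep, cc))
    }
    fits
  })
  lin_tab <- do.call(rbind, lapply(c("pre", "post"), function(ep)
    do.call(rbind, lapply(names(lin[[ep]]), function(k) {
      f <- lin[[ep]][[k]]
      data.frame(epoch = ep, condition = k, g_v = f$g_v, g_a = f$g_a,
                 delta_t = f$delta_t, residual_ss = f$residual_ss,
                 n_samples = f$n_samples)
    }))))
  utils::write.table(lin_tab, file.path(out_dir, "linear_fits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ratios <- compare_epochs(lin$pre, lin$post)
  utils::write.table(ratios$summary, file.path(out_dir,
                                               "linear_ratio_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  results <- list(session = session, linear = lin, linear_ratios = ratios)

  if (isTRUE(config$fit_model)) {
    mod <- pipeline_stage("fit-model", log, {
      fits <- list(pre = list(), post = list())
      for (i in seq_len(nrow(conds))) {
        cc <- conds[i, ]
        for (ep in c("pre", "post"))
          fits[[ep]][[cond_name(cc)]] <- optimize_parameters(
            subset_cond(ep, cc), config$pre_params,
            n_starts = config$n_starts, seed = config$seed + i)
      }
      fits
    })
    mod_tab <- do.call(rbind, lapply(c("pre", "post"), function(ep)
      do.call(rbind, lapply(names(mod[[ep]]), function(k) {
        f <- mod[[ep]][[k]]
        data.frame(epoch = ep, condition = k, tau_delay = f$tau_delay,
                   G_acc = f$G_acc, G_i = f$G_i,
                   residual_ss = f$residual_ss, converged = f$converged)
      }))))
    utils::write.table(mod_tab, file.path(out_dir, "model_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    contrast <- lesion_contrast(mod$pre, mod$post)
    utils::write.table(contrast$summary,
                       file.path(out_dir, "lesion_contrast.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$model_fits <- mod
    results$lesion_contrast <- contrast

    if (isTRUE(config$sensitivity)) {
      ref <- session_subset(session, epoch = "pre", direction = "left",
                            eye = config$eyes[1],
                            distance = config$distances[1])
      base <- mod$pre[[cond_name(data.frame(
        eye = config$eyes[1], distance = config$distances[1],
        direction = "left"))]]$params
      sens <- pipeline_stage("sensitivity", log, {
        lapply(c(g_a = "g_a", g_v = "g_v", delay = "delay"), function(pp)
          sweep_1d(base, pp, fractions = seq(-0.5, 0.5, 0.25),
                   trials = ref))
      })
      sens_tab <- do.call(rbind, lapply(names(sens), function(nm)
        cbind(parameter = nm, sens[[nm]])))
      utils::write.table(sens_tab, file.path(out_dir, "sensitivity.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      results$sensitivity <- sens
    }
  }

  if (isTRUE(config$compare_models)) {
    cmp <- pipeline_stage("compare-models", log, {
      traj <- make_trapezoid_profile(config$protocol)
      specs <- list(prior_model_spec("proposed"),
                    prior_model_spec("telford"),
                    prior_model_spec("green_galiana"),
                    prior_model_spec("angelaki"))
      step_comparison(specs, traj)
    })
    utils::write.table(cmp, file.path(out_dir, "model_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$comparison <- cmp
  }

  log("pipeline complete")
  invisible(results)
}
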
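test_that("thresholds are strict and exact on polynomial ramps", {
  t_grid <- seq(0, 0.5, by = 0.001)
  # constant velocity: nothing to flag
  flat <- data.frame(time = t_grid, velocity = rep(25, length(t_grid)))
  expect_false(any(detect_fast_phases(flat)))
  # the threshold is a strict inequality; probe it from both sides (an
  # exactly-threshold ramp is indeterminate at floating-point precision)
  ramp <- data.frame(time = t_grid, velocity = (1400 - 1e-6) * t_grid)
  expect_false(any(detect_fast_phases(ramp)))
  over <- data.frame(time = t_grid, velocity = 1402 * t_grid)
  expect_true(all(detect_fast_phases(over)))
  # jerk threshold, same convention; keep the window short so the
  # accompanying acceleration stays below its own threshold
  t_short <- seq(0, 0.02, by = 0.001)
  jerk <- data.frame(time = t_short,
                     velocity = 0.5 * (50000 - 0.1) * t_short^2)
  expect_false(any(detect_fast_phases(jerk)))
  jerk2 <- data.frame(time = t_short, velocity = 0.5 * 50400 * t_short^2)
  expect_true(any(detect_fast_phases(jerk2)))
  expect_error(detect_fast_phases(data.frame(time = t_grid[1:5],
                                             velocity = rep(0, 5))),
               "shorter")
})

test_that("an injected pulse is flagged with its shoulders dilated", {
  p <- model_parameters()
  tr <- noiseless_trial(p)
  pulse <- 30 * 0.5 * (1 - cos(2 * pi * pmax(pmin(
    (tr$eye$time - 0.4) / 0.03, 1), 0)))   # 30 deg/s, 30 ms: ~3100 deg/s^2
  tr$eye$velocity <- tr$eye$velocity + pulse
  flag <- detect_fast_phases(tr$eye)
  core <- tr$eye$time >= 0.4 & tr$eye$time <= 0.43
  expect_true(all(flag[core]))
  far <- tr$eye$time < 0.37 | tr$eye$time > 0.46
  expect_false(any(flag[far]))
})

test_that("detection separates quick phases from slow phase across a session", {
  p <- model_parameters()
  ns <- noise_spec(velocity_sd = 0, qp_rate = 2)
  hits <- misses <- false_pos <- slow_n <- 0
  set.seed(7)
  for (i in 1:100) {
    tr <- generate_trial(p, std_protocol(c("left", "right")[1 + i %% 2]), ns)
    flag <- detect_fast_phases(tr$eye)
    qp <- tr$meta$quick_phases
    inside <- rep(FALSE, nrow(tr$eye))
    for (k in seq_len(nrow(qp)))
      inside <- inside | (tr$eye$time >= qp$onset[k] &
                            tr$eye$time <= qp$onset[k] + qp$duration[k])
    # slow-phase reference: clear of the dilated quick-phase windows
    near <- rep(FALSE, nrow(tr$eye))
    for (k in seq_len(nrow(qp)))
      near <- near | (tr$eye$time >= qp$onset[k] - 0.015 &
                        tr$eye$time <= qp$onset[k] + qp$duration[k] + 0.015)
    hits <- hits + sum(flag & inside); misses <- misses + sum(!flag & inside)
    false_pos <- false_pos + sum(flag & !near)
    slow_n <- slow_n + sum(!near)
  }
  expect_gt(hits / (hits + misses), 0.99)
  expect_lt(false_pos / slow_n, 0.01)
})

test_that("synchronization lands within one chair sample of motion onset", {
  p <- model_parameters()
  tr <- noiseless_trial(p)
  out <- synchronize_trials(list(tr))
  ch <- out[[1]]$chair
  # threshold crossing: v/a = 1/254.97 s = 3.9 ms after true onset
  expect_equal(attr(ch, "motion_onset"), -0.004, tolerance = 0.0021)
  expect_identical(which(abs(ch$v) >= 1)[1], which(ch$time == 0))
  # idempotence
  again <- synchronize_trials(out)
  expect_identical(again[[1]]$chair$time, ch$time)
  expect_identical(again[[1]]$eye$time, out[[1]]$eye$time)
  # a stationary chair is rejected with a warning
  still <- tr
  still$chair$v <- 0 * still$chair$v
  expect_warning(res <- synchronize_trials(list(still)), "rejected")
  expect_length(res, 0)
})

test_that("velocity profiles use the documented percentile rule", {
  trials <- list(flat_trial(1), flat_trial(2), flat_trial(9))
  prof <- median_velocity_profile(trials)
  expect_true(all(prof$median == 2))
  expect_true(all(prof$p25 == 1.5))   # type-7 linear interpolation
  expect_true(all(prof$p75 == 5.5))
  expect_true(all(prof$n_trials == 3))
  expect_true(all(prof$p25 <= prof$median & prof$median <= prof$p75))

  # identical trials collapse the quartiles onto the median
  same <- list(flat_trial(4), flat_trial(4))
  ps <- median_velocity_profile(same)
  expect_true(all(ps$median == 4 & ps$p25 == 4 & ps$p75 == 4))

  # a masked trial drops out of the per-sample statistics
  masked <- list(flat_trial(1), flat_trial(2), flat_trial(9, mask = TRUE))
  pm <- median_velocity_profile(masked)
  expect_true(all(pm$median == 1.5))
  expect_true(all(pm$n_trials == 2))

  # all contributions masked -> missing values
  gone <- median_velocity_profile(list(flat_trial(1, mask = TRUE)))
  expect_true(all(is.na(gone$median)))
  expect_true(all(gone$n_trials == 0))
  expect_error(median_velocity_profile(list()), "at least one")
})
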
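test_that("parameter validation enforces the documented bounds", {
  expect_error(model_parameters(G_i = -0.1), "non-negative")
  expect_error(model_parameters(tau_delay = 0.08), "0.075")
  expect_error(model_parameters(ni_tc = -1), "positive")
  expect_error(model_parameters(plant_order = "first",
                                plant_tc = c(0.1, 0.2)), "1 time constant")
  expect_error(model_parameters(otolith = list(k = 1, T_lead = -1,
                                               T_lag = 0.1)), "positive")
})

test_that("the otolith block passes identity and lead-lag oracles", {
  p <- model_parameters()                       # T_lead == T_lag: pure gain
  traj <- make_trapezoid_profile(std_protocol())
  u <- traj$a
  y <- lti_simulate(otolith_tf(p)$den, list(otolith_tf(p)$num), u, 0.002)[, 1]
  expect_equal(y, u, tolerance = 1e-9)

  p2 <- model_parameters(otolith = list(k = 0.9, T_lead = 0.1, T_lag = 0.016))
  oto <- otolith_tf(p2)
  # DC limit: step input settles at k * amplitude
  step <- lti_simulate(oto$den, list(oto$num), rep(2, 2000), 0.001)[, 1]
  expect_equal(step[2000], 1.8, tolerance = 1e-4)
  # sinusoid amplitude ratio equals |k (1 + i w T_lead) / (1 + i w T_lag)|
  # (fine step: the zero-order hold leaves ripple on the lead feedthrough)
  f <- 2; dt <- 5e-5; t_grid <- seq(0, 5, by = dt)
  y <- lti_simulate(oto$den, list(oto$num), sin(2 * pi * f * t_grid),
                    dt)[, 1]
  w <- 2 * pi * f
  expect_equal(max(abs(y[t_grid > 4])),
               Mod(0.9 * (1 + 1i * w * 0.1) / (1 + 1i * w * 0.016)),
               tolerance = 1e-3)
})

test_that("both plant orders are unity-DC low-pass blocks", {
  p1 <- model_parameters(plant_order = "first")
  step <- lti_simulate(plant_tf(p1)$den, list(plant_tf(p1)$num),
                       rep(1, 2000), 0.001)[, 1]
  t_grid <- (0:1999) * 0.001
  expect_equal(step, 1 - exp(-t_grid / 0.25), tolerance = 2e-3)
  p3 <- model_parameters()
  expect_equal(sum(plant_tf(p3)$num) / plant_tf(p3)$den[length(plant_tf(p3)$den)], 1)
})

test_that("null gains give zero output and superposition holds exactly", {
  traj <- make_trapezoid_profile(std_protocol())
  p0 <- model_parameters(G_i = 0, G_acc = 0)
  expect_lt(max(abs(simulate_tvor(p0, traj)$eye_velocity)), 1e-12)

  p <- model_parameters()
  s1 <- simulate_tvor(p, traj)
  big <- traj; big$a <- 2 * big$a; big$v <- 2 * big$v; big$x <- 2 * big$x
  s2 <- simulate_tvor(p, big)
  expect_lt(max(abs(s2$eye_velocity - 2 * s1$eye_velocity)) /
              max(abs(s1$eye_velocity)), 1e-9)
  expect_lt(max(abs(s2$eye_position - 2 * s1$eye_position)) /
              max(abs(s1$eye_position)), 1e-9)
})

test_that("sustained head velocity drives the closed-form steady response", {
  # constant-velocity cruise: hold the plateau long enough for the plant to
  # settle; make the NI time constant effectively infinite so the velocity
  # response has a clean DC limit
  proto <- stimulus_protocol(t_const = 3)
  traj <- make_trapezoid_profile(proto, t_post = 0.1)
  p <- model_parameters(ni_tc = 1e6)
  sim <- simulate_tvor(p, traj)
  t_probe <- attr(traj, "motion_end") - 0.2
  v_sim <- stats::approx(sim$time, sim$eye_velocity, xout = t_probe)$y
  # closed-form DC gain of the chain for a velocity input
  v_pred <- p$G_i * p$otolith$k * (180 / pi) / p$distance * 40
  expect_equal(v_sim, v_pred, tolerance = 0.02)
})

test_that("halving the target distance doubles the angular response", {
  traj <- make_trapezoid_profile(std_protocol())
  s70 <- simulate_tvor(model_parameters(distance = 70), traj)
  s35 <- simulate_tvor(model_parameters(distance = 35), traj)
  expect_equal(s35$eye_velocity, 2 * s70$eye_velocity, tolerance = 1e-6)
})

test_that("eye position is held after motion end with the 20 s NI leak", {
  traj <- make_trapezoid_profile(std_protocol(), t_post = 1.0)
  sim <- simulate_tvor(model_parameters(), traj, duration = 2)
  t_end <- attr(traj, "motion_end")
  pos_end <- stats::approx(sim$time, sim$eye_position, xout = t_end + 0.05)$y
  pos_late <- stats::approx(sim$time, sim$eye_position,
                            xout = t_end + 0.05 + 0.5)$y
  decay <- 1 - pos_late / pos_end
  expect_lt(decay, 0.03)           # closed form: 1 - exp(-0.5/20) ~ 2.5%
  expect_gt(decay, 0.01)
})

test_that("simulation guards its preconditions", {
  traj <- make_trapezoid_profile(std_protocol())
  p <- model_parameters()
  expect_error(simulate_tvor(p, traj, duration = 0.5), "duration")
  expect_error(simulate_tvor(p, traj, dt = -1), "positive")
})

test_that("time-domain frequency response matches the analytic Bode oracle", {
  p <- model_parameters()
  freqs <- c(0.01, 0.05, 0.2, 1, 4)
  fr <- frequency_response(p, freqs)
  for (i in seq_along(freqs)) {
    o <- oracle_gain_phase(p, freqs[i])
    expect_lt(abs(fr$gain[i] - o[["gain"]]) / o[["gain"]], 0.01)
    dphi <- (fr$phase[i] - o[["phase"]] + 180) %% 360 - 180
    expect_lt(abs(dphi), 1)
  }
  expect_error(frequency_response(p, c(1, -2)), "positive")
})

test_that("normalization forces unit gain at 1 Hz", {
  fr <- frequency_response(model_parameters(), c(0.5, 1, 2),
                           normalize = TRUE)
  expect_identical(fr$gain[fr$freq == 1], 1)
})

test_that("a leaky tVOR integrator only alters the lowest frequencies", {
  freqs <- c(0.01, 2, 4)
  pure <- frequency_response(model_parameters(), freqs)
  leaky <- frequency_response(
    model_parameters(tvor_integrator_tc = 10), freqs)
  rel <- abs(leaky$gain - pure$gain) / pure$gain
  expect_gt(rel[1], 0.05)      # divergence at 0.01 Hz
  expect_lt(rel[2], 0.01)      # mid/high band unchanged
  expect_lt(rel[3], 0.01)
})
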
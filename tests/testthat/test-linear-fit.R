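test_that("robust regression matches OLS on clean data and resists outliers", {
  set.seed(42)
  n <- 1e4
  X <- cbind(v = rnorm(n), a = rnorm(n))
  y <- 2 * X[, 1] + 0.05 * X[, 2] + rnorm(n)
  b_rob <- robust_regress(X, y)
  ols <- stats::lm.fit(X, y)
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) *
               sum(ols$residuals^2) / (n - 2))
  expect_lt(max(abs(b_rob - ols$coefficients) / se), 2)

  # 5% gross one-sided outliers aligned with the first regressor
  y_out <- y
  bad <- sample(n, n * 0.05)
  y_out[bad] <- y_out[bad] + 10 * sign(X[bad, 1])
  ols_bias <- abs(stats::lm.fit(X, y_out)$coefficients[1] - 2)
  rob_bias <- abs(robust_regress(X, y_out)[[1]] - 2)
  expect_lt(rob_bias, 0.2 * ols_bias)

  # exact linear data: exact coefficients, and agreement with MASS::rlm on
  # the contaminated data as an independent cross-check
  b_exact <- robust_regress(X, 2 * X[, 1] + 0.05 * X[, 2])
  expect_equal(as.numeric(b_exact), c(2, 0.05), tolerance = 1e-12)
  rlm_fit <- MASS::rlm(X, y_out, psi = MASS::psi.huber, k = 1.345,
                       maxit = 100)
  expect_equal(as.numeric(robust_regress(X, y_out)),
               as.numeric(rlm_fit$coefficients), tolerance = 0.02)

  expect_error(robust_regress(cbind(X[, 1], 2 * X[, 1]), y), "singular")
})

test_that("the latency grid search recovers a constructed linear response", {
  chair <- make_trapezoid_profile(std_protocol())
  t_eye <- seq(0, max(chair$time), by = 0.001)
  lag <- function(y, d) stats::approx(chair$time + d, y, xout = t_eye,
                                      yleft = 0, yright = 0, rule = 2)$y
  omega <- 2.0 * lag(chair$v, 0.030) + 0.05 * lag(chair$a, 0.030)
  tr <- structure(list(
    chair = chair,
    eye = data.frame(time = t_eye, position = cumsum(omega) * 0.001,
                     velocity = omega, mask = FALSE),
    meta = list(direction = "left", distance = 70)), class = "tvor_trial")
  fit <- fit_linear_model(list(tr))
  expect_identical(fit$delta_t, 0.030)
  expect_equal(fit$g_v, 2.0, tolerance = 1e-9)
  expect_equal(fit$g_a, 0.05, tolerance = 1e-9)
  expect_lt(fit$residual_ss, 1e-14)
  # the winning latency beats every other grid point strictly
  others <- fit$grid_rss$rss[fit$grid_rss$delta_t != 0.030]
  expect_true(all(others > fit$residual_ss))

  # single-regressor fits are strictly worse
  fit_v <- fit_linear_model(list(tr), regressors = "velocity")
  fit_a <- fit_linear_model(list(tr), regressors = "acceleration")
  expect_gt(fit_v$residual_ss, fit$residual_ss)
  expect_gt(fit_a$residual_ss, fit$residual_ss)
  expect_gt(fit_a$residual_ss, fit_v$residual_ss)  # velocity carries more

  # a null response yields null coefficients
  tr0 <- tr
  tr0$eye$velocity <- 0 * tr0$eye$velocity
  fit0 <- fit_linear_model(list(tr0))
  expect_identical(c(fit0$g_v, fit0$g_a), c(0, 0))
})

test_that("masking saccade samples does not inflate the per-sample residual", {
  p <- model_parameters()
  ns <- noise_spec(velocity_sd = 1, qp_rate = 3)
  trials <- lapply(1:3, function(i)
    generate_trial(p, std_protocol(), ns, seed = 30 + i))
  masked <- mask_session(trials)
  fit_masked <- fit_linear_model(masked)
  unmasked <- lapply(masked, function(tr) {
    tr$eye$mask <- rep(FALSE, nrow(tr$eye)); tr
  })
  fit_all <- fit_linear_model(unmasked)
  expect_lte(fit_masked$residual_ss / fit_masked$n_samples,
             fit_all$residual_ss / fit_all$n_samples)
})

test_that("too little unmasked data raises an informative error", {
  tr <- noiseless_trial()
  tr$eye$mask <- rep(TRUE, nrow(tr$eye))
  tr$eye$mask[1:10] <- FALSE
  expect_error(fit_linear_model(list(tr)), "insufficient")
  expect_error(fit_linear_model(list()), "at least one")
})

test_that("epoch comparison reproduces known ratios and their statistics", {
  mk <- function(g_v, g_a) structure(list(g_v = g_v, g_a = g_a),
                                     class = "linear_fit_result")
  pre <- named_fits(mk(1, 0.2), mk(2, 0.3), mk(1.5, 0.25), mk(1, 0.4))
  expect_error(compare_epochs(pre, pre[1:3]), "matching")

  same <- compare_epochs(pre, pre)
  expect_true(all(same$ratios$g_v_ratio == 1))
  expect_equal(same$summary$mean_ratio, c(1, 1))

  # ratios {0.4, 0.5, 0.45, 0.5} average to 0.4625
  post <- named_fits(mk(0.4, 0.2 * 0.4), mk(1.0, 0.3 * 0.5),
                     mk(0.675, 0.25 * 0.45), mk(0.5, 0.4 * 0.5))
  cmp <- compare_epochs(pre, post)
  expect_equal(cmp$ratios$g_v_ratio, c(0.4, 0.5, 0.45, 0.5))
  expect_equal(cmp$summary$mean_ratio[1], 0.4625)
  expect_lt(cmp$summary$p_value[1], 0.05)   # clearly different from 1
})

test_that("a halved generating gain appears as a halved fitted g_v", {
  # trials generated from the linear model itself, plus noise, so the
  # recovered ratio is unconfounded by plant dynamics
  lin_trial <- function(direction, g_v, g_a, seed) {
    chair <- make_trapezoid_profile(std_protocol(direction))
    t_eye <- seq(0, max(chair$time), by = 0.001)
    lagf <- function(y, d) stats::approx(chair$time + d, y, xout = t_eye,
                                         yleft = 0, yright = 0, rule = 2)$y
    set.seed(seed)
    omega <- g_v * lagf(chair$v, 0.03) + g_a * lagf(chair$a, 0.03) +
      rnorm(length(t_eye), sd = 1)
    structure(list(chair = chair,
                   eye = data.frame(time = t_eye,
                                    position = cumsum(omega) * 0.001,
                                    velocity = omega, mask = FALSE),
                   meta = list(direction = direction, distance = 70)),
              class = "tvor_trial")
  }
  pre <- fit_linear_model(list(lin_trial("left", 0.8, 0.1, 1),
                               lin_trial("left", 0.8, 0.1, 2)))
  post <- fit_linear_model(list(lin_trial("left", 0.4, 0.1, 3),
                                lin_trial("left", 0.4, 0.1, 4)))
  expect_equal(post$g_v / pre$g_v, 0.5, tolerance = 0.05)
  expect_equal(post$g_a / pre$g_a, 1.0, tolerance = 0.15)
})
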
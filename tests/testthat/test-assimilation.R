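test_that("unscented update behaves like a Bayes update in limit cases", {
  m0 <- c(0.2, -0.5)
  P0 <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  h <- function(X) X[1, ] - 2 * X[2, ]
  # observation equal to the predicted observation: no mean shift
  up <- ukf_update(m0, P0, h, R = 0.1, y = m0[1] - 2 * m0[2])
  expect_equal(up$mean, m0, tolerance = 1e-12)
  expect_equal(drop(up$innovation), 0, tolerance = 1e-12)
  # infinite-noise limit: posterior collapses to the prior
  up2 <- ukf_update(m0, P0, h, R = 1e12, y = 5)
  expect_equal(up2$mean, m0, tolerance = 1e-5)
  expect_equal(up2$cov, P0, tolerance = 1e-5)
})

test_that("the unscented filter reproduces the closed-form Kalman filter", {
  # frozen linear-Gaussian system
  A <- matrix(c(0.9, 0.2, -0.1, 0.8), 2)
  H <- matrix(c(1, 0.5), 1)
  Q <- diag(c(0.01, 0.02))
  R <- matrix(0.05)
  set.seed(99)
  n <- 40
  x <- c(0, 0)
  y <- matrix(NA_real_, 1, n)
  for (k in 1:n) {
    x <- drop(A %*% x) + rnorm(2, 0, sqrt(diag(Q)))
    y[, k] <- drop(H %*% x) + rnorm(1, 0, sqrt(R[1, 1]))
  }
  m0 <- c(0, 0)
  P0 <- diag(2)
  kf <- kalman_oracle(A, H, Q, R, y, m0, P0)
  uk <- ukf_linear_run(A, H, Q, R, y, m0, P0)
  expect_lt(max(abs(kf$means - uk$means)), 1e-10)
  expect_lt(max(abs(kf$covs[[n]] - uk$covs[[n]])), 1e-10)
})

test_that("augmented propagation fixes rest and leaves parameter means alone", {
  cfg <- filter_config(q_state = 0, q_param = 0)
  stim <- stimulus_train(numeric(0), numeric(0))
  model_dim <- 9L
  mean0 <- c(0, 1, 1, 1, log(0.54), log(1.54), log(2.46), log(0.98),
             qlogis(0.34))
  cov0 <- diag(1e-8, model_dim)
  out <- propagate_augmented(mean0, cov0, stim, t_from = 0, dt = 2,
                             v0 = 0.1, config = cfg)
  expect_equal(out$mean[1:4], c(0, 1, 1, 1), tolerance = 1e-6)
  # parameter block follows identity dynamics: means unchanged exactly
  expect_equal(out$mean[5:9], mean0[5:9], tolerance = 1e-12)
  expect_equal(out$n_clamped, 0)
  # covariance stays symmetric PSD
  expect_equal(out$cov, t(out$cov))
  expect_gte(min(eigen(out$cov, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-12)
})

test_that("stand-alone measurement update skips non-finite observations", {
  cfg <- filter_config(meas_var = 1e-4)
  mean0 <- c(0, 1, 1, 1, log(0.54), log(1.54), log(2.46), log(0.98),
             qlogis(0.34))
  cov0 <- diag(1e-4, 9)
  out <- update_with_observation(mean0, cov0, NA_real_, v0 = 0.1,
                                 config = cfg)
  expect_true(out$skipped)
  expect_identical(out$mean, mean0)
  out2 <- update_with_observation(mean0, cov0, 0.01, v0 = 0.1, config = cfg)
  expect_false(out2$skipped)
  expect_true(is.finite(out2$innovation))
})

test_that("assimilation is self-consistent on a noiseless series", {
  ds <- short_dataset(seed = 2, n_scans = 60)
  ser <- data.frame(time_s = ds$series$time_s,
                    bold = ds$series$bold_noiseless)
  cfg <- filter_config(meas_var = 1e-8)
  fit <- run_assimilation(ser, ds$stimulus, v0 = 0.1, cfg)
  # truth parameters equal the filter's initial means: BOLD fit is tight
  # and parameters barely move
  rmse <- sqrt(mean((fit$bold$observed - fit$bold$filtered)^2))
  expect_lt(rmse, 0.01 * max(abs(ser$bold)))
  expect_lt(abs(fit$params$epsilon - 0.54) / 0.54, 0.05)
  expect_equal(nrow(fit$bold), nrow(ser))
  expect_equal(fit$bold$time_s, ser$time_s)
})

test_that("filter covariances stay PSD and results are deterministic", {
  ds <- short_dataset(seed = 4, n_scans = 50)
  ser <- series_frame(ds)
  cfg <- filter_config(meas_var = ds$truth$noise_sd^2)
  fit <- run_assimilation(ser, ds$stimulus, v0 = 0.1, cfg)
  ev <- eigen(fit$final_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
  expect_true(all(is.finite(fit$innovations)))
  fit2 <- run_assimilation(ser, ds$stimulus, v0 = 0.1, cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$states, fit2$states)
})

test_that("the smoothing pass runs and matches the filter at the endpoint", {
  ds <- short_dataset(seed = 6, n_scans = 40)
  cfg <- filter_config(meas_var = ds$truth$noise_sd^2, smooth = TRUE)
  fit <- run_assimilation(series_frame(ds), ds$stimulus, v0 = 0.1, cfg)
  expect_false(is.null(fit$states_smoothed))
  expect_equal(nrow(fit$states_smoothed), nrow(fit$states))
  n <- nrow(fit$states)
  expect_equal(unlist(fit$states_smoothed[n, -1]),
               unlist(fit$states[n, -1]))
})

test_that("a V0 below truth inflates the efficacy estimate", {
  ds <- short_dataset(seed = 3, n_scans = 100)
  cmp <- compare_v0_scenarios(series_frame(ds), ds$stimulus, 0.1, 0.02,
                              filter_config(meas_var = ds$truth$noise_sd^2))
  expect_gt(cmp$contrast$epsilon_ratio, 1)
  expect_gt(cmp$contrast$epsilon_assumed, 0.54)
  # identical V0s give identical runs
  cmp2 <- compare_v0_scenarios(series_frame(ds), ds$stimulus, 0.1, 0.1,
                               filter_config(meas_var = ds$truth$noise_sd^2))
  expect_identical(cmp2$actual$params, cmp2$assumed$params)
})
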
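test_that("neuronal derivatives are linear with rest as fixed point", {
  conn <- dcm_connectivity(a11 = -1, a12 = 0.2, a21 = 0.4, a22 = -1,
                           c1 = 1, c2 = 0.5)
  expect_equal(dcm_derivatives(c(0, 0), c(0, 0), conn), c(0, 0))
  # direct evaluation
  conn2 <- dcm_connectivity(a11 = -1, a21 = 0.4, c1 = 1, c2 = 1)
  expect_equal(dcm_derivatives(c(1, 0), c(0, 0), conn2), c(-1, 0.4))
  # decoupling: region 1's derivative ignores z2 when a12 = 0
  expect_equal(dcm_derivatives(c(0.3, 5), c(0, 0), conn2)[1],
               dcm_derivatives(c(0.3, -5), c(0, 0), conn2)[1])
  expect_error(dcm_connectivity(a11 = 1), "negative")
  expect_warning(dcm_connectivity(a12 = 2, a21 = 2), "unstable")
})

test_that("DCM trajectories match an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  # input-free decay from excited neuronal states, compared against an
  # independent integration of the full ten-state coupled system
  conn <- dcm_connectivity(a11 = -1, a12 = 0.2, a21 = 0.4, a22 = -0.8,
                           c1 = 1, c2 = 0.3)
  p1 <- hemodynamic_params(epsilon = 0.5, V0 = 0.1)
  p2 <- hemodynamic_params(epsilon = 0.6, V0 = 0.02)
  init <- c(0.3, -0.1, 0, 1, 1, 1, 0.05, 1.1, 1.02, 0.95)
  rhs <- function(t, y, parms) {
    reg <- function(x, eps, z) {
      E <- 1 - (1 - p1$E0)^(1 / x[2])
      fout <- x[3]^(1 / p1$alpha)
      c(eps * z - x[1] / p1$tau_s - (x[2] - 1) / p1$tau_f,
        x[1],
        (x[2] - fout) / p1$tau_0,
        (x[2] * E / p1$E0 - fout * x[4] / x[3]) / p1$tau_0)
    }
    list(c(conn$a11 * y[1] + conn$a12 * y[2],
           conn$a21 * y[1] + conn$a22 * y[2],
           reg(y[3:6], p1$epsilon, y[1]),
           reg(y[7:10], p2$epsilon, y[2])))
  }
  times <- seq(0, 40, by = 0.01)
  ref <- deSolve::ode(init, times, rhs, NULL, method = "rk4")
  got <- balloonassim:::integrate_dcm_cpp(
    init, c(p1$epsilon, p2$epsilon),
    c(p1$tau_s, p1$tau_f, p1$tau_0, p1$E0), p1$alpha,
    c(conn$a11, conn$a12, conn$a21, conn$a22, conn$c1, conn$c2),
    numeric(0), numeric(0), 0, numeric(0), numeric(0), 0,
    0, length(times) - 1L, 0.01)
  expect_lt(max(abs(got$states - ref[, 2:11])), 1e-10)
})

test_that("forward DCM simulation honors structure and V0 linearity", {
  # zero input coupling, zero initial states: output identically zero
  connq <- dcm_connectivity(c1 = 0, c2 = 0)
  p <- hemodynamic_params(V0 = 0.05)
  mq <- dcm_model(connq, p, p)
  stim <- make_block_design(2, 20, 20, amplitude = 0.25)
  ts <- seq(2, 100, by = 2)
  simq <- simulate_dcm(mq, stim, ts)
  expect_equal(max(abs(simq$bold1_noiseless)), 0)
  expect_equal(max(abs(simq$bold2_noiseless)), 0)

  # feedforward drive: downstream region responds later, not earlier
  connf <- dcm_connectivity(a21 = 0.4, c1 = 1, c2 = 0)
  mf <- dcm_model(connf, hemodynamic_params(V0 = 0.1),
                  hemodynamic_params(V0 = 0.02))
  simf <- simulate_dcm(mf, stim, ts)
  expect_gt(max(abs(simf$bold2_noiseless)), 0)
  expect_gte(ts[which.max(simf$bold2_noiseless)],
             ts[which.max(simf$bold1_noiseless)])

  # doubling only region 2's V0 doubles only region 2's output
  mf2 <- dcm_model(connf, hemodynamic_params(V0 = 0.1),
                   hemodynamic_params(V0 = 0.04))
  simf2 <- simulate_dcm(mf2, stim, ts)
  expect_identical(simf2$bold1_noiseless, simf$bold1_noiseless)
  expect_equal(simf2$bold2_noiseless, 2 * simf$bold2_noiseless)

  # reproducibility under a seed
  sa <- simulate_dcm(mf, stim, ts, noise_sd = c(1e-3, 1e-3), seed = 5)
  sb <- simulate_dcm(mf, stim, ts, noise_sd = c(1e-3, 1e-3), seed = 5)
  expect_identical(sa, sb)
})

test_that("identical regions fed identical data give symmetric estimates", {
  ds <- short_dataset(seed = 5, n_scans = 100, v0 = 0.05)
  ser <- data.frame(time_s = ds$series$time_s,
                    bold1 = ds$series$bold_noisy,
                    bold2 = ds$series$bold_noisy)
  cfg <- dcm_filter_config(meas_var = rep(ds$truth$noise_sd^2, 2))
  fit <- run_dcm_assimilation(ser, ds$stimulus, v0 = c(0.05, 0.05), cfg)
  expect_lt(abs(fit$connectivity$a12 - fit$connectivity$a21), 0.05)
  expect_lt(abs(fit$connectivity$c1 - fit$connectivity$c2), 0.05)
  expect_lt(abs(fit$connectivity$a11 - fit$connectivity$a22), 0.1)
})

test_that("connectivity is recovered with correct signs on synthetic data", {
  ds <- make_two_region_dataset(dcm_scenario(seed = 2))
  ser <- data.frame(time_s = ds$series$time_s,
                    bold1 = ds$series$bold1_noisy,
                    bold2 = ds$series$bold2_noisy)
  cfg <- dcm_filter_config(meas_var = ds$truth$noise_sd^2)
  fit <- run_dcm_assimilation(ser, ds$stimulus, v0 = ds$truth$v0, cfg)
  expect_gt(fit$connectivity$a12, 0)
  expect_gt(fit$connectivity$a21, 0)
  expect_gt(fit$connectivity$c1, 0)
  expect_lt(fit$connectivity$a11, 0)
  ev <- eigen(fit$final_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
})
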
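test_that("boxcar input uses half-open block intervals", {
  stim <- stimulus_train(onsets = 10, durations = 20, amplitude = 1)
  expect_identical(neural_input(stim, c(0, 9.999, 10, 29.999, 30, 100)),
                   c(0, 0, 1, 1, 0, 0))
  # multiple blocks, scaled amplitude
  stim2 <- stimulus_train(c(5, 50), c(10, 10), amplitude = 0.3)
  expect_equal(neural_input(stim2, c(5, 20, 55)), c(0.3, 0, 0.3))
  expect_error(stimulus_train(c(10, 5), c(1, 1)), "sorted")
  expect_error(stimulus_train(c(0, 5), c(10, 1)), "overlap")
})

test_that("oxygen extraction reduces to E0 at rest and saturates", {
  for (E0 in c(0.1, 0.34, 0.8))
    expect_equal(oxygen_extraction(1, E0), E0)
  # frozen high-precision value for f = 2, E0 = 0.4
  expect_equal(oxygen_extraction(2, 0.4), 0.22540333075851662,
               tolerance = 1e-14)
  # extraction falls toward 0 as flow rises, toward 1 as flow vanishes
  expect_lt(oxygen_extraction(1e4, 0.4), 1e-3)
  expect_lt(abs(oxygen_extraction(1e-3, 0.4) - 1), 1e-6)
  expect_true(all(diff(oxygen_extraction(seq(0.5, 5, 0.5), 0.4)) < 0))
  expect_error(oxygen_extraction(0, 0.4), "positive")
})

test_that("resting state is an exact fixed point for random parameters", {
  set.seed(42)
  for (i in 1:100) {
    p <- hemodynamic_params(epsilon = runif(1, 0, 2),
                            tau_s = runif(1, 0.5, 4),
                            tau_f = runif(1, 0.5, 4),
                            tau_0 = runif(1, 0.5, 3),
                            E0 = runif(1, 0.1, 0.9),
                            alpha = runif(1, 0.1, 0.5))
    d <- hemodynamic_derivatives(hemodynamic_state(), p, u = 0)
    expect_identical(unname(d), c(0, 0, 0, 0))
  }
})

test_that("hemodynamic derivatives match a high-precision oracle", {
  # at rest with input, only the signal equation is active
  p <- hemodynamic_params(epsilon = 0.5)
  d <- hemodynamic_derivatives(hemodynamic_state(), p, u = 1)
  expect_equal(unname(d), c(0.5, 0, 0, 0))
  # frozen values from term-by-term evaluation at 30-digit precision
  p2 <- hemodynamic_params(epsilon = 0.54, tau_s = 1.54, tau_f = 2.46,
                           tau_0 = 0.98, E0 = 0.34, alpha = 0.2)
  d2 <- hemodynamic_derivatives(c(0.1, 1.2, 1.05, 0.95), p2, u = 0)
  expect_equal(unname(d2),
               c(-0.14623587794319502, 0.1,
                 -0.07783832908163265, -0.12425075650390730),
               tolerance = 1e-14)
  expect_error(hemodynamic_derivatives(c(0, -1, 1, 1), p2, 0), "positive")
})

test_that("BOLD observation is zero at rest and exactly linear in V0", {
  expect_identical(bold_observation(hemodynamic_state(), 0.34, 0.02), 0)
  st <- c(0.1, 1.3, 1.1, 0.9)
  expect_equal(bold_observation(st, 0.34, 0.04),
               2 * bold_observation(st, 0.34, 0.02))
  # frozen value: v = 1.1, q = 0.9, E0 = 0.4, V0 = 0.02
  expect_equal(bold_observation(c(0, 1, 1.1, 0.9), 0.4, 0.02),
               0.011672727272727273, tolerance = 1e-14)
  # configurable coefficients override the 1.5 T defaults
  expect_equal(bold_observation(st, 0.34, 0.02,
                                coefs = bold_coefficients(0.34)),
               bold_observation(st, 0.34, 0.02))
  expect_error(bold_observation(c(0, 1, -1, 1), 0.4, 0.02), "positive")
})

test_that("integration preserves rest, converges with step halving, and relaxes", {
  p <- hemodynamic_params()
  quiet <- stimulus_train(numeric(0), numeric(0))
  traj <- integrate_balloon(p, quiet, c(0, 30), dt = 0.1)
  expect_equal(max(abs(as.matrix(traj[, c("s", "f", "v", "q")]) -
                         rep(c(0, 1, 1, 1), each = nrow(traj)))), 0)
  # step halving: error shrinks and is tiny at dt = 0.01
  stim <- stimulus_train(5, 20)
  t1 <- integrate_balloon(p, stim, c(0, 60), dt = 0.04)
  t2 <- integrate_balloon(p, stim, c(0, 60), dt = 0.02)
  t3 <- integrate_balloon(p, stim, c(0, 60), dt = 0.01)
  on_grid <- function(tr, step) tr[seq(1, nrow(tr), by = step), c("f", "v", "q")]
  e12 <- max(abs(on_grid(t1, 1) - on_grid(t2, 2)))
  e23 <- max(abs(on_grid(t2, 1) - on_grid(t3, 2)))
  expect_lt(e23, e12)
  expect_lt(e23, 1e-6)
  # after the stimulus the trajectory relaxes back toward rest
  tail_dist <- function(tr, t) {
    r <- tr[which.min(abs(tr$time - t)), ]
    sqrt(r$s^2 + (r$f - 1)^2 + (r$v - 1)^2 + (r$q - 1)^2)
  }
  long <- integrate_balloon(p, stim, c(0, 120), dt = 0.01)
  expect_lt(tail_dist(long, 120), tail_dist(long, 60))
  expect_lt(tail_dist(long, 120), 1e-3)
})

test_that("trajectory agrees with an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  # input-free relaxation from a perturbed state exercises every
  # nonlinear term without involving the boxcar sampling convention
  p <- hemodynamic_params(epsilon = 0.6, E0 = 0.4)
  quiet <- stimulus_train(numeric(0), numeric(0))
  init <- hemodynamic_state(s = 0.2, f = 1.3, v = 1.1, q = 0.9)
  rhs <- function(t, y, parms) {
    E <- 1 - (1 - p$E0)^(1 / y[2])
    fout <- y[3]^(1 / p$alpha)
    list(c(-y[1] / p$tau_s - (y[2] - 1) / p$tau_f,
           y[1],
           (y[2] - fout) / p$tau_0,
           (y[2] * E / p$E0 - fout * y[4] / y[3]) / p$tau_0))
  }
  times <- seq(0, 30, by = 0.01)
  ref <- deSolve::ode(as.numeric(init), times, rhs, NULL, method = "rk4")
  traj <- integrate_balloon(p, quiet, c(0, 30), dt = 0.01, init = init)
  expect_lt(max(abs(as.matrix(traj[, c("s", "f", "v", "q")]) -
                      ref[, 2:5])), 1e-10)
})

test_that("simulated noise is reproducible and has the requested scale", {
  p <- hemodynamic_params(V0 = 0.1)
  stim <- make_block_design(2, 20, 20)
  ts <- seq(2, 100, by = 2)
  clean <- simulate_bold(p, stim, ts, noise_sd = 0)
  expect_identical(clean$bold_noiseless, clean$bold_noisy)
  s1 <- simulate_bold(p, stim, ts, noise_sd = 0.005, seed = 7)
  s2 <- simulate_bold(p, stim, ts, noise_sd = 0.005, seed = 7)
  expect_identical(s1, s2)
  # pooled residual SD over 10 seeds stays near the nominal value
  resid <- unlist(lapply(1:10, function(seed) {
    s <- simulate_bold(p, stim, ts, noise_sd = 0.005, seed = seed)
    s$bold_noisy - s$bold_noiseless
  }))
  expect_gt(sd(resid), 0.004)
  expect_lt(sd(resid), 0.006)
})

test_that("efficacy and V0 trade off to first order for weak stimuli", {
  stim <- make_block_design(2, 20, 20, amplitude = 0.1)
  ts <- seq(2, 100, by = 2)
  peak <- function(eps, v0)
    max(abs(simulate_bold(hemodynamic_params(epsilon = eps, V0 = v0),
                          stim, ts)$bold_noiseless))
  ref <- peak(0.54, 0.1)
  for (c_ratio in c(0.5, 2, 5)) {
    scaled <- peak(0.54 / c_ratio, 0.1 * c_ratio)
    expect_lt(abs(scaled - ref) / ref, 0.1)
  }
})
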
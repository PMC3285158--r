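# Shared fixtures for the suite; everything is generated in code.

# short single-region dataset for fast filter tests
short_dataset <- function(seed = 1L, n_scans = 60L, v0 = 0.1, ...) {
  make_single_region_dataset(
    synthetic_scenario(params = hemodynamic_params(V0 = v0),
                       n_scans = n_scans, seed = seed, ...))
}

series_frame <- function(ds)
  data.frame(time_s = ds$series$time_s, bold = ds$series$bold_noisy)

# closed-form Kalman filter for a linear-Gaussian system: the independent
# oracle for the unscented filter on frozen linear dynamics
kalman_oracle <- function(A, H, Q, R, y, m0, P0) {
  m <- m0
  P <- P0
  means <- matrix(NA_real_, length(m0), ncol(y))
  covs <- vector("list", ncol(y))
  for (k in seq_len(ncol(y))) {
    m <- drop(A %*% m)
    P <- A %*% P %*% t(A) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    m <- m + drop(K %*% (y[, k] - H %*% m))
    P <- P - K %*% S %*% t(K)
    means[, k] <- m
    covs[[k]] <- P
  }
  list(means = means, covs = covs)
}

# run the package's unscented machinery on the same frozen linear system
ukf_linear_run <- function(A, H, Q, R, y, m0, P0, alpha = 0.5) {
  m <- m0
  P <- P0
  means <- matrix(NA_real_, length(m0), ncol(y))
  covs <- vector("list", ncol(y))
  for (k in seq_len(ncol(y))) {
    pr <- ukf_predict(m, P, function(X) A %*% X, Q, alpha = alpha)
    up <- ukf_update(pr$mean, pr$cov, function(X) H %*% X, R, y[, k],
                     alpha = alpha)
    m <- up$mean
    P <- up$cov
    means[, k] <- m
    covs[[k]] <- P
  }
  list(means = means, covs = covs)
}
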
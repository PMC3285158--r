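conn_names <- c("a11", "a12", "a21", "a22", "c1", "c2")

#' Two-region neuronal coupling coefficients
#'
#' Connectivity of the two-node neuronal model
#' `dz1/dt = a11*z1 + a12*z2 + c1*u1`,
#' `dz2/dt = a21*z1 + a22*z2 + c2*u2`:
#' `a11`, `a22` are the inner (self) connectivities in the absence of
#' input, `a12`, `a21` the fixed inter-region connectivities, and
#' `c1`, `c2` the extrinsic efficacies of the inputs (all per second).
#'
#' @param a11,a22 Self connectivity of each region (must be negative:
#'   stability of the uncoupled node).
#' @param a12,a21 Inter-region coupling (region 2 on region 1 and vice
#'   versa).
#' @param c1,c2 Input coupling per region.
#' @return An object of class `dcm_connectivity`.  Construction warns if
#'   the 2x2 coupling matrix has an eigenvalue with non-negative real
#'   part (the coupled neuronal system would be unstable).
#' @export
dcm_connectivity <- function(a11 = -1, a12 = 0, a21 = 0, a22 = -1,
                             c1 = 1, c2 = 1) {
  if (a11 >= 0 || a22 >= 0)
    stop("self connectivities a11, a22 must be negative")
  A <- matrix(c(a11, a21, a12, a22), 2L)
  if (any(Re(eigen(A, only.values = TRUE)$values) >= 0))
    warning("coupling matrix has an eigenvalue with non-negative real ",
            "part; the neuronal system is unstable")
  structure(list(a11 = a11, a12 = a12, a21 = a21, a22 = a22,
                 c1 = c1, c2 = c2),
            class = "dcm_connectivity")
}

#' @export
print.dcm_connectivity <- function(x, ...) {
  cat("Two-node connectivity (per s):\n")
  cat(sprintf("  A = [%7.3f %7.3f]    C = [%7.3f]\n", x$a11, x$a12, x$c1))
  cat(sprintf("      [%7.3f %7.3f]        [%7.3f]\n", x$a21, x$a22, x$c2))
  invisible(x)
}

conn_vector <- function(conn)
  vapply(conn_names, function(nm) conn[[nm]], numeric(1))

#' Two-region dynamic causal model
#'
#' Couples the two-node neuronal system to one Balloon model per region:
#' the neuronal state `z_i` replaces the extrinsic input in region `i`'s
#' flow-inducing-signal equation, and each region observes BOLD through
#' its own `V0`.
#'
#' @param connectivity A [dcm_connectivity()].
#' @param params_region1,params_region2 [hemodynamic_params()] per region
#'   (region-specific `V0` included).  `tau_s`, `tau_f`, `tau_0`, `E0`
#'   and `alpha` must agree across regions (shared hemodynamics;
#'   `epsilon` and `V0` may differ).
#' @return An object of class `dcm_model`.
#' @export
dcm_model <- function(connectivity, params_region1, params_region2) {
  stopifnot(inherits(connectivity, "dcm_connectivity"),
            inherits(params_region1, "hemodynamic_params"),
            inherits(params_region2, "hemodynamic_params"))
  for (nm in c("tau_s", "tau_f", "tau_0", "E0", "alpha"))
    if (params_region1[[nm]] != params_region2[[nm]])
      stop("hemodynamic parameter '", nm,
           "' must be shared across the two regions")
  structure(list(connectivity = connectivity,
                 params = list(params_region1, params_region2)),
            class = "dcm_model")
}

#' Neuronal derivatives of the two-node model
#'
#' @param z Numeric length-2 neuronal state `(z1, z2)`.
#' @param u Numeric length-2 inputs `(u1, u2)`.
#' @param conn A [dcm_connectivity()].
#' @return Length-2 derivative vector.  At `z = (0, 0)`, `u = (0, 0)` the
#'   derivatives vanish (neuronal rest is a fixed point).
#' @export
dcm_derivatives <- function(z, u, conn) {
  stopifnot(length(z) == 2L, length(u) == 2L, all(is.finite(u)),
            inherits(conn, "dcm_connectivity"))
  c(conn$a11 * z[1] + conn$a12 * z[2] + conn$c1 * u[1],
    conn$a21 * z[1] + conn$a22 * z[2] + conn$c2 * u[2])
}

#' Simulate a two-region DCM BOLD dataset
#'
#' Integrates the coupled neuronal + hemodynamic system (RK4, fixed step)
#' and samples both regions' BOLD observations, optionally with additive
#' Gaussian noise per region.
#'
#' @param model A [dcm_model()].
#' @param stimulus A [stimulus_train()] (routed to both inputs), or a
#'   list of two stimulus trains for distinct routing.
#' @param sample_times Scan times in seconds.
#' @param noise_sd Length-2 (or scalar) noise standard deviation per
#'   region.
#' @param seed Optional integer seed.
#' @param dt Internal integration step (seconds).
#' @return Data frame with `time_s`, `bold1_noiseless`, `bold1_noisy`,
#'   `bold2_noiseless`, `bold2_noisy`; attributes `model`, `seed`,
#'   `states` (the sampled trajectory of all ten states).
#' @export
simulate_dcm <- function(model, stimulus, sample_times, noise_sd = c(0, 0),
                         seed = NULL, dt = 0.01) {
  stopifnot(inherits(model, "dcm_model"), all(noise_sd >= 0),
            all(diff(sample_times) > 0))
  noise_sd <- rep_len(noise_sd, 2L)
  stims <- if (inherits(stimulus, "stimulus_train")) list(stimulus, stimulus)
  else stimulus
  stopifnot(length(stims) == 2L,
            all(vapply(stims, inherits, logical(1), "stimulus_train")))
  p1 <- model$params[[1]]; p2 <- model$params[[2]]
  t_end <- max(sample_times,
               unlist(lapply(stims, function(s)
                 if (length(s$onsets)) s$onsets + s$durations else 0)))
  n_steps <- as.integer(ceiling(t_end / dt))
  res <- integrate_dcm_cpp(
    c(0, 0, 0, 1, 1, 1, 0, 1, 1, 1), c(p1$epsilon, p2$epsilon),
    c(p1$tau_s, p1$tau_f, p1$tau_0, p1$E0), p1$alpha,
    conn_vector(model$connectivity),
    stims[[1]]$onsets, stims[[1]]$durations, stims[[1]]$amplitude,
    stims[[2]]$onsets, stims[[2]]$durations, stims[[2]]$amplitude,
    0, n_steps, dt)
  idx <- round(sample_times / dt) + 1L
  st <- res$states[idx, , drop = FALSE]
  colnames(st) <- c("z1", "z2", "s1", "f1", "v1", "q1",
                    "s2", "f2", "v2", "q2")
  y1 <- bold_observation(t(st[, c("s1", "f1", "v1", "q1")]), p1$E0, p1$V0)
  y2 <- bold_observation(t(st[, c("s2", "f2", "v2", "q2")]), p2$E0, p2$V0)
  if (!is.null(seed)) set.seed(seed)
  e1 <- if (noise_sd[1] > 0) stats::rnorm(length(y1), 0, noise_sd[1]) else 0
  e2 <- if (noise_sd[2] > 0) stats::rnorm(length(y2), 0, noise_sd[2]) else 0
  out <- data.frame(time_s = sample_times,
                    bold1_noiseless = y1, bold1_noisy = y1 + e1,
                    bold2_noiseless = y2, bold2_noisy = y2 + e2)
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  attr(out, "states") <- st
  out
}

#' Filter configuration for two-region DCM assimilation
#'
#' @param init_params List of two [hemodynamic_params()] (per-region
#'   initial/fixed hemodynamic parameters; shared fields must agree).
#' @param init_connectivity [dcm_connectivity()] initial means of the
#'   coupling coefficients.
#' @param estimate_connectivity Named logical over
#'   `a11, a12, a21, a22, c1, c2`: which coefficients to estimate
#'   (default: all six).
#' @param estimate_epsilon Also estimate the per-region neuronal
#'   efficacies on the log scale (default `FALSE`: with free input and
#'   inter-region couplings the efficacies trade off against the scale of
#'   the neuronal states, so they are held at their supplied values).
#' @param init_state_sd Initial SD of the ten states (two neuronal, eight
#'   hemodynamic).
#' @param init_conn_sd Initial SD of each estimated coupling coefficient.
#' @param init_epsilon_sd Initial SD of log-efficacy (when estimated).
#' @param q_state,q_conn,q_param Process-noise variances per observation
#'   interval (states, coupling random walk, log-efficacy random walk).
#' @param meas_var Length-2 (or scalar) measurement-noise variance;
#'   `NULL` estimates it per region as `var(diff(y))/2`.
#' @param ukf_alpha,ukf_beta,ukf_kappa,dt_integration As in
#'   [filter_config()].
#' @return An object of class `dcm_filter_config`.
#' @export
dcm_filter_config <- function(init_params = list(hemodynamic_params(),
                                                 hemodynamic_params()),
                              init_connectivity = dcm_connectivity(
                                a11 = -1, a12 = 0, a21 = 0, a22 = -1,
                                c1 = 0.5, c2 = 0.5),
                              estimate_connectivity = c(
                                a11 = TRUE, a12 = TRUE, a21 = TRUE,
                                a22 = TRUE, c1 = TRUE, c2 = TRUE),
                              estimate_epsilon = FALSE,
                              init_state_sd = 0.01, init_conn_sd = 0.5,
                              init_epsilon_sd = 0.5, q_state = 1e-6,
                              q_conn = 1e-6, q_param = 1e-6,
                              meas_var = NULL, ukf_alpha = 0.5,
                              ukf_beta = 2, ukf_kappa = 0,
                              dt_integration = 0.05) {
  stopifnot(length(init_params) == 2L,
            inherits(init_connectivity, "dcm_connectivity"),
            all(conn_names %in% names(estimate_connectivity)),
            init_state_sd > 0, init_conn_sd > 0,
            is.null(meas_var) || all(meas_var > 0))
  structure(list(init_params = init_params,
                 init_connectivity = init_connectivity,
                 estimate_connectivity =
                   estimate_connectivity[conn_names],
                 estimate_epsilon = estimate_epsilon,
                 init_state_sd = init_state_sd,
                 init_conn_sd = init_conn_sd,
                 init_epsilon_sd = init_epsilon_sd,
                 q_state = q_state, q_conn = q_conn, q_param = q_param,
                 meas_var = meas_var, ukf_alpha = ukf_alpha,
                 ukf_beta = ukf_beta, ukf_kappa = ukf_kappa,
                 dt_integration = dt_integration),
            class = "dcm_filter_config")
}

# self connectivities are filtered as log(-a_ii) so every sigma point
# keeps both neuronal nodes stable; off-diagonals and input couplings are
# unconstrained
conn_to_filter <- function(value, name)
  if (name %in% c("a11", "a22")) log(-value) else value

conn_from_filter <- function(value, name)
  if (name %in% c("a11", "a22")) -exp(value) else value

# augmented layout: 10 states, then estimated connectivity coefficients,
# then (optionally) log epsilon_1, log epsilon_2
dcm_augmented_model <- function(config, v0, stims) {
  stopifnot(length(v0) == 2L, all(v0 > 0), all(v0 < 1))
  est_conn <- conn_names[config$estimate_connectivity[conn_names]]
  n_c <- length(est_conn)
  n_e <- if (config$estimate_epsilon) 2L else 0L
  L <- 10L + n_c + n_e
  cidx <- if (n_c) stats::setNames(10L + seq_len(n_c), est_conn)
  eidx <- if (n_e) 10L + n_c + 1:2
  p1 <- config$init_params[[1]]; p2 <- config$init_params[[2]]
  conn0 <- conn_vector(config$init_connectivity)
  env <- new.env(parent = emptyenv())
  env$clamped <- 0L

  build_PC <- function(X) {
    m <- ncol(X)
    P <- matrix(0, 6L, m)
    P[1, ] <- if (n_e) exp(X[eidx[1], ]) else p1$epsilon
    P[2, ] <- if (n_e) exp(X[eidx[2], ]) else p2$epsilon
    P[3, ] <- p1$tau_s; P[4, ] <- p1$tau_f
    P[5, ] <- p1$tau_0; P[6, ] <- p1$E0
    C <- matrix(conn0, 6L, m)
    for (nm in est_conn)
      C[match(nm, conn_names), ] <- conn_from_filter(X[cidx[[nm]], ], nm)
    list(P = P, C = C)
  }

  propagate <- function(X, t_from, dt_obs) {
    pc <- build_PC(X)
    n_sub <- max(1L, as.integer(round(dt_obs / config$dt_integration)))
    res <- propagate_dcm_cols_cpp(
      X[1:10, , drop = FALSE], pc$P, pc$C, p1$alpha,
      stims[[1]]$onsets, stims[[1]]$durations, stims[[1]]$amplitude,
      stims[[2]]$onsets, stims[[2]]$durations, stims[[2]]$amplitude,
      t_from, n_sub, dt_obs / n_sub)
    env$clamped <- env$clamped + res$n_clamped
    X[1:10, ] <- res$states
    X
  }

  observe <- function(X) {
    obs_region <- function(v, q, E0, V0) {
      v <- pmax(v, 1e-6); q <- pmax(q, 1e-6)
      V0 * (7 * E0 * (1 - q) + 2 * (1 - q / v) + (2 * E0 - 0.2) * (1 - v))
    }
    rbind(obs_region(X[5, ], X[6, ], p1$E0, v0[1]),
          obs_region(X[9, ], X[10, ], p2$E0, v0[2]))
  }

  decode <- function(mean) {
    cv <- conn0
    for (nm in est_conn)
      cv[match(nm, conn_names)] <- conn_from_filter(mean[[cidx[[nm]]]], nm)
    cvl <- as.list(cv)
    names(cvl) <- conn_names
    list(connectivity = suppressWarnings(do.call(dcm_connectivity, cvl)),
         epsilon = if (n_e) exp(mean[eidx])
         else c(p1$epsilon, p2$epsilon))
  }

  init_mean <- c(rep(c(0, 0), 1L), rep(c(0, 1, 1, 1), 2L),
                 vapply(est_conn, function(nm)
                   conn_to_filter(conn0[[match(nm, conn_names)]], nm),
                   numeric(1)),
                 if (n_e) log(c(p1$epsilon, p2$epsilon)))
  init_cov <- diag(c(rep(config$init_state_sd^2, 10L),
                     rep(config$init_conn_sd^2, n_c),
                     rep(config$init_epsilon_sd^2, n_e)), L)
  Q <- diag(c(rep(config$q_state, 10L), rep(config$q_conn, n_c),
              rep(config$q_param, n_e)), L)
  list(L = L, est_conn = est_conn, cidx = cidx, eidx = eidx,
       propagate = propagate, observe = observe, decode = decode,
       init_mean = init_mean, init_cov = init_cov, Q = Q, env = env)
}

#' Assimilate two-region BOLD series against the DCM
#'
#' Joint unscented-Kalman filtering of the augmented state: two neuronal
#' states, two sets of four hemodynamic states, and the estimated coupling
#' coefficients (plus, optionally, log neuronal efficacies).  The
#' measurement is the two-region BOLD vector; each region's `V0` is fixed
#' (supplied, never estimated).
#'
#' @param series Data frame with columns `time_s`, `bold1`, `bold2` (the
#'   `bold*_noisy` columns of [simulate_dcm()] are also accepted).
#' @param stimulus A [stimulus_train()] or list of two.
#' @param v0 Length-2 resting blood volume fraction, one per region.
#' @param config A [dcm_filter_config()].
#' @return A `dcm_assimilation_result`: `connectivity` estimates (as a
#'   [dcm_connectivity()]) with posterior standard deviations `conn_sd`
#'   and covariance `conn_cov`, per-region `epsilon`, filtered `states`,
#'   two-region `bold` fits, `loglik`, and the echoed `config`.
#' @export
run_dcm_assimilation <- function(series, stimulus, v0,
                                 config = dcm_filter_config()) {
  stopifnot(is.data.frame(series), "time_s" %in% names(series))
  y1 <- if ("bold1" %in% names(series)) series$bold1 else series$bold1_noisy
  y2 <- if ("bold2" %in% names(series)) series$bold2 else series$bold2_noisy
  if (is.null(y1) || is.null(y2))
    stop("series must contain bold1/bold2 (or bold1_noisy/bold2_noisy)")
  times <- series$time_s
  n <- length(times)
  dts <- diff(times)
  if (max(abs(dts - dts[1])) > 1e-8 * max(dts))
    stop("series timestamps must be uniformly spaced")
  stims <- if (inherits(stimulus, "stimulus_train")) list(stimulus, stimulus)
  else stimulus
  R <- config$meas_var
  if (is.null(R)) R <- c(stats::var(diff(y1)) / 2, stats::var(diff(y2)) / 2)
  R <- diag(rep_len(R, 2L), 2L)

  model <- dcm_augmented_model(config, v0, stims)
  mean <- model$init_mean
  cov <- model$init_cov
  m_filt <- matrix(NA_real_, model$L, n)
  bold_pred <- matrix(NA_real_, n, 2L)
  loglik <- 0
  prev_t <- 0
  for (k in seq_len(n)) {
    dt <- times[k] - prev_t
    if (dt > 0) {
      pr <- ukf_predict(mean, cov,
                        function(X) model$propagate(X, prev_t, dt),
                        model$Q, config$ukf_alpha, config$ukf_beta,
                        config$ukf_kappa)
      mean <- pr$mean; cov <- pr$cov
    }
    up <- ukf_update(mean, cov, model$observe, R, c(y1[k], y2[k]),
                     config$ukf_alpha, config$ukf_beta, config$ukf_kappa)
    mean <- up$mean; cov <- up$cov
    bold_pred[k, ] <- up$pred_obs
    loglik <- loglik + up$loglik
    if (any(!is.finite(cov)))
      stop(sprintf("DCM filter diverged at t = %g s (scan %d)",
                   times[k], k))
    m_filt[, k] <- mean
    prev_t <- times[k]
  }
  dec <- model$decode(mean)
  yfit <- model$observe(m_filt)
  states <- as.data.frame(t(m_filt[1:10, , drop = FALSE]))
  names(states) <- c("z1", "z2", "s1", "f1", "v1", "q1",
                     "s2", "f2", "v2", "q2")
  states <- cbind(time_s = times, states)
  out <- list(
    connectivity = dec$connectivity,
    conn_sd = if (length(model$est_conn))
      stats::setNames(sqrt(diag(cov))[unlist(model$cidx)], model$est_conn),
    conn_cov = if (length(model$est_conn))
      cov[unlist(model$cidx), unlist(model$cidx), drop = FALSE],
    epsilon = dec$epsilon,
    states = states,
    bold = data.frame(time_s = times, observed1 = y1, observed2 = y2,
                      predicted1 = bold_pred[, 1], predicted2 = bold_pred[, 2],
                      filtered1 = yfit[1, ], filtered2 = yfit[2, ]),
    loglik = loglik, n_clamped = model$env$clamped, v0 = v0,
    config = config, final_mean = mean, final_cov = cov
  )
  class(out) <- "dcm_assimilation_result"
  out
}

#' @export
print.dcm_assimilation_result <- function(x, ...) {
  cat(sprintf("Two-region DCM assimilation (V0 = %.3g / %.3g, %d scans)\n",
              x$v0[1], x$v0[2], nrow(x$bold)))
  print(x$connectivity)
  if (!is.null(x$conn_sd))
    cat("  posterior SD:",
        paste(sprintf("%s %.3g", names(x$conn_sd), x$conn_sd),
              collapse = ", "), "\n")
  cat(sprintf("  log-likelihood %.6g\n", x$loglik))
  invisible(x)
}
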
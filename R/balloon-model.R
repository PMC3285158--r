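#' Hemodynamic Balloon-model parameters
#'
#' Bundles the free parameters of the Balloon model together with the fixed
#' stiffness exponent and the resting blood volume fraction.  All
#' parameters are validated against their physiological domains.
#'
#' @param epsilon Neuronal efficacy (dimensionless, per unit input;
#'   `>= 0`).  Scales how strongly the input drives the flow-inducing
#'   signal.
#' @param tau_s Signal-decay time constant in seconds (`> 0`).
#' @param tau_f Feedback autoregulation time constant in seconds (`> 0`).
#' @param tau_0 Mean transit time of the venous compartment in seconds
#'   (`> 0`).
#' @param E0 Resting oxygen extraction fraction, in `(0, 1)`.
#' @param alpha Stiffness exponent of the flow-volume relation, in
#'   `(0, 1)`.  Fixed (never estimated) because its influence on the output
#'   is marginal within the physiological range.
#' @param V0 Resting blood volume fraction, in `(0, 1)`.  Supplied
#'   externally (assumed or calibrated from angiography); never estimated.
#'
#' @return An object of class `hemodynamic_params` (a validated named list).
#' @examples
#' p <- hemodynamic_params()
#' p$epsilon
#' @export
hemodynamic_params <- function(epsilon = 0.54, tau_s = 1.54, tau_f = 2.46,
                               tau_0 = 0.98, E0 = 0.34, alpha = 0.2,
                               V0 = 0.02) {
  stopifnot(
    is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0,
    tau_s > 0, tau_f > 0, tau_0 > 0,
    E0 > 0, E0 < 1, alpha > 0, alpha < 1, V0 > 0, V0 < 1
  )
  structure(
    list(epsilon = epsilon, tau_s = tau_s, tau_f = tau_f, tau_0 = tau_0,
         E0 = E0, alpha = alpha, V0 = V0),
    class = "hemodynamic_params"
  )
}

#' @export
print.hemodynamic_params <- function(x, ...) {
  cat("Balloon-model parameters:\n")
  cat(sprintf("  epsilon = %.4g   tau_s = %.4g s   tau_f = %.4g s\n",
              x$epsilon, x$tau_s, x$tau_f))
  cat(sprintf("  tau_0   = %.4g s E0    = %.4g     alpha = %.4g (fixed)\n",
              x$tau_0, x$E0, x$alpha))
  cat(sprintf("  V0      = %.4g (supplied, never estimated)\n", x$V0))
  invisible(x)
}

#' Hemodynamic state vector
#'
#' The four hidden physiological states of the Balloon model, all in
#' normalized units relative to rest: flow-inducing signal `s`, blood
#' inflow `f`, venous volume `v` and deoxyhemoglobin content `q`.  The
#' resting state is `(0, 1, 1, 1)`.
#'
#' @param s Flow-inducing signal (dimensionless; 0 at rest).
#' @param f Normalized inflow (`> 0`; 1 at rest).
#' @param v Normalized venous volume (`> 0`; 1 at rest).
#' @param q Normalized deoxyhemoglobin content (`> 0`; 1 at rest).
#' @return Named numeric vector of class `hemodynamic_state`.
#' @export
hemodynamic_state <- function(s = 0, f = 1, v = 1, q = 1) {
  stopifnot(f > 0, v > 0, q > 0)
  structure(c(s = s, f = f, v = v, q = q), class = "hemodynamic_state")
}

#' Block-design stimulus train
#'
#' A boxcar (squarewave) input: the stimulus equals `amplitude` during the
#' half-open blocks `[onset, onset + duration)` and 0 elsewhere.
#'
#' @param onsets Block start times in seconds, sorted ascending.
#' @param durations Block durations in seconds (`> 0`), same length as
#'   `onsets`.  Blocks must not overlap.
#' @param amplitude Input level during blocks (dimensionless, default 1).
#' @return An object of class `stimulus_train`.
#' @examples
#' stim <- stimulus_train(onsets = c(20, 60), durations = c(20, 20))
#' neural_input(stim, c(10, 20, 39.9, 40))
#' @export
stimulus_train <- function(onsets, durations, amplitude = 1) {
  onsets <- as.numeric(onsets)
  durations <- as.numeric(durations)
  stopifnot(length(onsets) == length(durations), all(durations > 0),
            length(amplitude) == 1L)
  if (is.unsorted(onsets, strictly = FALSE))
    stop("stimulus onsets must be sorted ascending")
  if (length(onsets) > 1L &&
      any(onsets[-1L] < (onsets + durations)[-length(onsets)]))
    stop("stimulus blocks must not overlap")
  structure(list(onsets = onsets, durations = durations,
                 amplitude = amplitude),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("Boxcar stimulus: %d block(s), amplitude %.3g\n",
              length(x$onsets), x$amplitude))
  if (length(x$onsets))
    cat("  blocks [s]:",
        paste(sprintf("[%g, %g)", x$onsets, x$onsets + x$durations),
              collapse = " "), "\n")
  invisible(x)
}

#' Evaluate the stimulus at given times
#'
#' @param stimulus A [stimulus_train()].
#' @param t Numeric vector of times in seconds (`>= 0`).
#' @return Input level at each time (amplitude inside a block, 0 outside;
#'   block intervals are half-open, onset included, offset excluded).
#' @export
neural_input <- function(stimulus, t) {
  stopifnot(inherits(stimulus, "stimulus_train"), all(t >= 0))
  u <- numeric(length(t))
  for (i in seq_along(stimulus$onsets)) {
    on <- stimulus$onsets[i]
    u[t >= on & t < on + stimulus$durations[i]] <- stimulus$amplitude
  }
  u
}

#' Instantaneous oxygen extraction fraction
#'
#' The Balloon-model coupling of extraction to inflow:
#' `E(f, E0) = 1 - (1 - E0)^(1/f)`.  At resting inflow (`f = 1`) this
#' reduces to `E0`; as `f` grows the extraction tends to 1.
#'
#' @param f Normalized inflow (`> 0`); vectorized.
#' @param E0 Resting oxygen extraction fraction in `(0, 1)`.
#' @return Extraction fraction in `(0, 1)`, same length as `f`.
#' @export
oxygen_extraction <- function(f, E0) {
  if (any(f <= 0)) stop("inflow f must be strictly positive")
  stopifnot(E0 > 0, E0 < 1)
  # f = 1 returns E0 exactly (the identity would otherwise pick up
  # roundoff from 1 - (1 - E0))
  ifelse(f == 1, E0, 1 - (1 - E0)^(1 / f))
}

#' Time derivatives of the hemodynamic states
#'
#' The four-ODE Balloon system: the flow-inducing signal integrates the
#' input minus decay and flow feedback, inflow integrates the signal, and
#' the venous compartment balances inflow against outflow `v^(1/alpha)`
#' for volume and deoxyhemoglobin.
#'
#' @param state A [hemodynamic_state()] or numeric vector `(s, f, v, q)`.
#' @param params A [hemodynamic_params()].
#' @param u Input level (dimensionless scalar).
#' @return Named numeric vector of the four derivatives (per second).
#' @examples
#' p <- hemodynamic_params()
#' hemodynamic_derivatives(hemodynamic_state(), p, u = 0)  # all zero
#' @export
hemodynamic_derivatives <- function(state, params, u) {
  stopifnot(inherits(params, "hemodynamic_params"), is.numeric(u),
            length(u) == 1L)
  x <- unclass(state)
  if (length(x) != 4L) stop("state must have four components (s, f, v, q)")
  s <- x[[1]]; f <- x[[2]]; v <- x[[3]]; q <- x[[4]]
  if (f <= 0 || v <= 0 || q <= 0)
    stop("f, v and q must be strictly positive")
  fout <- v^(1 / params$alpha)
  E <- oxygen_extraction(f, params$E0)
  c(s = params$epsilon * u - s / params$tau_s - (f - 1) / params$tau_f,
    f = s,
    v = (f - fout) / params$tau_0,
    q = (f * E / params$E0 - fout * q / v) / params$tau_0)
}

#' BOLD observation coefficients
#'
#' Field-strength calibration of the three coefficients of the BOLD
#' observation equation.  The default is the 1.5 Tesla set
#' `k1 = 7*E0`, `k2 = 2`, `k3 = 2*E0 - 0.2`.
#'
#' @param E0 Resting oxygen extraction fraction.
#' @return Named numeric vector `c(k1, k2, k3)`.
#' @export
bold_coefficients <- function(E0) {
  stopifnot(E0 > 0, E0 < 1)
  c(k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2)
}

#' Nonlinear BOLD observation equation
#'
#' Maps venous volume and deoxyhemoglobin content to the fractional BOLD
#' signal change:
#' `y = V0 * (k1*(1 - q) + k2*(1 - q/v) + k3*(1 - v))`.
#' The output is exactly linear in `V0` and zero at rest (`v = q = 1`).
#'
#' @param state A [hemodynamic_state()], a numeric vector `(s, f, v, q)`,
#'   or a matrix with four rows (one state per column).
#' @param E0 Resting oxygen extraction fraction in `(0, 1)`.
#' @param V0 Resting blood volume fraction in `(0, 1)`.
#' @param coefs Optional explicit `c(k1, k2, k3)`; defaults to the 1.5 T
#'   calibration [bold_coefficients()].
#' @return BOLD signal change (dimensionless fraction), one value per
#'   state.
#' @export
bold_observation <- function(state, E0, V0, coefs = NULL) {
  stopifnot(V0 > 0, V0 < 1)
  if (is.null(coefs)) coefs <- bold_coefficients(E0)
  if (is.matrix(state)) {
    v <- state[3L, ]; q <- state[4L, ]
  } else {
    x <- unclass(state)
    v <- x[[3]]; q <- x[[4]]
  }
  if (any(v <= 0) || any(q <= 0))
    stop("v and q must be strictly positive")
  V0 * (coefs[[1L]] * (1 - q) + coefs[[2L]] * (1 - q / v) +
          coefs[[3L]] * (1 - v))
}

#' Integrate the Balloon model over a stimulus train
#'
#' Deterministic fixed-step fourth-order Runge-Kutta integration of the
#' four-ODE system, starting at rest.
#'
#' @param params A [hemodynamic_params()].
#' @param stimulus A [stimulus_train()].
#' @param t_span Numeric `c(start, end)` in seconds; must cover all blocks.
#' @param dt Internal integration step in seconds (default 0.01).
#' @param init Initial state (default: rest).
#' @return A `balloon_trajectory`: data frame with columns `time`, `s`,
#'   `f`, `v`, `q`; attribute `n_clamped` counts positivity-floor events
#'   (0 for well-posed runs).
#' @examples
#' stim <- stimulus_train(20, 20)
#' traj <- integrate_balloon(hemodynamic_params(), stim, c(0, 80))
#' max(traj$f)
#' @export
integrate_balloon <- function(params, stimulus, t_span, dt = 0.01,
                              init = hemodynamic_state()) {
  stopifnot(inherits(params, "hemodynamic_params"),
            inherits(stimulus, "stimulus_train"),
            length(t_span) == 2L, t_span[2] > t_span[1], dt > 0)
  ends <- stimulus$onsets + stimulus$durations
  if (length(ends) && (min(stimulus$onsets) < t_span[1] ||
                       max(ends) > t_span[2]))
    stop("t_span must cover all stimulus blocks")
  n_steps <- as.integer(round((t_span[2] - t_span[1]) / dt))
  res <- integrate_balloon_cpp(
    as.numeric(unclass(init)),
    c(params$epsilon, params$tau_s, params$tau_f, params$tau_0, params$E0),
    params$alpha, stimulus$onsets, stimulus$durations, stimulus$amplitude,
    t_span[1], n_steps, dt
  )
  out <- data.frame(time = t_span[1] + dt * (0:n_steps),
                    s = res$states[, 1], f = res$states[, 2],
                    v = res$states[, 3], q = res$states[, 4])
  attr(out, "n_clamped") <- res$n_clamped
  class(out) <- c("balloon_trajectory", "data.frame")
  out
}

#' Simulate a noisy BOLD time series
#'
#' Runs the forward model and samples the BOLD observation at the scan
#' times, optionally adding i.i.d. Gaussian measurement noise.
#'
#' @param params A [hemodynamic_params()] (its `V0` and `E0` enter the
#'   observation).
#' @param stimulus A [stimulus_train()].
#' @param sample_times Scan times in seconds (within the integrated span).
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise (`>= 0`).
#' @param seed Optional integer seed; given a seed, the output is
#'   reproducible.
#' @param dt Internal integration step (seconds).
#' @return Data frame with columns `time_s`, `bold_noiseless`,
#'   `bold_noisy`; attributes `params`, `seed`, `noise_sd`.
#' @export
simulate_bold <- function(params, stimulus, sample_times, noise_sd = 0,
                          seed = NULL, dt = 0.01) {
  stopifnot(noise_sd >= 0, all(diff(sample_times) > 0))
  t_end <- max(sample_times,
               if (length(stimulus$onsets))
                 stimulus$onsets + stimulus$durations else 0)
  traj <- integrate_balloon(params, stimulus, c(0, t_end), dt = dt)
  idx <- round((sample_times - traj$time[1]) / dt) + 1L
  if (any(idx < 1L | idx > nrow(traj)))
    stop("sample_times must lie within the integrated span")
  y <- bold_observation(t(as.matrix(traj[idx, c("s", "f", "v", "q")])),
                        params$E0, params$V0)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(length(y), 0, noise_sd) else 0
  out <- data.frame(time_s = sample_times, bold_noiseless = y,
                    bold_noisy = y + noise)
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "noise_sd") <- noise_sd
  out
}
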
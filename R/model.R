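# ---------------------------------------------------------------------------
# Stochastic Wilson-Cowan dynamics of the eight populations:
#   tau dr/dt = -r + phi(W r + I_ext) + eta,   phi(x) = a x / (1 - e^(-x/b))
# integrated by forward Euler at dt = 0.1 ms with additive Gaussian noise.
# ---------------------------------------------------------------------------

#' Model parameters for the rate dynamics
#'
#' @param tau Per-population time constants (ms); a scalar is recycled to
#'   all eight populations. Default 10 ms everywhere (a placeholder used
#'   when no cell-type-specific values are supplied; empirical values can
#'   be passed as a named vector in population order).
#' @param a Transfer-function slope (dimensionless, default 1).
#' @param b Transfer-function threshold parameter (Hz, default 1).
#' @param sigma Standard deviation of the additive Gaussian rate noise
#'   (Hz, default 0.01).
#' @param dt Euler integration step (ms, default 0.1).
#' @param sqrt_dt_noise If \code{TRUE}, scale the per-step noise increment
#'   by \code{sqrt(dt)/tau} (Euler-Maruyama convention) instead of the
#'   default \code{dt/tau}. Default \code{FALSE}: the noise enters the
#'   discrete update exactly as written in the model equation at the
#'   reference step of 0.1 ms.
#' @param clip_rates If \code{TRUE}, clip rates at zero after each step.
#'   Off by default: with sigma = 0.01 negative excursions are O(sigma)
#'   and negligible.
#' @return Object of class \code{model_params}.
#' @export
model_params <- function(tau = 10, a = 1, b = 1, sigma = 0.01, dt = 0.1,
                         sqrt_dt_noise = FALSE, clip_rates = FALSE) {
  if (length(tau) == 1L) tau <- rep(tau, 8L)
  stopifnot(length(tau) == 8L, all(tau > 0), length(dt) == 1L, dt > 0,
            length(sigma) == 1L, sigma >= 0, a > 0, b > 0)
  structure(list(tau = unname(tau), a = a, b = b, sigma = sigma, dt = dt,
                 sqrt_dt_noise = isTRUE(sqrt_dt_noise),
                 clip_rates = isTRUE(clip_rates)),
            class = "model_params")
}

#' Rate transfer function
#'
#' \code{phi(x) = a x / (1 - exp(-x/b))}: a smoothly rectifying
#' input-output curve that is ~0 for strongly negative input, crosses
#' \code{a b} at x = 0 (the removable singularity, filled by its limit) and
#' grows linearly with slope \code{a} for large positive input. Strictly
#' increasing and non-negative on the whole real line; overflow-safe.
#'
#' @param x Net input (Hz); vectorised.
#' @param a Slope parameter.
#' @param b Threshold parameter (Hz).
#' @return Firing rate(s) in Hz.
#' @export
rate_transfer <- function(x, a = 1, b = 1) {
  stopifnot(all(is.finite(x)), a > 0, b > 0)
  transfer_cpp(as.numeric(x), a, b)
}

# derivative of the transfer function (used by the linearisation)
transfer_deriv <- function(x, a = 1, b = 1) {
  u <- x / b
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  lo <- u <= -30
  mid <- !small & !lo
  out[small] <- 0.5 + u[small] / 6
  out[lo] <- -exp(u[lo]) * (1 + u[lo])        # ~0 from above
  if (any(mid)) {
    um <- u[mid]
    em <- -expm1(-um)                          # 1 - e^-u
    out[mid] <- (em - um * exp(-um)) / em^2
  }
  a * out
}

#' Define an external stimulation protocol
#'
#' External drive is piecewise constant per population: a baseline plus
#' optional timed steps. A per-population input-weight vector can scale a
#' scalar drive amplitude (used for feedforward/feedback input models).
#'
#' @param baseline Named numeric vector of constant drives (Hz) for a
#'   subset of populations (e.g. \code{c(PYR_sup = 5, PYR_deep = 5)}), or a
#'   full 8-vector in population order. Unnamed scalar = same drive to all.
#' @param steps Optional list of \code{list(window = c(t0, t1), drive =
#'   named vector)}; each drive is added to the baseline inside its window
#'   (ms). Windows must not overlap.
#' @param input_weights Optional per-population multiplier vector (named or
#'   full length 8); the effective baseline gains
#'   \code{input_weights * amplitude}.
#' @param amplitude Scalar drive amplitude used with \code{input_weights}
#'   (Hz, default 0).
#' @return Object of class \code{stimulus_protocol}.
#' @export
stimulus_protocol <- function(baseline = 0, steps = NULL,
                              input_weights = NULL, amplitude = 0) {
  base <- expand_drive(baseline)
  if (!is.null(input_weights))
    base <- base + expand_drive(input_weights) * amplitude
  if (!is.null(steps)) {
    for (s in steps) {
      stopifnot(length(s$window) == 2L, s$window[1] < s$window[2])
      s$drive <- expand_drive(s$drive)
    }
    w <- t(vapply(steps, function(s) s$window, numeric(2)))
    o <- order(w[, 1])
    if (any(w[o, 1][-1] < w[o, 2][-nrow(w)]))
      stop("stimulus step windows overlap", call. = FALSE)
  }
  structure(list(baseline = base, steps = steps), class = "stimulus_protocol")
}

# named/partial/scalar drive vector -> full 8-vector in population order
expand_drive <- function(x) {
  if (is.null(x)) return(numeric(8L))
  if (is.null(names(x))) {
    if (length(x) == 1L) return(rep(as.numeric(x), 8L))
    stopifnot(length(x) == 8L)
    return(as.numeric(x))
  }
  out <- numeric(8L)
  out[pop_index(names(x))] <- as.numeric(x)
  out
}

# protocol -> piecewise-constant segments on the step grid
# returns list(iext = 8 x n_seg matrix, seg_end = last step of each segment)
protocol_segments <- function(stim, duration, dt) {
  n_steps <- round(duration / dt)
  if (is.null(stim$steps)) {
    return(list(iext = matrix(stim$baseline, nrow = 8L),
                seg_end = as.integer(n_steps)))
  }
  bounds <- sort(unique(c(0, duration,
                          unlist(lapply(stim$steps, `[[`, "window")))))
  bounds <- bounds[bounds >= 0 & bounds <= duration]
  iext <- matrix(stim$baseline, nrow = 8L, ncol = length(bounds) - 1L)
  for (s in stim$steps) {
    mid <- (head(bounds, -1) + tail(bounds, -1)) / 2
    inside <- mid >= s$window[1] & mid < s$window[2]
    iext[, inside] <- iext[, inside] + expand_drive(s$drive)
  }
  seg_end <- as.integer(round(tail(bounds, -1) / dt))
  seg_end[length(seg_end)] <- as.integer(n_steps)
  list(iext = iext, seg_end = seg_end)
}

#' Simulate the stochastic rate dynamics
#'
#' Forward-Euler integration of the eight-population system. The noise term
#' is drawn i.i.d. per population and step. The recorded trace holds
#' block-averaged rates on a coarser grid (\code{record_dt}); the exact
#' terminal state is kept separately for warm starts.
#'
#' @param C A [connectivity_matrix()] (already scaled by the desired G).
#' @param params A [model_params()].
#' @param stim A [stimulus_protocol()].
#' @param duration Simulated time (ms).
#' @param seed Optional integer seed (noise reproducibility).
#' @param initial_rates Optional initial rate vector (Hz); default zero.
#' @param record_dt Spacing of recorded samples (ms); must be a multiple of
#'   \code{params$dt}. Default 1 ms (1 kHz trace).
#' @return Object of class \code{rate_trace}: \code{time} (ms),
#'   \code{rates} (samples x 8, block means), \code{r_final},
#'   \code{drift_final}, provenance fields.
#'   Raises a condition of class \code{microswitch_divergence} reporting
#'   the blow-up time if the rates leave the finite range.
#' @export
simulate_rates <- function(C, params, stim = stimulus_protocol(),
                           duration = 2000, seed = NULL,
                           initial_rates = NULL, record_dt = 1) {
  stopifnot(inherits(C, "connectivity_matrix"),
            inherits(params, "model_params"),
            inherits(stim, "stimulus_protocol"),
            duration >= params$dt)
  record_every <- round(record_dt / params$dt)
  stopifnot(record_every >= 1)
  r0 <- if (is.null(initial_rates)) numeric(8L) else {
    stopifnot(length(initial_rates) == 8L)
    as.numeric(initial_rates)
  }
  if (!is.null(seed)) set.seed(seed)
  seg <- protocol_segments(stim, duration, params$dt)
  n_steps <- round(duration / params$dt)
  res <- sim_euler(C$W, params$tau, params$a, params$b, params$sigma,
                   params$dt, as.integer(n_steps),
                   as.integer(record_every), r0, seg$iext, seg$seg_end,
                   params$sqrt_dt_noise)
  if (res$diverged_step > 0) {
    t_div <- res$diverged_step * params$dt
    stop(structure(
      class = c("microswitch_divergence", "error", "condition"),
      list(message = sprintf(
             "rate dynamics diverged at t = %.1f ms (G = %g)", t_div, C$G),
           call = sys.call(), time = t_div)))
  }
  rates <- res$rates
  colnames(rates) <- POPULATIONS
  if (params$clip_rates) rates[rates < 0] <- 0
  structure(list(
    time = seq_len(nrow(rates)) * record_dt,
    rates = rates,
    r_final = setNames(res$r_final, POPULATIONS),
    drift_final = setNames(res$drift_final, POPULATIONS),
    record_dt = record_dt,
    params = params, G = C$G, seed = seed
  ), class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("<rate_trace> %.0f ms at %.3g ms spacing, G = %g\n",
              max(x$time), x$record_dt, x$G))
  cat("terminal rates (Hz):\n")
  print(round(x$r_final, 4))
  invisible(x)
}

#' Noise-free steady state
#'
#' Runs a noise-free (sigma = 0) simulation for \code{duration} ms and
#' returns the terminal rate vector. Convergence is diagnosed from the
#' terminal drift \code{||dr/dt||}: a sustained limit cycle or slow
#' relaxation leaves the \code{converged} attribute \code{FALSE} rather
#' than raising an error.
#'
#' @inheritParams simulate_rates
#' @param duration Settling time (ms, default 2000).
#' @param tol Convergence tolerance on \code{max |dr/dt|} (Hz/ms).
#' @return Named rate vector (Hz) with attributes \code{converged}
#'   (logical) and \code{drift} (terminal max |dr/dt|).
#' @export
steady_state <- function(C, params = model_params(),
                         stim = stimulus_protocol(), duration = 2000,
                         initial_rates = NULL, tol = 1e-5) {
  p0 <- params
  p0$sigma <- 0
  tr <- simulate_rates(C, p0, stim, duration = duration,
                       initial_rates = initial_rates,
                       record_dt = max(1, p0$dt))
  drift <- max(abs(tr$drift_final))
  structure(tr$r_final, converged = drift < tol, drift = drift)
}

#' Oscillation frequency from linear stability analysis
#'
#' Locates a fixed point of the noise-free dynamics (settling run followed
#' by Newton refinement with the analytic Jacobian), linearises the system
#' there, and returns the frequency \code{Im(lambda)/(2 pi)} of the
#' least-damped complex-conjugate eigenpair. This is the resonance whose
#' noise-driven expression the spectral analysis measures.
#'
#' @inheritParams steady_state
#' @return Frequency in Hz, or \code{NA_real_} if every eigenvalue of the
#'   Jacobian is real. Attribute \code{damping}: real part (1/ms) of the
#'   reported eigenpair (negative = stable focus). Errors if no fixed
#'   point can be located.
#' @export
linearized_frequency <- function(C, params = model_params(),
                                 stim = stimulus_protocol()) {
  stopifnot(inherits(C, "connectivity_matrix"))
  iext <- stim$baseline
  W <- C$W
  fp <- function(r) -r + rate_transfer(W %*% r + iext, params$a, params$b)
  r <- as.numeric(steady_state(C, params, stim))
  # Newton refinement (converges from a limit cycle to the enclosed focus)
  ok <- FALSE
  for (it in 1:100) {
    f <- fp(r)
    if (max(abs(f)) < 1e-12) { ok <- TRUE; break }
    phip <- transfer_deriv(as.numeric(W %*% r + iext), params$a, params$b)
    Jf <- -diag(8L) + phip * W
    step <- tryCatch(solve(Jf, -f), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 1e6) break
    r <- r + step
  }
  if (!ok && max(abs(fp(r))) > 1e-6)
    stop("no fixed point found for linearisation", call. = FALSE)
  phip <- transfer_deriv(as.numeric(W %*% r + iext), params$a, params$b)
  J <- (1 / params$tau) * (-diag(8L) + phip * W)
  ev <- eigen(J, only.values = TRUE)$values
  cplx <- ev[abs(Im(ev)) > 1e-9]
  if (!length(cplx)) return(NA_real_)
  lead <- cplx[which.max(Re(cplx))]
  # eigenvalues are in 1/ms; convert cycles/ms -> Hz
  structure(abs(Im(lead)) / (2 * pi) * 1000, damping = Re(lead),
            fixed_point = setNames(r, POPULATIONS))
}
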
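# ---------------------------------------------------------------------------
# Ultrasensitivity and bistability metrics. Input-response curves are
# traced with warm-started noise-free sweeps; ultrasensitivity is the Hill
# exponent of the SST response, bistability the summed difference between
# ascending and descending branches.
# ---------------------------------------------------------------------------

#' Warm-started steady-state response sweep
#'
#' For each value of the input grid, adds that drive to the target
#' populations on top of the baseline protocol and computes the noise-free
#' steady state. When \code{warm_start} is \code{TRUE} (the sweep protocol
#' used throughout), the terminal rates at grid point i-1 initialise grid
#' point i, so coexisting attractors are followed and hysteresis becomes
#' visible; otherwise every point starts from zero rates.
#'
#' @param C A [connectivity_matrix()] (already scaled by G).
#' @param params A [model_params()] (sigma is forced to 0).
#' @param stim Baseline [stimulus_protocol()].
#' @param targets Population labels receiving the swept drive.
#' @param input_grid Drive values (Hz) in sweep order; strictly monotone.
#' @param direction \code{"ascending"} or \code{"descending"}; the grid
#'   must be monotone in this direction.
#' @param warm_start Logical (default \code{TRUE}).
#' @param settle_ms Settling time per grid point (ms, default 2000).
#' @param initial_rates Optional rates initialising the first grid point.
#' @return Object of class \code{response_curve}: \code{input},
#'   \code{rates} (grid x 8), \code{direction}, \code{warm_started},
#'   \code{converged} (per grid point).
#' @export
sweep_response <- function(C, params = model_params(),
                           stim = stimulus_protocol(), targets,
                           input_grid,
                           direction = c("ascending", "descending"),
                           warm_start = TRUE, settle_ms = 2000,
                           initial_rates = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(input_grid) >= 1)
  d <- diff(input_grid)
  if (direction == "ascending" && length(d) && any(d <= 0))
    stop("input_grid must be strictly increasing for an ascending sweep",
         call. = FALSE)
  if (direction == "descending" && length(d) && any(d >= 0))
    stop("input_grid must be strictly decreasing for a descending sweep",
         call. = FALSE)
  ti <- pop_index(targets)

  rates <- matrix(NA_real_, length(input_grid), 8L,
                  dimnames = list(NULL, POPULATIONS))
  converged <- logical(length(input_grid))
  r_prev <- initial_rates
  for (i in seq_along(input_grid)) {
    drive <- stim$baseline
    drive[ti] <- drive[ti] + input_grid[i]
    st <- stimulus_protocol(baseline = setNames(drive, POPULATIONS))
    r <- tryCatch(
      steady_state(C, params, st, duration = settle_ms,
                   initial_rates = if (warm_start) r_prev else NULL),
      microswitch_divergence = function(e)
        stop(sprintf("divergence at input = %g Hz: %s",
                     input_grid[i], conditionMessage(e)), call. = FALSE))
    rates[i, ] <- r
    converged[i] <- attr(r, "converged")
    r_prev <- as.numeric(r)
  }
  structure(list(input = input_grid, rates = rates, direction = direction,
                 warm_started = warm_start, converged = converged),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %d points, %s%s\n", length(x$input),
              x$direction, if (x$warm_started) ", warm-started" else ""))
  invisible(x)
}

# residuals of the Hill model y = c + d x^n / (k^n + x^n)
hill_resid <- function(par, x, y) {
  y - (par[1] + par[2] * x^par[4] / (par[3]^par[4] + x^par[4]))
}

#' Fit a Hill function to a response curve
#'
#' Least-squares fit of \code{y(x) = c + d x^n / (k^n + x^n)} with signed
#' amplitude \code{d} (negative for decreasing curves such as SST
#' suppression). The Hill exponent n quantifies ultrasensitivity: n = 1 is
#' hyperbolic, n >> 1 approaches a step. The fit is multi-started over
#' n in \{0.5, 1, 2, 4, 8, 16\} to escape local minima; box constraints
#' keep k within \[0.01, 100\] times the swept range and n in (0, 50\].
#'
#' @param curve A [sweep_response()] result, or a numeric input vector.
#' @param y Response values (Hz) if \code{curve} is a numeric vector.
#' @param population Population whose response is fitted when \code{curve}
#'   is a \code{response_curve} (default \code{"SST_sup"}).
#' @return Object of class \code{hill_fit}: \code{c}, \code{d}, \code{k},
#'   \code{n}, \code{goodness} (residual norm), \code{ok} and
#'   \code{message} (fit-quality warning for flat or poorly fit curves;
#'   never an exception).
#' @export
fit_hill <- function(curve, y = NULL, population = "SST_sup") {
  if (inherits(curve, "response_curve")) {
    x <- curve$input
    y <- curve$rates[, population]
  } else {
    x <- as.numeric(curve)
  }
  stopifnot(length(x) == length(y), length(x) >= 5,
            all(is.finite(x)), all(is.finite(y)), all(x >= 0))
  o <- order(x)
  x <- x[o]; y <- y[o]

  yr <- diff(range(y))
  xmax <- max(x[x > 0], 1)
  if (yr < 1e-9) {
    return(structure(list(c = mean(y), d = 0, k = xmax / 2, n = 1,
                          goodness = 0, ok = FALSE,
                          message = "flat response curve; Hill exponent not identifiable"),
                     class = "hill_fit"))
  }
  lower <- c(-Inf, -10 * yr, 0.01 * xmax, 1e-3)
  upper <- c(Inf, 10 * yr, 100 * xmax, 50)
  d0 <- y[length(y)] - y[1]
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4, 8, 16)) {
    start <- c(y[1], d0, stats::median(x[x > 0]), n0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = hill_resid, x = x, y = y,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(c = NA_real_, d = NA_real_, k = NA_real_,
                          n = NA_real_, goodness = NA_real_, ok = FALSE,
                          message = "all fit starts failed"),
                     class = "hill_fit"))
  }
  p <- best$fit$par
  resid_norm <- sqrt(best$rss)
  rel <- resid_norm / (sqrt(length(y)) * yr)
  ok <- rel < 0.1
  structure(list(c = p[1], d = p[2], k = p[3], n = p[4],
                 goodness = resid_norm, ok = ok,
                 message = if (ok) NULL else
                   sprintf("poor fit: relative residual %.3g", rel)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> c = %.4g, d = %.4g, k = %.4g, n = %.4g (resid %.3g)%s\n",
    x$c, x$d, x$k, x$n, x$goodness,
    if (isTRUE(x$ok)) "" else paste0("  [", x$message, "]")))
  invisible(x)
}

#' Hysteresis area between ascending and descending sweeps
#'
#' Quantifies bistability as the summed absolute difference between the
#' ascending and descending SST response curves, per layer, over the shared
#' input grid. Zero iff the branches coincide on the grid.
#'
#' @param up Ascending [sweep_response()] result.
#' @param down Descending result over the same grid (reversed).
#' @return Object of class \code{hysteresis_result}: \code{h_superficial},
#'   \code{h_deep}, \code{h_total} (Hz, summed over grid points), with both
#'   curves retained.
#' @export
hysteresis_area <- function(up, down) {
  stopifnot(inherits(up, "response_curve"), inherits(down, "response_curve"))
  if (!isTRUE(all.equal(up$input, rev(down$input))))
    stop("ascending and descending sweeps must share one input grid",
         call. = FALSE)
  dn <- down$rates[rev(seq_along(down$input)), , drop = FALSE]
  h_sup <- sum(abs(up$rates[, "SST_sup"] - dn[, "SST_sup"]))
  h_deep <- sum(abs(up$rates[, "SST_deep"] - dn[, "SST_deep"]))
  structure(list(h_superficial = h_sup, h_deep = h_deep,
                 h_total = h_sup + h_deep, up = up, down = down),
            class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf(
    "<hysteresis_result> h_sup = %.4g, h_deep = %.4g, h_total = %.4g Hz\n",
    x$h_superficial, x$h_deep, x$h_total))
  invisible(x)
}
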
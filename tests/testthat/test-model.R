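test_that("transfer function matches its closed form and limits", {
  expect_equal(rate_transfer(0), 1)                    # limit a*b
  expect_equal(rate_transfer(10), 10 / (1 - exp(-10)), tolerance = 1e-12)
  expect_equal(rate_transfer(10), 10.000454, tolerance = 1e-6)
  expect_equal(rate_transfer(0, a = 3, b = 2), 6)
  expect_equal(rate_transfer(5, a = 3, b = 2),
               3 * 5 / (1 - exp(-5 / 2)), tolerance = 1e-12)
  # x -> -Inf limit is 0 from above; overflow-safe at extreme inputs
  expect_lt(rate_transfer(-1e4), 1e-300)
  expect_gte(rate_transfer(-1e4), 0)
  expect_true(is.finite(rate_transfer(1e8)))
  expect_true(is.finite(rate_transfer(-1e8)))
  # continuity through the removable singularity
  expect_equal(rate_transfer(1e-9), 1, tolerance = 1e-8)
  # strictly increasing, non-negative
  x <- seq(-50, 50, by = 0.25)
  y <- rate_transfer(x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0))
})

test_that("decoupled populations relax to the transfer of their drive", {
  st <- stimulus_protocol(c(PYR_sup = 5))
  p <- model_params(sigma = 0)
  tr <- simulate_rates(zero_circuit(), p, st, duration = 2000)
  expect_equal(unname(tr$r_final[1]), rate_transfer(5), tolerance = 1e-6)
  expect_equal(unname(tr$r_final[-1]), rep(rate_transfer(0), 7),
               tolerance = 1e-6)
})

test_that("noise-free terminal rates solve the fixed-point equation", {
  skip_if_not_installed("pracma")
  set.seed(21)
  st <- stimulus_protocol(c(PYR_sup = 5, PYR_deep = 5))
  for (k in 1:5) {
    W <- matrix(rnorm(64, sd = 0.25), 8, 8)
    sgn <- rep(ifelse(EXCITATORY, 1, -1), each = 8)   # column-wise signs
    W <- abs(W) * matrix(sgn, 8, 8)
    W <- W / max(abs(eigen(W, only.values = TRUE)$values)) * 0.7
    C <- connectivity_matrix(W)
    r <- steady_state(C, model_params(), st)
    expect_true(attr(r, "converged"))
    resid <- max(abs(r - rate_transfer(C$W %*% r + st$baseline)))
    expect_lt(resid, 1e-4)
    # independent root-finding oracle from a naive start
    fr <- pracma::fsolve(function(x)
      x - rate_transfer(C$W %*% x + st$baseline),
      rate_transfer(st$baseline))$x
    expect_equal(as.numeric(r), as.numeric(fr), tolerance = 1e-4)
  }
})

test_that("noisy simulation is reproducible under a seed", {
  C <- default_circuit(G = 100)
  st <- stimulus_protocol(c(PYR_sup = 5, PYR_deep = 5))
  t1 <- simulate_rates(C, model_params(), st, duration = 1000, seed = 5)
  t2 <- simulate_rates(C, model_params(), st, duration = 1000, seed = 5)
  expect_identical(t1$rates, t2$rates)
  expect_identical(t1$r_final, t2$r_final)
  t3 <- simulate_rates(C, model_params(), st, duration = 1000, seed = 6)
  expect_false(identical(t1$rates, t3$rates))
})

test_that("a warm start at the fixed point is invariant", {
  C <- default_circuit(G = 100)
  st <- stimulus_protocol(c(PYR_sup = 5, PYR_deep = 5))
  r <- steady_state(C, model_params(), st)
  r2 <- steady_state(C, model_params(), st, duration = 500,
                     initial_rates = as.numeric(r))
  expect_equal(as.numeric(r2), as.numeric(r), tolerance = 1e-8)
})

test_that("halving the integration step barely moves the terminal state", {
  C <- default_circuit(G = 150)
  st <- stimulus_protocol(c(PYR_sup = 5, PYR_deep = 5))
  r1 <- steady_state(C, model_params(dt = 0.1), st)
  r2 <- steady_state(C, model_params(dt = 0.05), st)
  expect_lt(max(abs(r1 - r2)), 1e-4)
})

test_that("noise-free dynamics are permutation equivariant", {
  set.seed(31)
  C <- default_circuit(G = 120)
  st <- stimulus_protocol(c(PYR_sup = 5, SST_deep = 2))
  tau <- c(8, 10, 12, 9, 11, 10, 14, 10)
  perm <- sample(8)
  r <- steady_state(C, model_params(tau = tau, sigma = 0), st)
  Cp <- connectivity_matrix(C$W[perm, perm], check = FALSE)
  rp <- steady_state(Cp, model_params(tau = tau[perm], sigma = 0),
                     stimulus_protocol(setNames(st$baseline[perm],
                                                POPULATIONS)))
  expect_equal(as.numeric(rp), as.numeric(r)[perm], tolerance = 1e-10)
})

test_that("noise-free rates stay non-negative from non-negative starts", {
  C <- default_circuit(G = 300)
  st <- stimulus_protocol(c(PYR_sup = 5, PYR_deep = 5))
  tr <- simulate_rates(C, model_params(sigma = 0), st, duration = 3000)
  expect_true(all(tr$rates >= 0))
})

test_that("stochastic long-run mean agrees with the deterministic fixed point", {
  C <- default_circuit(G = 100)
  st <- stimulus_protocol(c(PYR_sup = 5, PYR_deep = 5))
  r0 <- steady_state(C, model_params(), st)
  tr <- simulate_rates(C, model_params(sigma = 0.01), st,
                       duration = 9000, seed = 8)
  x <- tr$rates[1001:9000, "PYR_sup"]
  batches <- matrix(x, ncol = 8)
  se <- sd(colMeans(batches)) / sqrt(8)
  expect_lt(abs(mean(x) - r0["PYR_sup"]), 3 * se + 1e-3)
})

test_that("explosive recurrence raises a structured divergence error", {
  W <- matrix(0, 8, 8)
  W[1, 1] <- 10                       # strong positive feedback
  C <- connectivity_matrix(W)
  st <- stimulus_protocol(c(PYR_sup = 5))
  err <- tryCatch(simulate_rates(C, model_params(sigma = 0), st,
                                 duration = 2000),
                  microswitch_divergence = function(e) e)
  expect_s3_class(err, "microswitch_divergence")
  expect_true(is.finite(err$time) && err$time > 0)
})

test_that("stepped stimulation protocols switch the drive mid-run", {
  st <- stimulus_protocol(c(PYR_sup = 1),
                          steps = list(list(window = c(500, 1000),
                                            drive = c(PYR_sup = 4))))
  tr <- simulate_rates(zero_circuit(), model_params(sigma = 0), st,
                       duration = 1500)
  expect_equal(unname(tr$rates[450, "PYR_sup"]), rate_transfer(1),
               tolerance = 1e-4)
  expect_equal(unname(tr$rates[990, "PYR_sup"]), rate_transfer(5),
               tolerance = 1e-4)
  expect_equal(unname(tr$rates[1500, "PYR_sup"]), rate_transfer(1),
               tolerance = 1e-4)
  expect_error(
    stimulus_protocol(steps = list(
      list(window = c(0, 600), drive = c(PYR_sup = 1)),
      list(window = c(500, 900), drive = c(PYR_sup = 1)))),
    "overlap")
})

test_that("linearised frequency matches an independent 2x2 eigen computation", {
  skip_if_not_installed("pracma")
  C <- ei_toy(w_ee = 0.5, w_ie = 3, w_ei = -3, w_ii = -0.5)
  st <- stimulus_protocol(c(PYR_sup = 2))
  f <- linearized_frequency(C, model_params(), st)
  # oracle: root-solve the two active equations, finite-difference slopes,
  # quadratic eigenvalue formula
  g <- function(x) x - rate_transfer(C$W[1:2, 1:2] %*% x + c(2, 0))
  fp <- pracma::fsolve(g, c(1, 1))$x
  inp <- as.numeric(C$W[1:2, 1:2] %*% fp + c(2, 0))
  h <- 1e-6
  slope <- (rate_transfer(inp + h) - rate_transfer(inp - h)) / (2 * h)
  J <- (diag(-1, 2) + slope * C$W[1:2, 1:2]) / 10
  tr <- sum(diag(J)); det_ <- det(J)
  disc <- tr^2 - 4 * det_
  expect_lt(disc, 0)
  f_oracle <- sqrt(-disc) / 2 / (2 * pi) * 1000
  expect_equal(as.numeric(f), f_oracle, tolerance = 1e-4)
})

test_that("linearised frequency is absent for a diagonal Jacobian", {
  expect_true(is.na(linearized_frequency(zero_circuit(), model_params(),
                                         stimulus_protocol(c(PYR_sup = 5)))))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(model_params(tau = c(10, -1)), "length")
  expect_error(model_params(tau = rep(-1, 8)))
  expect_error(model_params(dt = 0))
  expect_error(model_params(sigma = -0.1))
})
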
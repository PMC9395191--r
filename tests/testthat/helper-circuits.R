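# shared fixtures: small circuits and constructed traces/spectra

zero_circuit <- function() connectivity_matrix(matrix(0, 8, 8))

# independent brute-force implementation of the correction pipeline,
# used as the oracle for build_corrected_matrix
oracle_corrected <- function(raw) {
  morph <- morphological_types()
  n <- nrow(morph)
  prob <- raw$probability[morph$type, morph$type]
  amp <- raw$amplitude[morph$type, morph$type]
  W <- matrix(0, 8, 8,
              dimnames = list(target = POPULATIONS, source = POPULATIONS))
  for (ms in seq_len(n)) {
    for (mt in seq_len(n)) {
      w <- amp[ms, mt] * prob[ms, mt]
      if (morph$sign[ms] == "inhibitory") {
        w <- -abs(w) * raw$prevalence[[morph$type[ms]]] * raw$inhibitory_scale
      }
      W[morph$population[mt], morph$population[ms]] <-
        W[morph$population[mt], morph$population[ms]] + w
    }
  }
  W
}

# a complete raw-table skeleton (all zeros) over the 11 morphological types
empty_raw_tables <- function() {
  types <- morphological_types()$type
  m <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  prev <- setNames(rep(1, 9), setdiff(types, c("pyramidal_sup",
                                               "pyramidal_deep")))
  list(probability = m, amplitude = m, prevalence = prev)
}

# an 8x8 matrix coupling only superficial PYR and PV (two-population loop)
ei_toy <- function(w_ee = 0, w_ie = 3, w_ei = -3, w_ii = 0) {
  W <- matrix(0, 8, 8)
  dimnames(W) <- list(POPULATIONS, POPULATIONS)
  W["PYR_sup", "PYR_sup"] <- w_ee
  W["PV_sup", "PYR_sup"] <- w_ie
  W["PYR_sup", "PV_sup"] <- w_ei
  W["PV_sup", "PV_sup"] <- w_ii
  connectivity_matrix(W)
}

# mutual inhibition between SST_sup and VIP_sup (winner-take-all substrate)
mutual_inhibition_circuit <- function(w = 2) {
  W <- matrix(0, 8, 8)
  dimnames(W) <- list(POPULATIONS, POPULATIONS)
  W["SST_sup", "VIP_sup"] <- -w
  W["VIP_sup", "SST_sup"] <- -w
  connectivity_matrix(W)
}

# enumerate fixed points of r = phi(Wr + I) by damped iteration from a
# grid of starts; returns the distinct solutions (rows)
enumerate_fixed_points <- function(C, iext, starts = NULL, tol = 1e-9) {
  if (is.null(starts)) {
    g <- c(0, 2, 5, 10, 20)
    starts <- as.matrix(expand.grid(sst = g, vip = g))
  }
  sols <- NULL
  for (k in seq_len(nrow(starts))) {
    r <- numeric(8)
    r[pop_index("SST_sup")] <- starts[k, 1]
    r[pop_index("VIP_sup")] <- starts[k, 2]
    for (it in 1:5000) {
      r_new <- r + 0.3 * (-r + rate_transfer(C$W %*% r + iext))
      if (max(abs(r_new - r)) < tol) break
      r <- r_new
    }
    if (max(abs(-r + rate_transfer(C$W %*% r + iext))) > 1e-6) next
    if (is.null(sols) ||
        all(apply(sols, 1, function(s) max(abs(s - r)) > 1e-4))) {
      sols <- rbind(sols, as.numeric(r))
    }
  }
  sols
}

# wrap a plain numeric series as a rate_trace on the PYR channels
fake_trace <- function(x, record_dt = 1) {
  rates <- matrix(rep(x, 8), ncol = 8,
                  dimnames = list(NULL, POPULATIONS))
  structure(list(time = seq_along(x) * record_dt, rates = rates,
                 r_final = rates[nrow(rates), ],
                 drift_final = setNames(numeric(8), POPULATIONS),
                 record_dt = record_dt, params = model_params(),
                 G = NA_real_, seed = NULL),
            class = "rate_trace")
}

# construct a power_spectrum object directly
fake_spectrum <- function(frequency, power, layer = "superficial") {
  structure(list(frequency = frequency, power = power / sum(power),
                 layer = layer, n_trials = 1,
                 df = frequency[2] - frequency[1]),
            class = "power_spectrum")
}
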
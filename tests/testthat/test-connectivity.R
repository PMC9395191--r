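test_that("corrected matrix equals an independent brute-force correction", {
  set.seed(7)
  tabs <- empty_raw_tables()
  n <- nrow(tabs$probability)
  prob <- matrix(runif(n * n), n, n, dimnames = dimnames(tabs$probability))
  amp <- matrix(runif(n * n, 0, 2), n, n, dimnames = dimnames(tabs$probability))
  prev <- setNames(runif(9, 0.1, 0.9), names(tabs$prevalence))
  raw <- raw_connectivity(prob, amp, prev, inhibitory_scale = 0.2)
  C <- build_corrected_matrix(raw)
  expect_equal(C$W, oracle_corrected(raw), tolerance = 1e-12)
  expect_equal(C$G, 1)
  expect_length(C$manipulations, 0)
})

test_that("unit probabilities and amplitudes give the stated entries", {
  tabs <- empty_raw_tables()
  prob <- tabs$probability + 1
  amp <- tabs$amplitude + 1
  raw <- raw_connectivity(prob, amp, tabs$prevalence, inhibitory_scale = 0.2)
  W <- build_corrected_matrix(raw)$W
  # single-morphology inhibitory source onto a single-morphology target:
  # 1 * 1 * prevalence 1 * 0.2, negated
  expect_equal(W["PYR_sup", "SST_sup"], -0.2)
  # single-morphology excitatory source
  expect_equal(W["PYR_sup", "PYR_deep"], 1)
  # merged PV source (basket + chandelier) onto a single target
  expect_equal(W["PYR_sup", "PV_sup"], -0.4)
  # merged source and merged target: 2 x 2 morphology pairs
  expect_equal(W["PV_sup", "PV_sup"], -0.8)
})

test_that("zero probability annihilates and the build is linear in amplitude", {
  set.seed(11)
  tabs <- empty_raw_tables()
  n <- nrow(tabs$probability)
  amp <- matrix(runif(n * n), n, n, dimnames = dimnames(tabs$probability))
  raw0 <- raw_connectivity(tabs$probability, amp, tabs$prevalence)
  expect_true(all(build_corrected_matrix(raw0)$W == 0))

  prob <- matrix(runif(n * n), n, n, dimnames = dimnames(tabs$probability))
  raw1 <- raw_connectivity(prob, amp, tabs$prevalence)
  raw3 <- raw_connectivity(prob, 3 * amp, tabs$prevalence)
  expect_equal(build_corrected_matrix(raw3)$W,
               3 * build_corrected_matrix(raw1)$W, tolerance = 1e-12)
})

test_that("toy PV subtype merge equals the hand-computed sum of products", {
  tabs <- empty_raw_tables()
  prob <- tabs$probability; amp <- tabs$amplitude
  # printed toy numbers: two PV subtypes projecting onto superficial PYR
  prob["basket_sup", "pyramidal_sup"] <- 0.6
  amp["basket_sup", "pyramidal_sup"] <- 1.5
  prob["chandelier", "pyramidal_sup"] <- 0.25
  amp["chandelier", "pyramidal_sup"] <- 0.8
  prev <- tabs$prevalence
  prev["basket_sup"] <- 0.5
  prev["chandelier"] <- 0.3
  raw <- raw_connectivity(prob, amp, prev, inhibitory_scale = 0.2)
  W <- build_corrected_matrix(raw)$W
  # hand multiplication: -(0.6*1.5*0.5 + 0.25*0.8*0.3) * 0.2
  expect_equal(W["PYR_sup", "PV_sup"], -(0.45 + 0.06) * 0.2)
})

test_that("incomplete raw tables raise structured errors", {
  tabs <- empty_raw_tables()
  short <- tabs$probability[-1, ]
  expect_error(
    build_corrected_matrix(raw_connectivity(short, tabs$amplitude[-1, ],
                                            tabs$prevalence)),
    "pyramidal_sup")
  prev <- tabs$prevalence[-which(names(tabs$prevalence) == "bitufted")]
  expect_error(
    build_corrected_matrix(raw_connectivity(tabs$probability,
                                            tabs$amplitude, prev)),
    "bitufted")
})

test_that("G scaling is multiplicative, sign-preserving and guarded", {
  C <- default_circuit()
  expect_equal(scale_by_G(C, 1)$W, C$W)
  expect_true(all(scale_by_G(C, 0)$W == 0))
  twice <- scale_by_G(scale_by_G(C, 250), 250)
  once <- scale_by_G(C, 62500)
  expect_equal(twice$W, once$W)
  expect_equal(twice$G, once$G)
  expect_error(scale_by_G(C, -1), "non-negative")
  # sign pattern preserved under scaling
  G5 <- scale_by_G(C, 5)
  expect_true(all(G5$W[, EXCITATORY] >= 0))
  expect_true(all(G5$W[, !EXCITATORY] <= 0))
})

test_that("lesions edit exactly the targeted entries and are logged", {
  C <- default_circuit()
  sil <- apply_lesion(C, lesion_spec("silence_cell", source = "PV_sup"))
  expect_true(all(sil$W[, "PV_sup"] == 0))
  expect_equal(sil$W[, -pop_index("PV_sup")], C$W[, -pop_index("PV_sup")])
  expect_equal(sil$manipulations[[1]]$kind, "silence_cell")

  rem <- apply_lesion(C, lesion_spec("remove_connection",
                                     source = "PYR_sup",
                                     target = "PYR_deep"))
  expect_equal(rem$W["PYR_deep", "PYR_sup"], 0)
  delta <- rem$W != C$W
  expect_equal(sum(delta), 1L)

  set <- apply_lesion(C, lesion_spec("set_connection", source = "PYR_sup",
                                     target = "PV_sup", value = 0.123))
  expect_equal(set$W["PV_sup", "PYR_sup"], 0.123)

  eq <- apply_lesion(C, lesion_spec("equalize_pv_self"))
  expect_equal(eq$W["PV_sup", "PV_sup"], C$W["PV_deep", "PV_deep"])

  expect_error(lesion_spec("silence_cell", source = "PV_middle"),
               "unknown population")
})

test_that("equalize_pv_self assigns the deep value on a synthetic matrix", {
  W <- matrix(0, 8, 8)
  W[pop_index("PV_sup"), pop_index("PV_sup")] <- -0.5
  W[pop_index("PV_deep"), pop_index("PV_deep")] <- -0.9
  C <- apply_lesion(connectivity_matrix(W), lesion_spec("equalize_pv_self"))
  expect_equal(C$W[pop_index("PV_sup"), pop_index("PV_sup")], -0.9)
  expect_equal(C$W[pop_index("PV_deep"), pop_index("PV_deep")], -0.9)
})

test_that("self-connection swap exchanges PV and SST entries and is an involution", {
  C <- default_circuit()
  S <- apply_lesion(C, lesion_spec("swap_self_connections"))
  for (lay in c("sup", "deep")) {
    pv <- pop_index(paste0("PV_", lay)); sst <- pop_index(paste0("SST_", lay))
    expect_equal(S$W[sst, sst], C$W[pv, pv])
    expect_equal(S$W[pv, pv], C$W[sst, sst])
  }
  SS <- apply_lesion(S, lesion_spec("swap_self_connections"))
  expect_identical(SS$W, C$W)
})

test_that("jitter perturbs nonzero weights only, reproducibly and unbiasedly", {
  C <- default_circuit()
  expect_equal(jitter_matrix(C, scale = 0, seed = 1)$W, C$W)
  j1 <- jitter_matrix(C, scale = 0.2, seed = 42)
  j2 <- jitter_matrix(C, scale = 0.2, seed = 42)
  expect_identical(j1$W, j2$W)
  expect_false(identical(j1$W, jitter_matrix(C, 0.2, seed = 43)$W))
  # absent connections stay absent
  expect_true(all(j1$W[C$W == 0] == 0))
  # CLT bound on the per-entry mean over many trials
  n_rep <- 10000
  nz <- which(C$W != 0)
  probe <- nz[c(1, 5, 9)]
  acc <- matrix(0, n_rep, length(probe))
  set.seed(1)
  for (k in seq_len(n_rep)) {
    acc[k, ] <- jitter_matrix(C, scale = 0.2)$W[probe]
  }
  bound <- 3 * 0.2 / sqrt(n_rep)
  expect_true(all(abs(colMeans(acc) - C$W[probe]) < bound))
})

test_that("motif checks hold for the fixture and fail for violations", {
  expect_true(check_motifs(default_circuit()))
  W <- default_circuit()$W
  W["SST_sup", "SST_sup"] <- -0.01
  expect_error(check_motifs(connectivity_matrix(W)), "SST self")
  W2 <- default_circuit()$W
  W2["PV_sup", "PV_sup"] <- W2["PV_deep", "PV_deep"] * 1.1
  expect_error(check_motifs(connectivity_matrix(W2)), "deep PV")
})

test_that("connectivity CSV round trip is bit-stable at full precision", {
  C <- scale_by_G(jitter_matrix(default_circuit(), 0.05, seed = 9), pi)
  path <- tempfile(fileext = ".csv")
  write_connectivity(C, path)
  C2 <- read_connectivity(path)
  expect_identical(C$W, C2$W)
})

test_that("raw tables survive a CSV round trip through read_raw_tables", {
  raw <- attr(generate_matrix(motif_spec()), "raw")
  d <- tempfile(); dir.create(d)
  wr <- function(m, f) {
    df <- data.frame(type = rownames(m),
                     apply(m, 2, function(x) sprintf("%.17g", x)),
                     check.names = FALSE)
    write.csv(df, file.path(d, f), row.names = FALSE, quote = FALSE)
  }
  wr(raw$probability, "prob.csv"); wr(raw$amplitude, "amp.csv")
  write.csv(data.frame(type = names(raw$prevalence),
                       prevalence = sprintf("%.17g", raw$prevalence)),
            file.path(d, "prev.csv"), row.names = FALSE, quote = FALSE)
  raw2 <- read_raw_tables(file.path(d, "prob.csv"), file.path(d, "amp.csv"),
                          file.path(d, "prev.csv"))
  expect_equal(build_corrected_matrix(raw2)$W,
               build_corrected_matrix(raw)$W, tolerance = 1e-15)
})
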
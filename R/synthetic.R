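# ---------------------------------------------------------------------------
# Synthetic connectivity. Generates surrogate matrices carrying the motif
# structure of the empirical microcircuit -- strongest-in-matrix PV
# self-inhibition (deep > superficial), absent SST self-inhibition, mutual
# SST<->PV and SST<->VIP inhibition per layer, strong descending
# PYR_sup -> PYR_deep excitation, translaminar SST projections, layer-
# restricted VIP output -- so every analysis stage can be exercised without
# the empirical tables.
# ---------------------------------------------------------------------------

#' Motif specification for synthetic connectivity
#'
#' All weights are raw (un-G-scaled) effective weights in the corrected-
#' matrix convention (row = target, column = source); inhibitory entries
#' are negative. The default magnitudes place the circuit in the
#' oscillatory, switch-capable regime for global coupling G roughly in
#' \[100, 500\] and are committed once as the package fixture; they are a
#' calibration, not empirical data.
#'
#' @param pv_self Named vector \code{c(sup=, deep=)} of recurrent PV
#'   weights; must be the strongest magnitudes of the matrix, deep
#'   strictly stronger than superficial.
#' @param sst_to_pv,pv_to_sst,sst_to_vip,vip_to_sst Within-layer mutual
#'   inhibition weights (applied in both layers).
#' @param vip_to_pv Weak within-layer VIP inhibition of PV cells.
#' @param pyr_to_pv,pyr_to_sst,pyr_to_vip Within-layer excitatory drive
#'   onto interneurons.
#' @param pv_to_pyr,sst_to_pyr Within-layer inhibition of PYR cells.
#' @param vip_to_pyr_sup VIP inhibition of superficial PYR cells (the
#'   deep-layer analogue is absent).
#' @param pyr_self Recurrent PYR excitation within each layer.
#' @param pyr_sup_to_pyr_deep Descending excitatory weight.
#' @param sst_translaminar Named vector \code{c(deep_to_sup=,
#'   sup_to_deep=)} of translaminar SST weights applied to each
#'   opposite-layer target class (PYR, PV, VIP); the default carries only
#'   the deep-to-superficial projection, the ascending direction can be
#'   enabled by setting \code{sup_to_deep} nonzero.
#' @param background_scale Scale of the random weights filling the
#'   remaining permitted entries.
#' @param background_sparsity Fraction of background entries set to zero.
#' @param seed Integer seed for the background draw (motif entries are
#'   deterministic).
#' @return Object of class \code{motif_spec}.
#' @export
motif_spec <- function(pv_self = c(sup = -0.066, deep = -0.078),
                       sst_to_pv = -0.018,
                       pv_to_sst = -0.009,
                       sst_to_vip = -0.012,
                       vip_to_sst = -0.007,
                       vip_to_pv = -0.002,
                       pyr_to_pv = 0.065,
                       pyr_to_sst = 0.025,
                       pyr_to_vip = 0.003,
                       pv_to_pyr = -0.062,
                       sst_to_pyr = -0.017,
                       vip_to_pyr_sup = -0.0004,
                       pyr_self = 0.040,
                       pyr_sup_to_pyr_deep = 0.006,
                       sst_translaminar = c(deep_to_sup = -0.004,
                                            sup_to_deep = 0),
                       background_scale = 0.001,
                       background_sparsity = 0.5,
                       seed = 1L) {
  spec <- structure(as.list(environment()), class = "motif_spec")
  validate_motif_spec(spec)
  spec
}

validate_motif_spec <- function(spec) {
  pv <- spec$pv_self
  if (!all(c("sup", "deep") %in% names(pv)))
    stop("pv_self needs named entries 'sup' and 'deep'", call. = FALSE)
  if (any(pv >= 0))
    stop("PV self-connections must be negative", call. = FALSE)
  if (!(abs(pv["deep"]) > abs(pv["sup"])))
    stop("deep PV self-inhibition must exceed superficial", call. = FALSE)
  inh <- c(spec$sst_to_pv, spec$pv_to_sst, spec$sst_to_vip,
           spec$vip_to_sst, spec$vip_to_pv, spec$pv_to_pyr,
           spec$sst_to_pyr, spec$vip_to_pyr_sup, spec$sst_translaminar)
  if (any(inh > 0))
    stop("inhibitory motif weights must be <= 0", call. = FALSE)
  exc <- c(spec$pyr_to_pv, spec$pyr_to_sst, spec$pyr_to_vip,
           spec$pyr_self, spec$pyr_sup_to_pyr_deep)
  if (any(exc < 0))
    stop("excitatory motif weights must be >= 0", call. = FALSE)
  other <- max(abs(c(inh, exc)), spec$background_scale * 4)
  if (other >= abs(pv["sup"]))
    stop("PV self-connections must be the strongest magnitudes of the ",
         "matrix; reduce the other motif weights or background_scale",
         call. = FALSE)
  invisible(TRUE)
}

# entries that are never present: SST self-connections and cross-layer VIP
# output (each VIP type only innervates its functional layer)
structural_zero_mask <- function() {
  Z <- matrix(FALSE, 8, 8, dimnames = list(POPULATIONS, POPULATIONS))
  Z["SST_sup", "SST_sup"] <- TRUE
  Z["SST_deep", "SST_deep"] <- TRUE
  deep <- populations()$layer == "deep"
  Z[deep, "VIP_sup"] <- TRUE
  Z[!deep, "VIP_deep"] <- TRUE
  # no recurrent SST-SST coupling at all (within or across layers)
  Z["SST_sup", "SST_deep"] <- TRUE
  Z["SST_deep", "SST_sup"] <- TRUE
  Z
}

#' Generate a synthetic connectivity matrix from a motif specification
#'
#' Motif entries are placed deterministically; every remaining permitted
#' entry is filled with a sparse, sign-correct random background weight
#' drawn under \code{spec$seed}. The result satisfies all structural
#' invariants of the empirical matrix (verified with [check_motifs()]
#' before it is returned). A decomposed [raw_connectivity()] object whose
#' [build_corrected_matrix()] output reproduces the matrix exactly is
#' attached as attribute \code{"raw"}.
#'
#' @param spec A [motif_spec()].
#' @return A [connectivity_matrix()] with \code{G = 1}.
#' @export
generate_matrix <- function(spec = motif_spec()) {
  stopifnot(inherits(spec, "motif_spec"))
  validate_motif_spec(spec)
  W <- matrix(0, 8, 8, dimnames = list(POPULATIONS, POPULATIONS))
  lay <- list(sup = c("PYR_sup", "PV_sup", "SST_sup", "VIP_sup"),
              deep = c("PYR_deep", "PV_deep", "SST_deep", "VIP_deep"))
  fixed <- matrix(FALSE, 8, 8, dimnames = dimnames(W))
  set_w <- function(target, source, w) {
    W[target, source] <<- w
    fixed[target, source] <<- TRUE
  }
  for (l in c("sup", "deep")) {
    p <- function(cls) paste0(cls, "_", l)
    set_w(p("PV"), p("PV"), spec$pv_self[[l]])
    set_w(p("PV"), p("SST"), spec$sst_to_pv)
    set_w(p("SST"), p("PV"), spec$pv_to_sst)
    set_w(p("VIP"), p("SST"), spec$sst_to_vip)
    set_w(p("SST"), p("VIP"), spec$vip_to_sst)
    set_w(p("PV"), p("VIP"), spec$vip_to_pv)
    set_w(p("PV"), p("PYR"), spec$pyr_to_pv)
    set_w(p("SST"), p("PYR"), spec$pyr_to_sst)
    set_w(p("VIP"), p("PYR"), spec$pyr_to_vip)
    set_w(p("PYR"), p("PV"), spec$pv_to_pyr)
    set_w(p("PYR"), p("SST"), spec$sst_to_pyr)
    set_w(p("PYR"), p("PYR"), spec$pyr_self)
  }
  set_w("PYR_sup", "VIP_sup", spec$vip_to_pyr_sup)
  set_w("PYR_deep", "PYR_sup", spec$pyr_sup_to_pyr_deep)
  for (tgt in c("PYR_sup", "PV_sup", "VIP_sup"))
    set_w(tgt, "SST_deep", spec$sst_translaminar[["deep_to_sup"]])
  for (tgt in c("PYR_deep", "PV_deep", "VIP_deep"))
    set_w(tgt, "SST_sup", spec$sst_translaminar[["sup_to_deep"]])

  # sparse random background on the remaining permitted entries
  zeros <- structural_zero_mask()
  open <- !fixed & !zeros
  set.seed(spec$seed)
  n_open <- sum(open)
  mags <- abs(rnorm(n_open)) * spec$background_scale
  mags[stats::runif(n_open) < spec$background_sparsity] <- 0
  sgn <- ifelse(rep(EXCITATORY, each = 8)[open], 1, -1)
  W[open] <- mags * sgn
  # keep the SST translaminar structural zeros if a direction is disabled
  W[zeros] <- 0

  C <- connectivity_matrix(W, G = 1, manipulations = list())
  check_motifs(C)
  attr(C, "raw") <- decompose_raw(W)
  C
}

# split fractions of each population over its morphological source types
morph_fractions <- function() {
  c(pyramidal_sup = 1, basket_sup = 0.7, chandelier = 0.3,
    martinotti_sup = 1, bitufted = 1, bipolar = 1,
    pyramidal_deep = 1, basket_deep = 0.6, shrub = 0.2,
    horizontally_elongated = 0.2, martinotti_deep = 1)
}

# plausible relative prevalence fractions for the interneuron morphologies
# (synthetic placeholders, not empirical values)
synthetic_prevalence <- function() {
  c(basket_sup = 0.50, chandelier = 0.20, martinotti_sup = 0.60,
    bitufted = 0.40, bipolar = 0.40, basket_deep = 0.50, shrub = 0.25,
    horizontally_elongated = 0.25, martinotti_deep = 0.60)
}

# factor an 8x8 corrected matrix into morphological probability/amplitude/
# prevalence tables that rebuild to it exactly
decompose_raw <- function(W, probability = 0.5) {
  morph <- morphological_types()
  frac <- morph_fractions()[morph$type]
  prev <- synthetic_prevalence()
  inh <- morph$sign == "inhibitory"
  n <- nrow(morph)
  E <- matrix(0, n, n, dimnames = list(morph$type, morph$type))
  for (ms in seq_len(n)) {
    for (mt in seq_len(n)) {
      w <- W[morph$population[mt], morph$population[ms]]
      E[ms, mt] <- w * frac[ms] * frac[mt]
    }
  }
  amp <- E / probability
  amp[inh, ] <- amp[inh, , drop = FALSE] / (prev[morph$type[inh]] * 0.2)
  prob <- matrix(probability, n, n, dimnames = dimnames(E))
  raw_connectivity(probability = prob, amplitude = amp,
                   prevalence = prev, inhibitory_scale = 0.2)
}

#' The bundled synthetic microcircuit
#'
#' Convenience constructor: the default [motif_spec()] matrix scaled by a
#' global coupling G. This is the fixture circuit used throughout the
#' package's examples and experiments when no empirical tables are
#' supplied.
#'
#' @param G Global coupling (default 1).
#' @param seed Seed for the background weights (default 1).
#' @param ... Passed to [motif_spec()].
#' @return A [connectivity_matrix()].
#' @export
default_circuit <- function(G = 1, seed = 1L, ...) {
  scale_by_G(generate_matrix(motif_spec(seed = seed, ...)), G)
}
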
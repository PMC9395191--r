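#' @useDynLib microswitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm median setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Morphological cell types of the source dataset and their mapping onto the
# eight model populations. PV cells comprise basket + chandelier cells in
# L2/3 and basket + shrub + horizontally elongated cells in L5; SST cells are
# Martinotti cells in both layers; the two VIP morphologies are split by
# their target layer (bitufted -> superficial targets, bipolar -> deep
# targets) even though both somata sit in L2/3.
# ---------------------------------------------------------------------------

#' Morphological cell types and their population assignment
#'
#' Raw pairwise connectivity tables are indexed by morphologically defined
#' cell types. This table maps each morphological type to the model
#' population it is merged into by [build_corrected_matrix()].
#'
#' @return Data frame with columns \code{type}, \code{population},
#'   \code{sign}.
#' @export
morphological_types <- function() {
  data.frame(
    type = c(
      "pyramidal_sup", "basket_sup", "chandelier", "martinotti_sup",
      "bitufted", "bipolar",
      "pyramidal_deep", "basket_deep", "shrub", "horizontally_elongated",
      "martinotti_deep"
    ),
    population = c(
      "PYR_sup", "PV_sup", "PV_sup", "SST_sup",
      "VIP_sup", "VIP_deep",
      "PYR_deep", "PV_deep", "PV_deep", "PV_deep",
      "SST_deep"
    ),
    sign = c(
      "excitatory", "inhibitory", "inhibitory", "inhibitory",
      "inhibitory", "inhibitory",
      "excitatory", "inhibitory", "inhibitory", "inhibitory",
      "inhibitory"
    ),
    stringsAsFactors = FALSE
  )
}

#' Bundle raw pairwise connectivity data
#'
#' Holds the ingredients of the effective connectivity matrix: pairwise
#' connection probabilities, mean PSP amplitudes, the relative prevalence of
#' each interneuron type, and the global inhibitory down-scaling factor that
#' accounts for pyramidal cells outnumbering interneurons roughly five to
#' one.
#'
#' Both matrices are oriented source (rows) x target (columns), the natural
#' orientation of pairwise recording tables. [build_corrected_matrix()]
#' transposes to the model's target-row convention.
#'
#' @param probability Numeric matrix of connection probabilities in
#'   \[0, 1\], rows = source morphological types, columns = target types;
#'   dimnames required.
#' @param amplitude Numeric matrix of mean PSP amplitudes (mV), same
#'   dimnames. Inhibitory-source rows may be given as magnitudes or as
#'   negative values; they are coerced to non-positive. Excitatory rows must
#'   be non-negative.
#' @param prevalence Named numeric vector of relative prevalence fractions,
#'   one per interneuron morphological type (non-negative).
#' @param inhibitory_scale Scalar multiplying every inhibitory weight
#'   (default 0.2, i.e. one interneuron per five pyramidal cells).
#' @return An object of class \code{raw_connectivity}.
#' @export
raw_connectivity <- function(probability, amplitude, prevalence,
                             inhibitory_scale = 0.2) {
  stopifnot(is.matrix(probability), is.matrix(amplitude))
  if (is.null(dimnames(probability)) || is.null(dimnames(amplitude)))
    stop("probability and amplitude matrices need row and column names",
         call. = FALSE)
  if (any(probability < 0 | probability > 1))
    stop("connection probabilities must lie in [0, 1]", call. = FALSE)
  if (length(inhibitory_scale) != 1L || inhibitory_scale < 0)
    stop("inhibitory_scale must be a single non-negative number",
         call. = FALSE)
  if (any(prevalence < 0))
    stop("prevalence fractions must be non-negative", call. = FALSE)
  structure(
    list(probability = probability, amplitude = amplitude,
         prevalence = prevalence, inhibitory_scale = inhibitory_scale),
    class = "raw_connectivity"
  )
}

#' Construct a connectivity-matrix object
#'
#' The effective connectivity matrix is oriented row = target, column =
#' source, so that circuit input is \code{W \%*\% r} and silencing a cell
#' type's outputs amounts to zeroing its column.
#'
#' @param W 8x8 numeric matrix in canonical population order (see
#'   [populations()]); dimnames are set if absent.
#' @param G Global coupling scalar already applied to \code{W} (default 1).
#' @param manipulations List recording the lesions/jitters applied so far.
#' @param check If \code{TRUE} (default) verify the sign pattern: columns of
#'   excitatory populations non-negative, inhibitory columns non-positive.
#'   Jittered matrices may violate the pattern and are built with
#'   \code{check = FALSE}.
#' @return Object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(W, G = 1, manipulations = list(),
                                check = TRUE) {
  stopifnot(is.matrix(W), nrow(W) == 8L, ncol(W) == 8L, all(is.finite(W)))
  dimnames(W) <- list(target = POPULATIONS, source = POPULATIONS)
  if (check) {
    exc_ok <- all(W[, EXCITATORY] >= 0)
    inh_ok <- all(W[, !EXCITATORY] <= 0)
    if (!exc_ok || !inh_ok)
      stop("sign pattern violated: excitatory columns must be >= 0, ",
           "inhibitory columns <= 0 (use check = FALSE for jittered ",
           "matrices)", call. = FALSE)
  }
  structure(list(W = W, G = G, manipulations = manipulations),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix>  8 populations, G =", format(x$G), "\n")
  if (length(x$manipulations)) {
    cat("manipulations:",
        paste(vapply(x$manipulations, function(m) m$kind, ""),
              collapse = ", "), "\n")
  }
  print(round(x$W, 4))
  invisible(x)
}

#' Build the corrected 8x8 effective connectivity matrix
#'
#' Applies the correction pipeline to raw pairwise data: (1) element-wise
#' product of PSP amplitude and connection probability; (2) sign assignment
#' by source class; (3) each interneuron source row weighted by its relative
#' prevalence; (4) all inhibitory rows scaled by \code{inhibitory_scale};
#' (5) morphological types merged onto the eight populations by summing
#' weights; (6) transposition to the target-row convention.
#'
#' @param raw A [raw_connectivity()] object covering all morphological types
#'   in [morphological_types()].
#' @return A [connectivity_matrix()] with \code{G = 1} and an empty
#'   manipulation log.
#' @export
build_corrected_matrix <- function(raw) {
  stopifnot(inherits(raw, "raw_connectivity"))
  morph <- morphological_types()
  for (tab in c("probability", "amplitude")) {
    m <- raw[[tab]]
    missing_r <- setdiff(morph$type, rownames(m))
    missing_c <- setdiff(morph$type, colnames(m))
    if (length(missing_r) || length(missing_c))
      stop(sprintf("%s table is missing cell type(s): %s", tab,
                   paste(unique(c(missing_r, missing_c)), collapse = ", ")),
           call. = FALSE)
  }
  prob <- raw$probability[morph$type, morph$type, drop = FALSE]
  amp <- raw$amplitude[morph$type, morph$type, drop = FALSE]

  inh <- morph$sign == "inhibitory"
  # sign assignment by source class (rows)
  if (any(amp[!inh, , drop = FALSE] < 0))
    stop("excitatory source rows of the amplitude table must be >= 0",
         call. = FALSE)
  amp[inh, ] <- -abs(amp[inh, , drop = FALSE])

  inh_types <- morph$type[inh]
  missing_prev <- setdiff(inh_types, names(raw$prevalence))
  if (length(missing_prev))
    stop(sprintf("prevalence missing for interneuron type(s): %s",
                 paste(missing_prev, collapse = ", ")), call. = FALSE)

  E <- amp * prob                               # source x target
  E[inh, ] <- E[inh, , drop = FALSE] * raw$prevalence[inh_types]
  E[inh, ] <- E[inh, , drop = FALSE] * raw$inhibitory_scale

  # merge morphological types onto populations by summing, both axes
  M <- outer(POPULATIONS, morph$population, "==") * 1   # 8 x n_types
  W8 <- M %*% E %*% t(M)                                # source x target
  connectivity_matrix(t(W8), G = 1, manipulations = list())
}

#' Scale the connectivity matrix by the global coupling parameter G
#'
#' G multiplies every weight and loosely stands for the (unknown) absolute
#' population size behind each pairwise weight. Repeated scaling
#' accumulates multiplicatively.
#'
#' @param C A [connectivity_matrix()].
#' @param G Non-negative scalar.
#' @return The scaled [connectivity_matrix()] with the applied coupling
#'   recorded in its \code{G} field.
#' @export
scale_by_G <- function(C, G) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (length(G) != 1L || !is.finite(G) || G < 0)
    stop("G must be a single non-negative number", call. = FALSE)
  C$W <- C$W * G
  C$G <- C$G * G
  C
}

#' Specify a connectivity manipulation
#'
#' @param kind One of \code{"silence_cell"} (zero a source population's
#'   output column), \code{"remove_connection"} (zero one entry),
#'   \code{"set_connection"} (overwrite one entry),
#'   \code{"swap_self_connections"} (exchange the PV and SST self-weights
#'   within each layer) or \code{"equalize_pv_self"} (set the superficial
#'   PV self-weight equal to the deep one).
#' @param source,target Population labels where applicable.
#' @param value Replacement weight for \code{"set_connection"}.
#' @return Object of class \code{lesion_spec}.
#' @export
lesion_spec <- function(kind = c("silence_cell", "remove_connection",
                                 "set_connection", "swap_self_connections",
                                 "equalize_pv_self"),
                        source = NULL, target = NULL, value = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("silence_cell", "remove_connection", "set_connection"))
    pop_index(source)
  if (kind %in% c("remove_connection", "set_connection"))
    pop_index(target)
  if (kind == "set_connection" &&
      (is.null(value) || length(value) != 1L || !is.finite(value)))
    stop("set_connection needs a single finite replacement value",
         call. = FALSE)
  structure(list(kind = kind, source = source, target = target,
                 value = value),
            class = "lesion_spec")
}

#' Apply a lesion to the connectivity matrix
#'
#' Silencing a cell type zeroes its output column (all its projections),
#' mimicking optogenetic inactivation; the other kinds edit single entries
#' or exchange the recurrent self-weights of PV and SST cells.
#'
#' @param C A [connectivity_matrix()].
#' @param spec A [lesion_spec()].
#' @return The manipulated matrix with the lesion appended to its log.
#' @export
apply_lesion <- function(C, spec) {
  stopifnot(inherits(C, "connectivity_matrix"), inherits(spec, "lesion_spec"))
  W <- C$W
  switch(spec$kind,
    silence_cell = {
      W[, pop_index(spec$source)] <- 0
    },
    remove_connection = {
      W[pop_index(spec$target), pop_index(spec$source)] <- 0
    },
    set_connection = {
      W[pop_index(spec$target), pop_index(spec$source)] <- spec$value
    },
    swap_self_connections = {
      for (lay in c("sup", "deep")) {
        pv <- pop_index(paste0("PV_", lay))
        sst <- pop_index(paste0("SST_", lay))
        tmp <- W[pv, pv]
        W[pv, pv] <- W[sst, sst]
        W[sst, sst] <- tmp
      }
    },
    equalize_pv_self = {
      W[pop_index("PV_sup"), pop_index("PV_sup")] <-
        W[pop_index("PV_deep"), pop_index("PV_deep")]
    }
  )
  C$W <- W
  C$manipulations <- c(C$manipulations, list(unclass(spec)))
  C
}

#' Jitter the nonzero connectivity weights
#'
#' Adds independent zero-mean Gaussian perturbations of standard deviation
#' \code{scale} to every nonzero weight, emulating the pair-to-pair
#' variability of measured connection strengths. Absent connections stay
#' absent. Jittered weights may cross zero, so the sign-pattern check is
#' disabled for the result.
#'
#' @param C A [connectivity_matrix()].
#' @param scale Standard deviation of the perturbation (default 0.2).
#' @param seed Optional integer seed for reproducibility.
#' @return The jittered [connectivity_matrix()] (unchecked sign pattern).
#' @export
jitter_matrix <- function(C, scale = 0.2, seed = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (length(scale) != 1L || scale < 0)
    stop("scale must be a single non-negative number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  W <- C$W
  nz <- W != 0
  if (scale > 0 && any(nz))
    W[nz] <- W[nz] + rnorm(sum(nz), mean = 0, sd = scale)
  connectivity_matrix(W, G = C$G,
                      manipulations = c(C$manipulations,
                                        list(list(kind = "jitter",
                                                  scale = scale,
                                                  seed = seed))),
                      check = FALSE)
}

#' Assert the structural motifs of an unmanipulated matrix
#'
#' Checks the signature motifs of the empirical circuit: recurrent SST
#' connections absent in both layers; the recurrent PV weights the strongest
#' absolute entries of the whole matrix, with the deep one stronger than the
#' superficial one.
#'
#' @param C A [connectivity_matrix()].
#' @return Invisibly \code{TRUE}; otherwise an error describing the failed
#'   motif.
#' @export
check_motifs <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  W <- C$W
  i_pv_s <- pop_index("PV_sup"); i_pv_d <- pop_index("PV_deep")
  i_sst_s <- pop_index("SST_sup"); i_sst_d <- pop_index("SST_deep")
  if (W[i_sst_s, i_sst_s] != 0 || W[i_sst_d, i_sst_d] != 0)
    stop("SST self-connections must be exactly zero", call. = FALSE)
  pv_self <- c(abs(W[i_pv_s, i_pv_s]), abs(W[i_pv_d, i_pv_d]))
  if (max(abs(W)) > max(pv_self))
    stop("a PV self-connection must be the largest absolute weight",
         call. = FALSE)
  if (!(pv_self[2] > pv_self[1]))
    stop("deep PV self-inhibition must exceed superficial", call. = FALSE)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# CSV round trip (17 significant digits so doubles survive bit-exactly)
# ---------------------------------------------------------------------------

#' Write / read a connectivity matrix as labeled CSV
#'
#' Weights are serialised with 17 significant digits so that a write/read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param C A [connectivity_matrix()].
#' @param path File path.
#' @return \code{write_connectivity} returns \code{path} invisibly;
#'   \code{read_connectivity} returns a [connectivity_matrix()] (with
#'   \code{check = FALSE}: a stored matrix may carry manipulations).
#' @export
write_connectivity <- function(C, path) {
  stopifnot(inherits(C, "connectivity_matrix"))
  df <- data.frame(target = rownames(C$W),
                   apply(C$W, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(W) <- "double"
  rownames(W) <- df[[1]]
  W <- W[POPULATIONS, POPULATIONS]
  connectivity_matrix(W, check = FALSE)
}

#' Read raw connectivity tables from CSV files
#'
#' Expects labeled square CSVs for probability and amplitude (first column =
#' source type, remaining columns = target types) and a two-column CSV
#' (\code{type}, \code{prevalence}) for the prevalence fractions.
#'
#' @param probability_csv,amplitude_csv,prevalence_csv File paths.
#' @param inhibitory_scale Passed to [raw_connectivity()].
#' @return A [raw_connectivity()] object.
#' @export
read_raw_tables <- function(probability_csv, amplitude_csv, prevalence_csv,
                            inhibitory_scale = 0.2) {
  read_sq <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1]]
    m
  }
  prev_df <- read.csv(prevalence_csv, stringsAsFactors = FALSE)
  raw_connectivity(read_sq(probability_csv), read_sq(amplitude_csv),
                   setNames(prev_df$prevalence, prev_df$type),
                   inhibitory_scale = inhibitory_scale)
}
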
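#' Population metadata for the two-layer microcircuit
#'
#' The model comprises eight neuronal populations: pyramidal cells (PYR) and
#' three inhibitory interneuron classes (PV, SST, VIP) in each of a
#' superficial (L2/3) and a deep (L5) layer. The fixed population order used
#' by every matrix, rate vector and result table in the package is
#' \code{PYR_sup, PV_sup, SST_sup, VIP_sup, PYR_deep, PV_deep, SST_deep,
#' VIP_deep}.
#'
#' Note that the deep-targeting VIP population (\code{VIP_deep}, bipolar
#' cells) has its soma in the superficial layer but is functionally assigned
#' to the deep layer because its axons innervate L5.
#'
#' @return A data frame with one row per population and columns
#'   \code{label}, \code{layer} (\code{"superficial"}/\code{"deep"}),
#'   \code{cell_class} (\code{"PYR"}, \code{"PV"}, \code{"SST"},
#'   \code{"VIP"}) and \code{sign} (\code{"excitatory"}/\code{"inhibitory"}).
#' @examples
#' populations()
#' @export
populations <- function() {
  data.frame(
    label = POPULATIONS,
    layer = rep(c("superficial", "deep"), each = 4L),
    cell_class = rep(c("PYR", "PV", "SST", "VIP"), 2L),
    sign = rep(c("excitatory", "inhibitory", "inhibitory", "inhibitory"), 2L),
    stringsAsFactors = FALSE
  )
}

#' Canonical population labels, in matrix order
#' @format Character vector of length 8.
#' @export
POPULATIONS <- c(
  "PYR_sup", "PV_sup", "SST_sup", "VIP_sup",
  "PYR_deep", "PV_deep", "SST_deep", "VIP_deep"
)

#' Logical mask of excitatory populations (PYR), in matrix order
#' @format Logical vector of length 8.
#' @export
EXCITATORY <- POPULATIONS %in% c("PYR_sup", "PYR_deep")

# resolve a population label to its index, with a helpful error
pop_index <- function(label) {
  i <- match(label, POPULATIONS)
  if (anyNA(i)) {
    stop(sprintf(
      "unknown population '%s'; valid labels are: %s",
      paste(label[is.na(i)], collapse = ", "),
      paste(POPULATIONS, collapse = ", ")
    ), call. = FALSE)
  }
  i
}

# populations of one cell class (e.g. "PV" -> PV_sup, PV_deep)
class_pops <- function(cell_class) {
  p <- populations()
  p$label[p$cell_class %in% cell_class]
}

# the layer's PYR population label
layer_pyr <- function(layer) {
  layer <- match.arg(layer, c("superficial", "deep"))
  if (layer == "superficial") "PYR_sup" else "PYR_deep"
}
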
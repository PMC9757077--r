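#' Dissociation constant of a binding fit
#'
#' Accessor for the fitted dissociation constant: the apparent \eqn{K_D}
#' (nM) of a [HillFit] or the per-lattice-site \eqn{K_D} (\eqn{\mu}M) of an
#' [MvHFit].
#'
#' @param object a fit object.
#' @return numeric scalar.
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))

#' Standard error of the fitted dissociation constant
#'
#' @param object a fit object.
#' @return numeric scalar (may be `NA` when residuals are numerically zero).
#' @export
setGeneric("kdSe", function(object) standardGeneric("kdSe"))

#' Hill coefficient of a Hill fit
#'
#' @param object a [HillFit].
#' @return numeric scalar.
#' @export
setGeneric("hillCoefficient", function(object) standardGeneric("hillCoefficient"))

#' Residual sum of squares of a fit
#'
#' @param object a fit object.
#' @return numeric scalar.
#' @export
setGeneric("residualSS", function(object) standardGeneric("residualSS"))

#' Fitted saturation amplitude of an MST isotherm fit
#'
#' @param object an [MvHFit].
#' @return numeric scalar, \eqn{\Delta F_{norm}} at lattice saturation.
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))

#' Binding-site size (bp) of a lattice-binding object
#'
#' @param object an [MSTDataset] or [MvHFit].
#' @return integer scalar.
#' @export
setGeneric("siteSize", function(object) standardGeneric("siteSize"))

#' Mixture components of an RMS distribution fit
#'
#' @param object an [RMSMixtureFit].
#' @return `data.frame` with columns `mean`, `sd`, `weight`, sorted by
#'   ascending mean.
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' Fraction of bound DNA tethers estimated from a mixture fit
#'
#' @param object an [RMSMixtureFit].
#' @return numeric scalar in \[0, 1\], or `NA` when no role assignment has
#'   been made.
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' Location and scale of a fitted logistic null
#'
#' @param object a [LogisticNull].
#' @return numeric scalar.
#' @name logistic-null-accessors
NULL

#' @rdname logistic-null-accessors
#' @export
setGeneric("nullLocation", function(object) standardGeneric("nullLocation"))

#' @rdname logistic-null-accessors
#' @export
setGeneric("nullScale", function(object) standardGeneric("nullScale"))

#' Per-gene results table of a differential-expression call
#'
#' @param object a [DEGResult].
#' @return `data.frame` with columns `gene`, `diff`, `transformed`, `p`,
#'   `q`, `isDeg`.
#' @export
setGeneric("degTable", function(object) standardGeneric("degTable"))

#' Region counts of a three-set Venn partition
#'
#' @param object a [VennPartition].
#' @return named numeric vector of the 7 disjoint region counts
#'   (`onlyA`, `onlyB`, `onlyC`, `AB`, `AC`, `BC`, `ABC`).
#' @export
setGeneric("vennRegions", function(object) standardGeneric("vennRegions"))

#' Per-column information content of an alignment profile (bits)
#'
#' @param object an [AlignmentProfile].
#' @return numeric vector, one value per alignment column, in
#'   \[0, log2(20)\].
#' @export
setGeneric("informationContent", function(object) standardGeneric("informationContent"))
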
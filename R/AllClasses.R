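#' @include AllGenerics.R
NULL

#' NAPbind: binding biophysics and transcriptomics of DNA-bridging NAPs
#'
#' Quantitative analysis of the DNA-binding activity of bacterial
#' nucleoid-associated proteins (NAPs) of the Rok/H-NS functional family:
#' tethered particle motion (TPM) occupancy and Hill fitting, DNA-bridging
#' pull-down recovery, microscale thermophoresis (MST) McGhee-von Hippel
#' isotherm fitting, an empirical logistic-null differential-expression
#' caller, sequence utilities, and seeded synthetic-data generators for
#' every stage.
#'
#' @name NAPbind-package
#' @aliases NAPbind
#' @import methods
#' @importFrom stats dnorm rnorm rbinom rpois rnbinom rlogis runif plogis
#'   qlogis optim optimize quantile sd median setNames smooth.spline predict
#'   uniroot coef vcov residuals
#' @importFrom utils read.delim write.table packageVersion
"_PACKAGE"

## ---- validity helpers -----------------------------------------------------

.checkNumericSlot <- function(x, what, positive = FALSE, finite = TRUE) {
    if (!is.numeric(x))
        return(sprintf("'%s' must be numeric", what))
    if (finite && any(!is.finite(x)))
        return(sprintf("'%s' must be finite", what))
    if (positive && any(x <= 0))
        return(sprintf("'%s' must be > 0", what))
    NULL
}

## ---- OccupancyCurve -------------------------------------------------------

#' Occupancy versus protein concentration
#'
#' One point per titration condition: the protein concentration (nM), the
#' fraction \eqn{\theta} of DNA tethers carrying bound protein, a standard
#' deviation for \eqn{\theta}, and the number of beads behind the estimate.
#' Concentrations are strictly increasing and \eqn{\theta \in [0, 1]}.
#'
#' @slot concentration numeric, protein concentrations (nM), strictly
#'   increasing.
#' @slot theta numeric, occupancy per concentration.
#' @slot thetaSd numeric, standard deviation of each occupancy (`NA`
#'   allowed).
#' @slot nBeads integer, beads contributing to each point.
#' @seealso [buildOccupancyCurve()], [fitHill()]
#' @export
setClass("OccupancyCurve",
    representation(concentration = "numeric", theta = "numeric",
                   thetaSd = "numeric", nBeads = "integer"),
    prototype(concentration = numeric(), theta = numeric(),
              thetaSd = numeric(), nBeads = integer()))

setValidity("OccupancyCurve", function(object) {
    n <- length(object@concentration)
    if (length(object@theta) != n || length(object@thetaSd) != n ||
        length(object@nBeads) != n)
        return("all slots must have equal length")
    if (n == 0L) return(TRUE)
    if (any(object@concentration < 0))
        return("concentrations must be >= 0")
    if (is.unsorted(object@concentration, strictly = TRUE))
        return("concentrations must be strictly increasing")
    if (any(object@theta < -1e-9 | object@theta > 1 + 1e-9))
        return("theta must lie in [0, 1]")
    TRUE
})

#' Construct an occupancy curve
#'
#' @param concentration numeric, protein concentrations (nM).
#' @param theta numeric, occupancy at each concentration.
#' @param thetaSd numeric, standard deviation of each occupancy; recycled
#'   `NA` by default.
#' @param nBeads integer, beads per condition; `NA` by default.
#' @return an [OccupancyCurve].
#' @examples
#' OccupancyCurve(c(2, 4, 6), c(0.01, 0.1, 0.5))
#' @export
OccupancyCurve <- function(concentration, theta,
                           thetaSd = rep(NA_real_, length(concentration)),
                           nBeads = rep(NA_integer_, length(concentration))) {
    o <- order(concentration)
    new("OccupancyCurve", concentration = as.numeric(concentration)[o],
        theta = as.numeric(theta)[o], thetaSd = as.numeric(thetaSd)[o],
        nBeads = as.integer(nBeads)[o])
}

#' @describeIn OccupancyCurve-class points as a data.frame with columns
#'   `concentration_nM`, `theta`, `theta_sd`, `n_beads`.
#' @param x,row.names,optional,... see [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "OccupancyCurve",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(concentration_nM = x@concentration, theta = x@theta,
                   theta_sd = x@thetaSd, n_beads = x@nBeads,
                   row.names = row.names)
    })

setMethod("length", "OccupancyCurve", function(x) length(x@concentration))

setMethod("show", "OccupancyCurve", function(object) {
    cat(sprintf("OccupancyCurve with %d points (%.3g-%.3g nM)\n",
                length(object),
                if (length(object)) min(object@concentration) else NA,
                if (length(object)) max(object@concentration) else NA))
    if (length(object)) print(as.data.frame(object), digits = 4)
})

## ---- HillFit --------------------------------------------------------------

#' Hill binding-model fit
#'
#' Result of least-squares fitting of the Hill isotherm
#' \eqn{\theta(c) = 1 / ((K_D/c)^n + 1)} to an occupancy curve:
#' the apparent binding affinity \eqn{K_D} (nM), the Hill coefficient
#' \eqn{n}, their standard errors and the residual sum of squares.
#'
#' @slot kd numeric, apparent \eqn{K_D} (nM), > 0.
#' @slot n numeric, Hill coefficient, > 0.
#' @slot kdSe,nSe numeric, standard errors (`NA` when residuals vanish).
#' @slot residualSS numeric, residual sum of squares.
#' @slot curve the fitted [OccupancyCurve].
#' @seealso [fitHill()], [hillTheta()]
#' @export
setClass("HillFit",
    representation(kd = "numeric", n = "numeric", kdSe = "numeric",
                   nSe = "numeric", residualSS = "numeric",
                   curve = "OccupancyCurve"))

setValidity("HillFit", function(object) {
    msg <- c(.checkNumericSlot(object@kd, "kd", positive = TRUE),
             .checkNumericSlot(object@n, "n", positive = TRUE))
    if (length(msg)) msg else TRUE
})

#' @rdname kd
#' @export
setMethod("kd", "HillFit", function(object) object@kd)

#' @rdname kdSe
#' @export
setMethod("kdSe", "HillFit", function(object) object@kdSe)

#' @rdname hillCoefficient
#' @export
setMethod("hillCoefficient", "HillFit", function(object) object@n)

#' @rdname residualSS
#' @export
setMethod("residualSS", "HillFit", function(object) object@residualSS)

setMethod("show", "HillFit", function(object) {
    cat("HillFit\n")
    cat(sprintf("  K_D: %.4g nM (se %.3g)\n", object@kd, object@kdSe))
    cat(sprintf("  n:   %.4g (se %.3g)\n", object@n, object@nSe))
    cat(sprintf("  residual SS: %.3g over %d points\n", object@residualSS,
                length(object@curve)))
})

## ---- MSTDataset -----------------------------------------------------------

#' MST titration dataset
#'
#' \eqn{\Delta F_{norm}} as a function of ligand (protein) concentration,
#' with the constant DNA substrate concentration and the lattice
#' binding-site size carried along for fitting.
#'
#' @slot concentration numeric, ligand concentrations (\eqn{\mu}M), >= 0.
#' @slot dfnorm numeric, \eqn{\Delta F_{norm}} per concentration (Fnorm
#'   minus the DNA-only Fnorm; sign unconstrained).
#' @slot dnaConc numeric, DNA substrate concentration (nM); default 40.
#' @slot siteSize integer, binding-site size n (bp); default 30.
#' @seealso [fitMvH()], [mvhTheta()], [simulateMSTDataset()]
#' @export
setClass("MSTDataset",
    representation(concentration = "numeric", dfnorm = "numeric",
                   dnaConc = "numeric", siteSize = "integer"))

setValidity("MSTDataset", function(object) {
    if (length(object@concentration) != length(object@dfnorm))
        return("concentration and dfnorm must have equal length")
    if (any(object@concentration < 0))
        return("concentrations must be >= 0")
    if (length(object@siteSize) != 1L || object@siteSize < 1L)
        return("siteSize must be a single integer >= 1")
    TRUE
})

#' Construct an MST dataset
#'
#' @param concentration numeric, ligand concentrations (\eqn{\mu}M).
#' @param dfnorm numeric, \eqn{\Delta F_{norm}} values.
#' @param dnaConc numeric, DNA concentration (nM).
#' @param siteSize integer, binding-site size (bp).
#' @return an [MSTDataset] with points sorted by concentration.
#' @examples
#' MSTDataset(c(0.125, 0.25, 0.5, 1), c(0.01, 0.02, 0.05, 0.1))
#' @export
MSTDataset <- function(concentration, dfnorm, dnaConc = 40, siteSize = 30L) {
    o <- order(concentration)
    new("MSTDataset", concentration = as.numeric(concentration)[o],
        dfnorm = as.numeric(dfnorm)[o], dnaConc = as.numeric(dnaConc),
        siteSize = as.integer(siteSize))
}

#' @describeIn MSTDataset-class points as a data.frame with columns
#'   `conc_uM`, `dfnorm`.
#' @param x,row.names,optional,... see [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "MSTDataset",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(conc_uM = x@concentration, dfnorm = x@dfnorm,
                   row.names = row.names)
    })

#' @rdname siteSize
#' @export
setMethod("siteSize", "MSTDataset", function(object) object@siteSize)

setMethod("length", "MSTDataset", function(x) length(x@concentration))

setMethod("show", "MSTDataset", function(object) {
    cat(sprintf(
        "MSTDataset: %d points, DNA %.3g nM, site size %d bp\n",
        length(object), object@dnaConc, object@siteSize))
})

## ---- MvHFit ---------------------------------------------------------------

#' McGhee-von Hippel isotherm fit
#'
#' Result of fitting \eqn{\Delta F_{norm}(c) = A\,\theta_{MvH}(c; K_D, n)}
#' with the binding-site size \eqn{n} held fixed: the per-lattice-site
#' dissociation constant \eqn{K_D = 1/K} (\eqn{\mu}M) and the saturation
#' amplitude \eqn{A}.
#'
#' @slot kd numeric, dissociation constant (\eqn{\mu}M), > 0.
#' @slot amplitude numeric, \eqn{\Delta F_{norm}} at saturation.
#' @slot kdSe numeric, standard error of `kd` (`NA` when residuals vanish).
#' @slot residualSS numeric, residual sum of squares.
#' @slot siteSize integer, binding-site size used (bp).
#' @seealso [fitMvH()]
#' @export
setClass("MvHFit",
    representation(kd = "numeric", amplitude = "numeric", kdSe = "numeric",
                   residualSS = "numeric", siteSize = "integer"))

setValidity("MvHFit", function(object) {
    msg <- .checkNumericSlot(object@kd, "kd", positive = TRUE)
    if (length(msg)) msg else TRUE
})

#' @rdname kd
#' @export
setMethod("kd", "MvHFit", function(object) object@kd)

#' @rdname kdSe
#' @export
setMethod("kdSe", "MvHFit", function(object) object@kdSe)

#' @rdname amplitude
#' @export
setMethod("amplitude", "MvHFit", function(object) object@amplitude)

#' @rdname residualSS
#' @export
setMethod("residualSS", "MvHFit", function(object) object@residualSS)

#' @rdname siteSize
#' @export
setMethod("siteSize", "MvHFit", function(object) object@siteSize)

setMethod("show", "MvHFit", function(object) {
    cat("MvHFit (McGhee-von Hippel, non-cooperative)\n")
    cat(sprintf("  K_D: %.4g uM (se %.3g), site size %d bp\n",
                object@kd, object@kdSe, object@siteSize))
    cat(sprintf("  amplitude: %.4g, residual SS: %.3g\n",
                object@amplitude, object@residualSS))
})

## ---- RMSMixtureFit --------------------------------------------------------

#' Gaussian mixture fit of a per-bead RMS distribution
#'
#' Maximum-likelihood normal mixture fitted to the per-bead RMS values of
#' one TPM condition. Components are sorted by ascending mean; for a
#' two-component fit the lower-mean component is the protein-bound
#' (compacted) population and the higher-mean component the bare-DNA
#' population.
#'
#' @slot components data.frame with columns `mean`, `sd`, `weight`
#'   (weights sum to 1), rows sorted by ascending mean.
#' @slot logLik numeric, maximized log-likelihood.
#' @slot n integer, number of beads fitted.
#' @slot boundIndex,unboundIndex integer, component roles (`NA` for
#'   single-component fits with no role assignment).
#' @slot occupancy numeric, bound fraction computed from the component
#'   weights (`NA` when roles are unassigned).
#' @seealso [fitRMSMixture()], [occupancyFromFit()]
#' @export
setClass("RMSMixtureFit",
    representation(components = "data.frame", logLik = "numeric",
                   n = "integer", boundIndex = "integer",
                   unboundIndex = "integer", occupancy = "numeric"))

setValidity("RMSMixtureFit", function(object) {
    cmp <- object@components
    if (!all(c("mean", "sd", "weight") %in% names(cmp)))
        return("components must have columns mean, sd, weight")
    if (any(cmp$sd <= 0)) return("component sd must be > 0")
    if (any(cmp$weight < 0 | cmp$weight > 1))
        return("component weights must lie in [0, 1]")
    if (abs(sum(cmp$weight) - 1) > 1e-9)
        return("component weights must sum to 1")
    if (is.unsorted(cmp$mean)) return("components must be sorted by mean")
    if (!is.na(object@occupancy) &&
        (object@occupancy < 0 || object@occupancy > 1))
        return("occupancy must lie in [0, 1]")
    TRUE
})

#' @rdname components
#' @export
setMethod("components", "RMSMixtureFit", function(object) object@components)

#' @rdname occupancy
#' @export
setMethod("occupancy", "RMSMixtureFit", function(object) object@occupancy)

setMethod("show", "RMSMixtureFit", function(object) {
    cat(sprintf("RMSMixtureFit: %d component(s), %d beads, logLik %.3f\n",
                nrow(object@components), object@n, object@logLik))
    print(object@components, digits = 4)
    if (!is.na(object@occupancy))
        cat(sprintf("  occupancy (bound fraction): %.4f\n", object@occupancy))
})

## ---- LogisticNull ---------------------------------------------------------

#' Logistic null distribution of transformed count differences
#'
#' Location/scale parameters of the logistic distribution used as the
#' empirical null for signed-square-root-transformed differences of
#' normalized counts.
#'
#' @slot location numeric, \eqn{\mu} (transformed-count units).
#' @slot scale numeric, \eqn{s} (transformed-count units), > 0.
#' @seealso [fitLogisticNull()], [logisticPValue()]
#' @export
setClass("LogisticNull",
    representation(location = "numeric", scale = "numeric"))

setValidity("LogisticNull", function(object) {
    if (length(object@location) != 1L || !is.finite(object@location))
        return("location must be a finite scalar")
    if (length(object@scale) != 1L || !is.finite(object@scale) ||
        object@scale <= 0)
        return("scale must be a finite scalar > 0")
    TRUE
})

#' Construct a logistic null
#'
#' @param location numeric scalar.
#' @param scale numeric scalar > 0.
#' @return a [LogisticNull].
#' @examples
#' LogisticNull(0.0715, 0.66927)
#' @export
LogisticNull <- function(location, scale) {
    new("LogisticNull", location = as.numeric(location),
        scale = as.numeric(scale))
}

#' @rdname logistic-null-accessors
#' @export
setMethod("nullLocation", "LogisticNull", function(object) object@location)

#' @rdname logistic-null-accessors
#' @export
setMethod("nullScale", "LogisticNull", function(object) object@scale)

setMethod("show", "LogisticNull", function(object) {
    cat(sprintf("LogisticNull: location %.5g, scale %.5g\n",
                object@location, object@scale))
})

## ---- DEGResult ------------------------------------------------------------

#' Differential-expression call against a logistic null
#'
#' Per-gene transformed differences versus the deletion strain, two-sided
#' p-values under the fitted logistic null, Storey q-values and the DEG
#' flag at the selection threshold.
#'
#' @slot table data.frame with columns `gene`, `diff`, `transformed`, `p`,
#'   `q`, `isDeg`.
#' @slot null the [LogisticNull] used.
#' @slot strain,deletionStrain character, the contrast.
#' @slot threshold numeric, q-value cut-off (strict `<`).
#' @seealso [callDEGs()], [selectDEGs()]
#' @export
setClass("DEGResult",
    representation(table = "data.frame", null = "LogisticNull",
                   strain = "character", deletionStrain = "character",
                   threshold = "numeric"))

setValidity("DEGResult", function(object) {
    tb <- object@table
    need <- c("gene", "diff", "transformed", "p", "q", "isDeg")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    if (nrow(tb) && (any(tb$p < 0 | tb$p > 1) || any(tb$q < 0 | tb$q > 1)))
        return("p and q must lie in [0, 1]")
    if (nrow(tb) && !identical(tb$isDeg, tb$q < object@threshold))
        return("isDeg flag inconsistent with q < threshold")
    TRUE
})

#' @rdname degTable
#' @export
setMethod("degTable", "DEGResult", function(object) object@table)

setMethod("show", "DEGResult", function(object) {
    cat(sprintf("DEGResult: %s vs %s, %d genes, %d DEGs at q < %g\n",
                object@strain, object@deletionStrain, nrow(object@table),
                sum(object@table$isDeg), object@threshold))
    show(object@null)
})

## ---- VennPartition --------------------------------------------------------

#' Seven-region partition of three gene sets
#'
#' Exact disjoint-region counts of three DEG sets, the union size, and each
#' region's percentage of the union.
#'
#' @slot regions named numeric, counts for `onlyA`, `onlyB`, `onlyC`,
#'   `AB`, `AC`, `BC`, `ABC` (pairwise regions exclude the triple overlap).
#' @slot unionSize numeric, size of the three-set union.
#' @slot percentages named numeric, `100 * regions / unionSize`.
#' @slot setNames character(3), display names of the sets.
#' @seealso [vennPartition()]
#' @export
setClass("VennPartition",
    representation(regions = "numeric", unionSize = "numeric",
                   percentages = "numeric", setNames = "character"))

.VENN_REGIONS <- c("onlyA", "onlyB", "onlyC", "AB", "AC", "BC", "ABC")

setValidity("VennPartition", function(object) {
    if (!identical(names(object@regions), .VENN_REGIONS))
        return("regions must be named onlyA..ABC in canonical order")
    if (any(object@regions < 0)) return("region counts must be >= 0")
    if (abs(sum(object@regions) - object@unionSize) > 1e-9)
        return("region counts must sum to the union size")
    if (object@unionSize > 0 &&
        abs(sum(object@percentages) - 100) > 0.1)
        return("percentages must sum to 100")
    TRUE
})

#' @rdname vennRegions
#' @export
setMethod("vennRegions", "VennPartition", function(object) object@regions)

#' @describeIn VennPartition-class regions as a data.frame with columns
#'   `region`, `count`, `percent_of_union`.
#' @param x,row.names,optional,... see [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "VennPartition",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(region = names(x@regions), count = unname(x@regions),
                   percent_of_union = unname(x@percentages),
                   row.names = row.names)
    })

setMethod("show", "VennPartition", function(object) {
    cat(sprintf("VennPartition of (%s); union %d\n",
                paste(object@setNames, collapse = ", "),
                as.integer(object@unionSize)))
    print(as.data.frame(object), digits = 3)
})

## ---- AlignmentProfile -----------------------------------------------------

#' Column-wise profile of a protein multiple alignment
#'
#' Per-column residue frequencies over the 20 standard amino acids (gaps
#' excluded from normalization) and the per-column information content
#' \eqn{IC = \log_2 20 - H} in bits, where \eqn{H} is the Shannon entropy
#' of the column's residue frequencies. All-gap columns carry IC 0 and an
#' all-`NA` frequency vector, and are flagged.
#'
#' @slot frequencies 20 x L numeric matrix of residue probabilities
#'   (rows named by amino acid).
#' @slot ic numeric length-L vector of information content (bits).
#' @slot nSequences integer, number of aligned sequences.
#' @slot allGap logical length-L, `TRUE` for all-gap columns.
#' @seealso [alignmentProfile()]
#' @export
setClass("AlignmentProfile",
    representation(frequencies = "matrix", ic = "numeric",
                   nSequences = "integer", allGap = "logical"))

setValidity("AlignmentProfile", function(object) {
    L <- ncol(object@frequencies)
    if (length(object@ic) != L || length(object@allGap) != L)
        return("ic and allGap must have one entry per column")
    if (any(object@ic < -1e-9 | object@ic > log2(20) + 1e-9))
        return("information content must lie in [0, log2(20)]")
    ok <- !object@allGap
    if (any(ok)) {
        s <- colSums(object@frequencies[, ok, drop = FALSE])
        if (any(abs(s - 1) > 1e-9))
            return("column frequencies must sum to 1")
    }
    TRUE
})

#' @rdname informationContent
#' @export
setMethod("informationContent", "AlignmentProfile",
          function(object) object@ic)

setMethod("show", "AlignmentProfile", function(object) {
    cat(sprintf(
        "AlignmentProfile: %d columns, %d sequences, mean IC %.3f bits\n",
        ncol(object@frequencies), object@nSequences, mean(object@ic)))
})
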
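#' @include AllClasses.R
NULL

## strain map is carried in colData(se)$strain
.strainOf <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    if (!"strain" %in% names(cd))
        stop("colData(se) must contain a 'strain' column", call. = FALSE)
    as.character(cd$strain)
}

#' Library-size normalization of a count matrix
#'
#' Scales every sample to the mean library size: sample \eqn{j} is
#' multiplied by \eqn{\bar{N} / N_j} where \eqn{N_j} is its total count.
#' This keeps normalized values in count units so that per-gene differences
#' between strain means remain interpretable as count differences.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with an integer
#'   `counts` assay and a `strain` column in `colData`, e.g. from
#'   [readCountMatrix()] or [simulateCountMatrix()].
#' @return the same object with an additional `normalized` assay; the
#'   per-sample scale factors are stored in `colData(se)$sizeFactor`
#'   (normalized = counts * sizeFactor).
#' @examples
#' se <- simulateCountMatrix(nGenes = 50, seed = 1)
#' normalizeCounts(se)
#' @export
normalizeCounts <- function(se) {
    counts <- SummarizedExperiment::assay(se, "counts")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers", call. = FALSE)
    libs <- colSums(counts)
    if (any(libs == 0))
        stop("zero-total sample(s): ",
             paste(colnames(counts)[libs == 0], collapse = ", "),
             call. = FALSE)
    fac <- mean(libs) / libs
    SummarizedExperiment::assay(se, "normalized") <-
        sweep(counts, 2L, fac, "*")
    SummarizedExperiment::colData(se)$sizeFactor <- fac
    se
}

#' Transformed expression differences versus the deletion strain
#'
#' For every gene, the mean normalized count of the deletion strain is
#' subtracted from the mean normalized count of `strain`, and the
#' difference is transformed by its signed square root,
#' \eqn{t_g = \mathrm{sign}(d_g)\sqrt{|d_g|}}, so that induced and
#' repressed genes stay distinguishable. Swapping `strain` and
#' `deletionStrain` negates both columns.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with `counts`
#'   (the `normalized` assay is added via [normalizeCounts()] if absent)
#'   and a `strain` column in `colData`.
#' @param strain,deletionStrain character, strain labels present in the
#'   strain map.
#' @return data.frame with columns `gene`, `diff` (normalized-count
#'   units), `transformed` (signed square root).
#' @examples
#' se <- simulateCountMatrix(nGenes = 50, seed = 1)
#' head(diffProfile(se, "wt", "drok"))
#' @export
diffProfile <- function(se, strain, deletionStrain) {
    strains <- .strainOf(se)
    for (s in c(strain, deletionStrain))
        if (!s %in% strains)
            stop(sprintf("unknown strain '%s'", s), call. = FALSE)
    if (!"normalized" %in% SummarizedExperiment::assayNames(se))
        se <- normalizeCounts(se)
    norm <- SummarizedExperiment::assay(se, "normalized")
    m1 <- rowMeans(norm[, strains == strain, drop = FALSE])
    m0 <- rowMeans(norm[, strains == deletionStrain, drop = FALSE])
    d <- m1 - m0
    data.frame(gene = rownames(norm), diff = unname(d),
               transformed = unname(sign(d) * sqrt(abs(d))),
               stringsAsFactors = FALSE)
}

#' Maximum-likelihood fit of a logistic distribution
#'
#' Fits location \eqn{\mu} and scale \eqn{s} of the logistic distribution
#' (CDF \eqn{F(x) = 1/(1 + e^{-(x-\mu)/s})}) by direct maximization of the
#' log-likelihood with analytic gradients (BFGS on \eqn{(\mu, \log s)};
#' initialization at the median and the moment estimate
#' \eqn{s_0 = \sqrt{3}\,\hat\sigma/\pi}). The gradient norm at the
#' reported optimum is below 1e-8.
#'
#' @param values numeric, at least 10 finite values, not all identical.
#' @return a [LogisticNull].
#' @examples
#' set.seed(1)
#' fitLogisticNull(rlogis(1000, 0.0715, 0.66927))
#' @export
fitLogisticNull <- function(values) {
    values <- values[is.finite(values)]
    if (length(values) < 10L)
        stop("need at least 10 finite values", call. = FALSE)
    if (sd(values) == 0)
        stop("degenerate input: all values identical (scale undefined)",
             call. = FALSE)
    x <- values
    n <- length(x)
    negll <- function(par) {
        mu <- par[1]; s <- exp(par[2])
        z <- (x - mu) / s
        sum(abs(z) + 2 * log1p(exp(-abs(z)))) + n * log(s)
    }
    grad <- function(par) {
        mu <- par[1]; s <- exp(par[2])
        z <- (x - mu) / s
        tz <- tanh(z / 2)
        c(-sum(tz) / s, -sum(tz * z) + n)  # d/dmu, d/dlog(s)
    }
    p0 <- c(median(x), log(sd(x) * sqrt(3) / pi))
    opt <- optim(p0, negll, grad, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 1000))
    ## polish until the gradient norm meets the convergence contract
    for (i in 1:5) {
        if (sqrt(sum(grad(opt$par)^2)) < 1e-8) break
        opt <- optim(opt$par, negll, grad, method = "BFGS",
                     control = list(reltol = 1e-16, maxit = 1000))
    }
    LogisticNull(opt$par[1], exp(opt$par[2]))
}

#' Two-sided p-value under a logistic null
#'
#' \eqn{p = 2 \min(F(x), 1 - F(x))} with \eqn{F} the logistic CDF of the
#' fitted null; symmetric around the location
#' (\eqn{p(\mu + d) = p(\mu - d)}) and equal to 1 at \eqn{x = \mu}.
#'
#' @param x numeric, transformed difference values.
#' @param null a [LogisticNull].
#' @return numeric vector of p-values in \[0, 1\].
#' @examples
#' logisticPValue(0.0715, LogisticNull(0.0715, 0.66927))  # 1
#' @export
logisticPValue <- function(x, null) {
    stopifnot(is(null, "LogisticNull"))
    F <- plogis(x, location = null@location, scale = null@scale)
    pmin(2 * pmin(F, 1 - F), 1)
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion \eqn{\pi_0}
#' estimated by Storey's smoother method: \eqn{\hat\pi_0(\lambda) =
#' \#\{p > \lambda\} / (m(1-\lambda))} over \eqn{\lambda = 0.05, 0.10,
#' \dots, 0.95}, smoothed with a cubic smoothing spline (df = 3) and
#' evaluated at the largest \eqn{\lambda}. When the estimate falls outside
#' \eqn{(0, 1]} (or cannot be computed), \eqn{\pi_0 = 1} is used, which
#' reduces the procedure to Benjamini-Hochberg. q-values are monotone
#' non-decreasing in p-value rank and never exceed 1.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param lambda numeric grid for the smoother (default
#'   `seq(0.05, 0.95, 0.05)`).
#' @param pi0 optional numeric scalar overriding the \eqn{\pi_0} estimate
#'   (e.g. `pi0 = 1` for plain Benjamini-Hochberg).
#' @return numeric q-values in the original order, with attribute
#'   `"pi0"`.
#' @examples
#' qvalues(c(0.001, 0.01, 0.5, 0.9), pi0 = 1)
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    m <- length(p)
    if (m == 0L) return(numeric(0))
    if (is.null(pi0)) {
        pi0Hat <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                         numeric(1))
        pi0 <- tryCatch({
            sp <- smooth.spline(lambda, pi0Hat, df = 3)
            predict(sp, x = max(lambda))$y
        }, error = function(e) NA_real_)
        if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
    } else {
        .assertScalarNumeric(pi0, "pi0", 0, 1, strict = FALSE)
        if (pi0 <= 0) stop("'pi0' must be > 0", call. = FALSE)
    }
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q <- pmin(pi0 * p[o] * m / (m - seq_len(m) + 1), 1)
    q <- cummin(q)[ro]
    attr(q, "pi0") <- pi0
    q
}

#' Call differentially expressed genes against a logistic null
#'
#' The full differential-expression procedure for one contrast: normalize
#' counts, compute the per-gene signed-square-root-transformed difference
#' of strain means versus the deletion strain ([diffProfile()]), fit the
#' logistic null to the condition's transformed values by MLE (or use a
#' supplied null, e.g. one fitted on values pooled across conditions),
#' convert to two-sided p-values, Storey q-values, and flag genes with
#' q strictly below the threshold as DEGs.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with `counts`
#'   and a `strain` column in `colData`.
#' @param strain,deletionStrain the contrast, as in [diffProfile()].
#' @param threshold numeric, q-value cut-off (strict `<`); default 1e-3.
#' @param null optional prefitted [LogisticNull]; by default the null is
#'   fitted on this condition's transformed values.
#' @return a [DEGResult].
#' @examples
#' se <- simulateCountMatrix(nGenes = 300, degFraction = 0.05, seed = 3)
#' callDEGs(se, "wt", "drok")
#' @export
callDEGs <- function(se, strain, deletionStrain, threshold = 1e-3,
                     null = NULL) {
    .assertScalarNumeric(threshold, "threshold", 0, Inf, strict = TRUE)
    prof <- diffProfile(se, strain, deletionStrain)
    if (is.null(null)) null <- fitLogisticNull(prof$transformed)
    stopifnot(is(null, "LogisticNull"))
    p <- logisticPValue(prof$transformed, null)
    q <- as.numeric(qvalues(p))
    tb <- data.frame(gene = prof$gene, diff = prof$diff,
                     transformed = prof$transformed, p = p, q = q,
                     isDeg = q < threshold, stringsAsFactors = FALSE)
    new("DEGResult", table = tb, null = null, strain = strain,
        deletionStrain = deletionStrain, threshold = threshold)
}

#' Select DEGs from a results table
#'
#' Genes whose q-value is strictly below the threshold.
#'
#' @param x a [DEGResult] or a data.frame with columns `gene` and `q`.
#' @param threshold numeric; default 1e-3.
#' @return character vector of gene identifiers.
#' @examples
#' tb <- data.frame(gene = c("a", "b"), q = c(5e-4, 1e-3))
#' selectDEGs(tb)  # "a" (strict inequality)
#' @export
selectDEGs <- function(x, threshold = 1e-3) {
    tb <- if (is(x, "DEGResult")) degTable(x) else x
    if (!all(c("gene", "q") %in% names(tb)))
        stop("need columns 'gene' and 'q'", call. = FALSE)
    as.character(tb$gene[tb$q < threshold])
}
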
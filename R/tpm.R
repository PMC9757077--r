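#' @include AllClasses.R
NULL

## ---- Gaussian mixture fitting of per-bead RMS distributions ---------------

.mixtureLogLik <- function(x, mean, sd, weight) {
    dens <- vapply(seq_along(mean),
                   function(j) weight[j] * dnorm(x, mean[j], sd[j]),
                   numeric(length(x)))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
    sum(log(rowSums(dens)))
}

## One EM run from a given initialization; returns list(mean, sd, weight,
## logLik, iterations). sd is floored to avoid spike collapse.
.emRun <- function(x, mean, sd, weight, sdFloor, tol = 1e-10,
                   maxIter = 500L) {
    n <- length(x)
    k <- length(mean)
    ll <- -Inf
    for (it in seq_len(maxIter)) {
        dens <- vapply(seq_len(k),
                       function(j) weight[j] * dnorm(x, mean[j], sd[j]),
                       numeric(n))
        if (is.null(dim(dens))) dens <- matrix(dens, nrow = n)
        rowTot <- rowSums(dens)
        rowTot[rowTot == 0 | !is.finite(rowTot)] <- .Machine$double.xmin
        llNew <- sum(log(rowTot))
        resp <- dens / rowTot
        nk <- colSums(resp)
        nk[nk < 1e-12] <- 1e-12
        mean <- colSums(resp * x) / nk
        sd <- sqrt(vapply(seq_len(k), function(j)
            sum(resp[, j] * (x - mean[j])^2) / nk[j], numeric(1)))
        sd <- pmax(sd, sdFloor)
        weight <- nk / n
        if (is.finite(llNew) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
            ll <- llNew
            break
        }
        ll <- llNew
    }
    list(mean = mean, sd = sd, weight = weight / sum(weight), logLik = ll,
         iterations = it)
}

#' Fit a Gaussian mixture to per-bead RMS values
#'
#' Maximum-likelihood fit of a `k`-component normal mixture to the RMS
#' excursions of tethered beads from one titration condition, the
#' per-condition analogue of fitting Gaussians to RMS histograms. Fitting
#' uses expectation-maximization on the unbinned values with 10
#' deterministic quantile-based initializations; the run with the best
#' log-likelihood wins and ties are broken in favour of the lower
#' first-component mean, so the result is deterministic for given data.
#' Components are returned sorted by ascending mean. For `k = 2` the
#' lower-mean component is taken as the protein-bound (DNA-compacted)
#' population and the higher-mean component as bare DNA, and the occupancy
#' is the bound weight fraction.
#'
#' @param rms numeric, per-bead RMS values (nm), all > 0.
#' @param k integer, number of components (1 or 2).
#' @param assignRoles logical; for `k = 2`, compute the bound/unbound role
#'   assignment and occupancy (default `TRUE`).
#' @return an [RMSMixtureFit].
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 159, 12), rnorm(200, 105, 12))
#' fitRMSMixture(x, k = 2)
#' @seealso [occupancyFromFit()], [buildOccupancyCurve()]
#' @export
fitRMSMixture <- function(rms, k = 2L, assignRoles = TRUE) {
    k <- .assertCount(k, "k")
    if (!k %in% 1:2) stop("'k' must be 1 or 2", call. = FALSE)
    if (!is.numeric(rms) || length(rms) == 0L)
        stop("'rms' must be a non-empty numeric vector", call. = FALSE)
    if (any(!is.finite(rms) | rms <= 0))
        stop("'rms' values must be finite and > 0", call. = FALSE)
    n <- length(rms)
    if (n < 10L * k)
        stop(sprintf("need at least %d beads for a %d-component fit (got %d)",
                     10L * k, k, n), call. = FALSE)
    if (sd(rms) == 0)
        stop("degenerate data: all RMS values identical", call. = FALSE)

    sdFloor <- 1e-6 * sd(rms)
    if (k == 1L) {
        m <- mean(rms)
        s <- sqrt(mean((rms - m)^2))  # MLE
        cmp <- data.frame(mean = m, sd = s, weight = 1)
        ll <- .mixtureLogLik(rms, m, s, 1)
        return(new("RMSMixtureFit", components = cmp, logLik = ll,
                   n = n, boundIndex = NA_integer_,
                   unboundIndex = NA_integer_, occupancy = NA_real_))
    }

    ## 10 deterministic initializations: split the sample at quantile p,
    ## seed component moments from the two sides.
    splits <- (1:10) / 11
    best <- NULL
    xs <- sort(rms)
    for (p in splits) {
        cut <- quantile(xs, p, names = FALSE, type = 7)
        lo <- xs[xs <= cut]
        hi <- xs[xs > cut]
        if (length(lo) < 2L || length(hi) < 2L) next
        init <- .emRun(rms,
                       mean = c(mean(lo), mean(hi)),
                       sd = pmax(c(sd(lo), sd(hi)), sdFloor),
                       weight = c(p, 1 - p), sdFloor = sdFloor)
        if (is.null(best) ||
            init$logLik > best$logLik + 1e-9 ||
            (abs(init$logLik - best$logLik) <= 1e-9 &&
             min(init$mean) < min(best$mean)))
            best <- init
    }
    if (is.null(best))
        stop("mixture fit failed: no valid initialization", call. = FALSE)

    o <- order(best$mean)
    cmp <- data.frame(mean = best$mean[o], sd = best$sd[o],
                      weight = best$weight[o] / sum(best$weight))
    boundIndex <- if (assignRoles) 1L else NA_integer_
    unboundIndex <- if (assignRoles) 2L else NA_integer_
    occ <- if (assignRoles)
        occupancyFromFit(cmp$weight, boundIndex, unboundIndex)
    else NA_real_
    new("RMSMixtureFit", components = cmp, logLik = best$logLik, n = n,
        boundIndex = boundIndex, unboundIndex = unboundIndex,
        occupancy = occ)
}

#' Occupancy from fitted mixture component weights
#'
#' The fraction of DNA tethers carrying bound protein, computed from the
#' areas (weights) of the bound and unbound Gaussian components:
#' \deqn{\theta = A_{bound} / (A_{bound} + A_{unbound}).}
#'
#' @param weights numeric, component weights (or areas; any common scale).
#' @param boundIndex,unboundIndex indices of the bound and unbound
#'   components in `weights`; must be distinct and valid.
#' @return numeric scalar \eqn{\theta \in [0, 1]}.
#' @examples
#' occupancyFromFit(c(3, 1), 1, 2)  # 0.75
#' @export
occupancyFromFit <- function(weights, boundIndex, unboundIndex) {
    boundIndex <- .assertCount(boundIndex, "boundIndex")
    unboundIndex <- .assertCount(unboundIndex, "unboundIndex")
    if (boundIndex == unboundIndex)
        stop("bound and unbound indices must be distinct", call. = FALSE)
    if (boundIndex > length(weights) || unboundIndex > length(weights))
        stop("component index out of range", call. = FALSE)
    wb <- weights[boundIndex]
    wu <- weights[unboundIndex]
    if (any(c(wb, wu) < 0))
        stop("weights must be >= 0", call. = FALSE)
    if (wb + wu == 0)
        stop("bound and unbound weights are both zero", call. = FALSE)
    wb / (wb + wu)
}

## ---- occupancy curve construction -----------------------------------------

#' Build an occupancy curve from a per-bead titration table
#'
#' For every concentration of a TPM titration, fits the per-bead RMS
#' distribution as a two-component Gaussian mixture (one component when too
#' few beads or when the minor component falls below the weight threshold),
#' drops minor populations (weight < `minorThreshold`, mirroring the
#' exclusion of inconsistent low-occupancy populations from occupancy
#' calculations), renormalizes, and converts component weights to occupancy.
#' Components are classified as bound/unbound by proximity to reference
#' means obtained from a pooled two-component fit over all beads; a
#' concentration whose surviving components are all unbound gets
#' \eqn{\theta = 0}, all bound gets \eqn{\theta = 1}.
#'
#' @param beads data.frame with columns `label`, `concentration_nM`,
#'   `rms_nm` (one row per bead), e.g. from [readBeadTable()] or
#'   [simulateTPMTitration()].
#' @param minorThreshold numeric, weight below which a fitted component is
#'   treated as a minor population and excluded (default 0.05).
#' @return an [OccupancyCurve]; `thetaSd` is the binomial standard
#'   deviation \eqn{\sqrt{\theta(1-\theta)/n}}.
#' @examples
#' beads <- simulateTPMTitration(concentrations = c(0, 4, 6, 8, 10),
#'                               nBeads = 150, seed = 7)
#' buildOccupancyCurve(beads)
#' @export
buildOccupancyCurve <- function(beads, minorThreshold = 0.05) {
    .validateBeadTable(beads)
    .assertScalarNumeric(minorThreshold, "minorThreshold", 0, 0.5)
    concs <- sort(unique(beads$concentration_nM))
    if (length(concs) < 2L)
        stop("need at least 2 distinct concentrations to build a curve",
             call. = FALSE)

    ## reference bound/unbound means from a pooled fit over all beads
    pooled <- fitRMSMixture(beads$rms_nm, k = 2L, assignRoles = FALSE)
    refMeans <- components(pooled)$mean  # ascending: bound, unbound

    theta <- thetaSd <- numeric(length(concs))
    nBeads <- integer(length(concs))
    for (i in seq_along(concs)) {
        x <- beads$rms_nm[beads$concentration_nM == concs[i]]
        nBeads[i] <- length(x)
        fit <- if (length(x) >= 20L && sd(x) > 0)
            fitRMSMixture(x, k = 2L, assignRoles = FALSE)
        else fitRMSMixture(x, k = 1L)
        cmp <- components(fit)
        keep <- cmp$weight >= minorThreshold
        if (!any(keep)) keep <- cmp$weight == max(cmp$weight)
        cmp <- cmp[keep, , drop = FALSE]
        cmp$weight <- cmp$weight / sum(cmp$weight)
        isBound <- abs(cmp$mean - refMeans[1]) < abs(cmp$mean - refMeans[2])
        wb <- sum(cmp$weight[isBound])
        wu <- sum(cmp$weight[!isBound])
        theta[i] <- wb / (wb + wu)
        thetaSd[i] <- sqrt(theta[i] * (1 - theta[i]) / nBeads[i])
    }
    OccupancyCurve(concs, theta, thetaSd, nBeads)
}

## ---- Hill model ------------------------------------------------------------

#' Hill binding isotherm
#'
#' Occupancy as a function of ligand concentration under the Hill model,
#' \deqn{\theta(c) = \frac{1}{(K_D / c)^n + 1},}
#' with \eqn{\theta(0) = 0} by continuity. \eqn{\theta(K_D) = 1/2} for any
#' Hill coefficient.
#'
#' @param c numeric, ligand concentrations (nM), >= 0.
#' @param kd numeric scalar, apparent binding affinity \eqn{K_D} (nM), > 0.
#' @param n numeric scalar, Hill coefficient, > 0.
#' @return numeric vector of occupancies in \[0, 1\].
#' @examples
#' hillTheta(6.1, kd = 6.1, n = 6.5)   # 0.5
#' hillTheta(10, kd = 6.1, n = 6.5)    # 0.9613
#' @export
hillTheta <- function(c, kd, n) {
    .assertScalarNumeric(kd, "kd", 0, Inf, strict = TRUE)
    .assertScalarNumeric(n, "n", 0, Inf, strict = TRUE)
    if (any(c < 0)) stop("'c' must be >= 0", call. = FALSE)
    th <- ifelse(c == 0, 0, 1 / ((kd / c)^n + 1))
    as.numeric(th)
}

#' Fit the Hill model to an occupancy curve
#'
#' Unweighted nonlinear least squares of the Hill isotherm on occupancy,
#' with both parameters log-transformed to enforce positivity
#' (Levenberg-Marquardt). Initialization: \eqn{K_D} at the concentration
#' whose occupancy is nearest 0.5, \eqn{n = 4}. On noiseless model data the
#' generating parameters are recovered to relative error below 1e-6.
#'
#' @param curve an [OccupancyCurve] (or data.frame with columns
#'   `concentration_nM` and `theta`) with at least 3 points, at least one
#'   of them strictly between 0 and 1.
#' @return a [HillFit]. Standard errors come from the linearized
#'   covariance and are `NA` when the residuals are numerically zero.
#' @examples
#' cc <- 2:10
#' fitHill(OccupancyCurve(cc, hillTheta(cc, 6.1, 6.5)))
#' @export
fitHill <- function(curve) {
    if (is.data.frame(curve))
        curve <- OccupancyCurve(curve$concentration_nM, curve$theta)
    stopifnot(is(curve, "OccupancyCurve"))
    cc <- curve@concentration
    th <- pmin(pmax(curve@theta, 0), 1)
    if (length(cc) < 3L)
        stop("need at least 3 occupancy points to fit the Hill model",
             call. = FALSE)
    interior <- th > 0 & th < 1
    if (!any(interior))
        stop("non-identifiable: no occupancy strictly between 0 and 1",
             call. = FALSE)

    kd0 <- cc[which.min(abs(th - 0.5))]
    if (kd0 <= 0) kd0 <- median(cc[cc > 0])
    dat <- data.frame(cc = cc, th = th)
    fit <- minpack.lm::nlsLM(
        th ~ ifelse(cc == 0, 0, 1 / ((exp(lk) / cc)^exp(ln) + 1)),
        data = dat, start = list(lk = log(kd0), ln = log(4)),
        control = minpack.lm::nls.lm.control(
            ftol = .Machine$double.eps, ptol = .Machine$double.eps,
            maxiter = 500))
    est <- coef(fit)
    rss <- sum(residuals(fit)^2)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
        c(NA_real_, NA_real_), warning = function(w) c(NA_real_, NA_real_))
    kdHat <- exp(est[["lk"]])
    nHat <- exp(est[["ln"]])
    new("HillFit", kd = kdHat, n = nHat,
        kdSe = kdHat * se[[1]], nSe = nHat * se[[2]],
        residualSS = rss, curve = curve)
}

## shared bead-table validation (io module writes, tpm module consumes)
.validateBeadTable <- function(beads) {
    if (!is.data.frame(beads) ||
        !all(c("label", "concentration_nM", "rms_nm") %in% names(beads)))
        stop("bead table must have columns label, concentration_nM, rms_nm",
             call. = FALSE)
    if (nrow(beads) == 0L)
        stop("bead table is empty", call. = FALSE)
    if (!is.numeric(beads$concentration_nM) ||
        any(!is.finite(beads$concentration_nM)) ||
        any(beads$concentration_nM < 0))
        stop("'concentration_nM' must be finite and >= 0", call. = FALSE)
    if (!is.numeric(beads$rms_nm) || any(!is.finite(beads$rms_nm)) ||
        any(beads$rms_nm <= 0))
        stop("'rms_nm' must be finite and > 0", call. = FALSE)
    invisible(beads)
}
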
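#' @include AllClasses.R
NULL

## Synthetic-data generators. Each takes an explicit seed and runs under a
## locally seeded Mersenne-Twister RNG (normal inversion), leaving global
## RNG state untouched; a fixed seed gives bit-identical output.

#' Simulate a TPM titration of per-bead RMS values
#'
#' Draws, for every protein concentration, `nBeads` per-bead RMS values
#' from a two-population Gaussian mixture whose bound fraction follows the
#' Hill isotherm \eqn{\theta(c) = 1/((K_D/c)^n + 1)}: each bead is bound
#' with probability \eqn{\theta(c)} and its RMS is drawn from the bound or
#' bare normal population accordingly. Defaults mirror a Rok-like
#' titration: bare DNA at 159 nm, the compacted bound population at
#' 105 nm, \eqn{K_D} = 6.1 nM, \eqn{n} = 6.5, and 200 beads per
#' condition. The population SDs are simulation configuration, not
#' measured quantities.
#'
#' @param concentrations numeric, protein concentrations (nM), >= 0.
#' @param hillKd numeric, planted \eqn{K_D} (nM); default 6.1.
#' @param hillN numeric, planted Hill coefficient; default 6.5.
#' @param meanBare,meanBound numeric, population mean RMS (nm); defaults
#'   159 and 105.
#' @param sdBare,sdBound numeric, population SDs (nm); defaults 12.
#' @param nBeads integer, beads per concentration; default 200.
#' @param label character, condition label prefix; default "sim".
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return bead table: data.frame with columns `label`,
#'   `concentration_nM`, `rms_nm` (one row per bead) and attribute
#'   `"trueTheta"` giving \eqn{\theta(c)} per concentration.
#' @examples
#' beads <- simulateTPMTitration(c(0, 4, 6, 8, 10), nBeads = 50, seed = 1)
#' table(beads$concentration_nM)
#' @export
simulateTPMTitration <- function(concentrations = c(0:10),
                                 hillKd = 6.1, hillN = 6.5,
                                 meanBare = 159, meanBound = 105,
                                 sdBare = 12, sdBound = 12,
                                 nBeads = 200L, label = "sim",
                                 seed = NULL) {
    if (length(concentrations) == 0L || any(!is.finite(concentrations)) ||
        any(concentrations < 0))
        stop("'concentrations' must be finite and >= 0", call. = FALSE)
    .assertScalarNumeric(hillKd, "hillKd", 0, Inf, strict = TRUE)
    .assertScalarNumeric(hillN, "hillN", 0, Inf, strict = TRUE)
    .assertScalarNumeric(meanBare, "meanBare", 0, Inf, strict = TRUE)
    .assertScalarNumeric(meanBound, "meanBound", 0, Inf, strict = TRUE)
    .assertScalarNumeric(sdBare, "sdBare", 0, Inf, strict = TRUE)
    .assertScalarNumeric(sdBound, "sdBound", 0, Inf, strict = TRUE)
    nBeads <- .assertCount(nBeads, "nBeads")

    theta <- hillTheta(concentrations, hillKd, hillN)
    out <- .withSeed(seed, {
        do.call(rbind, lapply(seq_along(concentrations), function(i) {
            bound <- rbinom(nBeads, 1L, theta[i]) == 1L
            rms <- ifelse(bound,
                          rnorm(nBeads, meanBound, sdBound),
                          rnorm(nBeads, meanBare, sdBare))
            rms <- pmax(rms, .Machine$double.eps)
            data.frame(label = label,
                       concentration_nM = concentrations[i],
                       rms_nm = rms, stringsAsFactors = FALSE)
        }))
    })
    attr(out, "trueTheta") <- setNames(theta, concentrations)
    out
}

#' Simulate a bridging-assay count table
#'
#' Generates scintillation counts for a set of bridging conditions with
#' known true recovery fractions: each replicate's signal is
#' Poisson-distributed around `fraction * referenceCpm` (so the mean
#' recovery converges to the planted fraction), against a fixed reference
#' of labeled DNA. Defaults mirror a typical assay: a reference signal
#' around 8000 cpm and triplicate measurements.
#'
#' @param fractions named numeric in \[0, 1\]: true recovery fraction per
#'   condition (names become condition labels).
#' @param referenceCpm numeric > 0, reference counts; default 8000.
#' @param replicates integer >= 1; default 3.
#' @param seed integer RNG seed, or `NULL`.
#' @return data.frame with columns `label`, `replicate`, `signal_cpm`,
#'   `reference_cpm`.
#' @examples
#' simulateBridging(c(none = 0, rok = 0.8), seed = 1)
#' @export
simulateBridging <- function(fractions, referenceCpm = 8000,
                             replicates = 3L, seed = NULL) {
    if (length(fractions) == 0L || any(!is.finite(fractions)))
        stop("'fractions' must be finite", call. = FALSE)
    if (any(fractions < 0 | fractions > 1))
        stop("'fractions' must lie in [0, 1]", call. = FALSE)
    .assertScalarNumeric(referenceCpm, "referenceCpm", 0, Inf,
                         strict = TRUE)
    replicates <- .assertCount(replicates, "replicates")
    labels <- if (is.null(names(fractions)))
        paste0("cond", seq_along(fractions)) else names(fractions)
    .withSeed(seed, {
        do.call(rbind, lapply(seq_along(fractions), function(i) {
            data.frame(label = labels[i], replicate = seq_len(replicates),
                       signal_cpm = rpois(replicates,
                                          fractions[i] * referenceCpm),
                       reference_cpm = referenceCpm,
                       stringsAsFactors = FALSE)
        }))
    })
}

#' Simulate an MST titration dataset
#'
#' Generates \eqn{\Delta F_{norm}} values following the non-cooperative
#' McGhee-von Hippel isotherm,
#' \eqn{\Delta F_{norm}(c) = A\,\theta_{MvH}(c; K_D, n) + \epsilon} with
#' additive Gaussian noise, over a doubling concentration series of
#' 0.125-16 \eqn{\mu}M by default with binding-site size 30 bp. The
#' amplitude's sign is unconstrained (\eqn{\Delta F_{norm}} may run either
#' way). With `noiseSd = 0` the data are exactly on the model curve.
#'
#' @param kd numeric > 0, planted per-site \eqn{K_D} (\eqn{\mu}M).
#' @param siteSize integer >= 1, binding-site size (bp); default 30.
#' @param concentrations numeric, ligand concentrations (\eqn{\mu}M);
#'   default `0.125 * 2^(0:7)`.
#' @param amplitude numeric != 0, \eqn{\Delta F_{norm}} at saturation;
#'   default 1.
#' @param noiseSd numeric >= 0, noise SD; default 0.
#' @param dnaConc numeric, DNA concentration (nM); default 40.
#' @param seed integer RNG seed, or `NULL`.
#' @return an [MSTDataset].
#' @examples
#' simulateMSTDataset(kd = 79.4)
#' @export
simulateMSTDataset <- function(kd, siteSize = 30L,
                               concentrations = 0.125 * 2^(0:7),
                               amplitude = 1, noiseSd = 0,
                               dnaConc = 40, seed = NULL) {
    .assertScalarNumeric(kd, "kd", 0, Inf, strict = TRUE)
    .assertScalarNumeric(amplitude, "amplitude")
    if (amplitude == 0) stop("'amplitude' must be nonzero", call. = FALSE)
    .assertScalarNumeric(noiseSd, "noiseSd", 0, Inf)
    theta <- mvhTheta(concentrations, kd, siteSize)
    df <- amplitude * theta
    if (noiseSd > 0)
        df <- .withSeed(seed, df + rnorm(length(df), 0, noiseSd))
    MSTDataset(concentrations, df, dnaConc = dnaConc, siteSize = siteSize)
}

## unbiased randomized rounding: E[round] = x exactly
.randomRound <- function(x) {
    f <- floor(x)
    as.integer(f + (runif(length(x)) < (x - f)))
}

#' Simulate a gene-by-sample count matrix with a planted logistic signal
#'
#' Generates integer counts for a deletion-strain baseline plus effect
#' strains whose strain-vs-deletion transformed differences follow a
#' logistic distribution. Per gene, a baseline expression level is drawn
#' from a negative binomial (so the count marginal across genes is
#' NB-shaped); each effect strain receives a planted transformed
#' difference \eqn{t_g \sim \mathrm{logistic}(location, scale)} inverted
#' through the analysis transform: its mean is
#' \eqn{baseline + \mathrm{sign}(t_g)\,t_g^2}, clipped at 0 (clipped genes
#' are flagged in `rowData`). A fraction `degFraction` of genes
#' additionally gets a strong planted effect of `degEffect` transformed
#' units (random sign) - the true DEGs, recorded in
#' `rowData(se)$plantedDeg`. Integer counts are produced by unbiased
#' randomized rounding of depth-scaled means, so expectations are
#' preserved exactly; replicate-level biological overdispersion is
#' deliberately not simulated. Default logistic parameters: location
#' 0.0715, scale 0.66927.
#'
#' @param nGenes integer >= 1.
#' @param strains character, effect-strain labels; default
#'   `c("wt", "rok", "srok", "rok_srok")`.
#' @param deletionStrain character, baseline strain label; default
#'   `"drok"`.
#' @param replicates integer >= 1, samples per strain; default 2.
#' @param nbMean,nbDispersion numeric, negative-binomial baseline mean and
#'   dispersion (variance = mu + dispersion * mu^2); defaults 250 and 0.3.
#' @param logisticLocation,logisticScale numeric, planted null parameters;
#'   defaults 0.0715 and 0.66927.
#' @param degFraction numeric in \[0, 1\], fraction of genes with an extra
#'   planted effect; default 0.
#' @param degEffect numeric, size of the extra effect (transformed units);
#'   default 12.
#' @param depthRange numeric(2), per-sample relative sequencing-depth
#'   factors drawn uniformly from this interval; default `c(0.9, 1.1)`.
#' @param seed integer RNG seed, or `NULL`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `colData` columns `strain` and `depthFactor`, and `rowData`
#'   columns `plantedDeg` and `clipped` plus one
#'   `planted_<strain>` column of planted transformed differences per
#'   effect strain.
#' @examples
#' se <- simulateCountMatrix(nGenes = 100, seed = 1)
#' SummarizedExperiment::colData(se)
#' @export
simulateCountMatrix <- function(nGenes = 4000L,
                                strains = c("wt", "rok", "srok",
                                            "rok_srok"),
                                deletionStrain = "drok",
                                replicates = 2L,
                                nbMean = 250, nbDispersion = 0.3,
                                logisticLocation = 0.0715,
                                logisticScale = 0.66927,
                                degFraction = 0, degEffect = 12,
                                depthRange = c(0.9, 1.1),
                                seed = NULL) {
    nGenes <- .assertCount(nGenes, "nGenes")
    replicates <- .assertCount(replicates, "replicates")
    .assertScalarNumeric(nbMean, "nbMean", 0, Inf, strict = TRUE)
    .assertScalarNumeric(nbDispersion, "nbDispersion", 0, Inf,
                         strict = TRUE)
    .assertScalarNumeric(logisticScale, "logisticScale", 0, Inf,
                         strict = TRUE)
    .assertScalarNumeric(logisticLocation, "logisticLocation")
    .assertScalarNumeric(degFraction, "degFraction", 0, 1)
    if (length(strains) < 1L || deletionStrain %in% strains)
        stop("'strains' must be non-empty and distinct from the deletion strain",
             call. = FALSE)

    .withSeed(seed, {
        genes <- sprintf("gene%05d", seq_len(nGenes))
        baseline <- rnbinom(nGenes, mu = nbMean, size = 1 / nbDispersion)
        nDeg <- round(degFraction * nGenes)
        plantedDeg <- rep(FALSE, nGenes)
        if (nDeg > 0) plantedDeg[sample.int(nGenes, nDeg)] <- TRUE

        allStrains <- c(deletionStrain, strains)
        sampleStrain <- rep(allStrains, each = replicates)
        sampleNames <- paste(sampleStrain,
                             rep(seq_len(replicates),
                                 times = length(allStrains)), sep = "_")
        depth <- runif(length(sampleNames), depthRange[1], depthRange[2])

        means <- matrix(rep(baseline, length(allStrains)), nrow = nGenes,
                        dimnames = list(genes, allStrains))
        planted <- matrix(0, nrow = nGenes, ncol = length(strains),
                          dimnames = list(genes, strains))
        clipped <- rep(FALSE, nGenes)
        for (s in strains) {
            t <- rlogis(nGenes, logisticLocation, logisticScale)
            t[plantedDeg] <- t[plantedDeg] +
                sample(c(-1, 1), sum(plantedDeg), replace = TRUE) * degEffect
            planted[, s] <- t
            m <- baseline + sign(t) * t^2
            clip <- m < 0
            clipped <- clipped | clip
            means[, s] <- pmax(m, 0)
        }

        counts <- matrix(0L, nrow = nGenes, ncol = length(sampleNames),
                         dimnames = list(genes, sampleNames))
        for (j in seq_along(sampleNames))
            counts[, j] <- .randomRound(depth[j] *
                                        means[, sampleStrain[j]])

        rd <- S4Vectors::DataFrame(plantedDeg = plantedDeg,
                                   clipped = clipped)
        for (s in strains) rd[[paste0("planted_", s)]] <- planted[, s]
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(
                strain = sampleStrain, depthFactor = depth,
                row.names = sampleNames),
            rowData = rd)
    })
}

#' Simulate random protein sequences
#'
#' Uniform random sequences over the 20 standard amino acids with exactly
#' the requested lengths; a fixture generator for the sequence utilities.
#' A fixed seed gives byte-identical FASTA output on rerun.
#'
#' @param lengths integer vector, sequence lengths (aa), all >= 1.
#' @param prefix character, record-name prefix; default "prot".
#' @param seed integer RNG seed, or `NULL`.
#' @return an [Biostrings::AAStringSet] with names `<prefix>_<i>`.
#' @examples
#' simulateProteinSet(c(191, 150), seed = 1)
#' @export
simulateProteinSet <- function(lengths, prefix = "prot", seed = NULL) {
    if (length(lengths) == 0L || any(!is.finite(lengths)) ||
        any(lengths != round(lengths)) || any(lengths < 1))
        stop("'lengths' must be integers >= 1", call. = FALSE)
    aa <- Biostrings::AA_STANDARD
    .withSeed(seed, {
        seqs <- vapply(lengths, function(L)
            paste(sample(aa, L, replace = TRUE), collapse = ""),
            character(1))
        out <- Biostrings::AAStringSet(seqs)
        names(out) <- paste(prefix, seq_along(seqs), sep = "_")
        out
    })
}
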
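#' @include AllClasses.R
NULL

## Single tabular dialect everywhere: tab-delimited, header row, UTF-8,
## '.' decimal; FASTA via Biostrings; JSON fit reports via jsonlite.

.readTSV <- function(path, required) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    if (file.size(path) == 0L)
        stop(sprintf("empty file: %s", path), call. = FALSE)
    tab <- read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
    miss <- setdiff(required, names(tab))
    if (length(miss))
        stop(sprintf("%s: missing column(s): %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    if (nrow(tab) == 0L)
        stop(sprintf("%s: no data rows", path), call. = FALSE)
    tab
}

## parse a character column to numeric, reporting 1-based file line numbers
## (header = line 1) for malformed values
.numericColumn <- function(tab, col, path, integer = FALSE) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) & !is.na(tab[[col]]))
    if (length(bad))
        stop(sprintf("%s: non-numeric '%s' on line(s) %s", path, col,
                     paste(bad + 1L, collapse = ", ")), call. = FALSE)
    if (any(is.na(x)))
        stop(sprintf("%s: missing '%s' on line(s) %s", path, col,
                     paste(which(is.na(x)) + 1L, collapse = ", ")),
             call. = FALSE)
    if (integer && any(x != round(x)))
        stop(sprintf("%s: non-integer '%s' on line(s) %s", path, col,
                     paste(which(x != round(x)) + 1L, collapse = ", ")),
             call. = FALSE)
    x
}

.writeTSV <- function(tab, path) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read / write a per-bead RMS table
#'
#' Tab-delimited table with header columns `label`, `concentration_nM`,
#' `rms_nm`, one row per bead. Malformed rows are reported with their file
#' line numbers. Reading a written table reproduces the data losslessly.
#'
#' @param path file path.
#' @return `readBeadTable`: validated bead table (data.frame).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeBeadTable(simulateTPMTitration(c(0, 6), nBeads = 5, seed = 1), f)
#' head(readBeadTable(f))
#' @export
readBeadTable <- function(path) {
    tab <- .readTSV(path, c("label", "concentration_nM", "rms_nm"))
    out <- data.frame(label = tab$label,
                      concentration_nM = .numericColumn(tab,
                          "concentration_nM", path),
                      rms_nm = .numericColumn(tab, "rms_nm", path),
                      stringsAsFactors = FALSE)
    .validateBeadTable(out)
}

#' @rdname readBeadTable
#' @param beads bead table as produced by [simulateTPMTitration()].
#' @return `writeBeadTable`: the path, invisibly.
#' @export
writeBeadTable <- function(beads, path) {
    .validateBeadTable(beads)
    .writeTSV(beads[, c("label", "concentration_nM", "rms_nm")], path)
}

#' Read / write a bridging-assay count table
#'
#' Tab-delimited table with header columns `label`, `replicate`,
#' `signal_cpm`, `reference_cpm` and optional `background_cpm`.
#'
#' @param path file path.
#' @return `readBridgingTable`: validated data.frame.
#' @export
readBridgingTable <- function(path) {
    tab <- .readTSV(path, c("label", "replicate", "signal_cpm",
                            "reference_cpm"))
    out <- data.frame(label = tab$label,
                      replicate = .numericColumn(tab, "replicate", path,
                                                 integer = TRUE),
                      signal_cpm = .numericColumn(tab, "signal_cpm", path),
                      reference_cpm = .numericColumn(tab, "reference_cpm",
                                                     path),
                      stringsAsFactors = FALSE)
    if ("background_cpm" %in% names(tab))
        out$background_cpm <- .numericColumn(tab, "background_cpm", path)
    out
}

#' @rdname readBridgingTable
#' @param samples bridging table as produced by [simulateBridging()].
#' @return `writeBridgingTable`: the path, invisibly.
#' @export
writeBridgingTable <- function(samples, path) {
    .writeTSV(samples, path)
}

#' Read / write an MST titration table
#'
#' Tab-delimited table of precomputed \eqn{\Delta F_{norm}} points with
#' header columns `conc_uM`, `dfnorm`.
#'
#' @param path file path.
#' @param dnaConc,siteSize metadata passed to [MSTDataset()].
#' @return `readMSTTable`: an [MSTDataset].
#' @export
readMSTTable <- function(path, dnaConc = 40, siteSize = 30L) {
    tab <- .readTSV(path, c("conc_uM", "dfnorm"))
    MSTDataset(.numericColumn(tab, "conc_uM", path),
               .numericColumn(tab, "dfnorm", path),
               dnaConc = dnaConc, siteSize = siteSize)
}

#' @rdname readMSTTable
#' @param dataset an [MSTDataset].
#' @return `writeMSTTable`: the path, invisibly.
#' @export
writeMSTTable <- function(dataset, path) {
    stopifnot(is(dataset, "MSTDataset"))
    .writeTSV(as.data.frame(dataset), path)
}

#' Read / write a count matrix with its sample sheet
#'
#' The count matrix is a genes-by-samples tab-delimited table whose first
#' column (`gene`) holds unique gene identifiers and whose remaining
#' columns are integer counts; the sample sheet is a two-column
#' tab-delimited table (`sample`, `strain`) mapping every matrix column to
#' a strain. Write-then-read round-trips losslessly.
#'
#' @param matrixPath,samplesheetPath file paths.
#' @return `readCountMatrix`: a
#'   [SummarizedExperiment::SummarizedExperiment] with assay `counts` and
#'   `colData` column `strain`.
#' @examples
#' se <- simulateCountMatrix(nGenes = 20, seed = 1)
#' m <- tempfile(fileext = ".tsv"); s <- tempfile(fileext = ".tsv")
#' writeCountMatrix(se, m, s)
#' readCountMatrix(m, s)
#' @export
readCountMatrix <- function(matrixPath, samplesheetPath) {
    tab <- .readTSV(matrixPath, "gene")
    if (anyDuplicated(tab$gene))
        stop(sprintf("%s: duplicated gene id(s): %s", matrixPath,
                     paste(unique(tab$gene[duplicated(tab$gene)]),
                           collapse = ", ")), call. = FALSE)
    sampleCols <- setdiff(names(tab), "gene")
    if (length(sampleCols) == 0L)
        stop(sprintf("%s: no sample columns", matrixPath), call. = FALSE)
    counts <- vapply(sampleCols, function(cn) {
        x <- .numericColumn(tab, cn, matrixPath, integer = TRUE)
        if (any(x < 0))
            stop(sprintf("%s: negative count in column '%s'", matrixPath,
                         cn), call. = FALSE)
        as.integer(x)
    }, integer(nrow(tab)))
    if (is.null(dim(counts)))
        counts <- matrix(counts, nrow = nrow(tab),
                         dimnames = list(NULL, sampleCols))
    rownames(counts) <- tab$gene

    sheet <- .readTSV(samplesheetPath, c("sample", "strain"))
    unmapped <- setdiff(sampleCols, sheet$sample)
    if (length(unmapped))
        stop(sprintf("%s: sample(s) not in sample sheet: %s", matrixPath,
                     paste(unmapped, collapse = ", ")), call. = FALSE)
    strain <- sheet$strain[match(sampleCols, sheet$sample)]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(strain = strain,
                                       row.names = sampleCols))
}

#' @rdname readCountMatrix
#' @param se a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` and `colData` column `strain`.
#' @return `writeCountMatrix`: `matrixPath`, invisibly.
#' @export
writeCountMatrix <- function(se, matrixPath, samplesheetPath) {
    counts <- SummarizedExperiment::assay(se, "counts")
    tab <- data.frame(gene = rownames(counts), counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    .writeTSV(tab, matrixPath)
    .writeTSV(data.frame(sample = colnames(counts),
                         strain = .strainOf(se),
                         stringsAsFactors = FALSE), samplesheetPath)
    invisible(matrixPath)
}

#' Write a fit report as JSON with provenance
#'
#' Serializes a [HillFit], [MvHFit], [LogisticNull] or [DEGResult] summary
#' to JSON together with a provenance block (package version, fit
#' parameters, optional seed) so every output records the configuration
#' that produced it.
#'
#' @param fit the fit object.
#' @param path output path.
#' @param seed optional integer recorded in the provenance block.
#' @param extra optional named list merged into the report.
#' @return the path, invisibly.
#' @examples
#' cc <- 2:10
#' fit <- fitHill(OccupancyCurve(cc, hillTheta(cc, 6.1, 6.5)))
#' writeFitReport(fit, tempfile(fileext = ".json"))
#' @export
writeFitReport <- function(fit, path, seed = NULL, extra = list()) {
    body <-
        if (is(fit, "HillFit")) list(
            model = "hill", kd_nM = kd(fit), n = hillCoefficient(fit),
            kd_se = kdSe(fit), n_se = fit@nSe,
            residual_ss = residualSS(fit),
            curve = as.data.frame(fit@curve))
        else if (is(fit, "MvHFit")) list(
            model = "mcghee_von_hippel", kd_uM = kd(fit),
            amplitude = amplitude(fit), kd_se = kdSe(fit),
            residual_ss = residualSS(fit), site_size_bp = siteSize(fit))
        else if (is(fit, "LogisticNull")) list(
            model = "logistic_null", location = nullLocation(fit),
            scale = nullScale(fit))
        else if (is(fit, "DEGResult")) list(
            model = "deg_logistic", strain = fit@strain,
            deletion_strain = fit@deletionStrain,
            threshold = fit@threshold,
            n_genes = nrow(degTable(fit)),
            n_deg = sum(degTable(fit)$isDeg),
            null = list(location = nullLocation(fit@null),
                        scale = nullScale(fit@null)))
        else stop("unsupported fit object of class ", class(fit),
                  call. = FALSE)
    body$provenance <- c(list(package = "NAPbind",
                              version = as.character(
                                  packageVersion("NAPbind")),
                              seed = seed), extra)
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

#' Read / write protein FASTA
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] and
#' [Biostrings::writeXStringSet()] pinning the plain uncompressed FASTA
#' dialect used throughout the package.
#'
#' @param path file path.
#' @return `readProteinFasta`: an [Biostrings::AAStringSet].
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    Biostrings::readAAStringSet(path, format = "fasta")
}

#' @rdname readProteinFasta
#' @param x an [Biostrings::AAStringSet].
#' @return `writeProteinFasta`: the path, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
    stopifnot(is(x, "AAStringSet"))
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 60L)
    invisible(path)
}
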
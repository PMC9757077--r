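#' @include AllClasses.R
NULL

#' Classify Rok-family proteins by sequence length
#'
#' Full-length Rok and the short variant sRok (which lacks the central
#' linker) separate cleanly by length: sequences of at least 190 amino
#' acids are classified as Rok, sequences of at most 189 amino acids as
#' sRok.
#'
#' @param x an [Biostrings::AAStringSet], or a character vector of
#'   ungapped amino-acid sequences.
#' @return character vector of labels (`"Rok"` or `"sRok"`), named after
#'   the input sequences where names are available.
#' @examples
#' classifyRokLength(c(a = strrep("M", 190), b = strrep("M", 189)))
#' @export
classifyRokLength <- function(x) {
    if (is(x, "AAStringSet")) {
        lens <- Biostrings::width(x)
        seqs <- as.character(x)
    } else if (is.character(x)) {
        lens <- nchar(x)
        seqs <- x
    } else {
        stop("'x' must be an AAStringSet or character vector",
             call. = FALSE)
    }
    if (length(lens) == 0L || any(lens == 0L))
        stop("sequences must be non-empty", call. = FALSE)
    if (any(grepl("-", seqs, fixed = TRUE)))
        stop("sequences must be ungapped", call. = FALSE)
    setNames(ifelse(lens >= 190L, "Rok", "sRok"), names(x))
}

#' Column frequencies and information content of a protein alignment
#'
#' Computes, for every column of a multiple alignment, the residue
#' frequency vector over the 20 standard amino acids (gaps excluded from
#' normalization) and the information content
#' \eqn{IC = \log_2 20 - H} in bits, with \eqn{H} the Shannon entropy of
#' the column frequencies - the quantity displayed by profile-based
#' sequence logos. Optional pseudocounts regularize small alignments.
#' All-gap columns get IC 0, an all-`NA` frequency vector, and the
#' `allGap` flag.
#'
#' @param aln an [Biostrings::AAStringSet] of equal-width aligned
#'   sequences (gap character `-`), or a character vector of such
#'   sequences.
#' @param pseudocount numeric >= 0 added to every residue count before
#'   normalization; default 0 (none).
#' @return an [AlignmentProfile].
#' @examples
#' p <- alignmentProfile(c("MK-", "MR-"))
#' informationContent(p)
#' @export
alignmentProfile <- function(aln, pseudocount = 0) {
    .assertScalarNumeric(pseudocount, "pseudocount", 0, Inf)
    if (is.character(aln)) aln <- Biostrings::AAStringSet(aln)
    stopifnot(is(aln, "AAStringSet"))
    if (length(aln) < 1L)
        stop("alignment must contain at least one sequence", call. = FALSE)
    w <- Biostrings::width(aln)
    if (length(unique(w)) != 1L)
        stop("ragged alignment: sequences differ in length", call. = FALSE)
    aa <- Biostrings::AA_STANDARD  # the 20 standard residues
    cm <- Biostrings::consensusMatrix(aln)
    L <- w[1]
    counts <- matrix(0, nrow = 20L, ncol = L, dimnames = list(aa, NULL))
    present <- intersect(rownames(cm), aa)
    counts[present, ] <- cm[present, , drop = FALSE]
    unknown <- setdiff(rownames(cm), c(aa, "-", ".", "+"))
    if (length(unknown) && any(cm[unknown, , drop = FALSE] > 0))
        stop("non-standard residue(s) in alignment: ",
             paste(unknown[rowSums(cm[unknown, , drop = FALSE]) > 0],
                   collapse = ", "), call. = FALSE)

    tot <- colSums(counts)
    allGap <- tot == 0
    counts <- counts + pseudocount
    freq <- matrix(NA_real_, nrow = 20L, ncol = L,
                   dimnames = list(aa, NULL))
    ok <- which(!allGap)
    if (length(ok))
        freq[, ok] <- sweep(counts[, ok, drop = FALSE], 2L,
                            colSums(counts[, ok, drop = FALSE]), "/")
    ic <- numeric(L)
    for (j in ok) {
        f <- freq[, j]
        f <- f[f > 0]
        ic[j] <- log2(20) + sum(f * log2(f))
    }
    ic[allGap] <- 0
    ic <- pmin(pmax(ic, 0), log2(20))
    new("AlignmentProfile", frequencies = freq, ic = ic,
        nSequences = length(aln), allGap = allGap)
}
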
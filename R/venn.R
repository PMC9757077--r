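#' @include AllClasses.R
NULL

#' Seven-region partition of three gene sets
#'
#' Decomposes three sets of identifiers into the 7 disjoint regions of a
#' three-set Venn diagram (exclusive single-set regions, pairwise-only
#' intersections, and the triple intersection) plus the union size and
#' each region's percentage of the union. The regions always reconstruct
#' each input set: a set's total is the sum of its 4 regions, and the 7
#' regions sum to the union.
#'
#' @param setA,setB,setC vectors of identifiers (duplicates are ignored).
#' @param labels character(3), display names for the sets.
#' @return a [VennPartition].
#' @examples
#' vennPartition(c(1, 2), c(2, 3), 2)
#' @export
vennPartition <- function(setA, setB, setC, labels = c("A", "B", "C")) {
    setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
    u <- unique(c(setA, setB, setC))
    inA <- u %in% setA; inB <- u %in% setB; inC <- u %in% setC
    regions <- c(
        onlyA = sum(inA & !inB & !inC),
        onlyB = sum(!inA & inB & !inC),
        onlyC = sum(!inA & !inB & inC),
        AB    = sum(inA & inB & !inC),
        AC    = sum(inA & !inB & inC),
        BC    = sum(!inA & inB & inC),
        ABC   = sum(inA & inB & inC))
    unionSize <- length(u)
    pct <- if (unionSize > 0) 100 * regions / unionSize else regions * 0
    new("VennPartition",
        regions = setNames(as.numeric(regions), names(regions)),
        unionSize = as.numeric(unionSize),
        percentages = setNames(as.numeric(pct), names(regions)),
        setNames = as.character(labels))
}
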
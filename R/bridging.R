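#' @include AllClasses.R
NULL

#' DNA recovery percentage from scintillation counts
#'
#' Converts the scintillation signal of a bridging pull-down sample to a
#' DNA recovery percentage relative to a reference sample containing the
#' same amount of labeled DNA:
#' \deqn{recovery = 100 \times \frac{signal - background}
#'       {reference - background}.}
#' Negative values (signal below background) are clipped to 0; values above
#' 100 are kept but flagged via the `"flagged"` attribute.
#'
#' @param signal numeric, sample counts (cpm), >= 0.
#' @param reference numeric, reference counts (cpm); must exceed
#'   `background`. Around 8000 cpm in a typical titration.
#' @param background numeric, background counts (cpm), default 0.
#' @return numeric vector of recovery percentages with attribute
#'   `"flagged"`: logical, `TRUE` where the raw value fell outside
#'   \[0, 100\].
#' @examples
#' recoveryPercent(4000, 8000)  # 50
#' recoveryPercent(0, 8000)     # 0
#' @export
recoveryPercent <- function(signal, reference, background = 0) {
    k <- max(length(signal), length(reference), length(background))
    signal <- rep_len(as.numeric(signal), k)
    reference <- rep_len(as.numeric(reference), k)
    background <- rep_len(as.numeric(background), k)
    if (any(!is.finite(signal) | signal < 0))
        stop("'signal' must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(background) | background < 0))
        stop("'background' must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(reference) | reference <= background))
        stop("'reference' must exceed 'background'", call. = FALSE)
    raw <- 100 * (signal - background) / (reference - background)
    out <- pmax(raw, 0)
    attr(out, "flagged") <- raw < 0 | raw > 100
    out
}

#' Summarize a bridging titration across replicates
#'
#' Per-condition mean and sample (n-1) standard deviation of DNA recovery,
#' the summary plotted as mean +/- SD over independent measurements.
#' Conditions with fewer than `minReplicates` replicates are flagged as
#' below the replication standard (assays are performed at least in
#' triplicate).
#'
#' @param samples data.frame with columns `label`, `signal_cpm`,
#'   `reference_cpm` and optionally `background_cpm` (default 0), one row
#'   per replicate, e.g. from [simulateBridging()] or
#'   [readBridgingTable()].
#' @param minReplicates integer, replication standard (default 3).
#' @return data.frame with one row per condition, in first-appearance
#'   order: `label`, `mean_recovery`, `sd_recovery` (`NA` when n < 2),
#'   `n_replicates`, `below_replication_standard`.
#' @examples
#' tab <- data.frame(label = "a", signal_cpm = c(4000, 4800, 5600),
#'                   reference_cpm = 8000)
#' summarizeTitration(tab)
#' @export
summarizeTitration <- function(samples, minReplicates = 3L) {
    if (!is.data.frame(samples) || nrow(samples) == 0L)
        stop("'samples' must be a non-empty data.frame", call. = FALSE)
    need <- c("label", "signal_cpm", "reference_cpm")
    miss <- setdiff(need, names(samples))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    bg <- if ("background_cpm" %in% names(samples))
        samples$background_cpm else 0
    rec <- recoveryPercent(samples$signal_cpm, samples$reference_cpm, bg)
    labels <- unique(samples$label)  # preserve input order
    out <- lapply(labels, function(lab) {
        r <- rec[samples$label == lab]
        data.frame(label = lab, mean_recovery = mean(r),
                   sd_recovery = if (length(r) >= 2L) sd(r) else NA_real_,
                   n_replicates = length(r),
                   below_replication_standard = length(r) < minReplicates)
    })
    do.call(rbind, out)
}
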
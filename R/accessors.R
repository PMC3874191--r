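## Accessors and show() methods. Slots are never reached into by user code.

#' @describeIn WindowGrid-class number of windows in the grid
#' @param x a `WindowGrid` or an object carrying one.
#' @export
nWindows <- function(x) {
    if (is(x, "WindowGrid")) length(x@ranges) else nWindows(trackGrid(x))
}

#' @describeIn WindowGrid-class the window `GRanges`
#' @export
windowRanges <- function(x) {
    if (is(x, "WindowGrid")) x@ranges else windowRanges(trackGrid(x))
}

#' @describeIn WindowGrid-class nominal window width (bp)
#' @export
windowSize <- function(x) {
    if (is(x, "WindowGrid")) x@windowSize else windowSize(trackGrid(x))
}

#' @describeIn WindowGrid-class genome layout (`Seqinfo`) of the grid
#' @export
genomeLayout <- function(x) {
    if (is(x, "WindowGrid")) seqinfo(x@ranges) else genomeLayout(trackGrid(x))
}

#' @describeIn WindowGrid-class flags windows shorter than the nominal width
#' @export
isPartialWindow <- function(x) {
    g <- if (is(x, "WindowGrid")) x else trackGrid(x)
    GenomicRanges::width(g@ranges) < g@windowSize
}

#' Grid carried by a windowed track
#' @param x a `CountTrack`, `RatioProfile` or `TrepTrack`.
#' @return the underlying [WindowGrid-class].
#' @export
trackGrid <- function(x) x@grid

#' Per-window read counts of a `CountTrack`
#' @param x a `CountTrack`.
#' @export
readCounts <- function(x) x@counts

#' Total read count of a `CountTrack`
#' @param x a `CountTrack`.
#' @export
totalReads <- function(x) x@total

#' Per-window values of a `RatioProfile` (`NA` where excluded)
#' @param x a `RatioProfile`.
#' @export
profileValues <- function(x) x@values

#' Exclusion mask of a `RatioProfile`
#' @param x a `RatioProfile`.
#' @export
excludedWindows <- function(x) x@excluded

#' Normalization state tag of a `RatioProfile`
#' @param x a `RatioProfile`.
#' @export
normalizationTag <- function(x) x@normalization

#' Bulk replicated fraction a profile was scaled to (`NA` unless bulk-scaled)
#' @param x a `RatioProfile`.
#' @export
bulkFraction <- function(x) x@bulkFraction

#' Windows where smoothing retained the raw value
#' @param x a `RatioProfile`.
#' @export
notSmoothedFlags <- function(x) x@notSmoothed

#' Per-window Trep values of a `TrepTrack` (`NA` where masked)
#' @param x a `TrepTrack`.
#' @export
trepValues <- function(x) x@trep

#' Per-window residual norms of the sigmoid fits
#' @param x a `TrepTrack`.
#' @export
fitResiduals <- function(x) x@residual

#' Per-window optimizer convergence flags
#' @param x a `TrepTrack`.
#' @export
fitConverged <- function(x) x@converged

#' Per-window mask reasons (`""` where fitted)
#' @param x a `TrepTrack`.
#' @export
maskReasons <- function(x) x@maskReason

#' Origin table of a `ReplicationModel`
#' @param x a `ReplicationModel`.
#' @export
modelOrigins <- function(x) x@origins

#' Genome layout of a `ReplicationModel`
#' @param x a `ReplicationModel`.
#' @export
modelLayout <- function(x) x@layout

#' S-phase interval `[start, end]` of a `ReplicationModel`, in minutes
#' @param x a `ReplicationModel`.
#' @export
sPhaseInterval <- function(x) c(x@sPhaseStart, x@sPhaseStart + x@sPhaseDuration)

#' Fork velocity (bp/min) of a `ReplicationModel`
#' @param x a `ReplicationModel`.
#' @export
forkVelocity <- function(x) x@forkVelocity

#' Fitted parameters (c, d, b, e, f) of a `BulkCurve`
#' @param x a `BulkCurve`.
#' @export
bulkParams <- function(x) x@params

setMethod("show", "WindowGrid", function(object) {
    sl <- seqlengths(genomeLayout(object))
    cat(sprintf("WindowGrid: %d windows of %d bp over %d chromosome(s) (%s bp)\n",
        nWindows(object), windowSize(object), length(sl),
        format(sum(as.numeric(sl)), big.mark = ",")))
})

setMethod("show", "CountTrack", function(object) {
    cat(sprintf("CountTrack: %s reads over %d windows (mean %.1f/window)\n",
        format(object@total, big.mark = ","), nWindows(object),
        object@total / nWindows(object)))
})

setMethod("show", "RatioProfile", function(object) {
    v <- object@values[!object@excluded]
    cat(sprintf(
        "RatioProfile [%s]: %d/%d windows included, range [%.3f, %.3f]%s\n",
        object@normalization, length(v), nWindows(object),
        if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
        if (!is.na(object@bulkFraction))
            sprintf(", bulk fraction %.3f", object@bulkFraction) else ""))
})

setMethod("show", "TrepTrack", function(object) {
    ok <- !is.na(object@trep)
    cat(sprintf("TrepTrack: %d/%d windows fitted, Trep range [%.1f, %.1f] min\n",
        sum(ok), nWindows(object),
        if (any(ok)) min(object@trep[ok]) else NA,
        if (any(ok)) max(object@trep[ok]) else NA))
})

setMethod("show", "BulkCurve", function(object) {
    cat(sprintf(
        "BulkCurve: %d timepoints, midpoint (f = 0.5) at %.1f min\n",
        length(object@times),
        tryCatch(trepLikeMidpoint(object@params), error = function(e) NA)))
})

setMethod("show", "ReplicationModel", function(object) {
    cat(sprintf(
        "ReplicationModel: %d origins on %d chromosome(s), v = %g bp/min, S phase [%g, %g] min\n",
        nrow(object@origins), length(seqlengths(object@layout)),
        object@forkVelocity, object@sPhaseStart,
        object@sPhaseStart + object@sPhaseDuration))
})

## time at which the fitted bulk sigmoid crosses one half (for show())
trepLikeMidpoint <- function(p) {
    arg <- ((p[["d"]] - p[["c"]]) / (0.5 - p[["c"]]))^(1 / p[["f"]]) - 1
    p[["e"]] + log(arg) / p[["b"]]
}
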
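## Peak calling (peakdet), origin matching, and the HU peak-height versus
## replication-time relationship.

#' Alternating maxima/minima detection (peakdet)
#'
#' Scans left to right keeping a running extremum; a running maximum is
#' confirmed as a peak once the signal has dropped more than `delta` below
#' it, after which the scanner seeks a minimum (confirmed on a rise of more
#' than `delta`), and so on, alternating. Ties resolve to the earliest
#' index. The first extremum may be of either kind.
#'
#' @param values ordered numeric sequence (length >= 1, no NAs).
#' @param delta confirmation threshold (> 0) on the value scale.
#' @return list with data.frames `maxima` and `minima`, each with columns
#'   `index` and `value`.
#' @export
peakdet <- function(values, delta) {
    if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
        stop("delta must be a single value > 0")
    if (any(!is.finite(values))) stop("values must be finite")
    maxI <- integer(0); maxV <- numeric(0)
    minI <- integer(0); minV <- numeric(0)
    mn <- Inf; mx <- -Inf
    mnPos <- NA_integer_; mxPos <- NA_integer_
    lookForMax <- TRUE
    for (i in seq_along(values)) {
        this <- values[i]
        if (this > mx) { mx <- this; mxPos <- i }
        if (this < mn) { mn <- this; mnPos <- i }
        if (lookForMax) {
            if (this < mx - delta) {
                maxI <- c(maxI, mxPos); maxV <- c(maxV, mx)
                mn <- this; mnPos <- i
                lookForMax <- FALSE
            }
        } else {
            if (this > mn + delta) {
                minI <- c(minI, mnPos); minV <- c(minV, mn)
                mx <- this; mxPos <- i
                lookForMax <- TRUE
            }
        }
    }
    list(maxima = data.frame(index = maxI, value = maxV),
        minima = data.frame(index = minI, value = minV))
}

#' Call peaks on a windowed profile or Trep track
#'
#' Excluded/masked windows split each chromosome into independent
#' segments; [peakdet()] runs per segment, so peaks are never called
#' inside data gaps. Peak positions are window centers. For a Trep track
#' set `invert = TRUE`: origins are local minima of replication time, so
#' minima are the origin calls; on copy-number profiles origin calls are
#' maxima.
#'
#' @param x a [RatioProfile-class] or [TrepTrack-class].
#' @param delta [peakdet()] threshold; on the relative-copy-number scale
#'   0.1 is a reasonable default (about twice the counting-noise sd at
#'   1000 reads/window), on the Trep scale use minutes.
#' @param invert report minima as the origin-call kind (Trep tracks).
#' @return width-1 `GRanges` at peak window centers with columns `kind`
#'   (`"max"`/`"min"`), `value` and `windowIndex`;
#'   `metadata()$originKind` records which kind is the origin call.
#' @export
callPeaks <- function(x, delta = 0.1, invert = FALSE) {
    grid <- trackGrid(x)
    vals <- if (is(x, "TrepTrack")) trepValues(x) else profileValues(x)
    gr <- windowRanges(grid)
    chrom <- as.character(seqnames(gr))
    recs <- list()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        ok <- is.finite(vals[idx])
        r <- rle(ok)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in seq_along(r$lengths)) {
            if (!r$values[j] || r$lengths[j] < 1L) next
            seg <- idx[starts[j]:ends[j]]
            pd <- peakdet(vals[seg], delta)
            if (nrow(pd$maxima))
                recs[[length(recs) + 1L]] <- data.frame(
                    windowIndex = seg[pd$maxima$index],
                    value = pd$maxima$value, kind = "max")
            if (nrow(pd$minima))
                recs[[length(recs) + 1L]] <- data.frame(
                    windowIndex = seg[pd$minima$index],
                    value = pd$minima$value, kind = "min")
        }
    }
    if (!length(recs)) {
        out <- GRanges(seqinfo = genomeLayout(grid))
        mcols(out)$kind <- character(0)
        mcols(out)$value <- numeric(0)
        mcols(out)$windowIndex <- integer(0)
        metadata(out)$originKind <- if (invert) "min" else "max"
        return(out)
    }
    df <- do.call(rbind, recs)
    wgr <- gr[df$windowIndex]
    center0 <- (GenomicRanges::start(wgr) - 1L) +
        GenomicRanges::width(wgr) %/% 2L
    out <- GRanges(seqnames(wgr), IRanges(center0 + 1L, width = 1L),
        seqinfo = genomeLayout(grid))
    mcols(out)$kind <- df$kind
    mcols(out)$value <- df$value
    mcols(out)$windowIndex <- df$windowIndex
    out <- out[order(match(as.character(seqnames(out)),
        seqlevels(out)), GenomicRanges::start(out))]
    metadata(out)$originKind <- if (invert) "min" else "max"
    out
}

#' Match called peaks to known origins
#'
#' Each peak (of the origin-call kind) is matched to the nearest origin on
#' the same chromosome by absolute midpoint distance; equidistant ties
#' resolve to the leftmost origin. Peaks on origin-free chromosomes are
#' flagged unmatched.
#'
#' @param peaks `GRanges` from [callPeaks()].
#' @param origins width-1 `GRanges` of origin midpoints (see
#'   [readOriginsBed()]).
#' @param kind which peak kind to match; defaults to the call kind
#'   recorded by [callPeaks()].
#' @return list with `matches` (data.frame: chrom, peakPos, peakValue,
#'   origin, originPos, distance (signed, peak - origin), matched) and
#'   `medianAbsDistance` over matched peaks.
#' @export
matchToOrigins <- function(peaks, origins, kind = NULL) {
    if (length(peaks) == 0L || length(origins) == 0L)
        stop("peaks and origins must be non-empty")
    if (is.null(kind))
        kind <- metadata(peaks)$originKind %||% "max"
    sel <- peaks[mcols(peaks)$kind == kind]
    pChrom <- as.character(seqnames(sel))
    pPos <- GenomicRanges::start(sel)
    oChrom <- as.character(seqnames(origins))
    oPos <- GenomicRanges::start(origins)
    oName <- mcols(origins)$name
    n <- length(sel)
    origin <- character(n); originPos <- rep(NA_integer_, n)
    distance <- rep(NA_integer_, n); matched <- rep(FALSE, n)
    for (i in seq_len(n)) {
        j <- which(oChrom == pChrom[i])
        if (!length(j)) { origin[i] <- NA_character_; next }
        d <- pPos[i] - oPos[j]
        k <- j[which.min(abs(d))]   # origins sorted: first of a tie is leftmost
        origin[i] <- oName[k]
        originPos[i] <- oPos[k]
        distance[i] <- pPos[i] - oPos[k]
        matched[i] <- TRUE
    }
    matches <- data.frame(chrom = pChrom, peakPos = pPos,
        peakValue = mcols(sel)$value, origin = origin,
        originPos = originPos, distance = distance, matched = matched)
    list(matches = matches,
        medianAbsDistance = median(abs(distance[matched])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' HU peak height versus median replication time
#'
#' Pairs each HU copy-number peak with the Trep value of the window it
#' falls in and reports the Pearson correlation: later-activating origins
#' synthesize less DNA under HU, so heights should correlate negatively
#' with activation time.
#'
#' @param huPeaks `GRanges` of HU profile maxima (from [callPeaks()]).
#' @param trep a [TrepTrack-class] on the same genome.
#' @return list with `pairs` (data.frame: height, trep) and
#'   `correlation` (Pearson; `NA` with a warning when degenerate).
#' @export
peakHeightVsTime <- function(huPeaks, trep) {
    sel <- huPeaks[mcols(huPeaks)$kind == "max"]
    hits <- GenomicRanges::findOverlaps(sel, windowRanges(trep))
    h <- mcols(sel)$value[S4Vectors::queryHits(hits)]
    tv <- trepValues(trep)[S4Vectors::subjectHits(hits)]
    ok <- is.finite(tv)
    h <- h[ok]; tv <- tv[ok]
    if (length(h) < 3L) stop("fewer than 3 paired points")
    r <- if (sd(h) == 0 || sd(tv) == 0) {
        warning("correlation undefined: constant heights or times")
        NA_real_
    } else cor(h, tv)
    list(pairs = data.frame(height = h, trep = tv), correlation = r)
}
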
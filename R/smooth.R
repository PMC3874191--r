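## Fourier low-pass smoothing of windowed profiles.
##
## Per chromosome the terminal 5 kb are trimmed off (they keep their raw
## values, flagged "not smoothed"); the interior segment has short runs of
## excluded windows linearly interpolated, is mirror-padded (even
## extension), discrete-Fourier-transformed, components with wavelength
## below the cutoff are zeroed, and the inverse transform is taken. The
## even extension makes the filter an exact orthogonal projection:
## smoothing is idempotent, linear and never increases signal energy on
## the interior. Originally-excluded windows are re-masked afterwards, and
## windows inside low-density regions keep their raw values, flagged.

#' Low-density / chromosome-end mask for smoothing
#'
#' Marks windows where smoothing is withheld: runs of more than
#' `maxGapRun` consecutive excluded windows, dilated by two windows on
#' each side, plus all windows within `endExclusion` bp of either
#' chromosome end.
#'
#' @param profile a [RatioProfile-class].
#' @param maxGapRun longest run of consecutive excluded windows tolerated
#'   inside a smoothed region (default 5).
#' @param endExclusion bp excluded at each chromosome end (default 5000).
#' @return logical per-window mask (TRUE = not smoothed there).
#' @export
densityMask <- function(profile, maxGapRun = 5L, endExclusion = 5000L) {
    grid <- trackGrid(profile)
    gr <- windowRanges(grid)
    chrom <- as.character(seqnames(gr))
    sl <- seqlengths(genomeLayout(grid))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    mask <- start0 < endExclusion | end0 > sl[chrom] - endExclusion
    excl <- excludedWindows(profile)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        r <- rle(excl[idx])
        pos <- cumsum(c(1L, r$lengths))
        for (j in seq_along(r$lengths)) {
            if (r$values[j] && r$lengths[j] > maxGapRun) {
                lo <- max(1L, pos[j] - 2L)
                hi <- min(length(idx), pos[j + 1L] - 1L + 2L)
                mask[idx[lo:hi]] <- TRUE
            }
        }
    }
    unname(mask)
}

## exact low-pass projection of one uniform segment via even extension
.lowpassSegment <- function(x, w, minWavelength) {
    m <- length(x)
    y <- c(x, rev(x))
    n2 <- 2L * m
    k <- seq_len(n2) - 1L
    keff <- pmin(k, n2 - k)
    keep <- keff == 0L | (n2 * w / keff) >= minWavelength
    fy <- fft(y)
    fy[!keep] <- 0 + 0i
    Re(fft(fy, inverse = TRUE))[seq_len(m)] / n2
}

#' Fourier-transform smoothing of a windowed profile
#'
#' Removes all Fourier components with wavelength below `minWavelength`
#' from each chromosome's interior signal (see the file-level notes for
#' the boundary treatment). Windows within `endExclusion` bp of a
#' chromosome end and windows inside low-density regions (see
#' [densityMask()]) carry their raw values with the not-smoothed flag set;
#' excluded windows stay excluded. Chromosomes with fewer than 16 included
#' windows are left unsmoothed with a warning.
#'
#' @param profile a [RatioProfile-class] on a uniform grid.
#' @param minWavelength shortest retained wavelength in bp (default
#'   20000; must be at least twice the window size).
#' @param endExclusion bp left unsmoothed at chromosome ends (default 5000).
#' @param maxGapRun see [densityMask()].
#' @return a [RatioProfile-class] with the same normalization tag and
#'   `notSmoothedFlags()` marking raw-carried windows.
#' @export
fourierSmooth <- function(profile, minWavelength = 20000L,
        endExclusion = 5000L, maxGapRun = 5L) {
    grid <- trackGrid(profile)
    w <- windowSize(grid)
    if (minWavelength < 2 * w)
        stop("minWavelength must be at least twice the window size")
    gr <- windowRanges(grid)
    chrom <- as.character(seqnames(gr))
    sl <- seqlengths(genomeLayout(grid))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    vals <- profileValues(profile)
    excl <- excludedWindows(profile)
    dmask <- densityMask(profile, maxGapRun = maxGapRun,
        endExclusion = endExclusion)
    out <- vals
    flag <- rep(FALSE, length(vals))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        if (sum(!excl[idx]) < 16L) {
            warning("chromosome ", ch,
                " has fewer than 16 included windows; left unsmoothed")
            flag[idx] <- !excl[idx]
            next
        }
        endZone <- start0[idx] < endExclusion |
            end0[idx] > sl[ch] - endExclusion
        flag[idx[endZone & !excl[idx]]] <- TRUE
        interior <- idx[!endZone]
        if (length(interior) < 4L) next
        x <- vals[interior]
        miss <- !is.finite(x)
        if (all(miss)) { flag[interior] <- FALSE; next }
        if (any(miss)) {
            fill <- approx(x = which(!miss), y = x[!miss],
                xout = which(miss), rule = 2)$y
            x[miss] <- fill
        }
        sm <- .lowpassSegment(x, w, minWavelength)
        out[interior] <- sm
        ## low-density regions keep the raw value, flagged
        dense <- dmask[interior]
        out[interior[dense]] <- vals[interior[dense]]
        flag[interior[dense & !excl[interior]]] <- TRUE
        ## originally-excluded (interpolated) windows are re-masked
        out[interior[excl[interior]]] <- NA_real_
    }
    out[excl] <- NA_real_
    newRatioProfile(grid, out, excluded = excl,
        normalization = normalizationTag(profile),
        bulkFraction = bulkFraction(profile), notSmoothed = flag)
}
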
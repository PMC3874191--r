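## Measurement precision: coefficient of variation of nonreplicating /
## nonreplicating ratio profiles versus window size and read depth, and the
## theoretical floor for randomly distributed reads.

#' Observed coefficient of variation of a ratio profile
#'
#' Builds the mean-1 normalized ratio of two count tracks (applying the
#' quarter-of-expected exclusion rule) and returns sd/mean over included
#' windows (sample standard deviation, n - 1 denominator). CoV is
#' scale-free, so the normalization cannot change it.
#'
#' @param a,b [CountTrack-class] objects on the same grid.
#' @export
covObserved <- function(a, b) {
    p <- ratioProfile(a, b)
    v <- profileValues(p)[!excludedWindows(p)]
    if (length(v) < 2L) stop("fewer than 2 included windows")
    sd(v) / mean(v)
}

#' Theoretical minimum CoV for a ratio of two Poisson counts
#'
#' First-order (delta-method) coefficient of variation of the ratio of two
#' independent Poisson counts with means `nA` and `nB`:
#' `sqrt(1/nA + 1/nB)`. This is the floor attained when reads fall randomly
#' into windows.
#'
#' @param nA,nB expected reads per window in each sample.
#' @export
covTheoretical <- function(nA, nB) {
    if (any(nA <= 0) || any(nB <= 0)) stop("depths must be > 0")
    sqrt(1 / nA + 1 / nB)
}

#' CoV sweep over window sizes and read depths
#'
#' Subsamples each read set to the requested depth fractions (seeded
#' permutation then prefix take, so the fraction is exact and the draw
#' deterministic), re-windows at each window size, and tabulates observed
#' versus theoretical CoV.
#'
#' @param a,b width-1 `GRanges` of read anchors on a shared layout.
#' @param layout `Seqinfo` genome layout.
#' @param windowSizes window widths (bp) to evaluate.
#' @param fractions depth fractions in (0, 1].
#' @param seed integer seed for the subsampling permutations.
#' @return data.frame with one row per (windowSize, fraction): expected
#'   depths `nA`/`nB`, `covObserved`, `covTheoretical`, and `flagged` when
#'   the expected depth falls below 1 read/window.
#' @export
covSweep <- function(a, b, layout, windowSizes = c(1000L, 2000L),
        fractions = 1, seed = 1L) {
    if (any(fractions <= 0 | fractions > 1))
        stop("fractions must be in (0, 1]")
    genomeSize <- sum(as.numeric(seqlengths(layout)))
    out <- vector("list", length(windowSizes) * length(fractions))
    k <- 0L
    with_seed(as.integer(seed), {
        permA <- sample.int(length(a))
        permB <- sample.int(length(b))
        for (f in fractions) {
            subA <- GenomicRanges::sort(a[permA[seq_len(round(f * length(a)))]])
            subB <- GenomicRanges::sort(b[permB[seq_len(round(f * length(b)))]])
            for (w in windowSizes) {
                grid <- windowGrid(layout, windowSize = w)
                ta <- countReads(subA, grid)
                tb <- countReads(subB, grid)
                nA <- expectedPerWindow(totalReads(ta), genomeSize, w)
                nB <- expectedPerWindow(totalReads(tb), genomeSize, w)
                obs <- tryCatch(covObserved(ta, tb),
                    error = function(e) NA_real_)
                k <- k + 1L
                out[[k]] <- data.frame(windowSize = w, fraction = f,
                    nA = nA, nB = nB, covObserved = obs,
                    covTheoretical = covTheoretical(nA, nB),
                    flagged = min(nA, nB) < 1)
            }
        }
    })
    do.call(rbind, out)
}
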
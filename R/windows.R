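## Windowing, counting and the three profile normalizations.

#' Build a fixed-width window grid over a genome
#'
#' Windows tile each chromosome without gaps or overlap; the last window of
#' a chromosome is shortened to the chromosome end when necessary.
#'
#' @param layout `Seqinfo` genome layout (see [readChromSizes()]).
#' @param windowSize window width in bp (default 1000).
#' @return a [WindowGrid-class].
#' @export
windowGrid <- function(layout, windowSize = 1000L) {
    windowSize <- as.integer(windowSize)
    if (is.na(windowSize) || windowSize < 1L)
        stop("windowSize must be >= 1")
    gr <- tileGenome(seqlengths(layout), tilewidth = windowSize,
        cut.last.tile.in.chrom = TRUE)
    new("WindowGrid", ranges = gr, windowSize = windowSize)
}

#' Build a count track from per-window counts
#'
#' Useful when counts come from elsewhere than [countReads()] — a
#' precomputed count table, or a statistical draw such as `rpois()`.
#'
#' @param grid a [WindowGrid-class].
#' @param counts non-negative integer counts, one per window.
#' @return a [CountTrack-class].
#' @export
countTrack <- function(grid, counts) {
    if (length(counts) != nWindows(grid))
        stop("counts length does not match grid")
    new("CountTrack", grid = grid, counts = as.integer(counts),
        total = sum(as.numeric(counts)))
}

newCountTrack <- countTrack

#' Wrap per-window values as a ratio profile
#'
#' Packages an externally computed per-window value vector (for example a
#' simulator expectation) as a [RatioProfile-class]; `NA` values become
#' excluded windows.
#'
#' @param grid a [WindowGrid-class].
#' @param values per-window values (`NA` = excluded).
#' @param excluded optional explicit exclusion mask.
#' @param normalization tag to stamp on the profile.
#' @return a [RatioProfile-class].
#' @export
asRatioProfile <- function(grid, values, excluded = is.na(values),
        normalization = "raw") {
    values[excluded] <- NA_real_
    newRatioProfile(grid, values, excluded = excluded,
        normalization = normalization)
}

newRatioProfile <- function(grid, values, excluded,
        normalization = "raw", bulkFraction = NA_real_, notSmoothed = NULL) {
    if (is.null(notSmoothed)) notSmoothed <- rep(FALSE, nWindows(grid))
    new("RatioProfile", grid = grid, values = values, excluded = excluded,
        normalization = normalization, bulkFraction = bulkFraction,
        notSmoothed = notSmoothed)
}

#' Count read anchors in windows
#'
#' Each read is assigned to exactly one window by its anchor position
#' (half-open windows, so an anchor at a window boundary belongs to the
#' right-hand window).
#'
#' @param reads width-1 `GRanges` of read anchors (see [readReadsBed()]).
#' @param grid a [WindowGrid-class].
#' @return a [CountTrack-class].
#' @export
countReads <- function(reads, grid) {
    if (!all(as.character(seqnames(reads)) %in%
            seqlevels(windowRanges(grid))))
        stop("reads and grid have mismatched genome layouts")
    counts <- countOverlaps(windowRanges(grid), reads, ignore.strand = TRUE)
    newCountTrack(grid, counts)
}

#' Expected reads per window for uniformly distributed reads
#'
#' `total * w / genomeSize`: the count a window of width `w` would receive
#' if reads fell uniformly over the genome. Vectorized over `w`, so partial
#' terminal windows are pro-rated by their actual width.
#'
#' @param total total mapped reads in the sample.
#' @param genomeSize genome length in bp.
#' @param w window width(s) in bp.
#' @export
expectedPerWindow <- function(total, genomeSize, w) {
    if (genomeSize <= 0) stop("genomeSize must be > 0")
    total * w / genomeSize
}

.expectedCounts <- function(track) {
    g <- trackGrid(track)
    expectedPerWindow(totalReads(track),
        sum(as.numeric(seqlengths(genomeLayout(g)))),
        GenomicRanges::width(windowRanges(g)))
}

#' Replicating / nonreplicating ratio profile
#'
#' Forms the per-window ratio of read counts between a replicating and a
#' nonreplicating sample. A window is excluded when fewer than a quarter of
#' the expected number of reads (based on each sample's own total read
#' number and the genome size) mapped in either sample; zero-count
#' nonreplicating windows are excluded regardless. Included ratios are
#' rescaled by a single constant so their unweighted mean is exactly 1
#' (tag `"genome_mean_1"`).
#'
#' @param rep replicating-sample [CountTrack-class].
#' @param nonrep nonreplicating-sample [CountTrack-class].
#' @return a [RatioProfile-class] with normalization `"genome_mean_1"`.
#' @export
ratioProfile <- function(rep, nonrep) {
    if (!identical(windowRanges(rep@grid), windowRanges(nonrep@grid)))
        stop("rep and nonrep are on different grids")
    if (totalReads(rep) <= 0 || totalReads(nonrep) <= 0)
        stop("both samples need at least one read")
    cr <- readCounts(rep); cn <- readCounts(nonrep)
    eRep <- .expectedCounts(rep); eNon <- .expectedCounts(nonrep)
    included <- cr >= eRep / 4 & cn >= eNon / 4 & cn > 0L
    if (!any(included)) stop("all windows excluded")
    vals <- rep(NA_real_, length(cr))
    vals[included] <- cr[included] / cn[included]
    vals[included] <- vals[included] / mean(vals[included])
    newRatioProfile(trackGrid(rep), vals, excluded = !included,
        normalization = "genome_mean_1")
}

#' Empirical baseline normalization
#'
#' Rescales a profile so that the `q`-quantile of its included values is 1;
#' the default `q = 0` pins the minimum to 1, the convention for HU,
#' sort-seq and MFA profiles where unreplicated loci define the baseline.
#' Warns if any resulting value exceeds 2.05 (relative copy number should
#' not exceed two genome copies).
#'
#' @param profile a [RatioProfile-class] with at least one included window.
#' @param q baseline quantile in \[0, 1\] (0 = minimum).
#' @return the rescaled profile, tag `"baseline_1"`.
#' @export
normalizeBaseline <- function(profile, q = 0) {
    vals <- profileValues(profile)
    incl <- !excludedWindows(profile)
    if (!any(incl)) stop("all windows excluded")
    if (q < 0 || q > 1) stop("q must be in [0, 1]")
    base <- unname(quantile(vals[incl], probs = q, names = FALSE))
    if (base <= 0) stop("non-positive baseline value")
    vals[incl] <- vals[incl] / base
    if (max(vals[incl]) > 2.05)
        warning("baseline-normalized profile exceeds 2.05: copy number ",
            "should not exceed two genome copies")
    newRatioProfile(trackGrid(profile), vals,
        excluded = excludedWindows(profile), normalization = "baseline_1",
        notSmoothed = notSmoothedFlags(profile))
}

#' Scale a time-course profile to its bulk DNA content
#'
#' Multiplies a mean-1 profile by `1 + fRep`, where `fRep` is the bulk
#' replicated fraction at the time point (from flow cytometry, see
#' [fitBulk()]), so the genome mean becomes `1 + fRep`: 1 for a G1 sample
#' and exactly 2 once replication is complete.
#'
#' @param profile a [RatioProfile-class] with tag `"genome_mean_1"`.
#' @param fRep replicated fraction in \[0, 1\].
#' @return the scaled profile, tag `"bulk_scaled"`.
#' @export
scaleToBulk <- function(profile, fRep) {
    if (normalizationTag(profile) != "genome_mean_1")
        stop("scaleToBulk requires a genome_mean_1 profile")
    if (!is.finite(fRep) || fRep < 0 || fRep > 1)
        stop("fRep must be in [0, 1]")
    vals <- profileValues(profile)
    incl <- !excludedWindows(profile)
    vals[incl] <- vals[incl] * (1 + fRep)
    if (max(vals[incl]) > 2.05)
        warning("bulk-scaled profile exceeds 2.05: copy number should not ",
            "exceed two genome copies")
    newRatioProfile(trackGrid(profile), vals,
        excluded = excludedWindows(profile), normalization = "bulk_scaled",
        bulkFraction = fRep, notSmoothed = notSmoothedFlags(profile))
}
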
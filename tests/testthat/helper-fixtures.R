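# Shared fixture builders. Everything is generated in code; no data files.

tinyLayout <- function(lens = c(chrA = 10000L, chrB = 8000L)) {
    GenomeInfoDb::Seqinfo(seqnames = names(lens),
        seqlengths = unname(lens))
}

# independent Poisson counts on a grid (measurement-noise fixtures)
poissonTrack <- function(grid, mean, seed) {
    counts <- withr::with_seed(seed, stats::rpois(nWindows(grid), mean))
    countTrack(grid, counts)
}

# uniform random read anchors over a layout
uniformReads <- function(layout, n, seed) {
    sl <- GenomeInfoDb::seqlengths(layout)
    withr::with_seed(seed, {
        chrom <- sample(names(sl), n, replace = TRUE,
            prob = sl / sum(as.numeric(sl)))
        pos0 <- floor(stats::runif(n) * sl[chrom])
        gr <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(pos0 + 1, width = 1), seqinfo = layout)
        GenomicRanges::sort(gr)
    })
}

# one-origin-per-100kb deterministic model whose replication times span
# exactly the S-phase interval: copy number is then affine in Trep
fullSpanModel <- function(chromLength = 180000L, originPos = 90000L,
        firingMean = 20, sStart = 20, sDur = NULL, v = 1500) {
    if (is.null(sDur)) sDur <- (chromLength / 2) / v
    layout <- GenomeInfoDb::Seqinfo("chrS", chromLength)
    replicationModel(layout,
        data.frame(chrom = "chrS", position = originPos,
            firingMean = firingMean, firingSD = 0, competence = 1),
        forkVelocity = v, sPhaseStart = sStart, sPhaseDuration = sDur)
}

# simulate one timecourse experiment end to end: count tracks -> bulk-scaled
# profiles (shared nonreplicating reference, as in a synchronous release)
simulateTimecourse <- function(model, grid, times, readsPerWindow, seed,
        nCells = 4000L) {
    ec <- expectedCopyNumber(model, grid, "timecourse",
        sampleTimes = times, nCells = nCells, seed = seed)
    total <- readsPerWindow * nWindows(grid)
    nonrep <- sampleReads(rep(1, nWindows(grid)), grid, total,
        seed = seed + 900001L)
    profiles <- suppressWarnings(lapply(seq_along(times), function(j) {
        repTrack <- sampleReads(ec$expected[, j], grid, total,
            seed = seed + 1000L * j)
        scaleToBulk(ratioProfile(repTrack, nonrep), ec$fRep[j])
    }))
    list(profiles = profiles, truth = ec, nonrep = nonrep)
}

# distance (in windows) from each origin to its nearest called minimum
originCallDistances <- function(peaks, model, windowSizeBp = 1000L) {
    mins <- peaks[S4Vectors::mcols(peaks)$kind == "min"]
    o <- modelOrigins(model)
    vapply(seq_len(nrow(o)), function(i) {
        sel <- mins[as.character(GenomeInfoDb::seqnames(mins)) ==
            o$chrom[i]]
        if (!length(sel)) return(NA_real_)
        min(abs(floor((GenomicRanges::start(sel) - 1) / windowSizeBp) -
            floor(o$position[i] / windowSizeBp)))
    }, numeric(1))
}
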
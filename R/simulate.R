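## Ground-truth replication simulator and synthetic-read generator.
##
## Each simulated cell licenses every origin independently with its
## competence probability and draws a firing time from a normal
## distribution truncated at zero. Forks move at a constant velocity, so
## the replication time of position x in one cell is the minimum over
## licensed origins of T_i + |x - x_i| / v. Experiment kinds reduce the
## per-cell times to expected relative copy numbers; sequencing is a
## multinomial draw of reads over windows proportional to copy number.

#' Construct a replication model
#'
#' @param layout `Seqinfo` genome layout.
#' @param origins data.frame with columns `chrom`, `position` (bp),
#'   `firingMean` (min), and optionally `firingSD` (min, default 0),
#'   `competence` (default 1) and `name`.
#' @param forkVelocity fork speed in bp/min (default 1500).
#' @param sPhaseStart,sPhaseDuration S-phase interval in minutes (defaults
#'   20 and 30: S phase spans 20-50 min after release, as in a typical
#'   budding-yeast synchronous release).
#' @return a [ReplicationModel-class].
#' @export
replicationModel <- function(layout, origins, forkVelocity = 1500,
        sPhaseStart = 20, sPhaseDuration = 30) {
    if (is.null(origins$firingSD)) origins$firingSD <- 0
    if (is.null(origins$competence)) origins$competence <- 1
    if (is.null(origins$name))
        origins$name <- sprintf("origin_%s_%d", origins$chrom,
            as.integer(origins$position))
    origins <- origins[order(match(origins$chrom, seqnames(layout)),
        origins$position), ]
    rownames(origins) <- NULL
    new("ReplicationModel", layout = layout, origins = origins,
        forkVelocity = forkVelocity, sPhaseStart = sPhaseStart,
        sPhaseDuration = sPhaseDuration)
}

#' A ready-made two-chromosome replication model
#'
#' Two 1-Mb chromosomes carrying ten origins each (~100 kb spacing with
#' deterministic jitter), firing means spread across S phase, fork
#' velocity 1.5 kb/min and a 30-min S phase starting 20 min after release
#' — the scale of a small yeast genome fragment.
#'
#' @param nChrom,chromLength,originsPerChrom genome geometry.
#' @param firingSD per-origin firing-time sd in minutes.
#' @param competence per-origin licensing probability.
#' @param firingRange range of mean firing times (minutes).
#' @param seed seed for the jitter/firing-time assignment.
#' @inheritParams replicationModel
#' @return a [ReplicationModel-class].
#' @export
exampleModel <- function(nChrom = 2L, chromLength = 1e6,
        originsPerChrom = 10L, forkVelocity = 1500, sPhaseStart = 20,
        sPhaseDuration = 30, firingSD = 2.5, competence = 1,
        firingRange = c(27, 40), seed = 1L) {
    layout <- Seqinfo(seqnames = sprintf("chr%d", seq_len(nChrom)),
        seqlengths = rep(as.integer(chromLength), nChrom))
    origins <- with_seed(as.integer(seed), {
        do.call(rbind, lapply(seq_len(nChrom), function(i) {
            pos <- round((seq_len(originsPerChrom) - 0.5) /
                originsPerChrom * chromLength +
                runif(originsPerChrom, -20000, 20000))
            data.frame(chrom = sprintf("chr%d", i), position = pos,
                firingMean = round(runif(originsPerChrom,
                    firingRange[1L], firingRange[2L]), 1),
                firingSD = firingSD, competence = competence)
        }))
    })
    replicationModel(layout, origins, forkVelocity = forkVelocity,
        sPhaseStart = sPhaseStart, sPhaseDuration = sPhaseDuration)
}

## draw licensing and firing times for nCells cells;
## cells with an unlicensed chromosome are redrawn (counted)
.drawCells <- function(model, nCells, seed) {
    o <- modelOrigins(model)
    k <- nrow(o)
    with_seed(as.integer(seed), {
        lic <- matrix(runif(nCells * k), nCells, k) <=
            rep(o$competence, each = nCells)
        redraws <- 0L
        for (ch in unique(o$chrom)) {
            j <- which(o$chrom == ch)
            bad <- which(rowSums(lic[, j, drop = FALSE]) == 0L)
            while (length(bad)) {
                redraws <- redraws + length(bad)
                lic[bad, j] <- matrix(runif(length(bad) * length(j)),
                    length(bad), length(j)) <=
                    rep(o$competence[j], each = length(bad))
                bad <- bad[rowSums(lic[bad, j, drop = FALSE]) == 0L]
            }
        }
        t0 <- matrix(rnorm(nCells * k, mean = rep(o$firingMean,
            each = nCells), sd = rep(o$firingSD, each = nCells)),
            nCells, k)
        neg <- which(t0 < 0)
        while (length(neg)) {   # truncate at zero by redrawing
            t0[neg] <- rnorm(length(neg),
                mean = rep(o$firingMean, each = nCells)[neg],
                sd = rep(o$firingSD, each = nCells)[neg])
            neg <- neg[t0[neg] < 0]
        }
        list(licensed = lic, firingTimes = t0, redraws = redraws)
    })
}

## per-cell replication time at each position: min over licensed origins
## of T_i + |x - x_i| / v. positions: named list per chromosome (bp).
.replicationTimes <- function(model, cells, positions) {
    o <- modelOrigins(model)
    v <- forkVelocity(model)
    nCells <- nrow(cells$firingTimes)
    cols <- lapply(names(positions), function(ch) {
        x <- positions[[ch]]
        j <- which(o$chrom == ch)
        acc <- matrix(Inf, nCells, length(x))
        for (jj in j) {
            travel <- abs(x - o$position[jj]) / v
            tt <- ifelse(cells$licensed[, jj], cells$firingTimes[, jj], Inf)
            acc <- pmin(acc, outer(tt, travel, "+"))
        }
        acc
    })
    do.call(cbind, cols)
}

#' Per-cell, per-position replication times
#'
#' Simulates `nCells` cells of the model and returns each cell's
#' replication time at every queried position.
#'
#' @param model a [ReplicationModel-class].
#' @param nCells number of cells (>= 1).
#' @param seed integer seed.
#' @param positions named list (per chromosome) of bp positions; defaults
#'   to the centers of 1-kb windows.
#' @return list with `times` (matrix, cells x positions, columns in genome
#'   order), `positions`, and `redraws` (cells redrawn for having an
#'   unlicensed chromosome).
#' @export
cellReplicationTimes <- function(model, nCells, seed = 1L,
        positions = NULL) {
    if (nCells < 1L) stop("nCells must be >= 1")
    if (is.null(positions))
        positions <- .windowCenterPositions(
            windowGrid(modelLayout(model), 1000L))
    cells <- .drawCells(model, nCells, seed)
    list(times = .replicationTimes(model, cells, positions),
        positions = positions, redraws = cells$redraws)
}

.windowCenterPositions <- function(grid) {
    gr <- windowRanges(grid)
    chrom <- as.character(seqnames(gr))
    center0 <- (GenomicRanges::start(gr) - 1L) +
        GenomicRanges::width(gr) %/% 2L
    split(center0, factor(chrom, levels = unique(chrom)))
}

#' Expected relative copy number for an experiment design
#'
#' Averages over simulated cells to produce the per-window expected
#' relative copy number of one of the four experiment kinds, plus the
#' ground truth needed to score downstream recovery:
#' \describe{
#'   \item{timecourse}{at time t: `1 + P(t(x) <= t)`.}
#'   \item{hu}{`1 + P(origin-limited synthesis covers x)`. Under HU,
#'     origin activation is slowed by `huTimeScale`; a licensed origin
#'     with effective firing time `huTimeScale * T_i <= tHU` synthesizes
#'     only `vHU * (tHU - huTimeScale * T_i)` bp to each side of itself.}
#'   \item{sortseq}{S-phase cells uniform over S-phase progression:
#'     `1 + E[(sEnd - t(x))+ / S]` clipped to \[0, 1\]; affine in t(x)
#'     for deterministic firing.}
#'   \item{mfa}{population mixture `fG1 * 1 + fS * sortseq + fG2 * 2`,
#'     rescaled so the latest-replicating baseline is 1.}
#' }
#'
#' @param model a [ReplicationModel-class].
#' @param grid a [WindowGrid-class] on the model's layout.
#' @param kind `"timecourse"`, `"hu"`, `"sortseq"` or `"mfa"`.
#' @param sampleTimes timecourse sample times (minutes).
#' @param tHU minutes of HU exposure after release (default 60).
#' @param vHU residual fork velocity under HU in bp/min (default 50).
#' @param huTimeScale slow-down factor on origin firing times under HU
#'   (default 3).
#' @param fractions named population fractions `c(G1=, S=, G2=)` for MFA
#'   (must sum to 1).
#' @param ageWeighting distribution of S-phase cells over progression:
#'   `"uniform"` (sorted S-phase window, default) or `"exponential"`
#'   (exponentially growing culture, where a cell of age `a` carries
#'   weight `2^(1 - a)`).
#' @param nCells cells to simulate (default 4000).
#' @param seed integer seed.
#' @return list with `expected` (matrix windows x samples for a
#'   timecourse, otherwise a vector), `trueTrep` (per-window median
#'   replication time over cells), `fRep` (true bulk replicated fraction
#'   per timecourse sample), `redraws` and `kind`.
#' @export
expectedCopyNumber <- function(model, grid, kind = c("timecourse", "hu",
        "sortseq", "mfa"), sampleTimes = NULL, tHU = 60, vHU = 50,
        huTimeScale = 3, fractions = c(G1 = 0.75, S = 0.25, G2 = 0),
        ageWeighting = c("uniform", "exponential"),
        nCells = 4000L, seed = 1L) {
    kind <- match.arg(kind)
    ageWeighting <- match.arg(ageWeighting)
    positions <- .windowCenterPositions(grid)
    cells <- .drawCells(model, nCells, seed)
    tmat <- .replicationTimes(model, cells, positions)
    trueTrep <- apply(tmat, 2L, median)
    sInt <- sPhaseInterval(model)
    sortseqExpected <- function() {
        a0 <- (tmat - sInt[1L]) / (sInt[2L] - sInt[1L])
        a0[a0 < 0] <- 0
        a0[a0 > 1] <- 1
        u <- if (ageWeighting == "uniform") {
            1 - a0
        } else {
            ## exponential culture: cell age a carries weight 2^(1 - a),
            ## so P(progression >= a0) = 2^(1 - a0) - 1
            2^(1 - a0) - 1
        }
        1 + colMeans(u)
    }
    res <- switch(kind,
        timecourse = {
            if (is.null(sampleTimes)) stop("timecourse needs sampleTimes")
            cn <- vapply(sampleTimes,
                function(t) 1 + colMeans(tmat <= t), numeric(ncol(tmat)))
            colnames(cn) <- as.character(sampleTimes)
            fRep <- vapply(sampleTimes, function(t) mean(tmat <= t), 0)
            list(expected = cn, fRep = setNames(fRep,
                as.character(sampleTimes)))
        },
        hu = {
            o <- modelOrigins(model)
            eff <- cells$firingTimes * huTimeScale
            fires <- cells$licensed & eff <= tHU
            extent <- vHU * (tHU - eff)
            extent[extent < 0] <- 0
            covered <- matrix(FALSE, nrow(tmat), ncol(tmat))
            offset <- 0L
            for (ch in names(positions)) {
                x <- positions[[ch]]
                for (jj in which(o$chrom == ch)) {
                    dist <- abs(x - o$position[jj])
                    covered[, offset + seq_along(x)] <-
                        covered[, offset + seq_along(x)] |
                        (fires[, jj] & outer(extent[, jj], dist, ">="))
                }
                offset <- offset + length(x)
            }
            list(expected = 1 + colMeans(covered), fRep = NULL)
        },
        sortseq = list(expected = sortseqExpected(), fRep = NULL),
        mfa = {
            if (abs(sum(fractions) - 1) > 1e-9)
                stop("population fractions must sum to 1")
            mix <- fractions[["G1"]] * 1 + fractions[["S"]] *
                sortseqExpected() + fractions[["G2"]] * 2
            list(expected = mix / (1 + fractions[["G2"]]), fRep = NULL)
        })
    list(expected = res$expected, trueTrep = trueTrep, fRep = res$fRep,
        redraws = cells$redraws, kind = kind)
}

#' Draw sequencing reads over windows
#'
#' Multinomial draw of `totalReads` reads over the grid's windows with
#' probabilities proportional to expected copy number times window width.
#'
#' @param expected per-window expected relative copy number (> 0).
#' @param grid a [WindowGrid-class].
#' @param totalReads reads to draw (> 0).
#' @param seed integer seed (same seed, same counts).
#' @return a [CountTrack-class].
#' @export
sampleReads <- function(expected, grid, totalReads, seed = 1L) {
    if (totalReads <= 0) stop("totalReads must be > 0")
    if (length(expected) != nWindows(grid))
        stop("expected length does not match grid")
    if (any(expected <= 0)) stop("expected values must be > 0")
    probs <- expected * GenomicRanges::width(windowRanges(grid))
    counts <- with_seed(as.integer(seed),
        rmultinom(1L, size = totalReads, prob = probs)[, 1L])
    newCountTrack(grid, counts)
}

## uniform read positions within each window given per-window counts
.readsFromCounts <- function(track, seed) {
    gr <- windowRanges(trackGrid(track))
    counts <- readCounts(track)
    idx <- rep(seq_along(gr), counts)
    with_seed(as.integer(seed), {
        off <- floor(runif(length(idx)) *
            GenomicRanges::width(gr)[idx])
        pos1 <- GenomicRanges::start(gr)[idx] + as.integer(off)
        out <- GRanges(seqnames(gr)[idx], IRanges(pos1, width = 1L),
            seqinfo = seqinfo(gr))
        GenomicRanges::sort(out)
    })
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes everything a pipeline run needs: a chrom.sizes file, an origins
#' BED, one reads BED per sample (read positions uniform within their
#' window), ground-truth tables (per-window true Trep and expected copy
#' number; per-sample true replicated fraction for time courses), and a
#' YAML echo of the configuration. Sample sets per kind:
#' `timecourse` gets one BED per sample time plus a nonreplicating G1
#' reference; `hu` gets HU and G1 samples; `sortseq` gets S and G2
#' samples; `mfa` gets exponential and stationary samples.
#'
#' @param model a [ReplicationModel-class].
#' @param kind experiment kind (see [expectedCopyNumber()]).
#' @param outdir output directory (created if needed).
#' @param readsPerKb reads per kb per sample (default 1000; > 0).
#' @param windowSize simulation window size in bp.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param sampleTimes,tHU,vHU,huTimeScale,fractions,nCells forwarded to
#'   [expectedCopyNumber()].
#' @return invisible list with `files` (paths), `truth`, and `grid`.
#' @export
makeDataset <- function(model, kind = c("timecourse", "hu", "sortseq",
        "mfa"), outdir, readsPerKb = 1000, windowSize = 1000L, seed = 1L,
        sampleTimes = c(25, 30, 35, 40, 45, 50, 90), tHU = 60, vHU = 50,
        huTimeScale = 3, fractions = c(G1 = 0.75, S = 0.25, G2 = 0),
        nCells = 4000L) {
    kind <- match.arg(kind)
    if (readsPerKb <= 0) stop("readsPerKb must be > 0")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    layout <- modelLayout(model)
    grid <- windowGrid(layout, windowSize)
    genomeSize <- sum(as.numeric(seqlengths(layout)))
    totalReads <- round(readsPerKb * genomeSize / 1000)
    truth <- expectedCopyNumber(model, grid, kind,
        sampleTimes = sampleTimes, tHU = tHU, vHU = vHU,
        huTimeScale = huTimeScale, fractions = fractions,
        nCells = nCells, seed = seed)
    expected <- truth$expected
    if (is.null(dim(expected))) expected <- cbind(sample = expected)
    sampleNames <- switch(kind,
        timecourse = sprintf("t%g", sampleTimes),
        hu = "hu", sortseq = "s_phase", mfa = "exponential")
    colnames(expected) <- sampleNames
    refName <- switch(kind, timecourse = "g1", hu = "g1",
        sortseq = "g2", mfa = "stationary")
    files <- list()
    files$chromSizes <- file.path(outdir, "genome.chrom.sizes")
    writeChromSizes(layout, files$chromSizes)
    o <- modelOrigins(model)
    origins <- GRanges(o$chrom, IRanges(o$position + 1L, width = 1L),
        seqinfo = layout)
    mcols(origins)$name <- o$name
    files$origins <- file.path(outdir, "origins.bed")
    writeOriginsBed(origins, files$origins)
    files$reads <- character(0)
    for (j in seq_len(ncol(expected))) {
        track <- sampleReads(expected[, j], grid, totalReads,
            seed = as.integer(seed) + 101L * j)
        reads <- .readsFromCounts(track, seed = as.integer(seed) + 7919L * j)
        path <- file.path(outdir, sprintf("reads_%s.bed", sampleNames[j]))
        .writeReadsBed(reads, path)
        files$reads <- c(files$reads, path)
    }
    refTrack <- sampleReads(rep(1, nWindows(grid)), grid, totalReads,
        seed = as.integer(seed) + 33331L)
    files$reference <- file.path(outdir,
        sprintf("reads_%s.bed", refName))
    .writeReadsBed(.readsFromCounts(refTrack,
        seed = as.integer(seed) + 49999L), files$reference)
    gr <- windowRanges(grid)
    truthDf <- data.frame(chrom = as.character(seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
        true_trep = truth$trueTrep)
    truthDf <- cbind(truthDf, as.data.frame(expected))
    files$truth <- file.path(outdir, "truth.tsv")
    write.table(truthDf, files$truth, sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(truth$fRep)) {
        files$bulk <- file.path(outdir, "bulk.tsv")
        write.table(data.frame(time_min = sampleTimes,
            fraction_replicated = unname(truth$fRep)), files$bulk,
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    files$config <- file.path(outdir, "config.yaml")
    cfg <- list(kind = kind, readsPerKb = readsPerKb,
        windowSize = as.integer(windowSize), seed = as.integer(seed),
        nCells = as.integer(nCells), forkVelocity = forkVelocity(model),
        sPhase = as.list(setNames(sPhaseInterval(model),
            c("start", "end"))),
        samples = sampleNames, reference = refName)
    if (kind == "timecourse") cfg$sampleTimes <- sampleTimes
    if (kind == "hu") cfg[c("tHU", "vHU", "huTimeScale")] <-
        list(tHU, vHU, huTimeScale)
    if (kind == "mfa") cfg$fractions <- as.list(fractions)
    writeLines(yaml::as.yaml(cfg), files$config)
    invisible(list(files = files, truth = truth, grid = grid))
}

.writeReadsBed <- function(reads, path) {
    start0 <- GenomicRanges::start(reads) - 1L
    writeLines(sprintf("%s\t%d\t%d", as.character(seqnames(reads)),
        start0, start0 + 50L), path)
    invisible(path)
}
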
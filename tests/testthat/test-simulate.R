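test_that("deterministic single-origin kinetics are V-shaped", {
    layout <- GenomeInfoDb::Seqinfo("chrV", 100000L)
    model <- replicationModel(layout,
        data.frame(chrom = "chrV", position = 50000,
            firingMean = 25, firingSD = 0, competence = 1),
        forkVelocity = 1500, sPhaseStart = 20, sPhaseDuration = 60)
    ct <- cellReplicationTimes(model, nCells = 3L, seed = 1)
    x <- ct$positions$chrV
    expected <- 25 + abs(x - 50000) / 1500
    for (cell in 1:3)
        expect_equal(unname(ct$times[cell, ]), expected)
    expect_equal(ct$redraws, 0L)
})

test_that("equal origin pairs terminate at the midpoint", {
    layout <- GenomeInfoDb::Seqinfo("chrV", 200000L)
    # origins placed so the inter-origin midpoint is the latest point on
    # the chromosome (farther from both origins than either end is)
    model <- replicationModel(layout,
        data.frame(chrom = "chrV", position = c(40000, 160000),
            firingMean = 25, firingSD = 0, competence = 1),
        forkVelocity = 1500, sPhaseStart = 20, sPhaseDuration = 80)
    ct <- cellReplicationTimes(model, nCells = 1L, seed = 2)
    t <- ct$times[1, ]
    x <- ct$positions$chrV
    # window centers straddle 100 kb; the two central windows tie
    expect_true(which.max(t) %in% which(abs(x - 100000) <= 500))
    # the geometry is mirror-symmetric about the midpoint
    expect_equal(t, rev(t), tolerance = 1e-9)
})

test_that("Monte-Carlo medians match an independent brute-force draw", {
    layout <- GenomeInfoDb::Seqinfo("chrV", 120000L)
    model <- replicationModel(layout,
        data.frame(chrom = "chrV", position = c(30000, 90000),
            firingMean = c(26, 34), firingSD = 3, competence = c(1, 0.8)),
        forkVelocity = 1500, sPhaseStart = 20, sPhaseDuration = 60)
    probe <- list(chrV = c(10000, 30000, 55000, 60000, 90000, 110000))
    ct <- cellReplicationTimes(model, nCells = 100000L, seed = 3,
        positions = probe)
    med <- apply(ct$times, 2, median)
    # independent implementation of the same kinetics
    oracle <- withr::with_seed(99, {
        n <- 100000L
        t1 <- rnorm(n, 26, 3); t2 <- rnorm(n, 34, 3)
        while (any(t1 < 0)) t1[t1 < 0] <- rnorm(sum(t1 < 0), 26, 3)
        while (any(t2 < 0)) t2[t2 < 0] <- rnorm(sum(t2 < 0), 34, 3)
        lic2 <- runif(n) <= 0.8
        vapply(probe$chrV, function(x) {
            a <- t1 + abs(x - 30000) / 1500
            b <- ifelse(lic2, t2 + abs(x - 90000) / 1500, Inf)
            median(pmin(a, b))
        }, numeric(1))
    })
    expect_equal(unname(med), oracle, tolerance = 0.5)
})

test_that("expected copy numbers respect bounds, bulk and monotonicity", {
    model <- exampleModel()
    grid <- windowGrid(modelLayout(model), 1000L)
    sampleTimes <- c(25, 30, 35, 40, 45, 50, 90, 200)
    ec <- expectedCopyNumber(model, grid, "timecourse",
        sampleTimes = sampleTimes, nCells = 500L, seed = 7)
    expect_true(all(ec$expected >= 1 & ec$expected <= 2))
    # completion: a sample after all replication sits at exactly 2
    expect_true(all(ec$expected[, "200"] == 2))
    # genome mean equals 1 + true bulk fraction
    for (j in seq_along(sampleTimes))
        expect_equal(mean(ec$expected[, j]), 1 + ec$fRep[[j]],
            tolerance = 1e-9)
    # per-window expectations never decrease in time
    expect_true(all(apply(ec$expected, 1, function(r) all(diff(r) >= 0))))
    expect_true(all(diff(ec$fRep) >= 0))
})

test_that("deterministic sort-seq expectation is affine in true Trep", {
    model <- fullSpanModel()
    grid <- windowGrid(modelLayout(model), 1000L)
    ec <- expectedCopyNumber(model, grid, "sortseq", nCells = 50L,
        seed = 8)
    fit <- lm(ec$expected ~ ec$trueTrep)
    expect_lt(coef(fit)[2], 0)
    expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
    expect_equal(cor(ec$expected, ec$trueTrep), -1, tolerance = 1e-6)

    # exponential-age weighting: younger (less-replicated) cells are
    # overrepresented, so interior expectations drop below uniform, with
    # agreement at the fully-replicated and never-replicated extremes
    ecx <- expectedCopyNumber(model, grid, "sortseq", nCells = 50L,
        seed = 8, ageWeighting = "exponential")
    # closed form: 1 + 2^(1 - a0) - 1 for progression threshold a0
    a0 <- pmin(1, pmax(0, (ec$trueTrep - sPhaseInterval(model)[1]) /
        diff(sPhaseInterval(model))))
    expect_equal(unname(ecx$expected), unname(2^(1 - a0)),
        tolerance = 1e-9)
    expect_true(all(ecx$expected <= ec$expected + 1e-12))
})

test_that("MFA mixtures show the expected early/late excess", {
    # earliest windows replicated in every S-phase cell, latest in none
    model <- fullSpanModel(chromLength = 200000L, originPos = 100000L,
        firingMean = 10, sStart = 20, sDur = 30)
    grid <- windowGrid(modelLayout(model), 1000L)
    ec <- expectedCopyNumber(model, grid, "mfa",
        fractions = c(G1 = 0.75, S = 0.25, G2 = 0), nCells = 50L, seed = 9)
    expect_true(all(ec$expected >= 1 - 1e-12))
    ord <- order(ec$trueTrep)
    n <- length(ord)
    early <- ord[seq_len(n %/% 10)]
    late <- ord[(n - n %/% 10 + 1):n]
    excess <- mean(ec$expected[early]) / mean(ec$expected[late]) - 1
    expect_equal(excess, 0.25, tolerance = 0.005)
})

test_that("read sampling is proportional, Poisson-like and reproducible", {
    layout <- tinyLayout(c(chrA = 100000L))
    grid <- windowGrid(layout, 1000L)
    flat <- sampleReads(rep(1, 100), grid, 100000L, seed = 10)
    expect_equal(totalReads(flat), 100000)
    expect_equal(mean(readCounts(flat)), 1000)
    expect_equal(var(readCounts(flat)), 1000, tolerance = 0.3)

    bump <- rep(1, 100); bump[50] <- 2
    track <- sampleReads(bump, grid, 101000L, seed = 11)
    expect_equal(readCounts(track)[50] /
        mean(readCounts(track)[-50]), 2, tolerance = 0.15)

    expect_identical(readCounts(sampleReads(bump, grid, 5000L, seed = 12)),
        readCounts(sampleReads(bump, grid, 5000L, seed = 12)))
    expect_error(sampleReads(bump, grid, 0, seed = 1), "> 0")
})

test_that("datasets on disk are complete, consistent and reproducible", {
    model <- exampleModel(nChrom = 1L, chromLength = 200000L,
        originsPerChrom = 2L)
    outdir <- withr::local_tempdir()
    ds <- makeDataset(model, "timecourse", outdir, readsPerKb = 100,
        seed = 5, sampleTimes = c(25, 35, 45, 90), nCells = 200L)
    expect_true(all(file.exists(unlist(ds$files))))
    layout <- readChromSizes(ds$files$chromSizes)
    expect_identical(GenomeInfoDb::seqlengths(layout),
        GenomeInfoDb::seqlengths(modelLayout(model)))
    origins <- readOriginsBed(ds$files$origins, layout)
    expect_length(origins, 2L)
    reads <- readReadsBed(ds$files$reads[1], layout)
    expect_equal(length(reads), 100 * 200)  # readsPerKb * genome kb
    expect_true(!is.unsorted(GenomicRanges::start(reads)))
    truth <- read.table(ds$files$truth, header = TRUE, sep = "\t")
    expect_equal(nrow(truth), nWindows(ds$grid))

    # same seed -> byte-identical files
    outdir2 <- withr::local_tempdir()
    ds2 <- makeDataset(model, "timecourse", outdir2, readsPerKb = 100,
        seed = 5, sampleTimes = c(25, 35, 45, 90), nCells = 200L)
    for (nm in c("chromSizes", "origins", "truth", "reference")) {
        expect_identical(readLines(ds$files[[nm]]),
            readLines(ds2$files[[nm]]))
    }
    expect_identical(readLines(ds$files$reads[2]),
        readLines(ds2$files$reads[2]))

    expect_error(makeDataset(model, "timecourse", outdir,
        readsPerKb = 0), "> 0")
})

test_that("HU expectations enrich origin-proximal windows only", {
    model <- exampleModel(firingRange = c(10, 40), firingSD = 0)
    grid <- windowGrid(modelLayout(model), 1000L)
    ec <- expectedCopyNumber(model, grid, "hu", nCells = 300L, seed = 13)
    expect_true(all(ec$expected >= 1 & ec$expected <= 2))
    o <- modelOrigins(model)
    gr <- windowRanges(grid)
    centers <- GenomicRanges::start(gr) - 1 +
        GenomicRanges::width(gr) %/% 2
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    nearest <- vapply(seq_len(nWindows(grid)), function(i) {
        j <- o$chrom == chrom[i]
        min(abs(centers[i] - o$position[j]))
    }, numeric(1))
    # far from any origin nothing is synthesized under HU
    expect_true(all(ec$expected[nearest > 10000] == 1))
    expect_true(any(ec$expected[nearest < 1000] > 1.2))
})
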
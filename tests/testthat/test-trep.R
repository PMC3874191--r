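# independent oracle: locate F[t] = 3/2 by bisection on a wide bracket
bisectTrep <- function(p) {
    f <- function(t) sigmoidValue(p, t) - 1.5
    lo <- p[["e"]] - 400; hi <- p[["e"]] + 400
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

test_that("the sigmoid has the right asymptotes and midpoint", {
    p <- c(c = 1, d = 2, b = -1, e = 30, f = 1)
    expect_equal(sigmoidValue(p, -1e6), 1)
    expect_equal(sigmoidValue(p, 1e6), 2)
    expect_equal(sigmoidValue(p, 30), 1.5)  # symmetric f = 1 midpoint
    # no overflow far from the inflection
    expect_true(is.finite(sigmoidValue(c(c = 1, d = 2, b = -5, e = 0,
        f = 10), -500)))
})

test_that("closed-form Trep equals the bisection root", {
    # algebraic identity: c=1, d=2, f=1 makes the log argument 1
    for (b in c(-0.1, -1, -3))
        expect_equal(trepClosedForm(c(c = 1, d = 2, b = b, e = 40, f = 1)),
            40)
    for (p in list(c(c = 1, d = 2, b = -0.5, e = 40, f = 2),
                   c(c = 0.9, d = 2.1, b = -0.3, e = 35, f = 0.7))) {
        tr <- trepClosedForm(p)
        expect_equal(tr, bisectTrep(p), tolerance = 1e-8)
        expect_equal(sigmoidValue(p, tr), 1.5, tolerance = 1e-9)
    }
})

test_that("Trep errors name the violated existence condition", {
    expect_error(trepClosedForm(c(c = 1.6, d = 2, b = -1, e = 0, f = 1)),
        "c >= 1.5")
    expect_error(trepClosedForm(c(c = 1, d = 1.4, b = -1, e = 0, f = 1)),
        "d <= 1.5")
    expect_error(trepClosedForm(c(c = 1, d = 2, b = 0, e = 0, f = 1)),
        "non-zero")
})

test_that("noiseless window fits recover Trep within 0.1 min", {
    times <- c(25, 30, 35, 40, 45, 50, 90)
    for (p in list(c(c = 1, d = 2, b = -0.6, e = 33, f = 1),
                   c(c = 1.02, d = 1.97, b = -0.4, e = 42, f = 1.6),
                   c(c = 0.98, d = 2.05, b = -1.2, e = 29, f = 0.8))) {
        fit <- fitWindow(times, sigmoidValue(p, times))
        expect_equal(fit$reason, "")
        expect_equal(fit$trep, trepClosedForm(p), tolerance = 0.1)
    }
})

test_that("degenerate windows are masked, not extrapolated", {
    times <- c(25, 30, 35, 40, 45, 50, 90)
    flat <- fitWindow(times, rep(1, 7))
    expect_true(is.na(flat$trep))
    expect_equal(flat$reason, "never half-replicated")

    early <- fitWindow(times, rep(2, 7))
    expect_equal(early$reason, "replicated before first sample")

    few <- fitWindow(times[1:4], c(1, 1.2, 1.6, 2))
    expect_equal(few$reason, "insufficient data")

    # crossing inside the wide 50->90 sampling void is unresolvable
    p <- c(c = 1, d = 2, b = -0.8, e = 68, f = 1)
    void <- fitWindow(times, sigmoidValue(p, times))
    expect_equal(void$reason, "transition not sampled")
})

test_that("shifting all sample times shifts Trep by the same amount", {
    times <- c(25, 30, 35, 40, 45, 50, 90)
    p <- c(c = 1, d = 2, b = -0.5, e = 36, f = 1.3)
    vals <- sigmoidValue(p, times)
    base <- fitWindow(times, vals)$trep
    for (shift in c(-10, 15)) {
        shifted <- fitWindow(times + shift, vals)$trep
        expect_equal(shifted - base, shift, tolerance = 1e-3)
    }
})

test_that("the bulk curve interpolates the half-replication point", {
    times <- c(20, 27, 35, 43, 50)
    curve <- fitBulk(times, c(0, 0.15, 0.5, 0.85, 1))
    expect_equal(predictBulkFraction(curve, 35), 0.5, tolerance = 0.02)
    expect_true(all(diff(predictBulkFraction(curve, 20:50)) >= 0))
    expect_error(fitBulk(times, rep(0, 5)), "S-phase")
    expect_error(fitBulk(times, rev(c(0, 0.15, 0.5, 0.85, 1))), "S-phase")
    expect_error(fitBulk(c(1, 2, 3), c(0, 0.5, 1)), "4 timepoints")
})

test_that("a noisy bulk curve is recovered within 0.03 everywhere", {
    # origin spacing ~36 kb (budding-yeast-like) keeps the bulk curve in
    # the sigmoid family's domain; flow samples every 2.5 min
    model <- exampleModel(nChrom = 1L, originsPerChrom = 28L,
        firingRange = c(24, 40))
    grid <- windowGrid(modelLayout(model), 1000L)
    sampleTimes <- seq(20, 90, by = 2.5)
    truth <- expectedCopyNumber(model, grid, "timecourse",
        sampleTimes = sampleTimes, nCells = 1000L, seed = 5)
    # noiseless: family mismatch is small
    clean <- fitBulk(sampleTimes, truth$fRep)
    expect_lt(max(abs(predictBulkFraction(clean, sampleTimes) -
        truth$fRep)), 0.015)
    # 2% measurement noise: max |error| is a random variable; its typical
    # (median over noise draws) value stays within 0.03
    errs <- vapply(1:5, function(ns) {
        noisy <- pmin(1, pmax(0, truth$fRep +
            withr::with_seed(ns, rnorm(length(sampleTimes), 0, 0.02))))
        curve <- fitBulk(sampleTimes, noisy)
        max(abs(predictBulkFraction(curve, sampleTimes) - truth$fRep))
    }, numeric(1))
    expect_lt(median(errs), 0.03)
    expect_lt(max(errs), 0.06)
})

test_that("Trep profiles order origins correctly and propagate masks", {
    # two origins, one early (28 min) one late (38 min), planted at
    # window centers so the V-tip is unambiguous
    layout <- GenomeInfoDb::Seqinfo("chrT", 200000L)
    model <- replicationModel(layout,
        data.frame(chrom = "chrT", position = c(50500, 150500),
            firingMean = c(28, 38), firingSD = 2, competence = 1),
        forkVelocity = 1500, sPhaseStart = 20, sPhaseDuration = 30)
    grid <- windowGrid(layout, 1000L)
    times <- c(25, 30, 35, 40, 45, 50, 90)
    sim <- simulateTimecourse(model, grid, times, readsPerWindow = 3000L,
        seed = 31, nCells = 2000L)
    track <- trepProfile(sim$profiles, times)
    tv <- trepValues(track)
    expect_lt(tv[51], tv[151])  # early origin replicates first
    # the replicon-wide minimum of the unsmoothed Trep track sits within
    # one window of each origin
    expect_true((which.min(tv[31:71]) + 30L) %in% 50:52)
    expect_true((which.min(tv[131:171]) + 130L) %in% 150:152)
    peaks <- callPeaks(track, delta = 2, invert = TRUE)
    d <- originCallDistances(peaks, model)
    expect_true(all(d <= 1))

    expect_error(trepProfile(sim$profiles[1:2], times[1:2]), "3 timepoints")
    raw <- ratioProfile(sampleReads(rep(1, 200), grid, 200000, seed = 1),
        sampleReads(rep(1, 200), grid, 200000, seed = 2))
    expect_error(trepProfile(list(raw, raw, raw), c(1, 2, 3)),
        "bulk-scaled")
})
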
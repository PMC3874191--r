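## Sigmoid fits of windowed copy-number time series and the closed-form
## median replication time (Trep).
##
## The fitted family is F[t] = c + (d - c) / (1 + exp(b (t - e)))^f with
## c ~ 1 (pre-replication copy number), d ~ 2 (post-replication), b < 0
## (increasing curve), e an inflection-scale time and f > 0 a shape /
## asymmetry parameter. The locus is half-replicated (F = 3/2) at
## Trep = e + ln((-2 (c - d) / (3 - 2 c))^(1/f) - 1) / b.

.checkParams <- function(p) {
    need <- c("c", "d", "b", "e", "f")
    if (!all(need %in% names(p)))
        stop("params must be named c, d, b, e, f")
    p[need]
}

#' Evaluate the replication sigmoid
#'
#' Computed in log space (`exp(-f * log1p(exp(z)))`) so large `|b (t - e)|`
#' cannot overflow.
#'
#' @param params named numeric vector `c(c=, d=, b=, e=, f=)`.
#' @param t time(s) in minutes.
#' @return F\[t\], vectorized over `t`.
#' @export
sigmoidValue <- function(params, t) {
    p <- .checkParams(params)
    if (p[["f"]] <= 0) stop("f must be > 0")
    if (p[["b"]] == 0) stop("b must be non-zero")
    z <- p[["b"]] * (t - p[["e"]])
    l1p <- ifelse(z > 35, z, log1p(exp(pmin(z, 35))))
    p[["c"]] + (p[["d"]] - p[["c"]]) * exp(-p[["f"]] * l1p)
}

#' Closed-form median replication time
#'
#' The unique time at which the sigmoid crosses relative copy number 3/2,
#' i.e. the locus has been replicated in half the cells:
#' `Trep = e + ln((-2 (c - d) / (3 - 2 c))^(1/f) - 1) / b`. Requires
#' `c < 1.5 < d` and a positive log argument; violations raise an error
#' naming the condition.
#'
#' @param params named numeric vector `c(c=, d=, b=, e=, f=)`.
#' @return Trep in minutes.
#' @export
trepClosedForm <- function(params) {
    p <- .checkParams(params)
    if (p[["b"]] == 0) stop("Trep undefined: b must be non-zero")
    if (p[["f"]] <= 0) stop("Trep undefined: f must be > 0")
    if (p[["c"]] >= 1.5)
        stop("Trep undefined: pre-replication level c >= 1.5")
    if (p[["d"]] <= 1.5)
        stop("Trep undefined: post-replication level d <= 1.5")
    arg <- (-2 * (p[["c"]] - p[["d"]]) / (3 - 2 * p[["c"]]))^(1 / p[["f"]]) - 1
    if (arg <= 0)
        stop("Trep undefined: non-positive log argument")
    unname(p[["e"]] + log(arg) / p[["b"]])
}

## default optimizer bounds / start; the functional form is the model,
## these are numerical guard rails
.fitControl <- function(times, override = list()) {
    ctl <- list(
        lower = c(c = 0.5, d = 1.6, b = -5, e = min(times) - 20, f = 0.1),
        upper = c(c = 1.4, d = 2.5, b = -0.01, e = max(times) + 20, f = 10),
        start = c(c = 1, d = 2, b = -0.5, e = NA, f = 1),
        maxiter = 200L)
    ctl[names(override)] <- override
    ctl
}

## first crossing of `level` by linear interpolation, NA if never crossed
.firstCrossing <- function(times, values, level = 1.5) {
    above <- unname(values >= level)
    if (above[1L]) return(unname(times[1L]))
    i <- which(above)[1L]
    if (is.na(i)) return(NA_real_)
    t0 <- times[i - 1L]; t1 <- times[i]
    v0 <- values[i - 1L]; v1 <- values[i]
    unname(t0 + (level - v0) / (v1 - v0) * (t1 - t0))
}

#' Fit the replication sigmoid to one window's time series
#'
#' Bounded Levenberg-Marquardt least squares on raw (unsmoothed) windowed
#' values. Initialization: c = 1, d = 2, f = 1, b = -0.5/min, e = the time
#' at which the series first crosses 1.5 (linear interpolation). Trep is
#' an interpolation of the sampled copy-number transition, so windows are
#' masked rather than extrapolated when the transition is not sampled:
#' series that never reach 1.5, series already above 1.75 at the first
#' sample, fitted crossings that land inside a sampling gap wider than
#' `maxCrossingGap` (default three median sampling intervals), and
#' windows with fewer than five usable points.
#'
#' @param times sample times in minutes.
#' @param values relative copy-number values (bulk-scaled; `NA` for
#'   timepoints where the window was excluded).
#' @param control optional list overriding `lower`, `upper`, `start`,
#'   `maxiter`.
#' @return list with `params`, `trep`, `residual` (residual norm),
#'   `converged`, and `reason` (`""` when fitted, otherwise why masked).
#' @export
fitWindow <- function(times, values, control = list()) {
    ok <- is.finite(values) & is.finite(times)
    t <- times[ok]; v <- values[ok]
    masked <- function(reason) list(params = NULL, trep = NA_real_,
        residual = NA_real_, converged = FALSE, reason = reason)
    if (length(t) < 5L) return(masked("insufficient data"))
    if (max(v) < 1.5) return(masked("never half-replicated"))
    if (min(v) > 1.75) return(masked("replicated before first sample"))
    ctl <- .fitControl(t, control)
    start <- ctl$start
    if (is.na(start[["e"]])) start[["e"]] <- .firstCrossing(t, v)
    start <- pmin(pmax(start, ctl$lower), ctl$upper)
    fit <- tryCatch(
        nls.lm(par = start,
            fn = function(p) sigmoidValue(p, t) - v,
            lower = ctl$lower, upper = ctl$upper,
            control = nls.lm.control(maxiter = ctl$maxiter)),
        error = function(e) NULL)
    if (is.null(fit)) return(masked("fit failed"))
    converged <- fit$info %in% 1:3
    p <- fit$par
    trep <- tryCatch(trepClosedForm(p), error = function(e) NA_real_)
    if (is.na(trep))
        return(list(params = p, trep = NA_real_,
            residual = sqrt(sum(fit$fvec^2)), converged = converged,
            reason = "Trep undefined"))
    span <- diff(range(t))
    if (trep < min(t) - span || trep > max(t) + span)
        return(list(params = p, trep = NA_real_,
            residual = sqrt(sum(fit$fvec^2)), converged = converged,
            reason = "Trep out of sampled range"))
    ## Trep interpolates the sampled transition: a crossing that lands in
    ## a sampling gap much wider than the sampling cadence (default 3x
    ## the median interval) cannot be located and is masked.
    maxGap <- ctl$maxCrossingGap
    if (is.null(maxGap)) maxGap <- 3 * median(diff(sort(t)))
    i <- findInterval(trep, sort(t))
    if (i >= 1L && i < length(t) && diff(sort(t))[i] > maxGap)
        return(list(params = p, trep = NA_real_,
            residual = sqrt(sum(fit$fvec^2)), converged = converged,
            reason = "transition not sampled"))
    list(params = p, trep = trep, residual = sqrt(sum(fit$fvec^2)),
        converged = converged, reason = "")
}

#' Fit the bulk flow-cytometry replication curve
#'
#' Fits the same five-parameter sigmoid family to per-timepoint bulk
#' replicated fractions, with asymptotes pinned near 0 and 1. The fitted
#' curve (see [predictBulkFraction()]) supplies the `fRep` values used by
#' [scaleToBulk()].
#'
#' @param times timepoints in minutes (at least 4).
#' @param fractions replicated fractions in \[0, 1\].
#' @return a [BulkCurve-class].
#' @export
fitBulk <- function(times, fractions) {
    if (length(times) < 4L) stop("need at least 4 timepoints")
    if (any(fractions < 0 | fractions > 1))
        stop("fractions must be in [0, 1]")
    if (sd(fractions) > 0 &&
        cor(times, fractions, method = "spearman") < 0)
        stop("not an S-phase progression")
    if (all(fractions == fractions[1L]))
        stop("not an S-phase progression")
    e0 <- .firstCrossing(times, fractions, level = 0.5)
    if (is.na(e0)) e0 <- mean(range(times))
    start <- c(c = 0, d = 1, b = -0.2, e = e0, f = 1)
    lower <- c(c = -0.05, d = 0.8, b = -5, e = min(times) - 30, f = 0.1)
    upper <- c(c = 0.2, d = 1.05, b = -0.001, e = max(times) + 30, f = 10)
    fit <- nls.lm(par = pmin(pmax(start, lower), upper),
        fn = function(p) sigmoidValue(p, times) - fractions,
        lower = lower, upper = upper,
        control = nls.lm.control(maxiter = 500))
    new("BulkCurve", times = as.numeric(times),
        fractions = as.numeric(fractions), params = fit$par,
        converged = fit$info %in% 1:3)
}

#' Replicated fraction predicted by a fitted bulk curve
#' @param curve a [BulkCurve-class].
#' @param t time(s) in minutes.
#' @return predicted fraction(s), clipped to \[0, 1\].
#' @export
predictBulkFraction <- function(curve, t) {
    pmin(1, pmax(0, sigmoidValue(bulkParams(curve), t)))
}

#' Per-window Trep profile from a replication time course
#'
#' Fits [fitWindow()] in every window of a set of bulk-scaled profiles
#' sharing one grid and derives Trep by the closed form. Fits operate on
#' the raw windowed values; no smoothing is applied first.
#'
#' @param profiles list of [RatioProfile-class] objects with tag
#'   `"bulk_scaled"`, one per timepoint.
#' @param times sample times in minutes (same order as `profiles`).
#' @param control forwarded to [fitWindow()].
#' @return a [TrepTrack-class].
#' @export
trepProfile <- function(profiles, times, control = list()) {
    if (length(profiles) < 3L) stop("need at least 3 timepoints")
    if (length(profiles) != length(times))
        stop("profiles and times lengths differ")
    tags <- vapply(profiles, normalizationTag, "")
    if (any(tags != "bulk_scaled"))
        stop("trepProfile requires bulk-scaled profiles; got tag '",
            tags[tags != "bulk_scaled"][1L], "'")
    grid <- trackGrid(profiles[[1L]])
    for (p in profiles[-1L])
        if (!identical(windowRanges(trackGrid(p)), windowRanges(grid)))
            stop("profiles are on different grids")
    vals <- vapply(profiles, profileValues, numeric(nWindows(grid)))
    n <- nWindows(grid)
    trep <- rep(NA_real_, n); resid <- rep(NA_real_, n)
    conv <- rep(FALSE, n); reason <- character(n)
    for (i in seq_len(n)) {
        fw <- fitWindow(times, vals[i, ], control = control)
        trep[i] <- fw$trep; resid[i] <- fw$residual
        conv[i] <- fw$converged; reason[i] <- fw$reason
    }
    new("TrepTrack", grid = grid, trep = trep, residual = resid,
        converged = conv, maskReason = reason)
}

#' Write a Trep track as TSV
#'
#' Columns: chrom, start, end (0-based half-open), trep_min, residual,
#' converged, mask_reason.
#'
#' @param track a [TrepTrack-class].
#' @param path output path.
#' @export
writeTrepTSV <- function(track, path) {
    gr <- windowRanges(track)
    df <- data.frame(chrom = as.character(seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
        trep_min = trepValues(track), residual = fitResiduals(track),
        converged = as.integer(fitConverged(track)),
        mask_reason = maskReasons(track))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
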
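## Statistical comparison of two replication profiles (e.g. haploid versus
## diploid sort-seq): per-window significance from Poisson counting error
## and genome-wide correlation.

#' Compare two replication profiles window by window
#'
#' Builds the mean-1 ratio profile for each condition from its replicating
#' and nonreplicating count tracks, then tests each jointly-included
#' window for a difference. The variance of each ratio is propagated from
#' Poisson counting error by the delta method,
#' `var(ratio) ~ ratio^2 (1/n_rep + 1/n_nonrep)`, the z-score is
#' `diff / sqrt(var_A + var_B)`, and two-sided normal p-values are
#' thresholded at 0.001 and 0.01 (matching the conventional display
#' thresholds). No multiple-testing correction is applied by default; set
#' `adjust = TRUE` for Benjamini-Hochberg adjusted p-values in `padj`.
#'
#' @param aRep,aNonrep [CountTrack-class] pair for condition A.
#' @param bRep,bNonrep [CountTrack-class] pair for condition B.
#' @param adjust add Benjamini-Hochberg adjusted p-values.
#' @return list with `table` (per-window data.frame: chrom, start, end,
#'   included, valueA, valueB, diff, se, z, p, flag001, flag01),
#'   `correlation` (Pearson over jointly included windows),
#'   `flagRate001`, `flagRate01`, `biasFraction` (fraction of p < 0.01
#'   windows with A > B) and `nIncluded`.
#' @export
compareProfiles <- function(aRep, aNonrep, bRep, bNonrep, adjust = FALSE) {
    grid <- trackGrid(aRep)
    for (tr in list(aNonrep, bRep, bNonrep))
        if (!identical(windowRanges(trackGrid(tr)), windowRanges(grid)))
            stop("count tracks are on different grids")
    pa <- ratioProfile(aRep, aNonrep)
    pb <- ratioProfile(bRep, bNonrep)
    incl <- !excludedWindows(pa) & !excludedWindows(pb)
    va <- profileValues(pa); vb <- profileValues(pb)
    varA <- varB <- rep(NA_real_, nWindows(grid))
    ca <- readCounts(aRep); cna <- readCounts(aNonrep)
    cb <- readCounts(bRep); cnb <- readCounts(bNonrep)
    varA[incl] <- va[incl]^2 *
        (1 / pmax(ca[incl], 1L) + 1 / pmax(cna[incl], 1L))
    varB[incl] <- vb[incl]^2 *
        (1 / pmax(cb[incl], 1L) + 1 / pmax(cnb[incl], 1L))
    diffv <- va - vb
    se <- sqrt(varA + varB)
    z <- diffv / se
    p <- 2 * pnorm(-abs(z))
    flag001 <- !is.na(p) & p < 0.001
    flag01 <- !is.na(p) & p < 0.01
    gr <- windowRanges(grid)
    table <- data.frame(chrom = as.character(seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
        included = incl, valueA = va, valueB = vb, diff = diffv, se = se,
        z = z, p = p, flag001 = flag001, flag01 = flag01)
    if (adjust) {
        table$padj <- NA_real_
        table$padj[incl] <- p.adjust(p[incl], method = "BH")
    }
    nFlag01 <- sum(flag01)
    list(table = table,
        correlation = cor(va[incl], vb[incl]),
        flagRate001 = sum(flag001) / sum(incl),
        flagRate01 = nFlag01 / sum(incl),
        biasFraction = if (nFlag01 > 0)
            sum(diffv[flag01] > 0) / nFlag01 else NA_real_,
        nIncluded = sum(incl))
}

#' Contiguous runs of significantly different windows
#'
#' Maximal runs of at least `minRun` flagged windows per chromosome,
#' bridged across single-window gaps. A real change in origin activity
#' flags a large contiguous part of its replicon, whereas random counting
#' error flags isolated windows; runs separate the two patterns.
#'
#' @param result a [compareProfiles()] result.
#' @param minRun minimum run length in windows (default 5).
#' @param level which flag column to use: `"0.01"` or `"0.001"`.
#' @return `GRanges` of the runs with an `nWindows` column (possibly
#'   empty).
#' @export
flaggedRuns <- function(result, minRun = 5L, level = c("0.01", "0.001")) {
    level <- match.arg(level)
    tab <- result$table
    flags <- if (level == "0.01") tab$flag01 else tab$flag001
    out <- list()
    for (ch in unique(tab$chrom)) {
        idx <- which(tab$chrom == ch)
        f <- flags[idx]
        ## bridge single-window gaps between flagged neighbors
        if (length(f) >= 3L) {
            i <- 2:(length(f) - 1L)
            f[i[!f[i] & f[i - 1L] & f[i + 1L]]] <- TRUE
        }
        r <- rle(f)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in seq_along(r$lengths)) {
            if (!r$values[j] || r$lengths[j] < minRun) next
            i0 <- idx[starts[j]]; i1 <- idx[ends[j]]
            out[[length(out) + 1L]] <- data.frame(chrom = ch,
                start = tab$start[i0], end = tab$end[i1],
                nWindows = r$lengths[j])
        }
    }
    if (!length(out)) {
        gr <- GRanges()
        mcols(gr)$nWindows <- integer(0)
        return(gr)
    }
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    mcols(gr)$nWindows <- df$nWindows
    gr
}
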
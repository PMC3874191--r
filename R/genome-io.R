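## Standard-format I/O. Coordinates are 0-based half-open on disk (BED,
## bedGraph, chrom.sizes dialects) and 1-based closed inside GRanges, the
## usual Bioconductor convention; conversion happens only here.

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp. File order
#' is preserved and defines the genome-wide chromosome (and hence window)
#' ordering.
#'
#' @param path path to the chrom.sizes TSV.
#' @return a `Seqinfo` describing the genome layout.
#' @examples
#' tf <- tempfile()
#' writeLines("chrI\t230218", tf)
#' readChromSizes(tf)
#' @export
readChromSizes <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no chromosomes in ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(parts)) {
        if (length(parts[[i]]) < 2L)
            stop("malformed chrom.sizes line ", i, ": expected name<TAB>length")
    }
    nm <- vapply(parts, `[[`, "", 1L)
    lenChr <- vapply(parts, `[[`, "", 2L)
    len <- suppressWarnings(as.numeric(lenChr))
    bad <- which(is.na(len) | len != floor(len))
    if (length(bad))
        stop("non-integer chromosome length at line ", bad[1L])
    if (any(len < 1)) stop("chromosome length must be >= 1")
    dup <- nm[duplicated(nm)]
    if (length(dup)) stop("duplicate chromosome name: ", dup[1L])
    if (any(!nzchar(nm))) stop("empty chromosome name")
    Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Write a chrom.sizes file
#' @param layout a `Seqinfo`.
#' @param path output path.
#' @export
writeChromSizes <- function(layout, path) {
    sl <- seqlengths(layout)
    writeLines(sprintf("%s\t%d", names(sl), sl), path)
    invisible(path)
}

.readBedTable <- function(path) {
    # BED3+ lines may have differing field counts (named/unnamed records)
    nf <- max(utils::count.fields(path, sep = "\t", comment.char = "#"))
    df <- tryCatch(
        read.table(path, sep = "\t", header = FALSE, quote = "",
            comment.char = "#", stringsAsFactors = FALSE, fill = TRUE,
            col.names = paste0("V", seq_len(nf))),
        error = function(e) stop("cannot parse BED file ", path, ": ",
            conditionMessage(e)))
    if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
    if (!is.numeric(df[[2L]]) || !is.numeric(df[[3L]]))
        stop("BED start/end columns must be integer: ", path)
    df
}

#' Read uniquely-mapped read positions from a BED3/BED6 file
#'
#' Each record is one read; its anchor is the 5'-most genomic coordinate
#' (the interval start) irrespective of strand, so plus- and minus-strand
#' reads are counted identically. Reads on chromosomes absent from the
#' layout are dropped with a message. Uniqueness/duplicate filtering is
#' assumed to have happened upstream.
#'
#' @param path BED3/BED6 path (0-based half-open).
#' @param layout `Seqinfo` genome layout.
#' @return sorted width-1 `GRanges` of read anchors; `metadata()$dropped`
#'   holds the number of dropped off-layout reads.
#' @export
readReadsBed <- function(path, layout) {
    df <- .readBedTable(path)
    start0 <- df[[2L]]; end0 <- df[[3L]]
    bad <- which(start0 >= end0)
    if (length(bad)) stop("start >= end at line ", bad[1L], " of ", path)
    if (any(start0 < 0)) stop("negative start coordinate in ", path)
    sl <- seqlengths(layout)
    known <- df[[1L]] %in% names(sl)
    dropped <- sum(!known)
    if (dropped > 0L)
        message("readReadsBed: dropped ", dropped,
            " read(s) on chromosomes absent from layout")
    df <- df[known, , drop = FALSE]
    oob <- which(df[[2L]] >= sl[df[[1L]]])
    if (length(oob)) stop("read anchor outside chromosome bounds (line ",
        which(known)[oob[1L]], " of ", path, ")")
    gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, width = 1L),
        seqinfo = layout)
    gr <- GenomicRanges::sort(gr)
    metadata(gr)$dropped <- dropped
    metadata(gr)$total <- length(gr)
    gr
}

#' Read known replication origins from a BED file
#'
#' Each interval is reduced to its midpoint `floor((start + end) / 2)`.
#' Unnamed records are auto-named `origin_<chrom>_<midpoint>`; duplicate
#' names are made unique. Records are sorted by chromosome order, then
#' midpoint.
#'
#' @param path BED3+ path.
#' @param layout `Seqinfo` genome layout.
#' @return width-1 `GRanges` at origin midpoints with a `name` column.
#' @export
readOriginsBed <- function(path, layout) {
    df <- .readBedTable(path)
    sl <- seqlengths(layout)
    if (any(!df[[1L]] %in% names(sl)))
        stop("origin on chromosome absent from layout: ",
            df[[1L]][!df[[1L]] %in% names(sl)][1L])
    if (any(df[[2L]] < 0 | df[[3L]] > sl[df[[1L]]]))
        stop("origin interval out of chromosome bounds in ", path)
    if (any(df[[2L]] >= df[[3L]]))
        stop("origin interval with start >= end in ", path)
    mid0 <- (df[[2L]] + df[[3L]]) %/% 2
    nm <- if (ncol(df) >= 4L) as.character(df[[4L]]) else rep(NA_character_,
        nrow(df))
    auto <- is.na(nm) | !nzchar(nm) | nm == "."
    nm[auto] <- sprintf("origin_%s_%d", df[[1L]][auto], mid0[auto])
    nm <- make.unique(nm)
    gr <- GRanges(df[[1L]], IRanges(mid0 + 1L, width = 1L), seqinfo = layout)
    mcols(gr)$name <- nm
    GenomicRanges::sort(gr)
}

#' Write a BED6 file of origin midpoints
#' @param origins width-1 `GRanges` with a `name` column.
#' @param path output path.
#' @export
writeOriginsBed <- function(origins, path) {
    start0 <- GenomicRanges::start(origins) - 1L
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+",
        as.character(seqnames(origins)), start0, start0 + 1L,
        mcols(origins)$name), path)
    invisible(path)
}

#' Write a windowed profile as bedGraph
#'
#' One `chrom start end value` line per included window (excluded windows
#' are omitted); values are printed with 6 significant digits; coordinates
#' are 0-based half-open per the bedGraph standard.
#'
#' @param profile a [RatioProfile-class] (or numeric values congruent with
#'   `grid`).
#' @param path output path.
#' @param grid required when `profile` is a bare numeric vector.
#' @export
writeBedGraph <- function(profile, path, grid = NULL) {
    if (is(profile, "RatioProfile")) {
        grid <- trackGrid(profile)
        vals <- profileValues(profile)
        keep <- !excludedWindows(profile)
    } else {
        if (is.null(grid)) stop("grid required for bare values")
        vals <- as.numeric(profile)
        if (length(vals) != nWindows(grid))
            stop("values length does not match grid")
        keep <- !is.na(vals)
    }
    gr <- windowRanges(grid)[keep]
    writeLines(sprintf("%s\t%d\t%d\t%s", as.character(seqnames(gr)),
        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
        sprintf("%#.6g", vals[keep])), path)
    invisible(path)
}

#' Read a bedGraph written by [writeBedGraph()] back onto a grid
#'
#' Windows absent from the file become excluded windows.
#'
#' @param path bedGraph path.
#' @param grid the [WindowGrid-class] the file was written from.
#' @param normalization tag to stamp on the resulting profile.
#' @return a [RatioProfile-class].
#' @export
readBedGraph <- function(path, grid, normalization = "raw") {
    df <- read.table(path, sep = "\t", header = FALSE,
        stringsAsFactors = FALSE)
    if (ncol(df) != 4L) stop("bedGraph needs 4 columns: ", path)
    gr <- windowRanges(grid)
    key <- paste(as.character(seqnames(gr)), GenomicRanges::start(gr) - 1L)
    hit <- match(paste(df[[1L]], df[[2L]]), key)
    if (any(is.na(hit)))
        stop("bedGraph window not on grid at line ", which(is.na(hit))[1L])
    vals <- rep(NA_real_, nWindows(grid))
    vals[hit] <- df[[4L]]
    newRatioProfile(grid, vals, excluded = is.na(vals),
        normalization = normalization)
}

#' Write a lossless profile TSV
#'
#' Columns: chrom, start, end (0-based half-open), value (`NA` when
#' excluded), excluded flag, not_smoothed flag.
#'
#' @param profile a [RatioProfile-class].
#' @param path output path.
#' @export
writeProfileTSV <- function(profile, path) {
    gr <- windowRanges(profile)
    df <- data.frame(chrom = as.character(seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        value = profileValues(profile),
        excluded = as.integer(excludedWindows(profile)),
        not_smoothed = as.integer(notSmoothedFlags(profile)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a profile TSV written by [writeProfileTSV()]
#' @param path TSV path.
#' @param grid the grid the profile lives on (reconstructed from the file
#'   when `NULL`, using `layout`).
#' @param layout `Seqinfo`; required when `grid` is `NULL`.
#' @param normalization tag to stamp on the profile.
#' @return a [RatioProfile-class].
#' @export
readProfileTSV <- function(path, grid = NULL, layout = NULL,
        normalization = "raw") {
    df <- read.table(path, sep = "\t", header = TRUE,
        stringsAsFactors = FALSE)
    if (is.null(grid)) {
        if (is.null(layout)) stop("need grid or layout")
        grid <- windowGrid(layout, windowSize = max(df$end - df$start))
    }
    if (nrow(df) != nWindows(grid)) stop("profile TSV does not match grid")
    vals <- df$value
    vals[df$excluded == 1L] <- NA_real_
    newRatioProfile(grid, vals, excluded = df$excluded == 1L,
        normalization = normalization,
        notSmoothed = if ("not_smoothed" %in% names(df))
            df$not_smoothed == 1L else NULL)
}
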
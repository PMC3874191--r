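## Central S4 containers. The genome layout itself is a GenomeInfoDb::Seqinfo;
## mapped reads and origins are width-1 GRanges. The classes below add the
## windowed-track semantics (congruence with a grid, exclusion masks,
## normalization state) that plain vectors cannot police.

#' Fixed-width window grid over a genome
#'
#' Tiles every chromosome of a genome layout with non-overlapping windows of
#' a fixed width. The last window of each chromosome may be shorter
#' ("partial") when the chromosome length is not a multiple of the window
#' size. Window order follows the chromosome order of the layout and defines
#' the genome-wide window ordering used by every track type.
#'
#' @slot ranges `GRanges` of the windows, carrying the layout's `Seqinfo`.
#' @slot windowSize nominal window width in bp.
#' @exportClass WindowGrid
setClass("WindowGrid",
    representation(ranges = "GRanges", windowSize = "integer"))

setValidity("WindowGrid", function(object) {
    w <- object@windowSize
    if (length(w) != 1L || is.na(w) || w < 1L)
        return("windowSize must be a single integer >= 1")
    gr <- object@ranges
    sl <- seqlengths(seqinfo(gr))
    if (any(is.na(sl))) return("grid Seqinfo must have chromosome lengths")
    wd <- GenomicRanges::width(gr)
    if (any(wd > w)) return("window wider than windowSize")
    TRUE
})

#' Per-window integer read counts for one sample
#'
#' @slot grid the [WindowGrid-class] the counts live on.
#' @slot counts non-negative integer counts, one per window.
#' @slot total total number of reads (equals `sum(counts)`).
#' @exportClass CountTrack
setClass("CountTrack",
    representation(grid = "WindowGrid", counts = "integer", total = "numeric"))

setValidity("CountTrack", function(object) {
    if (length(object@counts) != nWindows(object@grid))
        return("counts length does not match grid")
    if (any(object@counts < 0L)) return("negative counts")
    if (sum(as.numeric(object@counts)) != object@total)
        return("total does not equal sum of counts")
    TRUE
})

#' Per-window relative copy number with exclusion mask
#'
#' Values are only defined (non-`NA`) for included windows. The
#' `normalization` tag records the profile's state and changes only through
#' the normalization operations: `"genome_mean_1"` after [ratioProfile()],
#' `"baseline_1"` after [normalizeBaseline()], `"bulk_scaled"` after
#' [scaleToBulk()] (with `bulkFraction` recording the replicated fraction).
#' `notSmoothed` flags windows where [fourierSmooth()] retained the raw
#' value (chromosome ends, low data density).
#'
#' @exportClass RatioProfile
setClass("RatioProfile",
    representation(grid = "WindowGrid", values = "numeric",
        excluded = "logical", normalization = "character",
        bulkFraction = "numeric", notSmoothed = "logical"))

setValidity("RatioProfile", function(object) {
    n <- nWindows(object@grid)
    if (length(object@values) != n || length(object@excluded) != n ||
        length(object@notSmoothed) != n)
        return("values/excluded/notSmoothed length does not match grid")
    if (any(!is.na(object@values[object@excluded])))
        return("excluded windows must carry no value")
    incl <- object@values[!object@excluded]
    if (any(!is.finite(incl)))
        return("included windows must carry finite values")
    if (!object@normalization %in%
            c("raw", "genome_mean_1", "baseline_1", "bulk_scaled"))
        return("unknown normalization tag")
    TRUE
})

#' Per-window median replication time derived from sigmoid fits
#'
#' @slot trep fitted median replication time (minutes); `NA` where masked.
#' @slot residual residual norm of the per-window fit.
#' @slot converged optimizer convergence flag per window.
#' @slot maskReason why a window is masked (`""` if fitted).
#' @exportClass TrepTrack
setClass("TrepTrack",
    representation(grid = "WindowGrid", trep = "numeric",
        residual = "numeric", converged = "logical", maskReason = "character"))

setValidity("TrepTrack", function(object) {
    n <- nWindows(object@grid)
    if (length(object@trep) != n || length(object@residual) != n ||
        length(object@converged) != n || length(object@maskReason) != n)
        return("slot lengths do not match grid")
    if (any(!is.na(object@trep) & object@maskReason != ""))
        return("masked windows must have NA trep")
    TRUE
})

#' Sigmoid fit of the bulk replicated fraction
#'
#' The flow-cytometry bulk curve: fraction of the genome replicated at each
#' time point of a synchronous S phase, fitted with the same five-parameter
#' sigmoid family as the per-window copy-number fits, rescaled to the
#' \[0, 1\] fraction scale.
#'
#' @exportClass BulkCurve
setClass("BulkCurve",
    representation(times = "numeric", fractions = "numeric",
        params = "numeric", converged = "logical"))

#' Ground-truth replication model for simulation
#'
#' Origins fire stochastically (normal firing time truncated at zero,
#' licensed with a per-origin competence probability) and forks move at a
#' constant velocity; the replication time of a locus in one cell is the
#' earliest arrival over that chromosome's licensed origins. S phase spans
#' `[sPhaseStart, sPhaseStart + sPhaseDuration]` minutes on the same clock
#' as the firing times.
#'
#' @slot layout `Seqinfo` of the simulated genome.
#' @slot origins data.frame with columns `chrom`, `position` (bp, 0-based),
#'   `name`, `firingMean` (min), `firingSD` (min), `competence` (0..1).
#' @slot forkVelocity fork speed in bp/min.
#' @slot sPhaseStart,sPhaseDuration S-phase interval in minutes.
#' @exportClass ReplicationModel
setClass("ReplicationModel",
    representation(layout = "Seqinfo", origins = "data.frame",
        forkVelocity = "numeric", sPhaseStart = "numeric",
        sPhaseDuration = "numeric"))

setValidity("ReplicationModel", function(object) {
    o <- object@origins
    need <- c("chrom", "position", "name", "firingMean", "firingSD",
        "competence")
    if (!all(need %in% names(o)))
        return(paste("origins must have columns:", paste(need, collapse = ", ")))
    if (object@forkVelocity <= 0) return("forkVelocity must be > 0")
    if (object@sPhaseDuration <= 0) return("sPhaseDuration must be > 0")
    if (any(o$firingSD < 0)) return("firingSD must be >= 0")
    if (any(o$competence < 0 | o$competence > 1))
        return("competence must be in [0, 1]")
    sl <- seqlengths(object@layout)
    if (!all(o$chrom %in% names(sl)))
        return("origin on chromosome absent from layout")
    if (any(o$position < 0 | o$position >= sl[o$chrom]))
        return("origin position outside chromosome bounds")
    if (!all(names(sl) %in% o$chrom))
        return("every chromosome needs at least one origin")
    TRUE
})
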
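#' @import methods
#' @importFrom stats optimize pnorm pt qnorm rpois runif rlnorm rexp setNames
#'   var cor complete.cases quantile median
#' @importFrom utils head read.delim write.table
NULL

#' F84 model parameters
#'
#' @slot freqs stationary base frequencies (A, C, G, T).
#' @slot tsTv expected transition/transversion ratio.
#' @slot a,b scaled within-class and any-base event intensities.
#' @aliases F84Params
#' @exportClass F84Params
setClass("F84Params",
  representation(freqs = "numeric", tsTv = "numeric",
                 a = "numeric", b = "numeric"))

setValidity("F84Params", function(object) {
  if (length(object@freqs) != 4L || any(object@freqs <= 0))
    return("freqs must be 4 positive values")
  if (abs(sum(object@freqs) - 1) > 1e-8) return("freqs must sum to 1")
  if (object@tsTv <= 0) return("tsTv must be > 0")
  TRUE
})

#' Calibrated ultrametric species tree
#'
#' Wraps an ape \code{phylo} tree whose branch lengths are in millions of
#' years, together with node ages and an enumerable branch table. Leaves are
#' at age 0; internal node ages increase towards the root.
#'
#' @slot tree rooted bifurcating \code{phylo} with edge lengths in My.
#' @slot ages numeric node ages (My), indexed by phylo node number.
#' @slot branches data.frame with one row per edge: \code{branch} (label:
#'   taxon name for terminal branches, child clade label otherwise),
#'   \code{parentAge}, \code{childAge}, \code{duration}, \code{terminal},
#'   \code{node} (child node number).
#' @aliases CalibratedTree
#' @exportClass CalibratedTree
setClass("CalibratedTree",
  representation(tree = "ANY", ages = "numeric", branches = "data.frame"))

setValidity("CalibratedTree", function(object) {
  b <- object@branches
  if (nrow(b) == 0L) return("no branches")
  if (any(b$parentAge <= b$childAge)) {
    return("parent age must exceed child age on every branch")
  }
  if (any(b$childAge < 0)) return("negative node age")
  TRUE
})

#' Pipeline configuration
#'
#' Holds every tunable threshold of the annotation/dating pipeline. Defaults
#' are the published settings of the genus-wide numt survey this package
#' models: 50-base maximum HSP separation, E-value 1e-6, 25-kb grouping
#' window, 200-base minimum rearrangement size, 200-base repeat adjacency,
#' 10-kb synteny flanks, alpha 0.05, ts/tv 2.0 and a 20-My recent-branch
#' cutoff.
#'
#' @aliases PipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    evalueThreshold = "numeric", hspSepMaxBases = "numeric",
    mergeWindowBases = "numeric", minEventBases = "numeric",
    repeatAdjacencyBases = "numeric", syntenyFlankBases = "numeric",
    minUnmaskedFlankBases = "numeric", significanceAlpha = "numeric",
    tsTvRatio = "numeric", recentBranchAgeCutoffMy = "numeric",
    exclusionSplitLabel = "character", recentBranches = "character",
    matchScore = "numeric", mismatchScore = "numeric",
    gapOpen = "numeric", gapExtend = "numeric", wordSize = "numeric",
    karlinK = "numeric", maskWindow = "numeric", maskLocut = "numeric",
    maskHicut = "numeric", randomSeed = "numeric"))

setValidity("PipelineConfig", function(object) {
  pos <- c(object@hspSepMaxBases, object@mergeWindowBases,
           object@minEventBases, object@repeatAdjacencyBases,
           object@syntenyFlankBases, object@minUnmaskedFlankBases,
           object@recentBranchAgeCutoffMy, object@wordSize,
           object@maskWindow)
  if (any(pos <= 0)) return("length/age parameters must be > 0")
  if (object@significanceAlpha <= 0 || object@significanceAlpha >= 1) {
    return("significanceAlpha must lie in (0, 1)")
  }
  if (object@evalueThreshold <= 0) return("evalueThreshold must be > 0")
  if (object@wordSize < 8) return("wordSize must be >= 8")
  TRUE
})

#' A merged numt annotation
#'
#' One annotated nuclear copy of mitochondrial DNA: an ordered set of
#' aligned fragments on one scaffold, each mapping a nuclear interval to a
#' mitochondrial origin interval and strand. All coordinates are 0-based
#' half-open; conversion to BED/GFF3 conventions happens only at
#' serialization.
#'
#' @slot numtId,species,scaffold identifiers.
#' @slot fragments data.frame: \code{nucStart}, \code{nucEnd},
#'   \code{mitoStart}, \code{mitoEnd}, \code{strand} (+/-),
#'   \code{identity}, \code{originSpanning} (logical; fragment is one of
#'   the two sub-intervals of a circular-origin crossing).
#' @slot numtLength bases of numt sequence, excluding interruptions and
#'   internal duplications (width of the union of mitochondrial origin
#'   intervals).
#' @aliases NumtAnnotation
#' @exportClass NumtAnnotation
setClass("NumtAnnotation",
  representation(numtId = "character", species = "character",
                 scaffold = "character", fragments = "data.frame",
                 numtLength = "numeric"))

setValidity("NumtAnnotation", function(object) {
  fr <- object@fragments
  need <- c("nucStart", "nucEnd", "mitoStart", "mitoEnd", "strand",
            "identity", "originSpanning")
  if (!all(need %in% names(fr))) {
    return(paste("fragments must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(fr) == 0L) return("annotation must contain >= 1 fragment")
  if (is.unsorted(fr$nucStart)) return("fragments must be sorted by nucStart")
  if (any(fr$nucEnd <= fr$nucStart)) return("empty nuclear fragment interval")
  if (any(fr$identity <= 0 | fr$identity > 1)) {
    return("identity must lie in (0, 1]")
  }
  if (!all(fr$strand %in% c("+", "-"))) return("strand must be + or -")
  TRUE
})

#' Phylogenetic placement of a numt
#'
#' Result of attaching a numt to every branch of the fixed mitochondrial
#' species tree: per-branch log-likelihoods, the maximum likelihood branch,
#' the set of branches not significantly worse (KH-style test), the implied
#' insertion age window, and per-branch frequency-density weights
#' (proportional to branch duration within the window, summing to 1).
#'
#' @aliases PlacementResult
#' @exportClass PlacementResult
setClass("PlacementResult",
  representation(numtId = "character", table = "data.frame",
                 bestBranch = "character", ageMin = "numeric",
                 ageMax = "numeric", attachTime = "numeric",
                 excluded = "logical", lowInfo = "logical"))

setValidity("PlacementResult", function(object) {
  tb <- object@table
  if (!object@bestBranch %in% tb$branch[tb$inSet]) {
    return("best branch must belong to the significance set")
  }
  d <- tb$density
  if (any(d < -1e-12)) return("negative density weight")
  if (abs(sum(d) - 1) > 1e-6 && !object@excluded) {
    return("density weights must sum to 1")
  }
  if (object@ageMin >= object@ageMax) return("ageMin must be < ageMax")
  TRUE
})

#' Paralogy/orthology verdict for a pair of numts
#'
#' @aliases HomologyVerdict
#' @exportClass HomologyVerdict
setClass("HomologyVerdict",
  representation(ids = "character", relation = "character",
                 deltaLogL = "numeric", pValue = "numeric",
                 synteny = "character"))

setValidity("HomologyVerdict", function(object) {
  if (!object@relation %in% c("paralog", "ortholog", "unresolved",
                              "untestable")) {
    return("unknown relation")
  }
  if (!object@synteny %in% c("yes", "no", "untestable")) {
    return("synteny must be yes/no/untestable")
  }
  TRUE
})

#' Numt turnover rate estimates
#'
#' @slot insertionRate insertions per million years (genus average).
#' @slot duplicationRate duplications per numt per million years.
#' @slot deletionRate steady-state deletions per numt per million years.
#' @slot halfLife ln(2)/deletionRate, in My (Inf when deletionRate is 0).
#' @slot perBranch per-branch rate table.
#' @slot inputs list with the N_i, T, Dp, N values used.
#' @aliases RateEstimates
#' @exportClass RateEstimates
setClass("RateEstimates",
  representation(insertionRate = "numeric", duplicationRate = "numeric",
                 deletionRate = "numeric", halfLife = "numeric",
                 perBranch = "data.frame", inputs = "list"))

setValidity("RateEstimates", function(object) {
  vals <- c(object@insertionRate, object@duplicationRate,
            object@deletionRate)
  if (any(vals < 0)) return("rates must be nonnegative")
  if (object@deletionRate > 0 &&
      abs(object@halfLife - log(2) / object@deletionRate) > 1e-8) {
    return("halfLife must equal ln(2)/deletionRate")
  }
  TRUE
})
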
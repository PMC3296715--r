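## Branches that arose within the last ~20 My on the default genus tree:
## seven terminal branches plus three internal branches (the two youngest
## cherries and the stem of the melanogaster subgroup).
.RECENT_BRANCHES <- c("Dmel", "Dsim", "Dsec", "Dyak", "Dere", "Dmoj", "Dvir",
                      "simsec", "yakere", "melsub")

#' Construct a pipeline configuration
#'
#' All thresholds of the annotation, dating and rate pipeline in one flat
#' object. Defaults reproduce the published survey settings; every value can
#' be overridden. See [PipelineConfig-class].
#'
#' @param evalueThreshold maximum E-value for a reported hit (1e-6).
#' @param hspSepMaxBases maximum separation, on both query and subject, of
#'   HSPs combined into one linked hit (50).
#' @param mergeWindowBases hits on one scaffold closer than this are grouped
#'   for merging (25000, strict "gap < window").
#' @param minEventBases minimum detectable rearrangement size (200).
#' @param repeatAdjacencyBases distance within which a repeat counts as
#'   numt-adjacent (200).
#' @param syntenyFlankBases flanking sequence used for micro-synteny
#'   confirmation (10000 per side).
#' @param minUnmaskedFlankBases minimum unmasked flanking bases for a numt
#'   to be testable for micro-synteny (200).
#' @param significanceAlpha significance level for placement and homology
#'   tests (0.05).
#' @param tsTvRatio F84 transition/transversion ratio (2.0).
#' @param recentBranchAgeCutoffMy age cutoff defining the recent-branch set
#'   used for genus-average rates (20 My).
#' @param exclusionSplitLabel label of the deep split; numts whose age
#'   window extends past it are excluded from rate inputs.
#' @param recentBranches branch labels entering genus-average rates.
#' @param matchScore,mismatchScore,gapOpen,gapExtend,wordSize nucleotide
#'   scoring scheme and seed word size of the similarity search.
#' @param karlinK Karlin-Altschul K for the scoring scheme (lambda is fit
#'   numerically to the background composition at run time).
#' @param maskWindow,maskLocut,maskHicut entropy masking window (bases) and
#'   trigger/extension thresholds (bits).
#' @param randomSeed seed recorded with the run.
#' @return a validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(evalueThreshold = 1e-6,
                           hspSepMaxBases = 50,
                           mergeWindowBases = 25000,
                           minEventBases = 200,
                           repeatAdjacencyBases = 200,
                           syntenyFlankBases = 10000,
                           minUnmaskedFlankBases = 200,
                           significanceAlpha = 0.05,
                           tsTvRatio = 2.0,
                           recentBranchAgeCutoffMy = 20,
                           exclusionSplitLabel = "DrosSoph",
                           recentBranches = .RECENT_BRANCHES,
                           matchScore = 5, mismatchScore = -4,
                           gapOpen = -10, gapExtend = -2,
                           wordSize = 11, karlinK = 0.1,
                           maskWindow = 21, maskLocut = 1.4,
                           maskHicut = 1.6,
                           randomSeed = 1) {
  new("PipelineConfig",
      evalueThreshold = evalueThreshold, hspSepMaxBases = hspSepMaxBases,
      mergeWindowBases = mergeWindowBases, minEventBases = minEventBases,
      repeatAdjacencyBases = repeatAdjacencyBases,
      syntenyFlankBases = syntenyFlankBases,
      minUnmaskedFlankBases = minUnmaskedFlankBases,
      significanceAlpha = significanceAlpha, tsTvRatio = tsTvRatio,
      recentBranchAgeCutoffMy = recentBranchAgeCutoffMy,
      exclusionSplitLabel = exclusionSplitLabel,
      recentBranches = recentBranches,
      matchScore = matchScore, mismatchScore = mismatchScore,
      gapOpen = gapOpen, gapExtend = gapExtend, wordSize = wordSize,
      karlinK = karlinK, maskWindow = maskWindow, maskLocut = maskLocut,
      maskHicut = maskHicut, randomSeed = randomSeed)
}

#' Read or write a pipeline configuration as a flat YAML document
#'
#' @param path file path.
#' @return `readPipelineConfig` returns a [PipelineConfig-class];
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class] object.
#' @export
writePipelineConfig <- function(config, path) {
  sl <- slotNames(config)
  vals <- lapply(sl, function(s) slot(config, s))
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

## configured F84 model with given frequencies
configModel <- function(config, freqs) {
  f84Params(freqs, tsTv = config@tsTvRatio)
}
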
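#' @describeIn NumtAnnotation fragment table accessor
#' @param x object.
#' @export
setMethod("fragments", "NumtAnnotation", function(x) x@fragments)

#' @describeIn NumtAnnotation numt length (bases of mitochondrial origin
#'   sequence represented, excluding interruptions and internal
#'   duplications)
#' @export
setMethod("numtLength", "NumtAnnotation", function(x) x@numtLength)

#' @describeIn CalibratedTree branch table accessor
#' @param x object.
#' @export
setMethod("branchTable", "CalibratedTree", function(x) x@branches)

#' @describeIn CalibratedTree node ages in My
#' @export
setMethod("nodeAges", "CalibratedTree", function(x) x@ages)

#' @describeIn CalibratedTree taxon labels
#' @export
setMethod("taxa", "CalibratedTree", function(x) x@tree$tip.label)

#' @describeIn PlacementResult maximum likelihood branch label
#' @param x object.
#' @export
setMethod("bestBranch", "PlacementResult", function(x) x@bestBranch)

#' @describeIn PlacementResult branches not significantly worse than the
#'   best branch at the configured alpha
#' @export
setMethod("significanceSet", "PlacementResult",
          function(x) x@table$branch[x@table$inSet])

#' @describeIn PlacementResult insertion age window (t_min, t_max) in My
#' @export
setMethod("ageWindow", "PlacementResult",
          function(x) c(tMin = x@ageMin, tMax = x@ageMax))

#' @describeIn PlacementResult per-branch frequency-density weights
#' @export
setMethod("branchDensities", "PlacementResult",
          function(x) setNames(x@table$density, x@table$branch))

#' @describeIn HomologyVerdict relation call accessor
#' @param x object.
#' @export
setMethod("relation", "HomologyVerdict", function(x) x@relation)

setMethod("show", "F84Params", function(object) {
  cat("F84 model: tsTv =", object@tsTv, "\n  freqs:",
      paste(sprintf("%s=%.3f", BASES, object@freqs), collapse = " "), "\n")
})

setMethod("show", "CalibratedTree", function(object) {
  cat("CalibratedTree:", length(object@tree$tip.label), "taxa, root age",
      sprintf("%.1f My\n", max(object@ages)))
  cat("  taxa:", paste(head(object@tree$tip.label, 6), collapse = ", "),
      if (length(object@tree$tip.label) > 6) "...", "\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n",
      sprintf("  E-value <= %g; HSP sep <= %d b; merge window %d b\n",
              object@evalueThreshold, as.integer(object@hspSepMaxBases),
              as.integer(object@mergeWindowBases)),
      sprintf("  min event %d b; repeat adjacency %d b; alpha %.3f\n",
              as.integer(object@minEventBases),
              as.integer(object@repeatAdjacencyBases),
              object@significanceAlpha))
})

setMethod("show", "NumtAnnotation", function(object) {
  fr <- object@fragments
  cat(sprintf("NumtAnnotation %s (%s) on %s: %d fragment(s), %d b\n",
              object@numtId, object@species, object@scaffold, nrow(fr),
              as.integer(object@numtLength)))
  cat(sprintf("  span [%d, %d); strands %s\n", min(fr$nucStart),
              max(fr$nucEnd), paste(unique(fr$strand), collapse = "/")))
})

setMethod("show", "PlacementResult", function(object) {
  cat(sprintf("PlacementResult %s: best branch %s; window [%.2f, %.2f] My%s\n",
              object@numtId, object@bestBranch, object@ageMin, object@ageMax,
              if (object@excluded) " [excluded: window reaches deep split]"
              else ""))
  cat(sprintf("  %d branch(es) in significance set\n",
              sum(object@table$inSet)))
})

setMethod("show", "HomologyVerdict", function(object) {
  cat(sprintf("HomologyVerdict [%s]: %s (dlogL=%.2f, P=%.3g, synteny=%s)\n",
              paste(object@ids, collapse = ", "), object@relation,
              object@deltaLogL, object@pValue, object@synteny))
})

setMethod("show", "RateEstimates", function(object) {
  cat(sprintf(paste0("RateEstimates: insertion %.3f /My; duplication %.4f",
                     " /numt/My;\n  deletion %.4f /numt/My (half-life %s My)\n"),
              object@insertionRate, object@duplicationRate,
              object@deletionRate,
              if (is.finite(object@halfLife))
                sprintf("%.1f", object@halfLife) else "Inf"))
})
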
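## Phylogenetic placement and dating of numts on the fixed mitochondrial
## species tree, and paralog/ortholog tree tests.

#' Reference-anchored panel alignment of mitochondrial genomes
#'
#' Builds the once-per-dataset alignment of the mitochondrial panel (all
#' species plus outgroup) by anchoring every sequence to the host/reference
#' genome with pairwise global alignment and projecting onto reference
#' coordinates (insertions relative to the reference are dropped; reference
#' deletions become gaps and are later removed column-wise). When all
#' sequences have equal length and no indels are detected the alignment is
#' positional. An externally computed alignment (aligned FASTA, equal
#' widths) can be supplied instead anywhere a panel is accepted.
#'
#' @param mitos named character vector of mitochondrial sequences
#'   (including the outgroup).
#' @param reference name of the reference (host) sequence.
#' @return list: `aln` (character matrix, rows = taxa), `refCoords`
#'   (0-based reference coordinate of each column).
#' @export
panelAlignment <- function(mitos, reference = names(mitos)[1]) {
  stopifnot(reference %in% names(mitos))
  lens <- nchar(mitos)
  refLen <- lens[[reference]]
  if (all(lens == refLen)) {
    aln <- do.call(rbind, lapply(mitos, function(s)
      strsplit(toupper(s), "")[[1]]))
    rownames(aln) <- names(mitos)
    return(list(aln = aln, refCoords = 0:(refLen - 1L)))
  }
  mat <- matrix("-", length(mitos), refLen,
                dimnames = list(names(mitos), NULL))
  mat[reference, ] <- strsplit(toupper(mitos[[reference]]), "")[[1]]
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = FALSE)
  for (tx in setdiff(names(mitos), reference)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(mitos[[tx]])),
      Biostrings::DNAString(toupper(mitos[[reference]])),
      type = "global", substitutionMatrix = sub,
      gapOpening = 10, gapExtension = 2)
    pch <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sch <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    refPos <- cumsum(sch != "-")
    keep <- sch != "-"
    mat[tx, refPos[keep]] <- pch[keep]
  }
  list(aln = mat, refCoords = 0:(refLen - 1L))
}

#' Project a numt onto the panel alignment
#'
#' Aligns each annotated fragment of the numt pairwise to its
#' mitochondrial origin segment of the host genome, projects the numt
#' residues onto panel columns through the reference coordinates, and
#' removes every column containing a gap or N in any row. Interrupting
#' (non-numt) sequence never enters the alignment.
#'
#' @param numt a [NumtAnnotation-class].
#' @param scaffoldSeq character sequence of the numt's scaffold.
#' @param panel result of [panelAlignment()] whose reference is the host
#'   species' mitochondrial genome.
#' @param host name of the host row in the panel.
#' @param minColumns minimum retained columns for a testable projection.
#' @return list: `aln` (character matrix, panel rows + `"numt"`),
#'   `columns` (reference coordinates retained), or the character string
#'   `"untestable"` when no usable columns remain.
#' @export
projectAlignment <- function(numt, scaffoldSeq, panel, host,
                             minColumns = 1L) {
  stopifnot(host %in% rownames(panel$aln))
  refLen <- length(panel$refCoords)
  numtRow <- rep(NA_character_, refLen)
  fr <- numt@fragments
  hostSeq <- paste(panel$aln[host, ], collapse = "")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = FALSE)
  for (i in seq_len(nrow(fr))) {
    nseq <- substr(scaffoldSeq, fr$nucStart[i] + 1L, fr$nucEnd[i])
    nseq <- toupper(nseq)
    if (fr$strand[i] == "-") {
      nseq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(nseq)))
    }
    m1 <- fr$mitoStart[i]; m2 <- fr$mitoEnd[i]
    if (m2 > refLen) m2 <- refLen
    ref <- substr(hostSeq, m1 + 1L, m2)
    if (nchar(ref) == 0L) next
    if (nchar(nseq) == nchar(ref)) {
      ## positional (no indels in fragment)
      numtRow[(m1 + 1L):m2] <- strsplit(nseq, "")[[1]]
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(nseq), Biostrings::DNAString(ref),
        type = "global", substitutionMatrix = sub,
        gapOpening = 10, gapExtension = 2)
      pch <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      sch <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      refPos <- m1 + cumsum(sch != "-")
      keep <- sch != "-" & pch != "-"
      numtRow[refPos[keep]] <- pch[keep]
    }
  }
  aln <- rbind(panel$aln, numt = numtRow)
  ok <- colSums(is.na(aln) | aln == "-" | aln == "N") == 0L
  if (sum(ok) < minColumns) return("untestable")
  list(aln = aln[, ok, drop = FALSE], columns = panel$refCoords[ok])
}

#' Fit panel branch lengths (expected substitutions) on a calibrated tree
#'
#' A strict-clock scaling of the calibrated branch durations is optimized
#' first (one rate parameter), followed by optional per-edge refinement by
#' coordinate ascent. Fit once per dataset on the panel-only alignment and
#' reuse for every placement.
#'
#' @param panelAln character matrix of the panel alignment (rows = taxa;
#'   gap/N-free columns are selected internally).
#' @param ct the [CalibratedTree-class].
#' @param model an [F84Params-class]; empirical frequencies by default.
#' @param refineSweeps per-edge coordinate-ascent sweeps after the clock
#'   fit (default 1).
#' @param maxColumns columns subsampled for fitting (default 2000).
#' @return `phylo` with fitted edge lengths; edge order matches
#'   `branchTable(ct)`.
#' @export
fitPanelBranchLengths <- function(panelAln, ct, model = NULL,
                                  refineSweeps = 1, maxColumns = 2000) {
  ok <- colSums(is.na(panelAln) | panelAln == "-" | panelAln == "N") == 0L
  aln <- panelAln[, ok, drop = FALSE]
  if (ncol(aln) > maxColumns) {
    aln <- aln[, sort(sample.int(ncol(aln), maxColumns)), drop = FALSE]
  }
  codes <- alnToCodes(aln)
  if (is.null(model)) {
    model <- f84Params(empiricalFreqs(as.integer(codes)), 2.0)
  }
  phy <- ct@tree
  dur <- ct@branches$duration
  pats <- alnPatterns(codes[phy$tip.label, , drop = FALSE])
  pt <- ptreeFromPhylo(phy)
  lik <- function(lengths) {
    pt$lengths <- lengths
    pruneLogLik(pt, pats$leafLike, model, pats$weights)$logL
  }
  rate <- optimize(function(r) lik(dur * r), c(1e-6, 0.2),
                   maximum = TRUE, tol = 1e-6)$maximum
  lens <- dur * rate
  for (s in seq_len(refineSweeps)) {
    for (e in seq_along(lens)) {
      o <- optimize(function(x) { l <- lens; l[e] <- x; lik(l) },
                    c(1e-8, max(4, 3 * lens[e])), maximum = TRUE,
                    tol = 1e-4)
      lens[e] <- o$maximum
    }
  }
  phy$edge.length <- lens
  phy
}

## KH-style one-sided P value that `alt` is worse than `best`, from
## per-pattern log-likelihood differences with pattern weights.
khPValue <- function(bestPat, altPat, weights) {
  D <- bestPat - altPat
  n <- sum(weights)
  total <- sum(weights * D)
  if (total <= 0) return(1)
  mu <- total / n
  v <- sum(weights * (D - mu)^2) / max(1, n - 1)
  if (v <= 0) return(0)
  z <- total / sqrt(n * v)
  1 - pnorm(z)
}

## Optimize attachment of a pendant leaf on edge e; returns logL, per
## pattern logLik, frac and pendant length at the optimum.
optimAttach <- function(pt, e, leafLike, model, weights, label = "numt",
                        tol = 1e-4) {
  at <- ptreeAttach(pt, e, 0.5, 0.01, label)
  edgeLen <- pt$lengths[e]
  ev <- function(frac, pend) {
    at$lengths[at$stemEdge] <- edgeLen * (1 - frac)
    at$lengths[at$childEdge] <- edgeLen * frac
    at$lengths[at$pendantEdge] <- pend
    pruneLogLik(at, leafLike, model, weights)
  }
  frac <- 0.5
  pend <- optimize(function(p) ev(frac, p)$logL, c(1e-9, 2),
                   maximum = TRUE, tol = tol)$maximum
  if (edgeLen > 1e-9) {
    frac <- optimize(function(f) ev(f, pend)$logL, c(0.001, 0.999),
                     maximum = TRUE, tol = 1e-3)$maximum
  }
  pend <- optimize(function(p) ev(frac, p)$logL, c(1e-9, 2),
                   maximum = TRUE, tol = tol)$maximum
  res <- ev(frac, pend)
  list(logL = res$logL, patLogLik = res$patLogLik, frac = frac,
       pend = pend)
}

#' Place a numt on every branch of the fixed species tree
#'
#' For each branch of the fixed mitochondrial topology the numt is attached
#' as a pendant leaf; the attachment point along the branch and the pendant
#' length are optimized (coarse then golden-section refinement via Brent's
#' method, tolerance 1e-4 expected substitutions). The significance set
#' contains every branch whose optimum is not significantly worse than the
#' best branch under a one-sided KH-style per-site log-likelihood test at
#' `alpha`. The insertion age window spans the node ages of the in-group
#' significance set; per-branch frequency-density weights are proportional
#' to branch durations within the window and sum to 1. Numts whose window
#' extends past the configured deep split are flagged `excluded` (left out
#' of rate inputs); alignments with no placement signal are flagged
#' `lowInfo` with a window spanning the whole tree.
#'
#' @param aln projection from [projectAlignment()] (matrix with panel rows
#'   and a `"numt"` row), or the list it returns.
#' @param ct the [CalibratedTree-class] (with outgroup).
#' @param panelLengths `phylo` from [fitPanelBranchLengths()]; `NULL` fits
#'   a clock on the panel rows of `aln`.
#' @param config a [PipelineConfig-class] (alpha, ts/tv, exclusion split).
#' @param model optional [F84Params-class]; empirical frequencies from the
#'   alignment by default.
#' @param numtId id stored in the result.
#' @return a [PlacementResult-class].
#' @export
placeNumt <- function(aln, ct, panelLengths = NULL,
                      config = pipelineConfig(), model = NULL,
                      numtId = "numt") {
  if (is.list(aln)) aln <- aln$aln
  codes <- alnToCodes(aln)
  if (is.null(model)) {
    model <- f84Params(empiricalFreqs(as.integer(codes)), config@tsTvRatio)
  }
  phy <- ct@tree
  if (is.null(panelLengths)) {
    panelLengths <- fitPanelBranchLengths(
      aln[setdiff(rownames(aln), "numt"), , drop = FALSE], ct, model)
  }
  br <- ct@branches
  pats <- alnPatterns(codes[c(phy$tip.label, "numt"), , drop = FALSE])
  pt <- ptreeFromPhylo(phy)
  pt$lengths <- panelLengths$edge.length
  fits <- vector("list", nrow(br))
  for (e in seq_len(nrow(br))) {
    fits[[e]] <- optimAttach(pt, e, pats$leafLike, model, pats$weights)
  }
  logLs <- vapply(fits, `[[`, 0, "logL")
  bestE <- which.max(logLs)
  pv <- vapply(seq_along(fits), function(e)
    khPValue(fits[[bestE]]$patLogLik, fits[[e]]$patLogLik, pats$weights),
    0)
  inSet <- pv >= config@significanceAlpha
  inSet[bestE] <- TRUE
  lowInfo <- max(logLs) - min(logLs) < 1e-6
  ## in-group branches: descendants of the exclusion split node
  splitNode <- which(nodeLabels(ct) == config@exclusionSplitLabel)
  desc <- splitNode
  repeat {
    newd <- setdiff(phy$edge[phy$edge[, 1] %in% desc, 2], desc)
    if (!length(newd)) break
    desc <- c(desc, newd)
  }
  genus <- br$node %in% setdiff(desc, splitNode)
  excluded <- any(inSet & !genus) || lowInfo
  sel <- inSet & genus
  dens <- rep(0, nrow(br))
  if (any(sel)) {
    dens[sel] <- br$duration[sel] / sum(br$duration[sel])
    ageMin <- min(br$childAge[sel])
    ageMax <- max(br$parentAge[sel])
  } else {
    ageMin <- 0; ageMax <- max(ct@ages)
    excluded <- TRUE
  }
  attachTime <- br$childAge[bestE] + fits[[bestE]]$frac * br$duration[bestE]
  tab <- data.frame(branch = br$branch, logL = logLs, pValue = pv,
                    inSet = inSet, density = dens,
                    parentAge = br$parentAge, childAge = br$childAge,
                    pendant = vapply(fits, `[[`, 0, "pend"),
                    stringsAsFactors = FALSE)
  new("PlacementResult", numtId = numtId, table = tab,
      bestBranch = br$branch[bestE], ageMin = ageMin, ageMax = ageMax,
      attachTime = attachTime, excluded = excluded, lowInfo = lowInfo)
}

#' Tree test for paralogy/orthology of two numts
#'
#' Compares the best tree in which the two numts form a clade against the
#' best tree in which they attach to distinct branches, with the
#' mitochondrial panel fixed to the species tree, using a one-sided
#' KH-style per-site test. The numts are called paralogs (or orthologs,
#' depending on `mode`) when the clustered tree is significantly more
#' likely (P < alpha); otherwise the pair is `unresolved`. Pairs sharing
#' fewer than 100 gap-free columns are `untestable`.
#'
#' @param alnA,alnB projections of the two numts from
#'   [projectAlignment()] (over the same panel).
#' @param ct the [CalibratedTree-class].
#' @param mode `"paralog"` (same host species, overlapping origins) or
#'   `"ortholog"` (different species dated to the same internal branches).
#' @param config a [PipelineConfig-class].
#' @param panelLengths optional `phylo` of fitted panel lengths.
#' @param ids ids recorded in the verdict.
#' @param minSharedColumns minimum overlap (100).
#' @return a [HomologyVerdict-class].
#' @export
testHomology <- function(alnA, alnB, ct, mode = c("paralog", "ortholog"),
                         config = pipelineConfig(), panelLengths = NULL,
                         ids = c("numtA", "numtB"),
                         minSharedColumns = 100L) {
  mode <- match.arg(mode)
  if (identical(alnA, "untestable") || identical(alnB, "untestable")) {
    return(new("HomologyVerdict", ids = ids, relation = "untestable",
               deltaLogL = NA_real_, pValue = NA_real_,
               synteny = "untestable"))
  }
  shared <- intersect(alnA$columns, alnB$columns)
  if (length(shared) < minSharedColumns) {
    return(new("HomologyVerdict", ids = ids, relation = "untestable",
               deltaLogL = NA_real_, pValue = NA_real_,
               synteny = "untestable"))
  }
  ia <- match(shared, alnA$columns)
  ib <- match(shared, alnB$columns)
  phy <- ct@tree
  aln <- rbind(alnA$aln[phy$tip.label, ia, drop = FALSE],
               numtA = alnA$aln["numt", ia],
               numtB = alnB$aln["numt", ib])
  codes <- alnToCodes(aln)
  model <- f84Params(empiricalFreqs(as.integer(codes)), config@tsTvRatio)
  if (is.null(panelLengths)) {
    panelLengths <- fitPanelBranchLengths(
      aln[phy$tip.label, , drop = FALSE], ct, model)
  }
  pats <- alnPatterns(codes)
  pt <- ptreeFromPhylo(phy)
  pt$lengths <- panelLengths$edge.length
  ## attach numtA at its ML edge
  fitsA <- lapply(seq_len(nrow(pt$edges)), function(e)
    optimAttach(pt, e, pats$leafLike, model, pats$weights, label = "numtA"))
  bestA <- which.max(vapply(fitsA, `[[`, 0, "logL"))
  atA <- ptreeAttach(pt, bestA, fitsA[[bestA]]$frac, fitsA[[bestA]]$pend,
                     "numtA")
  ## clustered: numtB on numtA's pendant edge
  clust <- optimAttach(atA, atA$pendantEdge, pats$leafLike, model,
                       pats$weights, label = "numtB")
  ## unclustered: numtB on any other edge
  others <- setdiff(seq_len(nrow(atA$edges)), atA$pendantEdge)
  fitsB <- lapply(others, function(e)
    optimAttach(atA, e, pats$leafLike, model, pats$weights,
                label = "numtB"))
  bestB <- which.max(vapply(fitsB, `[[`, 0, "logL"))
  apart <- fitsB[[bestB]]
  delta <- clust$logL - apart$logL
  p <- khPValue(clust$patLogLik, apart$patLogLik, pats$weights)
  relation <- if (delta > 0 && p < config@significanceAlpha) mode
              else "unresolved"
  new("HomologyVerdict", ids = ids, relation = relation,
      deltaLogL = delta, pValue = p, synteny = "untestable")
}

#' Close paralog pairs into paralog sets
#'
#' Transitive closure of pairwise paralog verdicts; each resulting set
#' counts as a single founding duplication event chain (set of size k
#' implies k - 1 duplications, one event per set for rate purposes).
#'
#' @param pairs data.frame with columns `idA`, `idB`, `relation`.
#' @return list of character vectors (paralog sets of size >= 2).
#' @export
paralogSets <- function(pairs) {
  pp <- pairs[pairs$relation == "paralog", , drop = FALSE]
  if (nrow(pp) == 0L) return(list())
  ids <- unique(c(pp$idA, pp$idB))
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(pp))) {
    ra <- find(pp$idA[i]); rb <- find(pp$idB[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, "")
  unname(split(ids, roots))
}

#' Extract the masked flanking/interrupting sequence context of a numt
#'
#' Retrieves `flank` bases on each side of the numt span plus any
#' interrupting sequence between fragments; numt-annotated sequence (this
#' numt and any other supplied annotation) is hard-masked to N, repeats
#' and low-complexity sequence are soft-masked to lowercase.
#'
#' @param numt a [NumtAnnotation-class].
#' @param scaffoldSeq scaffold character sequence.
#' @param otherNumts other annotations on the same scaffold to hard-mask.
#' @param repeats optional repeat data.frame (`scaffold`, `start`, `end`).
#' @param config a [PipelineConfig-class].
#' @return character string of masked context sequence.
#' @export
flankContext <- function(numt, scaffoldSeq, otherNumts = list(),
                         repeats = NULL, config = pipelineConfig()) {
  fr <- numt@fragments
  len <- nchar(scaffoldSeq)
  span <- c(min(fr$nucStart), max(fr$nucEnd))
  lo <- max(0L, span[1] - config@syntenyFlankBases)
  hi <- min(len, span[2] + config@syntenyFlankBases)
  s <- seqToCodes(substr(scaffoldSeq, lo + 1L, hi))
  code <- s$code; masked <- s$masked
  hardMask <- function(a, b) {       # 0-based genome coords
    a <- max(a, lo); b <- min(b, hi)
    if (b > a) code[(a - lo + 1L):(b - lo)] <<- NA_integer_
  }
  for (i in seq_len(nrow(fr))) hardMask(fr$nucStart[i], fr$nucEnd[i])
  for (on in otherNumts) {
    ofr <- on@fragments
    for (i in seq_len(nrow(ofr))) hardMask(ofr$nucStart[i], ofr$nucEnd[i])
  }
  if (!is.null(repeats) && nrow(repeats)) {
    rr <- repeats[repeats$scaffold == numt@scaffold, , drop = FALSE]
    for (i in seq_len(nrow(rr))) {
      a <- max(rr$start[i], lo); b <- min(rr$end[i], hi)
      if (b > a) masked[(a - lo + 1L):(b - lo)] <- TRUE
    }
  }
  out <- codesToSeq(code, masked = masked)
  maskLowComplexity(out, config@maskWindow, config@maskLocut,
                    config@maskHicut)
}

#' Micro-synteny confirmation of a numt pair
#'
#' Cross-searches the masked flanking/interrupting contexts of two numts
#' ([flankContext()]); any hit at the configured E-value threshold is
#' evidence of micro-synteny (`"yes"`). Pairs where either context has
#' fewer than `minUnmaskedFlankBases` unmasked bases are `"untestable"`.
#'
#' @param contextA,contextB masked context sequences from [flankContext()].
#' @param config a [PipelineConfig-class].
#' @return `"yes"`, `"no"` or `"untestable"`.
#' @export
confirmMicrosynteny <- function(contextA, contextB,
                                config = pipelineConfig()) {
  unmasked <- function(x) {
    s <- seqToCodes(x)
    sum(!is.na(s$code) & !s$masked)
  }
  if (unmasked(contextA) < config@minUnmaskedFlankBases ||
      unmasked(contextB) < config@minUnmaskedFlankBases) {
    return("untestable")
  }
  h <- findHsps(contextA, contextB, config)
  if (nrow(h) > 0L) "yes" else "no"
}
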
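## Grouping of linked hits into numt annotations, rearrangement
## classification, and genomic-context statistics.

## Nuclear overlaps between consecutive fragments arise from alignment-end
## jitter across rearrangement junctions and are trimmed back; an overlap
## that would consume an entire fragment means the same nuclear bases carry
## two mitochondrial origins, which is a genuine contradiction.

#' Group linked hits on a scaffold for potential merging
#'
#' Single-linkage clustering of hit spans: hits that overlap or are
#' separated by a gap strictly smaller than `mergeWindow` bases (25 kb by
#' default) fall in one group. Groups are the connected components of the
#' gap graph and are maximal.
#'
#' @param chains chain summary data.frame from [linkHsps()] (one scaffold).
#' @param mergeWindow grouping window in bases.
#' @return integer vector of group ids, one per chain row.
#' @export
groupHits <- function(chains, mergeWindow = 25000) {
  if (nrow(chains) == 0L) return(integer(0))
  r <- IRanges::IRanges(chains$sStart + 1L, chains$sEnd)
  red <- IRanges::reduce(r, min.gapwidth = mergeWindow)
  S4Vectors::subjectHits(IRanges::findOverlaps(r, red, maxgap = 0L))
}

#' Merge a group of linked hits into a single numt annotation
#'
#' Automates the micro-synteny consistency check applied during curation of
#' merged numts: a group is accepted as one numt when its fragments can be
#' explained as a single mitochondrial source region transformed by the
#' allowed event grammar (colinear runs, inversions, internal deletions,
#' internal duplications, interruptions). The grammar is permissive; the
#' one inconsistency it rejects outright is a contradictory overlap, i.e.
#' the same nuclear bases assigned two different mitochondrial origins (an
#' overlap consuming an entire fragment). Partial nuclear overlaps are
#' alignment-end jitter across rearrangement junctions and are trimmed.
#' Fragments crossing the origin of a circular mitochondrial genome are
#' recognised from their wrap-around coordinates and flagged.
#'
#' @param hspFrags data.frame of member HSPs (columns as [findHsps()],
#'   same scaffold).
#' @param mitoLength mitochondrial genome length in bases.
#' @param numtId,species,scaffold identifiers for the annotation.
#' @param mitoTopology `"circular"` or `"linear"`.
#' @return a [NumtAnnotation-class], or a `"RejectedGroup"` object carrying
#'   a `"reason"` attribute when the group is rejected.
#' @export
mergeGroup <- function(hspFrags, mitoLength, numtId = "numt1",
                       species = "sp", scaffold = "scf",
                       mitoTopology = "circular") {
  fr <- hspFrags[order(hspFrags$sStart, hspFrags$qStart), , drop = FALSE]
  n <- nrow(fr)
  if (n == 0L) stop("empty group")
  ## resolve nuclear overlaps between consecutive fragments
  if (n > 1L) {
    for (i in 2:n) {
      ov <- fr$sEnd[i - 1] - fr$sStart[i]
      if (ov >= fr$sEnd[i] - fr$sStart[i]) {
        return(structure(list(), class = "RejectedGroup", reason = sprintf(
          "contradictory overlap: nuclear [%d,%d) assigned two origins",
          fr$sStart[i], fr$sEnd[i - 1])))
      }
      if (ov > 0) {
        fr$sStart[i] <- fr$sStart[i] + ov
        if (fr$strand[i] == "+") fr$qStart[i] <- fr$qStart[i] + ov
        else fr$qEnd[i] <- fr$qEnd[i] - ov
      }
    }
    fr <- fr[fr$sEnd > fr$sStart & fr$qEnd > fr$qStart, , drop = FALSE]
    n <- nrow(fr)
  }
  ## flag origin-spanning pairs on circular mitochondria: nuclear-adjacent
  ## fragments whose mito coordinates wrap through position 0
  spanFlag <- rep(FALSE, n)
  if (mitoTopology == "circular" && n > 1L) {
    for (i in seq_len(n - 1L)) {
      gapN <- fr$sStart[i + 1] - fr$sEnd[i]
      wrapPlus <- fr$strand[i] == "+" && fr$strand[i + 1] == "+" &&
        fr$qEnd[i] >= mitoLength - 50L && fr$qStart[i + 1] <= 50L
      wrapMinus <- fr$strand[i] == "-" && fr$strand[i + 1] == "-" &&
        fr$qStart[i] <= 50L && fr$qEnd[i + 1] >= mitoLength - 50L
      if (gapN <= 50L && (wrapPlus || wrapMinus)) {
        spanFlag[i] <- spanFlag[i + 1] <- TRUE
      }
    }
  }
  mitoCover <- IRanges::reduce(IRanges::IRanges(fr$qStart + 1L, fr$qEnd))
  new("NumtAnnotation", numtId = numtId, species = species,
      scaffold = scaffold,
      fragments = data.frame(
        nucStart = fr$sStart, nucEnd = fr$sEnd,
        mitoStart = fr$qStart, mitoEnd = fr$qEnd,
        strand = fr$strand, identity = fr$identity,
        originSpanning = spanFlag, stringsAsFactors = FALSE),
      numtLength = sum(IRanges::width(mitoCover)))
}

#' Classify gross rearrangements within a merged numt
#'
#' Four event types are recognised between/among the ordered fragments of
#' one numt, each reported only when it affects at least `minEvent` bases:
#' \describe{
#'   \item{interruption}{non-numt nuclear sequence between consecutive
#'     fragments (size in nuclear bases).}
#'   \item{deletion}{missing mitochondrial sequence between consecutive
#'     same-strand colinear fragments (size in mitochondrial bases;
#'     measured around the circle for origin-spanning numts).}
#'   \item{inversion}{a maximal run of fragments on the minority strand
#'     (size = the run's mitochondrial length).}
#'   \item{internal_duplication}{mitochondrial origin covered two or more
#'     times (size = multiply-covered bases, one event per contiguous
#'     region).}
#' }
#'
#' @param numt a [NumtAnnotation-class].
#' @param config a [PipelineConfig-class] (supplies `minEventBases`).
#' @param mitoLength mitochondrial genome length (for circular deletion
#'   distances); `NULL` treats the molecule as linear.
#' @return data.frame of events: `numtId`, `type`, `size`, evidence
#'   intervals (`nucStart`/`nucEnd` or `mitoStart`/`mitoEnd`).
#' @export
classifyRearrangements <- function(numt, config = pipelineConfig(),
                                   mitoLength = NULL) {
  fr <- numt@fragments
  minEvent <- config@minEventBases
  ev <- list()
  addEv <- function(type, size, ns = NA, ne = NA, ms = NA, me = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      numtId = numt@numtId, type = type, size = size,
      nucStart = ns, nucEnd = ne, mitoStart = ms, mitoEnd = me,
      stringsAsFactors = FALSE)
  }
  n <- nrow(fr)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      gapN <- fr$nucStart[i + 1] - fr$nucEnd[i]
      if (gapN >= minEvent) {
        addEv("interruption", gapN, ns = fr$nucEnd[i],
              ne = fr$nucStart[i + 1])
      }
      if (fr$strand[i] == fr$strand[i + 1]) {
        if (fr$strand[i] == "+") {
          gapM <- fr$mitoStart[i + 1] - fr$mitoEnd[i]
          ms <- fr$mitoEnd[i]; me <- fr$mitoStart[i + 1]
        } else {
          gapM <- fr$mitoStart[i] - fr$mitoEnd[i + 1]
          ms <- fr$mitoEnd[i + 1]; me <- fr$mitoStart[i]
        }
        ## negative gaps between non-overlapping origins wrap around a
        ## circular mitochondrial genome (a deletion that removed the
        ## origin-crossing stretch); overlapping origins are duplication
        ## territory and never deletions
        if (!is.null(mitoLength) && gapM < 0) {
          overlaps <- fr$mitoStart[i + 1] < fr$mitoEnd[i] &&
            fr$mitoEnd[i + 1] > fr$mitoStart[i]
          if (!overlaps) gapM <- gapM + mitoLength
        }
        if (gapM >= minEvent) addEv("deletion", gapM, ms = ms, me = me)
      }
    }
    ## inversions: maximal runs of fragments on the minority strand; the
    ## numt's reference orientation is taken as the strand with more
    ## fragments (ties broken by total length, then "+" wins so that a
    ## lone flipped fragment reports as the inversion)
    cntPlus <- sum(fr$strand == "+"); cntMinus <- sum(fr$strand == "-")
    nPlus <- sum(fr$nucEnd[fr$strand == "+"] - fr$nucStart[fr$strand == "+"])
    nMinus <- sum(fr$nucEnd[fr$strand == "-"] - fr$nucStart[fr$strand == "-"])
    minority <- if (cntMinus < cntPlus) "-"
                else if (cntPlus < cntMinus) "+"
                else if (nMinus <= nPlus) "-" else "+"
    if (cntMinus > 0 && cntPlus > 0) {
      r <- rle(fr$strand == minority)
      endI <- cumsum(r$lengths); startI <- endI - r$lengths + 1L
      for (k in which(r$values)) {
        idx <- startI[k]:endI[k]
        size <- sum(fr$mitoEnd[idx] - fr$mitoStart[idx])
        if (size >= minEvent) {
          addEv("inversion", size, ms = min(fr$mitoStart[idx]),
                me = max(fr$mitoEnd[idx]))
        }
      }
    }
    ## internal duplications: mito origin covered >= 2 times
    cov <- IRanges::coverage(IRanges::IRanges(fr$mitoStart + 1L, fr$mitoEnd))
    dup <- IRanges::slice(cov, lower = 2L, rangesOnly = TRUE)
    for (k in seq_along(dup)) {
      size <- IRanges::width(dup)[k]
      if (size >= minEvent) {
        addEv("internal_duplication", size,
              ms = IRanges::start(dup)[k] - 1L, me = IRanges::end(dup)[k])
      }
    }
  }
  if (length(ev) == 0L) {
    return(data.frame(numtId = character(), type = character(),
                      size = numeric(), nucStart = numeric(),
                      nucEnd = numeric(), mitoStart = numeric(),
                      mitoEnd = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, ev)
}

#' Annotate numts in one nuclear genome
#'
#' Full per-species annotation: entropy masking of mitochondrial query and
#' scaffolds, seed-and-extend search, HSP linking under the 50-base
#' separation rule, 25-kb grouping, and merging into numt annotations.
#' A linked hit covering >= 95\% of the mitochondrial genome at >= 99\%
#' identity is flagged for review (likely the organellar genome itself
#' included in the assembly) rather than silently annotated.
#'
#' @param mito mitochondrial genome (character string, or `DNAStringSet`
#'   of length 1 from [loadSequences()]).
#' @param scaffolds named character vector or `DNAStringSet` of nuclear
#'   scaffolds.
#' @param species species label used in numt ids.
#' @param config a [PipelineConfig-class].
#' @param mask apply [maskLowComplexity()] to query and scaffolds first.
#' @return list with `numts` (list of [NumtAnnotation-class]), `events`
#'   (rearrangement table over all numts), `hsps` (all retained HSPs with
#'   scaffold and chain columns), `flagged` (review flags), `rejected`
#'   (rejected group diagnostics).
#' @export
annotateGenome <- function(mito, scaffolds, species = "sp",
                           config = pipelineConfig(), mask = TRUE) {
  if (inherits(mito, "DNAStringSet")) mito <- as.character(mito[[1]])
  if (inherits(scaffolds, "DNAStringSet")) {
    scaffolds <- setNames(as.character(scaffolds), names(scaffolds))
  }
  mitoLength <- nchar(mito)
  if (mask) {
    mito <- maskLowComplexity(mito, config@maskWindow, config@maskLocut,
                              config@maskHicut)
  }
  numts <- list(); events <- list(); allHsps <- list()
  flagged <- character(0); rejected <- list()
  counter <- 0L
  for (scf in names(scaffolds)) {
    subj <- scaffolds[[scf]]
    if (mask) {
      subj <- maskLowComplexity(subj, config@maskWindow, config@maskLocut,
                                config@maskHicut)
    }
    hsps <- findHsps(mito, subj, config)
    if (nrow(hsps) == 0L) next
    linked <- linkHsps(hsps, config@hspSepMaxBases, config)
    grp <- groupHits(linked$chains, config@mergeWindowBases)
    hs <- linked$hsps
    hs$scaffold <- scf
    allHsps[[scf]] <- hs
    for (g in unique(grp)) {
      chainIds <- linked$chains$chain[grp == g]
      members <- hs[hs$chain %in% chainIds, , drop = FALSE]
      counter <- counter + 1L
      id <- sprintf("%s_numt%03d", species, counter)
      ann <- mergeGroup(members, mitoLength, numtId = id, species = species,
                        scaffold = scf)
      if (inherits(ann, "RejectedGroup")) {
        rejected[[id]] <- attr(ann, "reason")
        counter <- counter - 1L
        next
      }
      covered <- ann@numtLength / mitoLength
      if (covered >= 0.95 && mean(ann@fragments$identity) >= 0.99) {
        flagged <- c(flagged, id)
      }
      numts[[id]] <- ann
      ee <- classifyRearrangements(ann, config, mitoLength)
      if (nrow(ee)) events[[id]] <- ee
    }
  }
  list(numts = numts,
       events = if (length(events)) do.call(rbind, c(events,
                                                     make.row.names = FALSE))
                else classifyRearrangements(
                  new("NumtAnnotation", numtId = "x", species = "x",
                      scaffold = "x",
                      fragments = data.frame(nucStart = 0L, nucEnd = 1L,
                                             mitoStart = 0L, mitoEnd = 1L,
                                             strand = "+", identity = 1,
                                             originSpanning = FALSE),
                      numtLength = 1), config),
       hsps = if (length(allHsps)) do.call(rbind, c(allHsps,
                                                    make.row.names = FALSE))
              else NULL,
       flagged = flagged, rejected = rejected)
}

#' Repeat adjacency of numts and association test
#'
#' Flags each numt that lies within `adjacency` bases of an annotated
#' repeat (or whose interrupting sequence contains one), excluding numts
#' with less than 100 b of retrievable flanking sequence, and tests the
#' association against matched random control loci with Fisher's exact
#' test.
#'
#' @param numts list of [NumtAnnotation-class].
#' @param repeats data.frame of repeat annotations: `scaffold`, `start`,
#'   `end` (0-based half-open).
#' @param scaffoldLengths named vector of scaffold lengths.
#' @param config a [PipelineConfig-class].
#' @param nControls number of random control loci.
#' @return list: `flags` (per testable numt), `nAdjacent`, `nTestable`,
#'   `nExcluded`, `table` (2x2), `pValue`.
#' @export
associateRepeats <- function(numts, repeats, scaffoldLengths,
                             config = pipelineConfig(), nControls = 1000) {
  adj <- config@repeatAdjacencyBases
  if (nrow(repeats) == 0L) {
    flags <- setNames(rep(FALSE, length(numts)),
                      vapply(numts, function(n) n@numtId, ""))
    return(list(flags = flags, nAdjacent = 0L, nTestable = length(numts),
                nExcluded = 0L, table = NULL, pValue = 1))
  }
  repByScf <- split(IRanges::IRanges(repeats$start + 1L, repeats$end),
                    repeats$scaffold)
  flags <- logical(0); excluded <- 0L
  numtByScf <- list()
  for (nm in numts) {
    fr <- nm@fragments
    span <- c(min(fr$nucStart), max(fr$nucEnd))
    len <- scaffoldLengths[[nm@scaffold]]
    if (is.null(len) || is.na(len)) stop("unknown scaffold ", nm@scaffold)
    if (span[1] < 100 || len - span[2] < 100) {   # insufficient flank
      excluded <- excluded + 1L
      next
    }
    numtByScf[[nm@scaffold]] <- rbind(numtByScf[[nm@scaffold]],
                                      data.frame(s = span[1], e = span[2]))
    rr <- repByScf[[nm@scaffold]]
    hit <- FALSE
    if (!is.null(rr) && length(rr)) {
      ## adjacency window around the numt span (covers interruptions too)
      win <- IRanges::IRanges(max(1L, span[1] - adj + 1L), span[2] + adj)
      hit <- any(IRanges::overlapsAny(rr, win))
    }
    flags[nm@numtId] <- hit
  }
  ## control loci: uniform positions with the same flank requirement,
  ## outside annotated numts
  scfs <- names(scaffoldLengths)
  probs <- scaffoldLengths / sum(scaffoldLengths)
  ctrlHit <- logical(nControls)
  for (k in seq_len(nControls)) {
    repeat {
      scf <- sample(scfs, 1L, prob = probs)
      pos <- sample.int(scaffoldLengths[[scf]], 1L)
      if (pos < 100 || scaffoldLengths[[scf]] - pos < 100) next
      nn <- numtByScf[[scf]]
      if (!is.null(nn) && any(pos > nn$s & pos <= nn$e)) next
      break
    }
    rr <- repByScf[[scf]]
    ctrlHit[k] <- !is.null(rr) && length(rr) &&
      any(IRanges::overlapsAny(rr, IRanges::IRanges(max(1L, pos - adj),
                                                    pos + adj)))
  }
  tab <- matrix(c(sum(flags), sum(!flags), sum(ctrlHit), sum(!ctrlHit)),
                2, 2, dimnames = list(c("adjacent", "notAdjacent"),
                                      c("numt", "control")))
  pv <- stats::fisher.test(tab)$p.value
  list(flags = flags, nAdjacent = sum(flags), nTestable = length(flags),
       nExcluded = excluded, table = tab, pValue = pv)
}

#' Count numts located inside introns of protein-coding genes
#'
#' A numt is counted when its whole span lies within an annotated
#' transcript and overlaps no exon, i.e. it is fully intronic.
#'
#' @param numts list of [NumtAnnotation-class].
#' @param genes GFF3 file path, or a data.frame with columns `scaffold`,
#'   `type` (`mRNA`/`transcript` and `exon`), `start`, `end` (1-based
#'   inclusive as in GFF3), `id`, `parent`.
#' @return list: `count`, `fraction`, `intronic` (named logical).
#' @export
intronOverlap <- function(numts, genes) {
  if (is.character(genes)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 files requires the rtracklayer package")
    }
    g <- as.data.frame(rtracklayer::readGFF(genes))
    if (!all(c("seqid", "type", "start", "end") %in% names(g))) {
      stop("malformed GFF3: required columns missing")
    }
    genes <- data.frame(scaffold = as.character(g$seqid),
                        type = as.character(g$type),
                        start = g$start, end = g$end,
                        id = if ("ID" %in% names(g)) as.character(g$ID)
                             else NA_character_,
                        parent = if ("Parent" %in% names(g))
                          vapply(g$Parent, function(p)
                            if (length(p)) as.character(p[1])
                            else NA_character_, "")
                          else NA_character_,
                        stringsAsFactors = FALSE)
  }
  tx <- genes[genes$type %in% c("mRNA", "transcript"), , drop = FALSE]
  ex <- genes[genes$type == "exon", , drop = FALSE]
  intronic <- logical(0)
  for (nm in numts) {
    fr <- nm@fragments
    span1 <- min(fr$nucStart) + 1L   # to 1-based inclusive
    span2 <- max(fr$nucEnd)
    inTx <- tx$scaffold == nm@scaffold & tx$start <= span1 & tx$end >= span2
    ok <- FALSE
    if (any(inTx)) {
      hitExon <- any(ex$scaffold == nm@scaffold & ex$start <= span2 &
                       ex$end >= span1)
      ok <- !hitExon
    }
    intronic[nm@numtId] <- ok
  }
  list(count = sum(intronic),
       fraction = if (length(intronic)) sum(intronic) / length(intronic)
                  else NA_real_,
       intronic = intronic)
}
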
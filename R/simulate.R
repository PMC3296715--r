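## Forward simulator of mitochondrial genome evolution along a calibrated
## tree with numt insertions, nuclear duplications/deletions of numts, and
## gross structural rearrangements, all at known times. Emits genomes plus
## truth tables so that every downstream stage can be validated against a
## known answer.

#' Simulation parameters
#'
#' Defaults emulate the genus-scale study conditions: a ~16-kb, 78% A+T
#' circular mitochondrial genome evolving along the calibrated 11-species
#' tree (Anopheles outgroup), numt insertions as a Poisson process at 0.75
#' per lineage-My, nuclear substitution 6-fold slower than mitochondrial
#' (the reported nuclear/mito synonymous-rate ratio spans 4.5-9), numt
#' duplication at 0.010 and deletion at 0.052 per numt per My, and
#' per-class gross-rearrangement propensities matching the observed event
#' spectrum. Fragment lengths are log-normal on [200, mitoLength] so that
#' near-complete mitochondrial copies occur with nonzero probability.
#'
#' @param tree a [CalibratedTree-class]; insertions occur only on branches
#'   within the in-group clade named by `ingroupLabel`.
#' @param mitoLength mitochondrial genome length (bases).
#' @param atFraction mitochondrial A+T fraction.
#' @param mitoSubstRate mitochondrial substitution rate
#'   (substitutions/site/My).
#' @param nuclearRateDivisor nuclear rate = mitoSubstRate / divisor
#'   (must be >= 1; default 6).
#' @param insertionRatePerMy numt insertions per lineage per My.
#' @param duplicationRatePerNumtPerMy,deletionRatePerNumtPerMy nuclear
#'   duplication/loss rates per extant numt per My.
#' @param tsTv transition/transversion ratio of the substitution model.
#' @param rearrangementMeans expected number of events per new numt, by
#'   class.
#' @param rearrangementSizes per-class size distributions, `list(mean, sd)`
#'   in bases (log-normal, truncated at `minEventBases`).
#' @param fragmentMeanLog,fragmentSdLog log-normal parameters of inserted
#'   fragment length.
#' @param scaffoldCount,scaffoldLength nuclear assembly shape per species.
#' @param nuclearAT nuclear background A+T fraction.
#' @param flankLength bases of (shared, co-duplicated) flanking sequence
#'   tracked per numt.
#' @param minEventBases minimum rearrangement size.
#' @param ingroupLabel node label of the clade receiving insertions.
#' @param controlRegion add an extra A+T-rich control-region-like segment
#'   to the mitochondrial root (off by default; several real assemblies
#'   lack it).
#' @param seed global seed governing all draws.
#' @return a validated `SimulationParams` list.
#' @export
simulationParams <- function(tree = drosophilaTree(),
                             mitoLength = 16000,
                             atFraction = 0.78,
                             mitoSubstRate = 0.004,
                             nuclearRateDivisor = 6.0,
                             insertionRatePerMy = 0.75,
                             duplicationRatePerNumtPerMy = 0.010,
                             deletionRatePerNumtPerMy = 0.052,
                             tsTv = 2.0,
                             rearrangementMeans = c(interruption = 0.195,
                                                    deletion = 0.16,
                                                    inversion = 0.02,
                                                    internal_duplication = 0.06),
                             rearrangementSizes = list(
                               interruption = c(mean = 5500, sd = 7900),
                               deletion = c(mean = 2000, sd = 2900),
                               inversion = c(mean = 550, sd = 320),
                               internal_duplication = c(mean = 1800,
                                                        sd = 2000)),
                             fragmentMeanLog = log(1000),
                             fragmentSdLog = 1.0,
                             scaffoldCount = 4,
                             scaffoldLength = 2e6,
                             nuclearAT = 0.60,
                             flankLength = 2000,
                             minEventBases = 200,
                             ingroupLabel = "DrosSoph",
                             controlRegion = FALSE,
                             seed = 1) {
  stopifnot(is(tree, "CalibratedTree"),
            mitoLength > 0, atFraction > 0, atFraction < 1,
            mitoSubstRate >= 0, nuclearRateDivisor >= 1,
            insertionRatePerMy >= 0, duplicationRatePerNumtPerMy >= 0,
            deletionRatePerNumtPerMy >= 0,
            all(rearrangementMeans >= 0))
  structure(list(tree = tree, mitoLength = mitoLength,
                 atFraction = atFraction, mitoSubstRate = mitoSubstRate,
                 nuclearRateDivisor = nuclearRateDivisor,
                 insertionRatePerMy = insertionRatePerMy,
                 duplicationRatePerNumtPerMy = duplicationRatePerNumtPerMy,
                 deletionRatePerNumtPerMy = deletionRatePerNumtPerMy,
                 tsTv = tsTv,
                 rearrangementMeans = rearrangementMeans,
                 rearrangementSizes = rearrangementSizes,
                 fragmentMeanLog = fragmentMeanLog,
                 fragmentSdLog = fragmentSdLog,
                 scaffoldCount = scaffoldCount,
                 scaffoldLength = scaffoldLength,
                 nuclearAT = nuclearAT, flankLength = flankLength,
                 minEventBases = minEventBases,
                 ingroupLabel = ingroupLabel,
                 controlRegion = controlRegion, seed = seed),
            class = "SimulationParams")
}

#' Simulate sequence evolution along a calibrated tree
#'
#' Independent per-site substitutions under F84: across a branch of
#' duration `d` My the expected number of substitutions per site is
#' `rate * d`. Sequences are retained at every node.
#'
#' @param rootSequence character string or integer codes for the root
#'   state.
#' @param tree a [CalibratedTree-class].
#' @param rate substitutions/site/My.
#' @param model an [F84Params-class].
#' @return named list of character sequences, one per node (tips by taxon
#'   label, internal nodes by their label).
#' @export
simulateSequenceEvolution <- function(rootSequence, tree, rate, model) {
  stopifnot(rate >= 0)
  code <- if (is.character(rootSequence)) seqToCodes(rootSequence)$code
          else as.integer(rootSequence)
  phy <- tree@tree
  ntip <- length(phy$tip.label)
  labs <- nodeLabels(tree)
  seqs <- list()
  recurse <- function(node, code) {
    seqs[[labs[node]]] <<- code
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (ch in kids) {
      d <- tree@ages[node] - tree@ages[ch]
      recurse(ch, evolveCodes(code, model, rate * d))
    }
  }
  recurse(ntip + 1L, code)
  lapply(seqs, codesToSeq)
}

nodeLabels <- function(ct) {
  phy <- ct@tree
  ntip <- length(phy$tip.label)
  labs <- character(ntip + phy$Nnode)
  labs[seq_len(ntip)] <- phy$tip.label
  labs[ntip + seq_len(phy$Nnode)] <-
    if (!is.null(phy$node.label)) phy$node.label
    else paste0("n", ntip + seq_len(phy$Nnode))
  labs
}

## ---- numt copy bookkeeping ----------------------------------------------

## A copy is a list:
##   eventId, insertionBranch, insertionTime, originStart, fragLen, strand,
##   fragSeq (mito-forward codes at origin), leftFlank, rightFlank,
##   interruptions (list of code vectors), layout (data.frame kind/start/
##   end/strand/foreignId), seqTime, parentEventId, rearr (df type/size),
##   insertionSeq (codes at insertion, for oracles)

newLayout <- function(fragLen) {
  data.frame(kind = "numt", start = 0L, end = as.integer(fragLen),
             strand = "+", foreignId = NA_integer_,
             stringsAsFactors = FALSE)
}

layoutLength <- function(lay) sum(lay$end - lay$start)

## split layout pieces at local coordinate a (0-based), return piece index
## boundaries such that a falls between pieces
layoutSplit <- function(lay, a) {
  pos <- 0L
  out <- lay[0, ]
  for (i in seq_len(nrow(lay))) {
    wdt <- lay$end[i] - lay$start[i]
    if (a <= pos || a >= pos + wdt) {
      out <- rbind(out, lay[i, ])
    } else {
      off <- a - pos
      p1 <- lay[i, ]; p2 <- lay[i, ]
      if (lay$strand[i] == "+" || lay$kind[i] == "foreign") {
        p1$end <- lay$start[i] + off; p2$start <- lay$start[i] + off
      } else {
        ## minus-strand numt piece: local left part is the RIGHT end
        p1$start <- lay$end[i] - off; p2$end <- lay$end[i] - off
      }
      out <- rbind(out, p1, p2)
    }
    pos <- pos + wdt
  }
  out
}

layoutExtract <- function(lay, a, b) {
  lay <- layoutSplit(layoutSplit(lay, a), b)
  pos <- 0L; keep <- logical(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    wdt <- lay$end[i] - lay$start[i]
    keep[i] <- pos >= a && pos + wdt <= b
    pos <- pos + wdt
  }
  lay[keep, , drop = FALSE]
}

layoutRemove <- function(lay, a, b) {
  lay <- layoutSplit(layoutSplit(lay, a), b)
  pos <- 0L; keep <- logical(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    wdt <- lay$end[i] - lay$start[i]
    keep[i] <- !(pos >= a && pos + wdt <= b)
    pos <- pos + wdt
  }
  lay[keep, , drop = FALSE]
}

layoutInsert <- function(lay, a, sub) {
  lay <- layoutSplit(lay, a)
  pos <- 0L; at <- nrow(lay) + 1L
  for (i in seq_len(nrow(lay))) {
    if (pos >= a) { at <- i; break }
    pos <- pos + lay$end[i] - lay$start[i]
  }
  rbind(lay[seq_len(at - 1L), ], sub,
        if (at <= nrow(lay)) lay[at:nrow(lay), ])
}

layoutReverse <- function(lay) {
  lay <- lay[rev(seq_len(nrow(lay))), , drop = FALSE]
  lay$strand <- ifelse(lay$strand == "+", "-", "+")
  lay
}

## draw and apply gross rearrangements to a fresh copy's layout
applyRearrangements <- function(copy, params) {
  sizes <- params$rearrangementSizes
  means <- params$rearrangementMeans
  drawSize <- function(cls) {
    m <- sizes[[cls]][["mean"]]; s <- sizes[[cls]][["sd"]]
    sl <- sqrt(log(1 + (s / m)^2))
    ml <- log(m) - sl^2 / 2
    max(params$minEventBases, round(rlnorm(1, ml, sl)))
  }
  rearr <- list()
  ## at most one deletion/inversion/duplication, Poisson interruptions
  if (runif(1) < 1 - exp(-means[["internal_duplication"]])) {
    L <- layoutLength(copy$layout)
    s <- drawSize("internal_duplication")
    if (L >= s + 2 * params$minEventBases) {
      a <- sample.int(L - s, 1L) - 1L
      sub <- layoutExtract(copy$layout, a, a + s)
      copy$layout <- layoutInsert(copy$layout, a + s, sub)
      rearr[[length(rearr) + 1L]] <- c("internal_duplication", s)
    }
  }
  if (runif(1) < 1 - exp(-means[["deletion"]])) {
    L <- layoutLength(copy$layout)
    s <- min(drawSize("deletion"), L - 2 * params$minEventBases)
    if (s >= params$minEventBases) {
      a <- params$minEventBases +
        sample.int(L - s - 2 * params$minEventBases + 1L, 1L) - 1L
      copy$layout <- layoutRemove(copy$layout, a, a + s)
      rearr[[length(rearr) + 1L]] <- c("deletion", s)
    }
  }
  if (runif(1) < 1 - exp(-means[["inversion"]])) {
    L <- layoutLength(copy$layout)
    s <- min(drawSize("inversion"), L - 2 * params$minEventBases)
    if (s >= params$minEventBases) {
      a <- params$minEventBases +
        sample.int(L - s - 2 * params$minEventBases + 1L, 1L) - 1L
      sub <- layoutReverse(layoutExtract(copy$layout, a, a + s))
      copy$layout <- layoutInsert(layoutRemove(copy$layout, a, a + s), a, sub)
      rearr[[length(rearr) + 1L]] <- c("inversion", s)
    }
  }
  nInt <- rpois(1, means[["interruption"]])
  for (k in seq_len(nInt)) {
    L <- layoutLength(copy$layout)
    if (L < 2 * params$minEventBases + 2L) break
    s <- drawSize("interruption")
    a <- params$minEventBases +
      sample.int(L - 2 * params$minEventBases, 1L) - 1L
    copy$interruptions[[length(copy$interruptions) + 1L]] <-
      randomCodes(s, freqsFromAT(params$nuclearAT))
    sub <- data.frame(kind = "foreign", start = 0L, end = as.integer(s),
                      strand = "+",
                      foreignId = length(copy$interruptions),
                      stringsAsFactors = FALSE)
    copy$layout <- layoutInsert(copy$layout, a, sub)
    rearr[[length(rearr) + 1L]] <- c("interruption", s)
  }
  copy$rearr <- if (length(rearr)) {
    data.frame(type = vapply(rearr, `[`, "", 1),
               size = as.numeric(vapply(rearr, `[`, "", 2)),
               stringsAsFactors = FALSE)
  } else data.frame(type = character(), size = numeric())
  copy
}

## evolve a copy's sequences down to age t (ages decrease toward present)
touchCopy <- function(copy, t, model, nucRate, withSeq) {
  if (!withSeq || copy$seqTime <= t) { copy$seqTime <- min(copy$seqTime, t); return(copy) }
  d <- (copy$seqTime - t) * nucRate
  copy$fragSeq <- evolveCodes(copy$fragSeq, model, d)
  copy$leftFlank <- evolveCodes(copy$leftFlank, model, d)
  copy$rightFlank <- evolveCodes(copy$rightFlank, model, d)
  copy$seqTime <- t
  copy
}

## realize the nuclear body sequence and local fragment table of a copy
realizeCopy <- function(copy, mitoLength) {
  lay <- copy$layout
  pieces <- vector("list", nrow(lay))
  frs <- list()
  pos <- 0L
  for (i in seq_len(nrow(lay))) {
    if (lay$kind[i] == "numt") {
      s <- copy$fragSeq[(lay$start[i] + 1L):lay$end[i]]
      if (lay$strand[i] == "-") s <- revcompCodes(s)
      wdt <- length(s)
      ## mitochondrial coordinates (may wrap around the origin)
      m1 <- (copy$originStart + lay$start[i]) %% mitoLength
      m2raw <- m1 + (lay$end[i] - lay$start[i])
      if (m2raw <= mitoLength) {
        frs[[length(frs) + 1L]] <- data.frame(
          nucStart = pos, nucEnd = pos + wdt, mitoStart = m1, mitoEnd = m2raw,
          strand = lay$strand[i], originSpanning = FALSE,
          stringsAsFactors = FALSE)
      } else {
        w1 <- mitoLength - m1
        if (lay$strand[i] == "+") {
          frs[[length(frs) + 1L]] <- data.frame(
            nucStart = c(pos, pos + w1), nucEnd = c(pos + w1, pos + wdt),
            mitoStart = c(m1, 0), mitoEnd = c(mitoLength, m2raw - mitoLength),
            strand = "+", originSpanning = TRUE, stringsAsFactors = FALSE)
        } else {
          frs[[length(frs) + 1L]] <- data.frame(
            nucStart = c(pos, pos + (wdt - w1)),
            nucEnd = c(pos + (wdt - w1), pos + wdt),
            mitoStart = c(0, m1), mitoEnd = c(m2raw - mitoLength, mitoLength),
            strand = "-", originSpanning = TRUE, stringsAsFactors = FALSE)
        }
      }
    } else {
      s <- copy$interruptions[[lay$foreignId[i]]]
      if (lay$strand[i] == "-") s <- revcompCodes(s)
    }
    pieces[[i]] <- s
    pos <- pos + length(s)
  }
  body <- unlist(pieces)
  frTab <- do.call(rbind, frs)
  if (copy$strand == "-") {
    bl <- length(body)
    body <- revcompCodes(body)
    frTab <- frTab[rev(seq_len(nrow(frTab))), , drop = FALSE]
    ns <- bl - frTab$nucEnd; ne <- bl - frTab$nucStart
    frTab$nucStart <- ns; frTab$nucEnd <- ne
    frTab$strand <- ifelse(frTab$strand == "+", "-", "+")
  }
  list(body = body, fragments = frTab)
}

#' Simulate a full numt insertion/duplication/deletion history
#'
#' Runs the generative counterpart of the annotation-and-dating analysis:
#' the mitochondrial genome evolves along the calibrated tree; on each
#' in-group branch numt insertions arise as a Poisson process, each copying
#' the mitochondrial sequence \emph{at the insertion time} on that lineage
#' (a contiguous, possibly origin-spanning fragment, either strand) into a
#' random scaffold position; thereafter the copy evolves at the slower
#' nuclear rate, may be duplicated (with its flanks) or deleted, and may
#' undergo gross rearrangements. Deleted copies are censored from the
#' output but logged. Truth tables record every surviving copy with its
#' insertion branch and time, mitochondrial origin, parentage and applied
#' rearrangements.
#'
#' @param params a `SimulationParams` object from [simulationParams()].
#' @param sequences realize sequences and genome FASTA (default TRUE);
#'   `FALSE` runs the event process only (fast path for rate experiments).
#' @return list with `truth` (per extant copy), `fragments` (per-fragment
#'   truth with genome coordinates; `sequences = TRUE` only), `eventsTruth`
#'   (planted rearrangements), `deletions` (censored copies), `genomes`
#'   (named list of per-species named scaffold character vectors), `mito`
#'   (per-taxon mitochondrial sequences incl. outgroup), `params`.
#' @export
simulateNumtHistory <- function(params, sequences = TRUE) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  ct <- params$tree
  phy <- ct@tree
  ntip <- length(phy$tip.label)
  labs <- nodeLabels(ct)
  model <- f84Params(freqsFromAT(params$atFraction), params$tsTv)
  nucRate <- params$mitoSubstRate / params$nuclearRateDivisor
  L <- params$mitoLength
  ## in-group node set (insertions allowed below this clade root)
  ingroupRoot <- which(labs == params$ingroupLabel)
  if (length(ingroupRoot) != 1L) stop("ingroup label not found in tree")
  desc <- ingroupRoot
  repeat {
    more <- phy$edge[phy$edge[, 1] %in% desc, 2]
    newd <- setdiff(more, desc)
    if (!length(newd)) break
    desc <- c(desc, newd)
  }
  rootSeq <- if (sequences) randomCodes(L, freqsFromAT(params$atFraction))
             else integer(0)
  eventCounter <- 0L
  truthRows <- list(); fragRows <- list(); evRows <- list()
  delRows <- list()
  mitoOut <- list(); genomes <- list()
  branchLabel <- setNames(ct@branches$branch, ct@branches$node)

  newInsertion <- function(t, branch, mitoNow) {
    eventCounter <<- eventCounter + 1L
    fragLen <- min(L, max(200L, round(rlnorm(1, params$fragmentMeanLog,
                                             params$fragmentSdLog))))
    o <- sample.int(L, 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    idxs <- ((o + seq_len(fragLen) - 1L) %% L) + 1L
    copy <- list(eventId = sprintf("E%04d", eventCounter),
                 insertionBranch = branch, insertionTime = t,
                 originStart = o, fragLen = fragLen, strand = strand,
                 fragSeq = if (sequences) mitoNow[idxs] else integer(0),
                 leftFlank = if (sequences)
                   randomCodes(params$flankLength,
                               freqsFromAT(params$nuclearAT)) else integer(0),
                 rightFlank = if (sequences)
                   randomCodes(params$flankLength,
                               freqsFromAT(params$nuclearAT)) else integer(0),
                 interruptions = list(), layout = newLayout(fragLen),
                 seqTime = t, parentEventId = NA_character_)
    copy <- applyRearrangements(copy, params)
    copy$insertionSeq <- copy$fragSeq
    copy
  }

  recurse <- function(node, mitoSeq, copies) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (length(kids) == 0L) {
      finalizeLeaf(labs[node], mitoSeq, copies)
      return(invisible(NULL))
    }
    for (ch in kids) {
      t0 <- ct@ages[node]; t1 <- ct@ages[ch]
      branch <- branchLabel[[as.character(ch)]]
      eligible <- ch %in% desc && ch != ingroupRoot
      mito <- mitoSeq; mitoT <- t0
      cps <- copies
      t <- t0
      repeat {
        insR <- if (eligible) params$insertionRatePerMy else 0
        totR <- insR + length(cps) *
          (params$duplicationRatePerNumtPerMy +
           params$deletionRatePerNumtPerMy)
        if (totR <= 0) break
        t <- t - rexp(1, totR)
        if (t <= t1) break
        u <- runif(1) * totR
        if (u < insR) {
          if (sequences) {
            mito <- evolveCodes(mito, model,
                                params$mitoSubstRate * (mitoT - t))
            mitoT <- t
          }
          cps[[length(cps) + 1L]] <- newInsertion(t, branch, mito)
        } else if (u < insR + length(cps) *
                     params$duplicationRatePerNumtPerMy) {
          src <- sample.int(length(cps), 1L)
          cps[[src]] <- touchCopy(cps[[src]], t, model, nucRate, sequences)
          eventCounter <<- eventCounter + 1L
          child <- cps[[src]]
          child$eventId <- sprintf("E%04d", eventCounter)
          child$parentEventId <- cps[[src]]$eventId
          child$insertionBranch <- branch
          child$insertionTime <- t
          cps[[length(cps) + 1L]] <- child
        } else {
          victim <- sample.int(length(cps), 1L)
          delRows[[length(delRows) + 1L]] <<- data.frame(
            eventId = cps[[victim]]$eventId, branch = branch,
            time = t, stringsAsFactors = FALSE)
          cps[[victim]] <- NULL
        }
      }
      if (sequences) {
        mito <- evolveCodes(mito, model, params$mitoSubstRate * (mitoT - t1))
        cps <- lapply(cps, touchCopy, t = t1, model = model,
                      nucRate = nucRate, withSeq = sequences)
      }
      recurse(ch, mito, cps)
    }
  }

  finalizeLeaf <- function(species, mitoSeq, copies) {
    if (sequences) mitoOut[[species]] <<- codesToSeq(mitoSeq)
    if (!sequences || species == "Agam") {
      for (cp in copies) {
        if (species == "Agam") next
        truthRows[[length(truthRows) + 1L]] <<- data.frame(
          numtId = paste0(species, "_", cp$eventId), eventId = cp$eventId,
          species = species, insertionBranch = cp$insertionBranch,
          insertionTime = cp$insertionTime, originStart = cp$originStart,
          fragLen = cp$fragLen, strand = cp$strand,
          parentEventId = cp$parentEventId,
          scaffold = NA_character_, numtStart = NA_real_,
          numtEnd = NA_real_, identityToInsertion = NA_real_,
          stringsAsFactors = FALSE)
        recordEvents(species, cp)
      }
      return(invisible(NULL))
    }
    ## assemble scaffolds with copies spliced at random positions
    nScf <- params$scaffoldCount
    scfLen <- params$scaffoldLength
    inserts <- lapply(copies, function(cp) {
      r <- realizeCopy(cp, L)
      list(cp = cp, body = r$body, frags = r$fragments)
    })
    scfIdx <- sample.int(nScf, length(inserts), replace = TRUE)
    scfs <- list()
    for (s in seq_len(nScf)) {
      bg <- randomCodes(scfLen, freqsFromAT(params$nuclearAT))
      mine <- which(scfIdx == s)
      if (length(mine)) {
        pts <- sort(sample.int(scfLen - 1L, length(mine)))
        ord <- mine[order(pts)]   # stable pairing of insert to point
        segs <- list(); cursor <- 0L; shift <- 0L
        for (k in seq_along(ord)) {
          i <- ord[k]
          cp <- inserts[[i]]$cp
          ins <- c(cp$leftFlank, inserts[[i]]$body, cp$rightFlank)
          segs[[length(segs) + 1L]] <- bg[(cursor + 1L):pts[k]]
          segs[[length(segs) + 1L]] <- ins
          bodyStart <- pts[k] + shift + length(cp$leftFlank)
          fr <- inserts[[i]]$frags
          fr$nucStart <- fr$nucStart + bodyStart
          fr$nucEnd <- fr$nucEnd + bodyStart
          scfName <- sprintf("%s_scf%d", species, s)
          ident <- if (length(cp$insertionSeq))
            mean(cp$fragSeq == cp$insertionSeq) else NA_real_
          truthRows[[length(truthRows) + 1L]] <<- data.frame(
            numtId = paste0(species, "_", cp$eventId), eventId = cp$eventId,
            species = species, insertionBranch = cp$insertionBranch,
            insertionTime = cp$insertionTime, originStart = cp$originStart,
            fragLen = cp$fragLen, strand = cp$strand,
            parentEventId = cp$parentEventId,
            scaffold = scfName, numtStart = bodyStart,
            numtEnd = bodyStart + length(inserts[[i]]$body),
            identityToInsertion = ident, stringsAsFactors = FALSE)
          fragRows[[length(fragRows) + 1L]] <<- data.frame(
            numtId = paste0(species, "_", cp$eventId), scaffold = scfName,
            fr, stringsAsFactors = FALSE)
          recordEvents(species, cp)
          shift <- shift + length(ins)
          cursor <- pts[k]
        }
        segs[[length(segs) + 1L]] <- bg[(cursor + 1L):scfLen]
        scfs[[sprintf("%s_scf%d", species, s)]] <-
          codesToSeq(unlist(segs))
      } else {
        scfs[[sprintf("%s_scf%d", species, s)]] <- codesToSeq(bg)
      }
    }
    genomes[[species]] <<- unlist(scfs)
  }

  recordEvents <- function(species, cp) {
    if (nrow(cp$rearr)) {
      evRows[[length(evRows) + 1L]] <<- data.frame(
        numtId = paste0(species, "_", cp$eventId), species = species,
        cp$rearr, stringsAsFactors = FALSE)
    }
  }

  recurse(ntip + 1L, rootSeq, list())
  emptyTruth <- data.frame(numtId = character(), eventId = character(),
                           species = character(),
                           insertionBranch = character(),
                           insertionTime = numeric(),
                           originStart = integer(), fragLen = integer(),
                           strand = character(), parentEventId = character(),
                           scaffold = character(), numtStart = numeric(),
                           numtEnd = numeric(),
                           identityToInsertion = numeric(),
                           stringsAsFactors = FALSE)
  list(truth = if (length(truthRows))
         do.call(rbind, c(truthRows, make.row.names = FALSE))
       else emptyTruth,
       fragments = if (length(fragRows))
         do.call(rbind, c(fragRows, make.row.names = FALSE)) else NULL,
       eventsTruth = if (length(evRows))
         do.call(rbind, c(evRows, make.row.names = FALSE))
       else data.frame(numtId = character(), species = character(),
                       type = character(), size = numeric()),
       deletions = if (length(delRows))
         do.call(rbind, c(delRows, make.row.names = FALSE))
       else data.frame(eventId = character(), branch = character(),
                       time = numeric()),
       genomes = genomes, mito = mitoOut, params = params)
}

#' Write a simulated dataset to disk
#'
#' Per-species nuclear and mitochondrial FASTA, truth TSV and BED, and a
#' parameter echo (YAML).
#'
#' @param sim result of [simulateNumtHistory()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genomes[[sp]]),
      file.path(dir, paste0(sp, "_nuclear.fa")))
  }
  if (length(sim$mito)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(sim$mito)),
      file.path(dir, "mito_genomes.fa"))
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$fragments)) {
    bed <- sprintf("%s\t%d\t%d\t%s\t0\t%s", sim$fragments$scaffold,
                   as.integer(sim$fragments$nucStart),
                   as.integer(sim$fragments$nucEnd),
                   sim$fragments$numtId, sim$fragments$strand)
    writeLines(c("#chrom\tchromStart\tchromEnd\tname\tscore\tstrand", bed),
               file.path(dir, "truth_fragments.bed"))
  }
  p <- sim$params
  p$tree <- NULL
  yaml::write_yaml(p, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' A small synthetic repeat library
#'
#' Six repeat families (LTR/LINE/DNA-like labels) of varying length,
#' generated from the given seed; used as a default library for
#' [plantRepeats()]. Synthetic stand-in, not derived from any curated
#' repeat database.
#'
#' @param seed seed for the family sequences.
#' @return named character vector of repeat consensus sequences.
#' @export
syntheticRepeatLibrary <- function(seed = 99) {
  withseed <- function(expr) { set.seed(seed); expr }
  lens <- c(LTR1 = 4500, LTR2 = 2800, LINE1 = 5200, LINE2 = 3600,
            DNA1 = 1500, DNA2 = 800)
  withseed({
    out <- vapply(lens, function(l)
      codesToSeq(randomCodes(l, freqsFromAT(0.55))), "")
    names(out) <- names(lens)
    out
  })
}

#' Plant repeat elements into simulated genomes
#'
#' Inserts diverged copies of library repeats uniformly across scaffolds,
#' plus an excess placed within `adjacency` bases of annotated numts
#' controlled by `adjacencyBias` (expected extra repeats per numt; 0 gives
#' the unbiased null). Repeats are never placed inside numt bodies; all
#' truth coordinates are updated for the resulting shifts. Every planted
#' copy is recorded.
#'
#' @param sim simulation result from [simulateNumtHistory()] (with
#'   sequences).
#' @param library named character vector of repeat sequences (default
#'   [syntheticRepeatLibrary()]).
#' @param densityPerMb expected uniform repeat copies per Mb.
#' @param adjacencyBias expected numt-adjacent extra copies per numt.
#' @param adjacency adjacency window in bases.
#' @param divergence per-base substitution applied to planted copies.
#' @return `sim` with modified `genomes`, shifted `truth`/`fragments`, and
#'   a new `repeats` data.frame (scaffold, start, end, family; 0-based
#'   half-open).
#' @export
plantRepeats <- function(sim, library = syntheticRepeatLibrary(),
                         densityPerMb = 5, adjacencyBias = 0.6,
                         adjacency = 200, divergence = 0.10) {
  stopifnot(length(library) > 0)
  repRows <- list()
  for (sp in names(sim$genomes)) {
    scfs <- sim$genomes[[sp]]
    for (scf in names(scfs)) {
      len <- nchar(scfs[[scf]])
      numtIdx <- which(sim$truth$scaffold == scf)
      spans <- sim$truth[numtIdx, c("numtStart", "numtEnd"), drop = FALSE]
      n_u <- rpois(1, densityPerMb * len / 1e6)
      pts <- if (n_u > 0) sample.int(len - 1L, n_u) else integer(0)
      if (nrow(spans) && length(pts)) {
        bad <- vapply(pts, function(p)
          any(p > spans$numtStart & p <= spans$numtEnd), TRUE)
        pts <- pts[!bad]
      }
      for (i in seq_len(nrow(spans))) {
        nb <- rpois(1, adjacencyBias)
        for (k in seq_len(nb)) {
          d <- sample.int(adjacency, 1L)
          pts <- c(pts, if (runif(1) < 0.5)
            max(1L, spans$numtStart[i] - d) else
              min(len - 1L, spans$numtEnd[i] + d))
        }
      }
      if (!length(pts)) next
      pts <- sort(pts)
      fams <- sample(names(library), length(pts), replace = TRUE)
      seqs <- lapply(fams, function(f) {
        cd <- seqToCodes(library[[f]])$code
        nmut <- rpois(1, divergence * length(cd))
        if (nmut > 0) {
          at <- sample.int(length(cd), min(nmut, length(cd)))
          cd[at] <- ((cd[at] + sample.int(3L, length(at),
                                          replace = TRUE) - 1L) %% 4L) + 1L
        }
        cd
      })
      ## splice and shift
      cd <- seqToCodes(scfs[[scf]])$code
      segs <- list(); cursor <- 0L; shift <- 0L
      for (k in seq_along(pts)) {
        segs[[length(segs) + 1L]] <- cd[(cursor + 1L):pts[k]]
        segs[[length(segs) + 1L]] <- seqs[[k]]
        repRows[[length(repRows) + 1L]] <- data.frame(
          scaffold = scf, start = pts[k] + shift,
          end = pts[k] + shift + length(seqs[[k]]), family = fams[k],
          stringsAsFactors = FALSE)
        shift <- shift + length(seqs[[k]])
        cursor <- pts[k]
      }
      segs[[length(segs) + 1L]] <- cd[(cursor + 1L):len]
      sim$genomes[[sp]][[scf]] <- codesToSeq(unlist(segs))
      ## shift truth coordinates on this scaffold
      shiftAt <- function(x) {
        x + vapply(x, function(v)
          sum(lengths(seqs)[pts <= v]), numeric(1))
      }
      if (length(numtIdx)) {
        sim$truth$numtStart[numtIdx] <- shiftAt(sim$truth$numtStart[numtIdx])
        sim$truth$numtEnd[numtIdx] <- shiftAt(sim$truth$numtEnd[numtIdx])
      }
      if (!is.null(sim$fragments)) {
        fi <- which(sim$fragments$scaffold == scf)
        if (length(fi)) {
          sim$fragments$nucStart[fi] <- shiftAt(sim$fragments$nucStart[fi])
          sim$fragments$nucEnd[fi] <- shiftAt(sim$fragments$nucEnd[fi])
        }
      }
    }
  }
  sim$repeats <- if (length(repRows))
    do.call(rbind, c(repRows, make.row.names = FALSE))
  else data.frame(scaffold = character(), start = integer(),
                  end = integer(), family = character(),
                  stringsAsFactors = FALSE)
  sim
}
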
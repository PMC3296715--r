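## Independent oracles used across tests: brute-force likelihood by state
## enumeration, exhaustive HSP chaining, direct windowed-entropy masking,
## and small scenario builders on top of the simulator primitives.

## Likelihood by explicit summation over all internal-node states.
bruteForceLogLik <- function(aln, phy, model) {
  ntip <- length(phy$tip.label)
  nn <- phy$Nnode
  codes <- match(toupper(aln), c("A", "C", "G", "T"))
  dim(codes) <- dim(aln)
  rownames(codes) <- rownames(aln)
  codes <- codes[phy$tip.label, , drop = FALSE]
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e)
    f84TransitionMatrix(model, phy$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
  S <- ncol(codes)
  lik <- numeric(S)
  for (g in seq_len(nrow(grid))) {
    stInt <- grid[g, ]
    p <- rep(model@freqs[stInt[1]], S)
    for (e in seq_len(nrow(phy$edge))) {
      pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      stP <- if (pa > ntip) rep(stInt[pa - ntip], S) else codes[pa, ]
      stC <- if (ch > ntip) rep(stInt[ch - ntip], S) else codes[ch, ]
      p <- p * Ps[[e]][cbind(stP, stC)]
    }
    lik <- lik + p
  }
  sum(log(lik))
}

## All maximal-score chainings by exhaustive path enumeration (n <= 8).
## Mirrors the greedy extract-remove semantics of linkHsps but finds the
## best path by enumeration rather than DP.
bruteForceChains <- function(hsps, sepMax) {
  hsps <- hsps[order(hsps$sStart, hsps$qStart), ]
  rownames(hsps) <- NULL
  linkable <- function(i, j) {
    if (hsps$strand[i] != hsps$strand[j]) return(FALSE)
    gs <- hsps$sStart[j] - hsps$sEnd[i]
    if (gs > sepMax || hsps$sStart[j] <= hsps$sStart[i] ||
        hsps$sEnd[j] <= hsps$sEnd[i]) return(FALSE)
    if (hsps$strand[i] == "+") {
      gq <- hsps$qStart[j] - hsps$qEnd[i]
      okq <- hsps$qStart[j] > hsps$qStart[i] & hsps$qEnd[j] > hsps$qEnd[i]
    } else {
      gq <- hsps$qStart[i] - hsps$qEnd[j]
      okq <- hsps$qStart[j] < hsps$qStart[i] & hsps$qEnd[j] < hsps$qEnd[i]
    }
    gq <= sepMax && okq
  }
  allPaths <- function(nodes) {
    paths <- lapply(nodes, function(i) list(path = i,
                                            score = hsps$score[i]))
    out <- paths
    repeat {
      grew <- list()
      for (p in paths) {
        last <- p$path[length(p$path)]
        for (j in nodes[nodes > last]) {
          if (linkable(last, j)) {
            grew[[length(grew) + 1L]] <- list(
              path = c(p$path, j), score = p$score + hsps$score[j])
          }
        }
      }
      if (!length(grew)) break
      out <- c(out, grew)
      paths <- grew
    }
    out
  }
  remaining <- seq_len(nrow(hsps))
  chains <- list()
  while (length(remaining)) {
    cand <- allPaths(remaining)
    scores <- vapply(cand, `[[`, 0, "score")
    top <- cand[scores == max(scores)]
    starts <- vapply(top, function(p) hsps$sStart[p$path[1]], 0)
    pick <- top[[which.min(starts)]]
    chains[[length(chains) + 1L]] <- hsps[pick$path, , drop = FALSE]
    remaining <- setdiff(remaining, pick$path)
  }
  chains
}

## Direct per-window entropy recomputation of the masked set.
bruteEntropyMask <- function(seq, window, locut, hicut) {
  v <- strsplit(toupper(seq), "")[[1]]
  L <- length(v)
  nw <- L - window + 1L
  H <- vapply(seq_len(nw), function(i) {
    tab <- table(factor(v[i:(i + window - 1L)], levels = c("A", "C", "G", "T")))
    p <- tab[tab > 0] / sum(tab)
    if (sum(tab) == 0) return(Inf)
    -sum(p * log2(p))
  }, 0)
  flag <- logical(L)
  ext <- H <= hicut
  trig <- H <= locut
  i <- 1L
  while (i <= nw) {
    if (ext[i]) {
      j <- i
      while (j < nw && ext[j + 1L]) j <- j + 1L
      if (any(trig[i:j])) flag[i:(j + window - 1L)] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  flag
}

randomDNA <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

## NumtAnnotation built from simulator truth (fragment coordinates made
## numt-local so the body substring can be used as "scaffold")
annotationFromTruth <- function(sim, numtId, identity = 0.95) {
  fr <- sim$fragments[sim$fragments$numtId == numtId, , drop = FALSE]
  tr <- sim$truth[sim$truth$numtId == numtId, , drop = FALSE]
  fr <- fr[order(fr$nucStart), ]
  base <- min(fr$nucStart)
  new("NumtAnnotation", numtId = numtId, species = tr$species,
      scaffold = tr$scaffold,
      fragments = data.frame(
        nucStart = fr$nucStart - base, nucEnd = fr$nucEnd - base,
        mitoStart = fr$mitoStart, mitoEnd = fr$mitoEnd,
        strand = fr$strand, identity = identity,
        originSpanning = fr$originSpanning, stringsAsFactors = FALSE),
      numtLength = sum(fr$nucEnd - fr$nucStart))
}

numtBody <- function(sim, numtId) {
  tr <- sim$truth[sim$truth$numtId == numtId, , drop = FALSE]
  substr(sim$genomes[[tr$species]][[tr$scaffold]], tr$numtStart + 1L,
         tr$numtEnd)
}

simMitoPanel <- function(sim) {
  setNames(as.character(unlist(sim$mito)), names(sim$mito))
}

## eventId -> insertion branch of the founding insertion of its paralog
## chain (a duplicate's mitochondrial divergence dates to the founder)
founderBranchMap <- function(sim) {
  ev <- unique(sim$truth[, c("eventId", "insertionBranch",
                             "parentEventId")])
  par <- setNames(ev$parentEventId, ev$eventId)
  branch <- setNames(ev$insertionBranch, ev$eventId)
  out <- list()
  for (e in ev$eventId) {
    r <- e
    while (r %in% names(par) && !is.na(par[[r]]) &&
           par[[r]] %in% names(par)) r <- par[[r]]
    out[[e]] <- branch[[r]]
  }
  out
}

## random single-fragment annotations for serialization round-trips
randomAnnotations <- function(n) {
  lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    ns <- sort(sample.int(100000, 2 * k))
    ms <- sort(sample.int(16000, 2 * k))
    new("NumtAnnotation", numtId = sprintf("rnd%03d", i), species = "SpX",
        scaffold = sprintf("scf%d", sample.int(5, 1)),
        fragments = data.frame(
          nucStart = ns[seq(1, 2 * k, 2)], nucEnd = ns[seq(2, 2 * k, 2)],
          mitoStart = ms[seq(1, 2 * k, 2)], mitoEnd = ms[seq(2, 2 * k, 2)],
          strand = sample(c("+", "-"), k, replace = TRUE),
          identity = round(runif(k, 0.7, 1), 4),
          originSpanning = FALSE, stringsAsFactors = FALSE),
        numtLength = sum(ns[seq(2, 2 * k, 2)] - ns[seq(1, 2 * k, 2)]))
  })
}
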
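## Controlled evolutionary scenarios for placement/homology tests: a
## mitochondrial panel simulated along the calibrated tree with sequence
## snapshots taken at chosen time points on chosen lineages, from which
## numts of known history are derived.

## Simulate mito evolution along ct, returning leaf sequences plus the
## mitochondrial state at given (lineage tip, age) snapshot points.
panelWithSnapshots <- function(ct, model, rate, snapshots = list(),
                               mitoLength = 16000) {
  phy <- ct@tree
  ntip <- length(phy$tip.label)
  labs <- numtdyn:::nodeLabels(ct)
  ages <- nodeAges(ct)
  evolve <- numtdyn:::evolveCodes
  root <- numtdyn:::randomCodes(mitoLength, model@freqs)
  leaves <- list(); snaps <- vector("list", length(snapshots))
  onPath <- function(tip, node) {
    k <- which(phy$tip.label == tip)
    repeat {
      if (k == node) return(TRUE)
      e <- which(phy$edge[, 2] == k)
      if (!length(e)) return(FALSE)
      k <- phy$edge[e, 1]
    }
  }
  recurse <- function(node, seq) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (!length(kids)) {
      leaves[[labs[node]]] <<- seq
      return(invisible(NULL))
    }
    for (ch in kids) {
      t0 <- ages[node]; t1 <- ages[ch]
      times <- numeric(0); idx <- integer(0)
      for (si in seq_along(snapshots)) {
        s <- snapshots[[si]]
        if (s$age < t0 && s$age >= t1 && onPath(s$tip, ch)) {
          times <- c(times, s$age); idx <- c(idx, si)
        }
      }
      o <- order(-times)
      cur <- seq; tcur <- t0
      for (k in o) {
        cur <- evolve(cur, model, rate * (tcur - times[k]))
        snaps[[idx[k]]] <<- cur
        tcur <- times[k]
      }
      recurse(ch, evolve(cur, model, rate * (tcur - t1)))
    }
  }
  recurse(ntip + 1L, root)
  list(leaves = lapply(leaves, numtdyn:::codesToSeq), snaps = snaps)
}

singleFragAnnotation <- function(id, host, o, len, strand = "+") {
  new("NumtAnnotation", numtId = id, species = host, scaffold = "scf",
      fragments = data.frame(nucStart = 0L, nucEnd = as.integer(len),
                             mitoStart = as.integer(o),
                             mitoEnd = as.integer(o + len),
                             strand = strand, identity = 0.95,
                             originSpanning = FALSE),
      numtLength = len)
}

## One panel realization shared by several homology replicates: mito
## evolution with snapshots on the host terminal branch at tIns and tIns2.
makeHomologyPanel <- function(ct, host = "Dmoj", tIns = 15, tIns2 = 8,
                              mitoRate = 0.004, mitoLength = 16000,
                              at = 0.78) {
  model <- f84Params(numtdyn:::freqsFromAT(at), 2)
  pw <- panelWithSnapshots(ct, model, mitoRate,
                           list(list(tip = host, age = tIns),
                                list(tip = host, age = tIns2)),
                           mitoLength)
  panelSeqs <- unlist(pw$leaves)
  panel <- panelAlignment(panelSeqs, host)
  lens <- fitPanelBranchLengths(panel$aln, ct)
  list(model = model, pw = pw, panel = panel, panelLengths = lens,
       host = host, tIns = tIns, tIns2 = tIns2, mitoRate = mitoRate,
       mitoLength = mitoLength)
}

## A homology replicate on a prepared panel: either a recent duplicate pair
## (shared nuclear history from insertion to a duplication tDup My ago) or
## two independent insertions of the same mitochondrial region.
homologyReplicate <- function(hp, mode = c("paralog", "independent"),
                              fragLen = 1500, divisor = 6, tDup = 1,
                              config = pipelineConfig(), ct) {
  mode <- match.arg(mode)
  evolve <- numtdyn:::evolveCodes
  nucRate <- hp$mitoRate / divisor
  o <- sample.int(hp$mitoLength - fragLen, 1L) - 1L
  fragAt <- function(snap) snap[(o + 1L):(o + fragLen)]
  if (mode == "paralog") {
    stem <- evolve(fragAt(hp$pw$snaps[[1]]), hp$model,
                   nucRate * (hp$tIns - tDup))
    a <- evolve(stem, hp$model, nucRate * tDup)
    b <- evolve(stem, hp$model, nucRate * tDup)
  } else {
    a <- evolve(fragAt(hp$pw$snaps[[1]]), hp$model, nucRate * hp$tIns)
    b <- evolve(fragAt(hp$pw$snaps[[2]]), hp$model, nucRate * hp$tIns2)
  }
  annA <- singleFragAnnotation("numtA", hp$host, o, fragLen)
  annB <- singleFragAnnotation("numtB", hp$host, o, fragLen)
  prA <- projectAlignment(annA, numtdyn:::codesToSeq(a), hp$panel, hp$host)
  prB <- projectAlignment(annB, numtdyn:::codesToSeq(b), hp$panel, hp$host)
  testHomology(prA, prB, ct, mode = "paralog", config = config,
               panelLengths = hp$panelLengths,
               ids = c("numtA", "numtB"))
}

## A genome with rearrangement classes planted singly at ~8% divergence,
## for classifier accuracy measurement through the full pipeline.
makeSinglyPlantedGenome <- function(perClass = 12, mitoLength = 16000,
                                    at = 0.78, nuclearAT = 0.6,
                                    divergence = 0.08) {
  mito <- numtdyn:::randomCodes(mitoLength, numtdyn:::freqsFromAT(at))
  rcv <- numtdyn:::revcompCodes
  mutate <- function(v, d) {
    k <- rpois(1, d * length(v))
    if (k > 0) {
      at_ <- sample.int(length(v), min(k, length(v)))
      v[at_] <- ((v[at_] + sample.int(3L, length(at_), replace = TRUE) - 1L)
                 %% 4L) + 1L
    }
    v
  }
  classes <- c("deletion", "interruption", "inversion",
               "internal_duplication")
  events <- list(); bodies <- list()
  id <- 0L
  for (cls in classes) {
    for (k in seq_len(perClass)) {
      id <- id + 1L
      s <- sample(500:1500, 1)
      if (cls == "interruption") s <- sample(500:3000, 1)
      margin <- 500L
      fragLen <- 2L * margin + s + sample(300:1200, 1)
      if (cls == "interruption") {
        fragLen <- 2L * margin + sample(600:1800, 1)
      }
      o <- sample.int(mitoLength - fragLen, 1L) - 1L
      f <- mutate(mito[(o + 1L):(o + fragLen)], divergence)
      a <- margin
      body <- switch(cls,
        deletion = c(f[1:a], f[(a + s + 1):fragLen]),
        interruption = c(f[1:a],
                         numtdyn:::randomCodes(
                           s, numtdyn:::freqsFromAT(nuclearAT)),
                         f[(a + 1):fragLen]),
        inversion = c(f[1:a], rcv(f[(a + 1):(a + s)]),
                      f[(a + s + 1):fragLen]),
        internal_duplication = c(f[1:(a + s)], f[(a + 1):(a + s)],
                                 f[(a + s + 1):fragLen]))
      bodies[[id]] <- body
      events[[id]] <- data.frame(id = id, type = cls, size = s,
                                 stringsAsFactors = FALSE)
    }
  }
  spacing <- 30000L
  segs <- list(); spans <- numeric(0)
  pos <- 0L
  for (i in seq_along(bodies)) {
    bg <- numtdyn:::randomCodes(spacing, numtdyn:::freqsFromAT(nuclearAT))
    segs[[length(segs) + 1L]] <- bg
    segs[[length(segs) + 1L]] <- bodies[[i]]
    spans <- rbind(spans, c(pos + spacing, pos + spacing +
                              length(bodies[[i]])))
    pos <- pos + spacing + length(bodies[[i]])
  }
  segs[[length(segs) + 1L]] <-
    numtdyn:::randomCodes(spacing, numtdyn:::freqsFromAT(nuclearAT))
  ev <- do.call(rbind, events)
  ev$spanStart <- spans[, 1]; ev$spanEnd <- spans[, 2]
  list(mito = numtdyn:::codesToSeq(mito),
       scaffold = setNames(numtdyn:::codesToSeq(unlist(segs)), "scfP"),
       events = ev)
}
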
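## Seed-and-extend nucleotide similarity search with Karlin-Altschul
## E-values and HSP linking under maximum-separation constraints.

.TWO_HIT_WINDOW <- 40L   # second seed on a diagonal within this many bases
.XDROP <- 80             # raw-score drop terminating ungapped extension

#' Karlin-Altschul lambda for an ungapped scoring scheme
#'
#' Solves sum_ij p_i q_j exp(lambda * s_ij) = 1 for lambda > 0, where s is
#' the match/mismatch scoring matrix and p, q are the background base
#' compositions of the two sequences. The expected score must be negative.
#'
#' @param p,q background base frequency vectors (A, C, G, T).
#' @param match,mismatch scores.
#' @return lambda (nats per score unit).
#' @export
karlinLambda <- function(p, q, match = 5, mismatch = -4) {
  p <- p / sum(p); q <- q / sum(q)
  S <- matrix(mismatch, 4, 4); diag(S) <- match
  es <- sum(outer(p, q) * S)
  if (es >= 0) stop("expected score must be negative for E-value theory")
  f <- function(l) sum(outer(p, q) * exp(l * S)) - 1
  stats::uniroot(f, c(1e-9, 10), tol = 1e-12)$root
}

## word codes for seeding; NA where window includes N or a masked base
wordCodes <- function(code, masked, w) {
  L <- length(code)
  if (L < w) return(integer(0))
  bad <- is.na(code) | masked
  v <- code - 1L
  v[bad] <- 0L
  nw <- L - w + 1L
  out <- numeric(nw)
  anybad <- logical(nw)
  for (k in 0:(w - 1L)) {
    out <- out + v[(1L + k):(nw + k)] * 4^k
    anybad <- anybad | bad[(1L + k):(nw + k)]
  }
  out[anybad] <- NA_real_
  out
}

.TRIM_P1 <- 0.85  # per-base identity at the design detectability envelope

## One-directional chunked X-drop walk; returns best offset (bases gained).
## The raw-score maximum is refined by a changepoint log-likelihood ratio:
## each base scores log(p1/p0) for a match and log((1-p1)/(1-p0)) for a
## mismatch, where p0 is the chance match probability of the two
## backgrounds; the boundary is the earliest LLR argmax. This keeps the
## near-neutral chance tails that a +5/-4 argmax accumulates (10-20 bases
## into flanking sequence) out of the reported interval.
xdropWalk <- function(qc, sc, qFrom, sFrom, step, nMax, match, mismatch,
                      xdrop, p0 = 0.3, chunk = 64L) {
  bestOff <- 0L; bestScore <- 0; cur <- 0; peak <- 0
  done <- 0L
  while (done < nMax) {
    n <- min(chunk, nMax - done)
    chunk <- min(chunk * 8L, 65536L)   # most spurious walks die early
    qi <- qFrom + step * (done + seq_len(n) - 1L)
    si <- sFrom + step * (done + seq_len(n) - 1L)
    qs <- qc[qi]; ss <- sc[si]
    m <- !is.na(qs) & !is.na(ss) & qs == ss
    cs <- cur + cumsum(mismatch + (match - mismatch) * m)
    peaks <- cummax(pmax(cs, peak))
    stop_at <- match(TRUE, peaks - cs > xdrop)
    lim <- if (is.na(stop_at)) n else stop_at
    wm <- which.max(cs[seq_len(lim)])
    if (cs[wm] > bestScore) { bestScore <- cs[wm]; bestOff <- done + wm }
    cur <- cs[lim]; peak <- peaks[lim]
    done <- done + lim
    if (!is.na(stop_at)) break
  }
  if (bestOff > 0L) {
    ## second bounded pass: changepoint LLR boundary within the raw-score
    ## extension
    qi <- qFrom + step * (seq_len(bestOff) - 1L)
    si <- sFrom + step * (seq_len(bestOff) - 1L)
    m <- !is.na(qc[qi]) & !is.na(sc[si]) & qc[qi] == sc[si]
    sMatch <- log(.TRIM_P1 / p0)
    sMis <- log((1 - .TRIM_P1) / (1 - p0))
    llr <- cumsum(sMis + (sMatch - sMis) * m)
    best <- which.max(llr)
    if (llr[best] > 0) bestOff <- best else bestOff <- 0L
  }
  bestOff
}

## Ungapped X-drop extension of seed diagonals. qc, sc: integer codes.
## seeds: data.frame(qpos, spos) 1-based seed START positions (word length w).
## Returns data.frame of HSP intervals (0-based half-open) with counts.
extendSeeds <- function(qc, sc, seeds, w, match, mismatch, xdrop = .XDROP,
                        p0 = 0.3) {
  Lq <- length(qc); Ls <- length(sc)
  diag <- seeds$spos - seeds$qpos
  ord <- order(diag, seeds$qpos)
  seeds <- seeds[ord, , drop = FALSE]
  diag <- diag[ord]
  out <- vector("list", 64L); nout <- 0L
  lastDiag <- NA_integer_; coveredTo <- -1L
  for (i in seq_len(nrow(seeds))) {
    d <- diag[i]; qp <- seeds$qpos[i]
    if (!is.na(lastDiag) && d == lastDiag && qp <= coveredTo) next
    sp <- seeds$spos[i]
    right <- xdropWalk(qc, sc, qp + w, sp + w, 1L,
                       min(Lq - (qp + w) + 1L, Ls - (sp + w) + 1L),
                       match, mismatch, xdrop, p0)
    left <- xdropWalk(qc, sc, qp - 1L, sp - 1L, -1L,
                      min(qp - 1L, sp - 1L), match, mismatch, xdrop, p0)
    q1 <- qp - left; q2 <- qp + w - 1L + right   # 1-based inclusive
    s1 <- sp - left; s2 <- sp + w - 1L + right
    qs <- qc[q1:q2]; ss <- sc[s1:s2]
    nm <- sum(!is.na(qs) & !is.na(ss) & qs == ss)
    len <- q2 - q1 + 1L
    nout <- nout + 1L
    if (nout > length(out)) out <- c(out, vector("list", length(out)))
    out[[nout]] <- c(q1 - 1L, q2, s1 - 1L, s2, nm, len - nm)
    lastDiag <- d; coveredTo <- q2
  }
  if (nout == 0L) {
    return(data.frame(qStart = integer(), qEnd = integer(),
                      sStart = integer(), sEnd = integer(),
                      nMatch = integer(), nMismatch = integer()))
  }
  m <- do.call(rbind, out[seq_len(nout)])
  data.frame(qStart = m[, 1], qEnd = m[, 2], sStart = m[, 3], sEnd = m[, 4],
             nMatch = m[, 5], nMismatch = m[, 6])
}

#' Find high-scoring pairs between a mitochondrial query and a scaffold
#'
#' Seed-and-extend ungapped local search on both strands: exact seed words
#' of `wordSize` bases (masked or ambiguous positions never seed, but
#' extension runs through them on the actual residues), a two-hit diagonal
#' trigger, X-drop extension, and Karlin-Altschul E-values with lambda
#' fitted numerically to the observed background composition. Hits with
#' E-value above the configured threshold are discarded. Small indels
#' between ungapped segments are handled downstream by [linkHsps()].
#'
#' @param query mitochondrial sequence (character string; lowercase =
#'   masked).
#' @param subject nuclear scaffold (character string; lowercase = masked).
#' @param config a [PipelineConfig-class].
#' @return data.frame of HSPs: `qStart`, `qEnd`, `sStart`, `sEnd` (0-based
#'   half-open; query coordinates always on the forward mitochondrial
#'   strand), `strand`, `score`, `bitScore`, `eValue`, `identity`.
#' @export
findHsps <- function(query, subject, config = pipelineConfig()) {
  w <- as.integer(config@wordSize)
  qs <- seqToCodes(query)
  ss <- seqToCodes(subject)
  Lq <- length(qs$code); Ls <- length(ss$code)
  if (Ls < w || Lq < w) return(emptyHsps())
  bgS <- empiricalFreqs(ss$code[!ss$masked & !is.na(ss$code)])
  bgQ <- empiricalFreqs(qs$code[!qs$masked & !is.na(qs$code)])
  lambda <- karlinLambda(bgQ, bgS, config@matchScore, config@mismatchScore)
  K <- config@karlinK
  p0 <- min(0.6, sum(bgQ * bgS))   # chance match probability for boundary
                                   # refinement (capped away from .TRIM_P1)
  swords <- wordCodes(ss$code, ss$masked, w)
  sdt <- data.table::data.table(word = swords,
                                spos = seq_along(swords))[!is.na(word)]
  data.table::setkey(sdt, word)
  res <- list()
  for (strand in c("+", "-")) {
    if (strand == "+") {
      qcode <- qs$code; qmask <- qs$masked
    } else {
      qcode <- revcompCodes(qs$code); qmask <- rev(qs$masked)
    }
    qwords <- wordCodes(qcode, qmask, w)
    qdt <- data.table::data.table(word = qwords,
                                  qpos = seq_along(qwords))[!is.na(word)]
    if (nrow(qdt) == 0L) next
    seeds <- sdt[qdt, on = "word", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(seeds) == 0L) next
    ## two-hit trigger per diagonal
    seeds[, diag := spos - qpos]
    data.table::setorder(seeds, diag, qpos)
    gap <- c(NA, diff(seeds$qpos))
    same <- c(FALSE, diff(seeds$diag) == 0)
    trig <- same & gap > 0 & gap <= .TWO_HIT_WINDOW + w
    if (!any(trig)) next
    hit <- extendSeeds(qcode, ss$code, seeds[trig, c("qpos", "spos")],
                       w, config@matchScore, config@mismatchScore,
                       p0 = p0)
    if (nrow(hit) == 0L) next
    hit$score <- hit$nMatch * config@matchScore +
      hit$nMismatch * config@mismatchScore
    hit$strand <- strand
    if (strand == "-") {
      q1 <- Lq - hit$qEnd; q2 <- Lq - hit$qStart
      hit$qStart <- q1; hit$qEnd <- q2
    }
    res[[strand]] <- hit
  }
  if (length(res) == 0L) return(emptyHsps())
  hsps <- do.call(rbind, res)
  ## dedup: same (strand, diagonal) overlapping intervals keep best score
  hsps <- hsps[order(-hsps$score), ]
  key <- paste(hsps$strand, hsps$sStart - hsps$qStart, hsps$sStart, sep = ":")
  hsps <- hsps[!duplicated(key), ]
  keep <- rep(TRUE, nrow(hsps))
  dg <- ifelse(hsps$strand == "+", hsps$sStart - hsps$qStart,
               hsps$sStart + hsps$qEnd)
  for (grp in split(seq_len(nrow(hsps)), paste(hsps$strand, dg))) {
    if (length(grp) < 2L) next
    taken <- IRanges::IRanges()
    for (i in grp) {
      r <- IRanges::IRanges(hsps$sStart[i] + 1L, hsps$sEnd[i])
      if (length(taken) && any(IRanges::overlapsAny(r, taken))) {
        keep[i] <- FALSE
      } else taken <- c(taken, r)
    }
  }
  hsps <- hsps[keep, ]
  hsps$eValue <- K * Lq * Ls * exp(-lambda * hsps$score)
  hsps$bitScore <- (lambda * hsps$score - log(K)) / log(2)
  hsps$identity <- hsps$nMatch / (hsps$nMatch + hsps$nMismatch)
  hsps <- hsps[hsps$eValue <= config@evalueThreshold, ]
  hsps <- hsps[order(hsps$sStart, hsps$qStart), ]
  rownames(hsps) <- NULL
  hsps[, c("qStart", "qEnd", "sStart", "sEnd", "strand", "score",
           "bitScore", "eValue", "identity", "nMatch", "nMismatch")]
}

emptyHsps <- function() {
  data.frame(qStart = integer(), qEnd = integer(), sStart = integer(),
             sEnd = integer(), strand = character(), score = numeric(),
             bitScore = numeric(), eValue = numeric(), identity = numeric(),
             nMatch = integer(), nMismatch = integer(),
             stringsAsFactors = FALSE)
}

#' Link colinear HSPs separated by at most `sepMax` bases
#'
#' Combines same-strand, colinear HSPs whose separation on BOTH the query
#' (mitochondrial) and subject (scaffold) axis is at most `sepMax` into
#' linked hits, mirroring the maximum-HSP-separation semantics of classic
#' BLAST hit linking (50 bases by default). Chains are extracted greedily:
#' the maximum-combined-score chain first (ties broken by leftmost subject
#' start), its members removed, and so on, so that every HSP belongs to
#' exactly one chain.
#'
#' @param hsps data.frame from [findHsps()] (one query-subject pair).
#' @param sepMax maximum separation in bases on each axis.
#' @param config optional [PipelineConfig-class] supplying `sepMax` and
#'   E-value parameters for combined scores.
#' @return list with `hsps` (input rows plus a `chain` id column) and
#'   `chains` (per-chain summary: subject/query span, strand, combined
#'   score, combined E-value, member count).
#' @export
linkHsps <- function(hsps, sepMax = NULL, config = pipelineConfig()) {
  if (is.null(sepMax)) sepMax <- config@hspSepMaxBases
  hsps <- hsps[order(hsps$sStart, hsps$qStart), ]
  rownames(hsps) <- NULL
  n <- nrow(hsps)
  chain <- rep(NA_integer_, n)
  if (n > 0) {
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
    nextChain <- 0L
    remaining <- seq_len(n)
    while (length(remaining)) {
      ## DP for maximum-score path among remaining HSPs (subject order)
      best <- setNames(hsps$score[remaining], NULL)
      pred <- rep(NA_integer_, length(remaining))
      for (jj in seq_along(remaining)) {
        j <- remaining[jj]
        for (ii in seq_len(jj - 1L)) {
          i <- remaining[ii]
          if (linkable(i, j)) {
            cand <- best[ii] + hsps$score[j]
            if (cand > best[jj] ||
                (cand == best[jj] && !is.na(pred[jj]) &&
                 hsps$sStart[i] < hsps$sStart[pred[jj]])) {
              best[jj] <- cand
              pred[jj] <- ii
            }
          }
        }
      }
      top <- which(best == max(best))
      ## tie-break: leftmost subject start of the chain head
      heads <- vapply(top, function(jj) {
        while (!is.na(pred[jj])) jj <- pred[jj]
        hsps$sStart[remaining[jj]]
      }, numeric(1))
      jj <- top[which.min(heads)]
      members <- integer(0)
      while (TRUE) {
        members <- c(remaining[jj], members)
        if (is.na(pred[jj])) break
        jj <- pred[jj]
      }
      nextChain <- nextChain + 1L
      chain[members] <- nextChain
      remaining <- setdiff(remaining, members)
    }
  }
  hsps$chain <- chain
  chains <- if (n == 0L) {
    data.frame(chain = integer(), sStart = integer(), sEnd = integer(),
               qStart = integer(), qEnd = integer(), strand = character(),
               score = numeric(), eValue = numeric(), nHsps = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(split(seq_len(n), chain), function(idx) {
      data.frame(chain = chain[idx[1]],
                 sStart = min(hsps$sStart[idx]), sEnd = max(hsps$sEnd[idx]),
                 qStart = min(hsps$qStart[idx]), qEnd = max(hsps$qEnd[idx]),
                 strand = hsps$strand[idx[1]],
                 score = sum(hsps$score[idx]),
                 eValue = min(hsps$eValue[idx]),
                 nHsps = length(idx), stringsAsFactors = FALSE)
    }))
  }
  rownames(chains) <- NULL
  list(hsps = hsps, chains = chains[order(chains$chain), ])
}
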
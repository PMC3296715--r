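cfgSearch <- pipelineConfig()

test_that("planted copies are recovered as single HSPs on both strands", {
  set.seed(21)
  mito <- randomDNA(16000, at = 0.78)
  bg <- randomDNA(60000, at = 0.60)
  frag <- substr(mito, 5001, 5500)
  subj <- paste0(substr(bg, 1, 30000), frag, substr(bg, 30001, 60000))
  h <- findHsps(maskLowComplexity(mito), maskLowComplexity(subj), cfgSearch)
  expect_equal(nrow(h), 1L)
  expect_lt(h$eValue, 1e-6)
  expect_equal(h$strand, "+")
  ## boundaries near the planted copy (individual ends can wander a few
  ## extra bases on chance-matching flank; the population-level +-10 b
  ## accuracy is measured in the recall experiment)
  expect_lt(abs(h$sStart - 30000), 25)
  expect_lt(abs(h$sEnd - 30500), 25)
  expect_lt(abs(h$qStart - 5000), 25)
  ## reverse-complement planting gives the same mito interval on "-"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  subj2 <- paste0(substr(bg, 1, 30000), rc, substr(bg, 30001, 60000))
  h2 <- findHsps(maskLowComplexity(mito), maskLowComplexity(subj2),
                 cfgSearch)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$qStart, h$qStart, tolerance = 12)
  expect_equal(h2$qEnd, h$qEnd, tolerance = 12)
})

test_that("reported HSP scores match a recomputation from the sequences", {
  set.seed(22)
  mito <- randomDNA(8000, at = 0.78)
  bg <- randomDNA(40000, at = 0.6)
  frag <- strsplit(substr(mito, 2001, 2800), "")[[1]]
  idx <- sample(800, 80)
  frag[idx] <- vapply(frag[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  subj <- paste0(substr(bg, 1, 20000), paste(frag, collapse = ""),
                 substr(bg, 20001, 40000))
  h <- findHsps(maskLowComplexity(mito), maskLowComplexity(subj), cfgSearch)
  expect_gte(nrow(h), 1L)
  for (i in seq_len(nrow(h))) {
    q <- substr(mito, h$qStart[i] + 1, h$qEnd[i])
    s <- substr(subj, h$sStart[i] + 1, h$sEnd[i])
    if (h$strand[i] == "-") {
      s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
    nm <- sum(qv == sv)
    expect_equal(h$score[i], 5 * nm - 4 * (length(qv) - nm))
    expect_equal(h$identity[i], nm / length(qv))
  }
})

test_that("random unrelated subjects yield no hits at the E-value threshold", {
  set.seed(23)
  mito <- maskLowComplexity(randomDNA(16000, at = 0.78))
  hits <- vapply(1:20, function(k) {
    nrow(findHsps(mito, maskLowComplexity(randomDNA(100000, at = 0.6)),
                  cfgSearch))
  }, 0L)
  expect_equal(sum(hits), 0L)
})

test_that("linking obeys the separation rule on both axes", {
  mk <- function(qs, qe, ss, se, st = "+", sc = 100) {
    data.frame(qStart = qs, qEnd = qe, sStart = ss, sEnd = se, strand = st,
               score = sc, bitScore = 1, eValue = 1e-10, identity = 0.95,
               nMatch = 90, nMismatch = 10)
  }
  r1 <- linkHsps(rbind(mk(0, 100, 1000, 1100), mk(140, 240, 1140, 1240)), 50)
  expect_equal(nrow(r1$chains), 1L)
  expect_equal(r1$chains$nHsps, 2L)
  r2 <- linkHsps(rbind(mk(0, 100, 1000, 1100), mk(140, 240, 1160, 1260)), 50)
  expect_equal(nrow(r2$chains), 2L)
  r3 <- linkHsps(rbind(mk(0, 100, 1000, 1100), mk(160, 260, 1140, 1240)), 50)
  expect_equal(nrow(r3$chains), 2L)   # 60 b on query
  ## strand mixing is never chained
  r4 <- linkHsps(rbind(mk(0, 100, 1000, 1100),
                       mk(140, 240, 1140, 1240, st = "-")), 50)
  expect_equal(nrow(r4$chains), 2L)
})

test_that("chains match exhaustive enumeration on random HSP sets", {
  set.seed(24)
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    qs <- sort(sample.int(4000, n))
    ss <- sort(sample.int(4000, n)) + 5000L
    hsps <- data.frame(
      qStart = qs, qEnd = qs + sample(40:200, n, replace = TRUE),
      sStart = ss, sEnd = ss + sample(40:200, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE, prob = c(0.8, 0.2)),
      score = sample(50:500, n, replace = TRUE),
      bitScore = 1, eValue = 1e-9, identity = 0.9, nMatch = 50,
      nMismatch = 5)
    got <- linkHsps(hsps, 60)
    want <- bruteForceChains(hsps, 60)
    expect_equal(nrow(got$chains), length(want))
    ## identical chain membership (compare sorted member signatures)
    sig <- function(df) paste(sort(paste(df$qStart, df$sStart)),
                              collapse = ";")
    gotSigs <- sort(vapply(split(got$hsps, got$hsps$chain), sig, ""))
    wantSigs <- sort(vapply(want, sig, ""))
    expect_equal(unname(gotSigs), unname(wantSigs))
  }
})

test_that("every HSP belongs to exactly one chain", {
  set.seed(25)
  n <- 12
  qs <- sort(sample.int(3000, n))
  hsps <- data.frame(
    qStart = qs, qEnd = qs + 80L, sStart = qs + 2000L, sEnd = qs + 2080L,
    strand = "+", score = sample(50:100, n, replace = TRUE), bitScore = 1,
    eValue = 1e-8, identity = 0.9, nMatch = 40, nMismatch = 4)
  got <- linkHsps(hsps, 50)
  expect_false(any(is.na(got$hsps$chain)))
  expect_equal(sum(got$chains$nHsps), n)
})
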
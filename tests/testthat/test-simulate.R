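smallTree <- function() {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:10,B:10)ab:10,C:20)root;", nwk)
  loadCalibratedTree(nwk)
}

test_that("zero rate leaves all node sequences identical to the root", {
  set.seed(31)
  ct <- smallTree()
  m <- f84Params(freqsFromAT(0.7))
  root <- randomDNA(500, at = 0.7)
  seqs <- simulateSequenceEvolution(root, ct, rate = 0, model = m)
  for (s in seqs) expect_equal(s, root)
})

test_that("pairwise divergence matches the closed-form F84 expectation", {
  set.seed(32)
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(A:5,B:5)r;", nwk)
  ct <- loadCalibratedTree(nwk)
  m <- f84Params(freqsFromAT(0.78), tsTv = 2)
  rate <- 0.004
  len <- 400
  nrep <- 200
  pExp <- f84ExpectedPDistance(m, 2 * 5 * rate)
  diffs <- vapply(seq_len(nrep), function(k) {
    root <- codesToSeq(randomCodes(len, m@freqs))
    seqs <- simulateSequenceEvolution(root, ct, rate, m)
    mean(strsplit(seqs$A, "")[[1]] != strsplit(seqs$B, "")[[1]])
  }, 0)
  se <- sd(diffs) / sqrt(nrep)
  expect_lt(abs(mean(diffs) - pExp), 3 * se + 1e-9)
})

test_that("simulated root composition matches the requested AT fraction", {
  set.seed(33)
  p <- simulationParams(seed = 33, mitoLength = 20000)
  sim <- simulateNumtHistory(p, sequences = TRUE)
  rootish <- strsplit(as.character(sim$mito[["Dmel"]]), "")[[1]]
  at <- mean(rootish %in% c("A", "T"))
  ## stationary process: leaf composition stays near the root composition
  expect_lt(abs(at - 0.78), 3 * sqrt(0.78 * 0.22 / 20000) + 0.02)
})

test_that("null processes produce no numts and no changes", {
  p <- simulationParams(insertionRatePerMy = 0,
                        duplicationRatePerNumtPerMy = 0, seed = 34)
  sim <- simulateNumtHistory(p, sequences = FALSE)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("a duplication-only regime only propagates the seeded origin", {
  set.seed(35)
  ## high duplication, no new insertions after the first: approximate by
  ## very low insertion rate and high duplication rate
  p <- simulationParams(insertionRatePerMy = 0.005,
                        duplicationRatePerNumtPerMy = 0.05,
                        deletionRatePerNumtPerMy = 0, seed = 35)
  sim <- simulateNumtHistory(p, sequences = FALSE)
  dup <- sim$truth[!is.na(sim$truth$parentEventId), ]
  ins <- sim$truth[is.na(sim$truth$parentEventId), ]
  expect_gt(nrow(dup), 0)
  ## every duplicate's origin coincides with an inserted ancestor's origin
  byEvent <- unique(sim$truth[, c("eventId", "originStart", "fragLen",
                                  "parentEventId")])
  originOf <- setNames(byEvent$originStart, byEvent$eventId)
  parentOf <- setNames(byEvent$parentEventId, byEvent$eventId)
  for (ev in byEvent$eventId[!is.na(byEvent$parentEventId)]) {
    root <- ev
    while (!is.na(parentOf[[root]])) root <- parentOf[[root]]
    expect_equal(originOf[[ev]], originOf[[root]])
  }
})

test_that("insertion counts follow the Poisson mean over the tree", {
  ## expected insertions = rate * total in-group branch time
  ct <- drosophilaTree()
  br <- branchTable(ct)
  genus <- br$parentAge <= 63.1 + 1e-6  # all branches below the genus root
  Ttot <- sum(br$duration[genus])
  rate <- 0.3
  nrep <- 60
  counts <- vapply(seq_len(nrep), function(k) {
    p <- simulationParams(insertionRatePerMy = rate,
                          duplicationRatePerNumtPerMy = 0,
                          deletionRatePerNumtPerMy = 0,
                          rearrangementMeans = c(interruption = 0,
                                                 deletion = 0, inversion = 0,
                                                 internal_duplication = 0),
                          seed = 1000 + k)
    sim <- simulateNumtHistory(p, sequences = FALSE)
    length(unique(sim$truth$eventId))
  }, 0)
  expected <- rate * Ttot
  se <- sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("truth tables and emitted genomes are mutually consistent", {
  p <- simulationParams(seed = 36)
  sim <- simulateNumtHistory(p, sequences = TRUE)
  expect_gt(nrow(sim$truth), 10)
  for (i in sample(nrow(sim$truth), 10)) {
    tr <- sim$truth[i, ]
    s <- substr(sim$genomes[[tr$species]][[tr$scaffold]],
                tr$numtStart + 1, tr$numtEnd)
    expect_equal(nchar(s), tr$numtEnd - tr$numtStart)
    ## fragment mito intervals are consistent with recorded lengths
    fr <- sim$fragments[sim$fragments$numtId == tr$numtId, ]
    expect_equal(sum(fr$mitoEnd - fr$mitoStart),
                 sum(fr$nucEnd - fr$nucStart))
    ## a numt keeps >= the identity expected from nuclear-rate divergence
    expect_gt(tr$identityToInsertion,
              1 - f84ExpectedPDistance(
                f84Params(freqsFromAT(p$atFraction)),
                tr$insertionTime * p$mitoSubstRate / p$nuclearRateDivisor) -
                0.1)
  }
  ## insertion times lie within their branch age interval
  br <- branchTable(p$tree)
  for (i in seq_len(nrow(sim$truth))) {
    b <- br[br$branch == sim$truth$insertionBranch[i], ]
    expect_true(sim$truth$insertionTime[i] > b$childAge - 1e-9)
    expect_true(sim$truth$insertionTime[i] <= b$parentAge + 1e-9)
  }
})

test_that("without deletion, numt counts never decrease toward the leaves", {
  p <- simulationParams(deletionRatePerNumtPerMy = 0, seed = 37)
  sim <- simulateNumtHistory(p, sequences = FALSE)
  ct <- p$tree
  br <- branchTable(ct)
  phy <- ct@tree
  ## count events ancestral to each leaf: a leaf's complement must include
  ## every insertion on its root path; with deletion off, counts along a
  ## root-to-leaf path are cumulative sums of nonnegative increments
  for (sp in c("Dmel", "Dvir", "Dwil")) {
    n <- sum(sim$truth$species == sp)
    pathBranches <- character(0)
    node <- which(phy$tip.label == sp)
    repeat {
      e <- which(phy$edge[, 2] == node)
      if (!length(e)) break
      pathBranches <- c(pathBranches, br$branch[e])
      node <- phy$edge[e, 1]
    }
    onPath <- sum(sim$truth$species == sp &
                    sim$truth$insertionBranch %in% pathBranches)
    expect_equal(onPath, n)   # every copy arises on the root path
  }
})

test_that("repeat planting respects density and bias settings", {
  p <- simulationParams(seed = 38, scaffoldCount = 2,
                        scaffoldLength = 300000)
  sim <- simulateNumtHistory(p, sequences = TRUE)
  ## density 0: nothing changes
  sim0 <- plantRepeats(sim, densityPerMb = 0, adjacencyBias = 0)
  expect_equal(nrow(sim0$repeats), 0L)
  expect_equal(sim0$genomes, sim$genomes)
  ## biased planting puts repeats near numts and updates coordinates
  simB <- plantRepeats(sim, densityPerMb = 2, adjacencyBias = 2)
  expect_gt(nrow(simB$repeats), 0L)
  for (i in sample(nrow(simB$truth), min(8, nrow(simB$truth)))) {
    tr <- simB$truth[i, ]
    s <- substr(simB$genomes[[tr$species]][[tr$scaffold]],
                tr$numtStart + 1, tr$numtEnd)
    orig <- sim$truth[sim$truth$numtId == tr$numtId, ]
    sOrig <- substr(sim$genomes[[tr$species]][[tr$scaffold]],
                    orig$numtStart + 1, orig$numtEnd)
    expect_equal(s, sOrig)   # numt bodies unchanged, coordinates shifted
  }
  ## planted repeats never fall inside numt bodies
  for (i in seq_len(nrow(simB$repeats))) {
    rp <- simB$repeats[i, ]
    tr <- simB$truth[simB$truth$scaffold == rp$scaffold, , drop = FALSE]
    if (nrow(tr)) {
      expect_false(any(rp$start < tr$numtEnd & rp$end > tr$numtStart &
                         rp$start >= tr$numtStart))
    }
  }
})
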
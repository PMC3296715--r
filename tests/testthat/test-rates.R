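twoCladeTree <- function() {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:5,B:5)ab:5,C:10)r;", nwk)
  loadCalibratedTree(nwk)
}

test_that("insertion rate is N_i / T with density weighting", {
  ct <- twoCladeTree()
  cfg <- pipelineConfig(recentBranches = c("A", "B"))
  ## T = 5 + 5 = 10; N_i = 19.2 -> 1.92 insertions/My
  dens <- data.frame(numtId = "x", branch = "A", mass = 19.2)
  ir <- insertionRate(dens, ct, cfg)
  expect_equal(ir$T, 10)
  expect_equal(ir$rate, 1.92)
  ## zero insertions give rate zero
  ir0 <- insertionRate(data.frame(numtId = character(),
                                  branch = character(), mass = numeric()),
                       ct, cfg)
  expect_equal(ir0$rate, 0)
  ## mass outside the recent set does not enter the genus rate
  densOut <- rbind(dens, data.frame(numtId = "y", branch = "C", mass = 7))
  expect_equal(insertionRate(densOut, ct, cfg)$rate, 1.92)
  ## invariant to row order
  expect_equal(insertionRate(densOut[2:1, ], ct, cfg)$rate, 1.92)
  ## branches older than the cutoff are truncated at the cutoff
  cfg2 <- pipelineConfig(recentBranches = c("A", "B", "C"),
                         recentBranchAgeCutoffMy = 8)
  expect_equal(insertionRate(dens, ct, cfg2)$T, 18)
  ## empty branch set errors
  expect_error(insertionRate(dens, ct,
                             pipelineConfig(recentBranches = "nope")),
               "recent branch")
})

test_that("duplication rate uses half the branch time per numt", {
  ct <- twoCladeTree()
  cfg <- pipelineConfig(recentBranches = c("A", "B"))
  ## Dp = 1, N = 20, T = 10 -> Thalf = 5 -> 1/(20*5) = 0.01
  dr <- duplicationRate(Dp = 1, N = 20, ct, cfg)
  expect_equal(dr$Thalf, 5)
  expect_equal(dr$rate, 0.01)
  expect_equal(duplicationRate(Dp = 0, N = 20, ct, cfg)$rate, 0)
  expect_error(duplicationRate(Dp = 1, N = 0, ct, cfg), "N")
  ## counting modes from paralog set sizes: 93 members in 26 sets
  sizes <- c(rep(2, 20), rep(3, 3), rep(4, 2), 36)
  expect_equal(sum(sizes), 93)
  expect_length(sizes, 26L)
  one <- duplicationRate(N = 20, ct = ct, config = cfg,
                         countMode = "one_per_set",
                         paralogSetSizes = sizes)
  tot <- duplicationRate(N = 20, ct = ct, config = cfg,
                         countMode = "total", paralogSetSizes = sizes)
  expect_equal(one$Dp, length(sizes))
  ## duplicate-derived numts = members - sets = 67
  expect_equal(tot$Dp, 93 - length(sizes))
})

test_that("steady-state deletion rate and half-life", {
  d <- deletionRateSteadyState(1.0, 20)
  expect_equal(d$rate, 0.05)
  expect_equal(d$halfLife, log(2) / 0.05)
  expect_equal(round(d$halfLife, 2), 13.86)
  d0 <- deletionRateSteadyState(0, 20)
  expect_equal(d0$rate, 0)
  expect_equal(d0$halfLife, Inf)
  expect_error(deletionRateSteadyState(1, 0), "N")
  ## combined estimates object enforces the half-life identity
  ct <- twoCladeTree()
  cfg <- pipelineConfig(recentBranches = c("A", "B"))
  re <- rateEstimates(
    insertionRate(data.frame(numtId = "x", branch = "A", mass = 10), ct,
                  cfg),
    duplicationRate(Dp = 1, N = 20, ct, cfg),
    deletionRateSteadyState(1.0, 20))
  expect_s4_class(re, "RateEstimates")
  expect_equal(re@halfLife, log(2) / re@deletionRate)
})

test_that("correlations use average ranks and the t approximation", {
  set.seed(61)
  x <- sort(runif(12)); y <- x^3 + 2   # perfectly monotone
  cs <- correlationSuite(x, y)
  expect_equal(cs["spearman", "estimate"], 1)
  expect_lt(cs["pearson", "pValue"], 0.01)
  ## constant column: undefined, reported as NA
  csNA <- correlationSuite(x, rep(1, 12))
  expect_true(all(is.na(csNA$estimate)))
  ## Pearson estimate agrees with cor()
  a <- rnorm(15); b <- a + rnorm(15)
  expect_equal(correlationSuite(a, b)["pearson", "estimate"], cor(a, b))
  expect_error(correlationSuite(1:2, 2:3), "at least 3")
})

test_that("terminal fraction reproduces the density split arithmetic", {
  ct <- drosophilaTree()
  dens <- rbind(
    data.frame(numtId = "t", branch = "Dvir", mass = 238.7),
    data.frame(numtId = "i", branch = "melsub", mass = 27.3))
  tf <- terminalInsertionFraction(dens, ct)
  expect_equal(round(tf$fraction, 1), 89.7)
})

test_that("density tables sum to the dated insertion count", {
  mkPl <- function(id, branches, dens, excluded = FALSE) {
    tb <- data.frame(branch = branches, logL = 0, pValue = 1,
                     inSet = dens > 0, density = dens,
                     parentAge = 10, childAge = 0, pendant = 0.01)
    new("PlacementResult", numtId = id, table = tb,
        bestBranch = branches[which.max(dens)], ageMin = 0, ageMax = 10,
        attachTime = 1, excluded = excluded, lowInfo = FALSE)
  }
  pls <- list(mkPl("n1", c("Dvir", "Dmoj"), c(0.5, 0.5)),
              mkPl("n2", c("Dvir", "Dmoj"), c(1, 0)),
              mkPl("n3", c("Dvir", "Dmoj"), c(1, 0), excluded = TRUE))
  dt <- insertionDensityTable(pls)
  expect_equal(sum(dt$mass), 2)           # excluded numt contributes 0
  expect_equal(attr(dt, "nDated"), 2L)
  ## ortholog copies sharing one event count once
  pls2 <- list(mkPl("a_E1", "Dvir", 1), mkPl("b_E1", "Dvir", 1),
               mkPl("c_E2", "Dmoj", 1))
  dt2 <- insertionDensityTable(pls2, eventOf = c(a_E1 = "E1", b_E1 = "E1",
                                                 c_E2 = "E2"))
  expect_equal(sum(dt2$mass), 2)
  expect_equal(attr(dt2, "nDated"), 2L)
})

test_that("report rows are consistent with the bundled survey tables", {
  s <- drosophilaNumtSurvey()
  expect_equal(nrow(s), 11L)
  expect_equal(sum(s$nNumts), 302L)
  r <- drosophilaRearrangementCounts()
  ## totals match the published column sums
  expect_equal(sum(r$interruptionEvents), 59L)
  expect_equal(sum(r$deletionEvents), 48L)
  expect_equal(sum(r$inversionEvents), 6L)
  expect_equal(sum(r$duplicationEvents), 18L)
})
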
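ctPl <- drosophilaTree()
cfgPl <- pipelineConfig()

test_that("projection reproduces identical rows and filters gap/N columns", {
  set.seed(51)
  model <- f84Params(freqsFromAT(0.78), 2)
  pw <- panelWithSnapshots(ctPl, model, 0.004, list(), mitoLength = 3000)
  mitos <- unlist(pw$leaves)
  panel <- panelAlignment(mitos, "Dsec")
  ## numt identical to the host segment projects identically
  ann <- singleFragAnnotation("t", "Dsec", 500, 800)
  body <- substr(mitos[["Dsec"]], 501, 1300)
  pr <- projectAlignment(ann, body, panel, "Dsec")
  expect_equal(unname(pr$aln["numt", ]), unname(pr$aln["Dsec", ]))
  expect_equal(ncol(pr$aln), 800L)
  ## a column with N in any row (outgroup) is removed
  mitosN <- mitos
  substr(mitosN[["Agam"]], 521, 530) <- strrep("N", 10)
  panelN <- panelAlignment(mitosN, "Dsec")
  prN <- projectAlignment(ann, body, panelN, "Dsec")
  expect_equal(ncol(prN$aln), 790L)
  expect_false(any(prN$columns %in% 520:529))
  ## a numt with no usable columns is untestable
  annBad <- singleFragAnnotation("t2", "Dsec", 500, 10)
  prBad <- projectAlignment(annBad, strrep("N", 10), panel, "Dsec",
                            minColumns = 5)
  expect_identical(prBad, "untestable")
})

test_that("a numt equal to a species' mito segment places on its branch", {
  set.seed(52)
  model <- f84Params(freqsFromAT(0.78), 2)
  pw <- panelWithSnapshots(ctPl, model, 0.004, list(), mitoLength = 4000)
  mitos <- unlist(pw$leaves)
  panel <- panelAlignment(mitos, "Dyak")
  ann <- singleFragAnnotation("t", "Dyak", 1000, 1200)
  body <- substr(mitos[["Dyak"]], 1001, 2200)
  pr <- projectAlignment(ann, body, panel, "Dyak")
  pl <- placeNumt(pr, ctPl, config = cfgPl, numtId = "t")
  expect_equal(bestBranch(pl), "Dyak")
  expect_true("Dyak" %in% significanceSet(pl))
  ## density weights: nonnegative, sum to 1, proportional to duration
  tb <- pl@table
  expect_true(all(tb$density >= 0))
  expect_equal(sum(tb$density), 1)
  sel <- tb$inSet & tb$density > 0
  if (sum(sel) > 1) {
    expect_equal(tb$density[sel] / sum(tb$density[sel]),
                 (tb$parentAge[sel] - tb$childAge[sel]) /
                   sum(tb$parentAge[sel] - tb$childAge[sel]))
  }
  ## the age window covers the best branch's node ages
  w <- ageWindow(pl)
  expect_lte(w[["tMin"]], tb$childAge[tb$branch == "Dyak"])
  expect_gte(w[["tMax"]], tb$parentAge[tb$branch == "Dyak"] - 1e-9)
  ## relabeling alignment rows does not change the placement
  pr2 <- pr
  perm <- sample(nrow(pr$aln))
  pr2$aln <- pr$aln[perm, , drop = FALSE]
  pl2 <- placeNumt(pr2, ctPl, config = cfgPl, numtId = "t")
  expect_equal(bestBranch(pl2), bestBranch(pl))
  expect_equal(pl2@table$logL, pl@table$logL, tolerance = 1e-6)
})

test_that("loosening the rejection threshold never shrinks the set", {
  set.seed(53)
  model <- f84Params(freqsFromAT(0.78), 2)
  pw <- panelWithSnapshots(ctPl, model, 0.004,
                           list(list(tip = "Dvir", age = 10)),
                           mitoLength = 3000)
  mitos <- unlist(pw$leaves)
  frag <- pw$snaps[[1]][101:700]
  body <- numtdyn:::codesToSeq(
    numtdyn:::evolveCodes(frag, model, 10 * 0.004 / 6))
  ann <- singleFragAnnotation("t", "Dvir", 100, 600)
  panel <- panelAlignment(mitos, "Dvir")
  pr <- projectAlignment(ann, body, panel, "Dvir")
  pl <- placeNumt(pr, ctPl, config = cfgPl)
  pv <- pl@table$pValue
  ## the set of branches retained at threshold a is {P >= a}: smaller a
  ## (harder to reject) gives a superset
  for (aPair in list(c(0.01, 0.05), c(0.05, 0.2))) {
    keepLo <- pl@table$branch[pv >= aPair[1]]
    keepHi <- pl@table$branch[pv >= aPair[2]]
    expect_true(all(keepHi %in% keepLo))
  }
})

test_that("homology pairs with too little overlap are untestable", {
  v <- testHomology("untestable", "untestable", ctPl, "paralog", cfgPl)
  expect_equal(relation(v), "untestable")
  fake <- list(aln = matrix("A", 1, 1), columns = 1L)
  fake2 <- list(aln = matrix("A", 1, 1), columns = 500L)
  v2 <- testHomology(fake, fake2, ctPl, "paralog", cfgPl)
  expect_equal(relation(v2), "untestable")
})

test_that("paralog sets close transitively", {
  pairs <- data.frame(idA = c("a", "b", "x", "p"),
                      idB = c("b", "c", "y", "q"),
                      relation = c("paralog", "paralog", "paralog",
                                   "unresolved"))
  sets <- paralogSets(pairs)
  sizes <- sort(vapply(sets, length, 0L))
  expect_equal(sizes, c(2L, 3L))
  expect_true(any(vapply(sets, function(s) setequal(s, c("a", "b", "c")),
                         TRUE)))
  ## duplicate-derived copies = members - sets
  expect_equal(sum(lengths(sets)) - length(sets), 3L)
})

test_that("micro-synteny confirmation distinguishes shared flanks", {
  set.seed(54)
  cfgLocal <- pipelineConfig(syntenyFlankBases = 3000)
  shared <- randomDNA(2000, at = 0.6)
  mkScaffold <- function(flank) {
    paste0(randomDNA(3000, at = 0.6), flank, randomDNA(1000, at = 0.6),
           strrep("G", 0), randomDNA(4000, at = 0.6))
  }
  ## two numts carrying 2 kb of shared flank upstream
  scfA <- paste0(randomDNA(2000, 0.6), shared, randomDNA(500, 0.6))
  scfB <- paste0(randomDNA(1500, 0.6), shared, randomDNA(800, 0.6))
  annA <- new("NumtAnnotation", numtId = "a", species = "sp",
              scaffold = "sA",
              fragments = data.frame(nucStart = nchar(scfA) - 400L,
                                     nucEnd = nchar(scfA) - 100L,
                                     mitoStart = 0L, mitoEnd = 300L,
                                     strand = "+", identity = 0.9,
                                     originSpanning = FALSE),
              numtLength = 300)
  annB <- new("NumtAnnotation", numtId = "b", species = "sp",
              scaffold = "sB",
              fragments = data.frame(nucStart = nchar(scfB) - 700L,
                                     nucEnd = nchar(scfB) - 400L,
                                     mitoStart = 0L, mitoEnd = 300L,
                                     strand = "+", identity = 0.9,
                                     originSpanning = FALSE),
              numtLength = 300)
  cA <- flankContext(annA, scfA, config = cfgLocal)
  cB <- flankContext(annB, scfB, config = cfgLocal)
  expect_equal(confirmMicrosynteny(cA, cB, cfgLocal), "yes")
  ## fully masked flanks are untestable
  expect_equal(confirmMicrosynteny(strrep("n", 5000), cB, cfgLocal),
               "untestable")
  ## independent random flanks give no evidence
  wrong <- 0L
  for (k in 1:8) {
    sA <- paste0(randomDNA(2500, 0.6), randomDNA(300, 0.78),
                 randomDNA(500, 0.6))
    sB <- paste0(randomDNA(2500, 0.6), randomDNA(300, 0.78),
                 randomDNA(500, 0.6))
    aA <- new("NumtAnnotation", numtId = "ra", species = "sp",
              scaffold = "s",
              fragments = data.frame(nucStart = 2500L, nucEnd = 2800L,
                                     mitoStart = 0L, mitoEnd = 300L,
                                     strand = "+", identity = 0.9,
                                     originSpanning = FALSE),
              numtLength = 300)
    wrong <- wrong + (confirmMicrosynteny(
      flankContext(aA, sA, config = cfgLocal),
      flankContext(aA, sB, config = cfgLocal), cfgLocal) == "yes")
  }
  expect_equal(wrong, 0L)
})
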
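cfgAnn <- pipelineConfig()

mkChain <- function(ss, se, qs = 0, qe = NULL, chain = 1, strand = "+") {
  if (is.null(qe)) qe <- qs + (se - ss)
  data.frame(chain = chain, sStart = ss, sEnd = se, qStart = qs, qEnd = qe,
             strand = strand, score = 100, eValue = 1e-9, nHsps = 1L)
}

mkFrag <- function(ss, se, qs, qe, strand = "+", id = 0.95) {
  data.frame(qStart = qs, qEnd = qe, sStart = ss, sEnd = se, strand = strand,
             score = 5 * (se - ss), bitScore = 1, eValue = 1e-9,
             identity = id, nMatch = se - ss, nMismatch = 0)
}

mkNumt <- function(frs, id = "n1", mitoLen = 16000) {
  mergeGroup(frs, mitoLen, numtId = id)
}

test_that("hits group under the strict 25-kb separation rule", {
  g1 <- groupHits(rbind(mkChain(0, 1000), mkChain(20000, 21000, chain = 2)))
  expect_equal(g1[1], g1[2])
  g2 <- groupHits(rbind(mkChain(0, 1000), mkChain(30000, 31000, chain = 2)))
  expect_false(g2[1] == g2[2])
  ## boundary: gap of exactly 25 kb is NOT grouped (strict <)
  g3 <- groupHits(rbind(mkChain(0, 1000), mkChain(26000, 27000, chain = 2)))
  expect_false(g3[1] == g3[2])
  g4 <- groupHits(rbind(mkChain(0, 1000), mkChain(25999, 27000, chain = 2)))
  expect_equal(g4[1], g4[2])
})

test_that("groups equal connected components of the gap graph", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    ss <- sort(sample.int(2e5, n))
    chains <- do.call(rbind, lapply(seq_len(n), function(i)
      mkChain(ss[i], ss[i] + sample(500:3000, 1), chain = i)))
    got <- groupHits(chains, 25000)
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      gap <- max(chains$sStart[i], chains$sStart[j]) -
        min(chains$sEnd[i], chains$sEnd[j])
      gap < 25000
    }))
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    expect_equal(length(unique(got)), comp$no)
    expect_true(all(tapply(comp$membership, got,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("merging explains fragment sets through the event grammar", {
  ## colinear with a mito gap: single numt, deletion candidate
  n1 <- mkNumt(rbind(mkFrag(0, 2000, 0, 2000),
                     mkFrag(2000, 3500, 2500, 4000)))
  expect_s4_class(n1, "NumtAnnotation")
  ev1 <- classifyRearrangements(n1, cfgAnn)
  expect_equal(ev1$type, "deletion")
  expect_equal(ev1$size, 500)
  ## repeated mito interval: single numt with duplication candidate
  n2 <- mkNumt(rbind(mkFrag(0, 2000, 0, 2000),
                     mkFrag(2000, 4000, 0, 2000)))
  ev2 <- classifyRearrangements(n2, cfgAnn)
  expect_true("internal_duplication" %in% ev2$type)
  expect_equal(ev2$size[ev2$type == "internal_duplication"], 2000)
  ## contradictory nuclear overlap is rejected with a diagnostic
  bad <- mergeGroup(rbind(mkFrag(0, 2000, 0, 2000),
                          mkFrag(500, 1500, 9000, 10000)), 16000)
  expect_s3_class(bad, "RejectedGroup")
  expect_match(attr(bad, "reason"), "contradictory")
})

test_that("rearrangement classes follow their defining evidence", {
  ## deletion: colinear fragments, contiguous in the nucleus
  d <- classifyRearrangements(
    mkNumt(rbind(mkFrag(0, 400, 100, 500), mkFrag(400, 800, 1200, 1600))),
    cfgAnn)
  expect_equal(d$type, "deletion")
  expect_equal(d$size, 700)
  ## interruption: 5 kb of foreign sequence between fragments
  i <- classifyRearrangements(
    mkNumt(rbind(mkFrag(0, 400, 100, 500), mkFrag(5400, 5800, 500, 900))),
    cfgAnn)
  expect_equal(i$type, "interruption")
  expect_equal(i$size, 5000)
  ## inversion: strand flip between mito-adjacent fragments
  v <- classifyRearrangements(
    mkNumt(rbind(mkFrag(0, 400, 100, 500),
                 mkFrag(400, 800, 500, 900, strand = "-"))),
    cfgAnn)
  expect_equal(v$type, "inversion")
  expect_equal(v$size, 400)
  ## sizes below the minimum are never reported
  s <- classifyRearrangements(
    mkNumt(rbind(mkFrag(0, 400, 100, 500), mkFrag(400, 800, 650, 1050))),
    cfgAnn)
  expect_equal(nrow(s), 0L)
  expect_true(all(rbind(d, i, v)$size >= cfgAnn@minEventBases))
})

test_that("fragment length sums never exceed the span", {
  set.seed(42)
  for (ann in randomAnnotations(10)) {
    fr <- fragments(ann)
    span <- max(fr$nucEnd) - min(fr$nucStart)
    expect_lte(sum(fr$nucEnd - fr$nucStart), span)
  }
})

test_that("repeat adjacency flags and the association test behave", {
  mk1 <- function(s, e, scf = "scf1", id = "n1") {
    new("NumtAnnotation", numtId = id, species = "sp", scaffold = scf,
        fragments = data.frame(nucStart = s, nucEnd = e, mitoStart = 0L,
                               mitoEnd = e - s, strand = "+",
                               identity = 0.9, originSpanning = FALSE),
        numtLength = e - s)
  }
  scfLen <- c(scf1 = 100000)
  ## repeat 150 b from the numt end -> adjacent; 300 b away -> not
  numt <- mk1(50000, 51000)
  repsNear <- data.frame(scaffold = "scf1", start = 51150, end = 51800)
  repsFar <- data.frame(scaffold = "scf1", start = 51300, end = 51800)
  set.seed(43)
  a1 <- associateRepeats(list(numt), repsNear, scfLen, cfgAnn,
                         nControls = 50)
  expect_true(a1$flags[["n1"]])
  a2 <- associateRepeats(list(numt), repsFar, scfLen, cfgAnn,
                         nControls = 50)
  expect_false(a2$flags[["n1"]])
  ## numts too close to a scaffold edge are excluded from the test
  edge <- mk1(10, 500, id = "n2")
  a3 <- associateRepeats(list(edge), repsFar, scfLen, cfgAnn,
                         nControls = 10)
  expect_equal(a3$nExcluded, 1L)
  ## empty repeat annotation: all flags false, P = 1
  a4 <- associateRepeats(list(numt),
                         data.frame(scaffold = character(),
                                    start = integer(), end = integer()),
                         scfLen, cfgAnn)
  expect_equal(a4$pValue, 1)
})

test_that("the published adjacency contingency is significant", {
  ## 92 adjacent of 233 numts against a 15% background over 1000 controls;
  ## cross-checked against the exact hypergeometric tail
  tab <- matrix(c(92, 233 - 92, 150, 850), 2, 2)
  p <- fisher.test(tab)$p.value
  expect_lt(p, 0.01)
  pHyper <- phyper(92 - 1, 92 + 150, 141 + 850, 233, lower.tail = FALSE)
  expect_lt(pHyper, 0.01)
})

test_that("intron overlap counts fully intronic numts only", {
  genes <- data.frame(
    scaffold = "scf1", type = c("mRNA", "exon", "exon"),
    start = c(1000, 1000, 8000), end = c(9000, 1500, 9000),
    id = c("tx1", "ex1", "ex2"), parent = c(NA, "tx1", "tx1"))
  mk1 <- function(s, e, id) {
    new("NumtAnnotation", numtId = id, species = "sp", scaffold = "scf1",
        fragments = data.frame(nucStart = s, nucEnd = e, mitoStart = 0L,
                               mitoEnd = e - s, strand = "+",
                               identity = 0.9, originSpanning = FALSE),
        numtLength = e - s)
  }
  inside <- mk1(2000, 3000, "in1")       # intron between the exons
  onExon <- mk1(1400, 2500, "ex1")       # crosses an exon boundary
  outside <- mk1(20000, 21000, "out1")
  ov <- intronOverlap(list(inside, onExon, outside), genes)
  expect_equal(ov$count, 1L)
  expect_true(ov$intronic[["in1"]])
  expect_false(ov$intronic[["ex1"]])
  expect_false(ov$intronic[["out1"]])
  ## 24 intronic of 302 is the published 8%
  expect_equal(round(100 * 24 / 302), 8)
})

test_that("GFF3 files are parsed for intron overlap", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scf1\tsrc\tmRNA\t1000\t9000\t.\t+\t.\tID=tx1",
               "scf1\tsrc\texon\t1000\t1500\t.\t+\t.\tID=ex1;Parent=tx1",
               "scf1\tsrc\texon\t8000\t9000\t.\t+\t.\tID=ex2;Parent=tx1"),
             gff)
  numt <- new("NumtAnnotation", numtId = "in1", species = "sp",
              scaffold = "scf1",
              fragments = data.frame(nucStart = 2000L, nucEnd = 3000L,
                                     mitoStart = 0L, mitoEnd = 1000L,
                                     strand = "+", identity = 0.9,
                                     originSpanning = FALSE),
              numtLength = 1000)
  ov <- intronOverlap(list(numt), gff)
  expect_equal(ov$count, 1L)
})

test_that("summary report mirrors the survey table schema", {
  n1 <- new("NumtAnnotation", numtId = "a1", species = "spA",
            scaffold = "s",
            fragments = data.frame(nucStart = 0L, nucEnd = 1000L,
                                   mitoStart = 0L, mitoEnd = 1000L,
                                   strand = "+", identity = 0.9,
                                   originSpanning = FALSE),
            numtLength = 1000)
  ev <- data.frame(numtId = c("a1", "a1"), type = c("deletion", "deletion"),
                   size = c(300, 400), nucStart = NA, nucEnd = NA,
                   mitoStart = NA, mitoEnd = NA)
  rep <- summaryReport(list(n1), ev, speciesOrder = c("spA", "spB"))
  expect_equal(rep$perSpecies$nNumts, c(1L, 0L))
  ## species with no numts: zero row, absent average
  expect_true(is.na(rep$perSpecies$avgLengthBp[2]))
  ## two deletion events in one numt -> "2 (1)" and totals match row sums
  expect_equal(rep$rearrangements$deletion[1], "2 (1)")
  tot <- rep$rearrangements[rep$rearrangements$species == "Total", ]
  expect_equal(tot$deletionEvents,
               sum(rep$rearrangements$deletionEvents[-3]))
})
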
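test_that("hypergeometric p-values match hand and enumeration oracles", {
  bg <- sprintf("g%02d", 1:20)
  # N=20, K=5, n=10, k=5: C(5,5) C(15,5) / C(20,10) = 3003/184756
  res <- hypergeomORA(bg[1:10], list(hit = bg[1:5]), bg)
  expect_equal(oraTable(res)$p, 3003 / 184756, tolerance = 1e-12)

  # oracle equivalence on random small universes
  set.seed(20)
  for (i in 1:5) {
    N <- sample(10:20, 1); K <- sample(3:6, 1); n <- sample(4:8, 1)
    bgI <- sprintf("x%02d", seq_len(N))
    query <- sample(bgI, n)
    setI <- bgI[1:K]
    p <- oraTable(hypergeomORA(query, list(s = setI), bgI, minSize = 1))$p
    k <- length(intersect(query, setI))
    expect_equal(p, enumHyperP(N, K, n, k), tolerance = 1e-10)
  }
})

test_that("ORA degenerate cases behave as set algebra dictates", {
  bg <- sprintf("g%02d", 1:20)
  # query = background: every set fully overlaps, p = 1
  res <- hypergeomORA(bg, list(s1 = bg[1:5], s2 = bg[6:12]), bg)
  expect_true(all(oraTable(res)$p == 1))
  expect_equal(oraTable(res)$k, oraTable(res)$K)
  # zero overlap: p = P(X >= 0) = 1
  res0 <- hypergeomORA(bg[1:5], list(s = bg[10:14]), bg)
  expect_equal(oraTable(res0)$p, 1)
  # query outside background is an error naming offenders
  expect_error(hypergeomORA(c(bg[1], "NOPE"), list(s = bg[1:5]), bg), "NOPE")
  # set-size limits are applied after background intersection
  resF <- hypergeomORA(bg[1:5], list(tiny = bg[1:2], ok = bg[1:5]), bg)
  expect_equal(oraTable(resF)$set, "ok")
})

test_that("BH q-values are monotone in p, bounded, and growing a disjoint set never helps", {
  set.seed(21)
  bg <- sprintf("g%03d", 1:100)
  sets <- lapply(1:10, function(i) sample(bg, 20))
  names(sets) <- sprintf("s%02d", 1:10)
  res <- oraTable(hypergeomORA(sample(bg, 30), sets, bg))
  expect_true(all(res$q <= 1))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))

  # adding a background gene the query misses can only dilute the set
  query <- bg[1:10]
  pBefore <- oraTable(hypergeomORA(query, list(s = bg[1:8]), bg))$p
  pAfter <- oraTable(hypergeomORA(query, list(s = c(bg[1:8], bg[50])), bg))$p
  expect_gte(pAfter, pBefore)
})

test_that("threshold ORA keeps the best-scoring replicate per gene", {
  map <- data.frame(probeset = c("p1", "p2", "p3", "p4", "px"),
                    gene = c("A", "A", "B", "C", NA))
  scores <- c(p1 = -2.1, p2 = 0.3, p3 = 0.5, p4 = 1.7, px = 9)
  sets <- list(s = c("A", "B", "C"))
  expect_message(
    res <- thresholdORA(scores, map, sets, minSize = 1),
    "1 probesets dropped")
  gs <- attr(res, "geneScores")
  expect_equal(unname(gs["A"]), -2.1)  # max |score| wins, sign kept
  expect_equal(res@nUnmapped, 1L)
  # query = {A (2.1), C (1.7)}; B stays background-only
  expect_equal(oraTable(res)$k, 2L)
  expect_equal(oraTable(res)$n, 2L)

  # all scores below threshold: empty query, all p = 1
  low <- c(p1 = 0.2, p2 = 0.1, p3 = -0.4, p4 = 1.0)
  resLow <- thresholdORA(low, map[1:4, ], sets, minSize = 1)
  expect_true(all(oraTable(resLow)$p == 1))
})

test_that("a planted down-regulated module is flagged only in affected regions", {
  hits <- 0L
  nSeeds <- 20
  for (sd in 1:nSeeds) {
    sim <- simulateKOExperiment(seed = 400 + sd)  # module down in NAC+PFC only
    map <- data.frame(
      probeset = rownames(sim$se),
      gene = SummarizedExperiment::rowData(sim$se)$gene,
      stringsAsFactors = FALSE)
    set.seed(500 + sd)
    decoys <- lapply(1:10, function(i) sample(map$gene, 40))
    names(decoys) <- sprintf("d%02d", 1:10)
    sets <- geneSetList(c(list(MODULE = moduleGenes(sim$truth)), decoys))
    qOf <- function(rg) {
      tb <- sscoreContrast(sim$se, rg, "KO.Sal", "CTL.Sal", contrast = "basal")
      res <- thresholdORA(rowMeans(scoreMatrix(tb)), map, sets, fdr = 0.10)
      tbl <- oraTable(res)
      tbl$q[tbl$set == "MODULE"]
    }
    ok <- qOf("NAC") <= 0.10 && qOf("PFC") <= 0.10 && qOf("VMB") > 0.10
    hits <- hits + ok
  }
  expect_gte(hits / nSeeds, 0.9)
})

test_that("GMT round trip and the bundled myelin stand-in set", {
  gmtFile <- tempfile(fileext = ".gmt")
  writeLines("myelin\tcustom\tMbp\tPlp1\tMal", gmtFile)
  gs <- readGMT(gmtFile)
  expect_length(geneSets(gs)$myelin, 3)
  expect_setequal(geneSets(gs)$myelin, c("MBP", "PLP1", "MAL"))

  out <- tempfile(fileext = ".gmt")
  writeGMT(gs, out)
  expect_identical(geneSets(readGMT(out)), geneSets(gs))

  my <- myelinGeneSet()
  expect_length(geneSets(my)$MYELIN_EXTENDED, 12)
  expect_true(all(c("MAL", "MBP", "PLP1", "TSPAN2", "MOBP") %in%
                    geneSets(my)$MYELIN_EXTENDED))
})
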
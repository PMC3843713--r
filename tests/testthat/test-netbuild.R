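test_that("Pearson r and p follow the product-moment and t formulas", {
  # identity: r = 1, p = 0
  res <- pearsonWithP(1:10, 1:10)
  expect_equal(unname(res["r"]), 1)
  expect_equal(unname(res["p"]), 0)
  # hand computation: x=(1,2,3,4), y=(2,1,4,3) -> r=0.6, t=1.0607 on 2 df
  res2 <- pearsonWithP(1:4, c(2, 1, 4, 3))
  expect_equal(unname(res2["r"]), 0.6)
  expect_equal(unname(res2["p"]), 0.40, tolerance = 0.01)
  expect_equal(unname(res2["n"]), 4)
  # agrees with the stock implementation on random draws
  set.seed(30)
  x <- rnorm(15); y <- rnorm(15)
  ct <- cor.test(x, y)
  res3 <- pearsonWithP(x, y)
  expect_equal(unname(res3["r"]), unname(ct$estimate))
  expect_equal(unname(res3["p"]), ct$p.value)
  # name-based alignment drops unmatched strains
  xa <- setNames(rnorm(8), sprintf("s%d", 1:8))
  ya <- setNames(rnorm(6), sprintf("s%d", 3:8))
  expect_equal(unname(pearsonWithP(xa, ya)["n"]), 6)

  expect_error(pearsonWithP(1:2, 1:2), "3 complete pairs")
  expect_error(pearsonWithP(rep(1, 5), 1:5), "zero variance")
})

test_that("the screen-level critical correlation inverts the t tail", {
  # n = 29 strains at alpha = 0.01: the smallest significant |r| is ~0.4705
  expect_equal(criticalR(29, 0.01), 0.4705, tolerance = 1e-3)
  # consistency: the t tail evaluated at the critical r gives back alpha
  rc <- criticalR(20, 0.05)
  tt <- rc * sqrt(18 / (1 - rc^2))
  expect_equal(2 * pt(-tt, 18), 0.05, tolerance = 1e-10)
})

test_that("anchor and phenotype screens recover a planted module", {
  recallA <- recallP <- numeric(20)
  for (sd in 1:20) {
    sim <- simulateRIPanel(nStrains = 30, nProbesets = 800, moduleSize = 50,
                           seed = 600 + sd)
    sa <- anchorScreen(sim$panel, "Fyn")
    sp <- phenotypeScreen(sim$panel)
    mp <- moduleProbesets(sim$truth)
    recallA[sd] <- mean(mp %in% screenRecords(sa)$probeset)
    recallP[sd] <- mean(mp %in% screenRecords(sp)$probeset)
  }
  expect_gte(mean(recallA), 0.8)
  expect_gte(mean(recallP), 0.8)
})

test_that("screens handle trivial and error cases", {
  sim <- simulateRIPanel(nStrains = 10, nProbesets = 100, moduleSize = 10,
                         seed = 31)
  # alpha = 1 retains everything except the anchor itself
  all <- anchorScreen(sim$panel, "Fyn", alpha = 1)
  expect_equal(nrow(screenRecords(all)), all@nTested)
  expect_false(sim$truth@anchorProbeset %in% screenRecords(all)$probeset)
  expect_error(anchorScreen(sim$panel, "NOSUCHGENE"), "no probeset")

  noPheno <- simulateRIPanel(nStrains = 10, nProbesets = 100, moduleSize = 10,
                             withPhenotype = FALSE, seed = 32)
  expect_error(phenotypeScreen(noPheno$panel), "no phenotype")
})

test_that("list intersection follows set algebra with the anchor appended", {
  expect_setequal(intersectLists(list(c("a", "b"), c("b", "a"))), c("A", "B"))
  expect_equal(intersectLists(list(c("A", "B", "C"), c("B", "C", "D"),
                                   c("C", "E"), c("C", "B"))), "C")
  expect_setequal(
    intersectLists(list(c("A", "B"), c("B", "C"), c("C", "D")),
                   mode = "threshold", m = 2), c("B", "C"))
  expect_true("FYN" %in% intersectLists(list("A", "A"), anchorGene = "Fyn"))
  expect_error(intersectLists(list("A")), "2 lists")

  # four lists of module + 10% noise: strict core keeps the module, drops noise
  set.seed(33)
  pool <- sprintf("G%04d", 1:2000)
  module <- pool[1:50]
  rec <- noise <- numeric(20)
  for (sd in 1:20) {
    set.seed(700 + sd)
    lists <- lapply(1:4, function(i) c(module, sample(pool[-(1:50)], 200)))
    core <- intersectLists(lists)
    rec[sd] <- mean(toupper(module) %in% core)
    noise[sd] <- (length(core) - sum(toupper(module) %in% core)) / length(core)
  }
  expect_gte(mean(rec), 0.6)
  expect_lte(mean(noise), 0.01)
})

test_that("network construction collapses probesets and deduplicates edges", {
  strains <- sprintf("s%d", 1:10)
  v <- rnorm(10)
  # two perfectly correlated genes: one edge with r = 1
  ex <- rbind(p1 = v, p2 = v)
  colnames(ex) <- strains
  nw <- buildNetwork(c("ga", "gb"), makePanel(ex, genes = c("ga", "gb")))
  expect_equal(nrow(networkEdges(nw)), 1)
  expect_equal(networkEdges(nw)$r, 1)

  # a gene with 2 probesets both correlated to its partner: one edge survives
  ex2 <- rbind(p1 = v + rnorm(10, sd = 0.01), p2 = v + rnorm(10, sd = 0.01),
               p3 = v + rnorm(10, sd = 0.01))
  colnames(ex2) <- strains
  nw2 <- buildNetwork(c("ga", "gb"), makePanel(ex2, genes = c("ga", "ga", "gb")))
  ed <- networkEdges(nw2)
  expect_equal(nrow(ed), 1)          # duplicate edges removed, no self-loops
  expect_setequal(c(ed$geneA, ed$geneB), c("GA", "GB"))

  # isolated core genes stay as nodes; unmapped ones flagged annotation-only
  set.seed(34)
  ex3 <- rbind(p1 = rnorm(10), p2 = rnorm(10))
  colnames(ex3) <- strains
  expect_message(
    nw3 <- buildNetwork(c("ga", "gb", "gz"), makePanel(ex3, genes = c("ga", "gb"))),
    "annotation-only")
  nd <- networkNodes(nw3)
  expect_setequal(nd$gene, c("GA", "GB", "GZ"))
  expect_false(nd$inPanel[nd$gene == "GZ"])
})

test_that("a planted module yields a dense strong-edge network", {
  dens <- medR <- numeric(20)
  for (sd in 1:20) {
    sim <- simulateRIPanel(nStrains = 30, nProbesets = 300, moduleSize = 50,
                           seed = 800 + sd)
    nw <- buildNetwork(moduleGenes(sim$truth), sim$panel)
    ed <- networkEdges(nw)
    nPairs <- choose(length(moduleGenes(sim$truth)), 2)
    dens[sd] <- nrow(ed) / nPairs
    medR[sd] <- median(abs(ed$r))
  }
  expect_gte(mean(dens), 0.5)        # far above the alpha = 0.01 null rate
  expect_gte(mean(medR), 0.5)
})

test_that("networks are invariant to probeset order and value-identical duplicates", {
  set.seed(35)
  strains <- sprintf("s%d", 1:12)
  ex <- matrix(rnorm(8 * 12), 8, 12,
               dimnames = list(sprintf("p%d", 1:8), strains))
  genes <- sprintf("g%d", 1:8)
  nw1 <- buildNetwork(genes, makePanel(ex, genes), alpha = 0.3)
  perm <- sample(8)
  nw2 <- buildNetwork(genes, makePanel(ex[perm, ], genes[perm]), alpha = 0.3)
  key <- function(nw) {
    ed <- networkEdges(nw)
    ed[order(ed$geneA, ed$geneB), c("geneA", "geneB", "r", "p")]
  }
  expect_equal(key(nw1), key(nw2), ignore_attr = TRUE)

  # a duplicate probeset with identical values changes nothing
  exDup <- rbind(ex, p1b = ex["p1", ])
  nw3 <- buildNetwork(genes, makePanel(exDup, c(genes, "g1")), alpha = 0.3)
  expect_equal(key(nw1), key(nw3), ignore_attr = TRUE)
})

test_that("under the global null the edge rate matches alpha", {
  rates <- numeric(10)
  for (sd in 1:10) {
    set.seed(900 + sd)
    ex <- matrix(rnorm(60 * 30), 60, 30,
                 dimnames = list(sprintf("p%d", 1:60), sprintf("s%d", 1:30)))
    genes <- sprintf("g%d", 1:60)
    nw <- buildNetwork(genes, makePanel(ex, genes), alpha = 0.01)
    rates[sd] <- nrow(networkEdges(nw)) / choose(60, 2)
  }
  expect_lt(abs(mean(rates) - 0.01), 0.005)
})
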
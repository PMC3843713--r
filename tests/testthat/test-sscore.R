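test_that("pairwise S-score follows the stated formula", {
  # identical arrays score exactly zero
  a <- setNames(runif(50, 6, 12), sprintf("PS%02d", 1:50))
  expect_equal(unname(pairwiseSScore(a, a)), rep(0, 50))
  # hand evaluation: a=10, b=6, alpha=0, beta^2=2, gamma=1 -> (10-6)/sqrt(4) = 2
  s <- pairwiseSScore(c(g = 10), c(g = 6), errorModel(alpha = 0, beta = sqrt(2)))
  expect_equal(unname(s), 2)
  # antisymmetry for arbitrary arrays and models
  set.seed(1)
  b <- setNames(runif(50, 6, 12), names(a))
  m <- errorModel(alpha = 0.05, beta = 0.4, gamma = 1.3)
  expect_equal(pairwiseSScore(a, b, m), -pairwiseSScore(b, a, m))
  # misaligned universes are rejected
  expect_error(pairwiseSScore(c(x = 1), c(y = 1)), "universes")
})

test_that("error-model calibration recovers the same/same scale", {
  # generative model: Var(a - b | mu) = 2 * (alpha * mu + beta^2), which the
  # fitted model expresses as alpha * (a + b) + 2 * beta^2, so true gamma = 1
  simPairs <- function(alpha, beta, m, nPairs, seed) {
    set.seed(seed)
    mu <- runif(m, 6, 12)
    sdv <- sqrt(alpha * mu + beta^2)
    lapply(seq_len(nPairs), function(i)
      list(a = setNames(mu + rnorm(m, sd = sdv), sprintf("p%d", 1:m)),
           b = setNames(mu + rnorm(m, sd = sdv), sprintf("p%d", 1:m))))
  }
  gammas <- vapply(1:20, function(sd) {
    calibrateErrorModel(simPairs(0.05, 0.5, 2000, 3, sd))@gamma
  }, numeric(1))
  expect_true(all(abs(gammas - 1) < 0.1))

  # identical arrays cannot calibrate anything
  a <- setNames(runif(100, 6, 12), sprintf("p%d", 1:100))
  expect_error(calibrateErrorModel(list(list(a = a, b = a))), "degenerate")
})

test_that("calibrated scores are scale-equivariant and unit-normal under the null", {
  set.seed(42)
  m <- 10000
  mu <- runif(m, 6, 12)
  mkPair <- function() list(a = setNames(mu + rnorm(m, sd = 0.3), sprintf("p%d", 1:m)),
                            b = setNames(mu + rnorm(m, sd = 0.3), sprintf("p%d", 1:m)))
  pairs <- list(mkPair(), mkPair(), mkPair())
  em <- calibrateErrorModel(pairs)
  sc <- pairwiseSScore(pairs[[1]]$a, pairs[[1]]$b, em)
  # empirical two-sided tail at |S| = 2 within binomial 99% CI of 0.0455
  phat <- mean(abs(sc) >= 2)
  half <- 2.576 * sqrt(0.0455 * (1 - 0.0455) / m)
  expect_lt(abs(phat - 0.0455), half)

  # doubling every intensity leaves calibrated scores unchanged
  pairs2 <- lapply(pairs, function(p) list(a = 2 * p$a, b = 2 * p$b))
  em2 <- calibrateErrorModel(pairs2)
  sc2 <- pairwiseSScore(pairs2[[1]]$a, pairs2[[1]]$b, em2)
  expect_equal(unname(sc2), unname(sc), tolerance = 1e-6)
})

test_that("replicate averaging groups pairwise comparisons by treated array", {
  # single comparison: replicate equals the pairwise score
  m1 <- matrix(c(1, -2), 2, 1, dimnames = list(c("a", "b"), NULL))
  tb <- replicateAverage(m1, treated = "t1")
  expect_equal(unname(scoreMatrix(tb)[, 1]), c(1, -2))

  # 3x3 all equal to c: three replicates all equal c
  mC <- matrix(0.7, 2, 9, dimnames = list(c("a", "b"), NULL))
  treated <- rep(c("t1", "t2", "t3"), each = 3)
  tbC <- replicateAverage(mC, treated)
  expect_equal(dim(scoreMatrix(tbC)), c(2L, 3L))
  expect_true(all(scoreMatrix(tbC) == 0.7))

  # treated array 1 comparisons (1, 2, 3) average to 2
  mX <- matrix(0, 1, 9, dimnames = list("a", NULL))
  mX[1, treated == "t1"] <- c(1, 2, 3)
  tbX <- replicateAverage(mX, treated)
  expect_equal(unname(scoreMatrix(tbX)[1, "t1"]), 2)

  # pooled alternative collapses to one column
  expect_equal(ncol(scoreMatrix(replicateAverage(mX, treated, groupBy = "none"))), 1)
  expect_error(replicateAverage(mX[, 0, drop = FALSE], character()), "empty")
})

test_that("same/same normalization divides by max(1, SD) and never inflates", {
  tb <- makeScoreTable(matrix(c(3, 3, 3, 3), 2, 2,
                              dimnames = list(c("a", "b"), NULL)))
  # probeset a: same/same SD 0.5 -> divisor 1; probeset b: SD 2 -> 3 becomes 1.5
  ss <- rbind(a = c(-0.5, 0, 0.5),   # SD exactly 0.5
              b = c(-2, 0, 2))       # SD exactly 2

  norm <- sameSameNormalize(tb, ss)
  expect_equal(unname(scoreMatrix(norm)["a", ]), c(3, 3))
  expect_equal(unname(scoreMatrix(norm)["b", ]), c(1.5, 1.5))

  # all SDs <= 1: output identical to input
  ssSmall <- matrix(rnorm(2 * 10, sd = 0.2), 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(scoreMatrix(sameSameNormalize(tb, ssSmall)), scoreMatrix(tb))

  # contraction property on random inputs
  set.seed(2)
  tbR <- makeScoreTable(matrix(rnorm(300), 100, 3))
  ssR <- matrix(rnorm(100 * 6, sd = 1.5), 100,
                dimnames = list(rownames(scoreMatrix(tbR)), NULL))
  normR <- sameSameNormalize(tbR, ssR)
  expect_true(all(abs(scoreMatrix(normR)) <= abs(scoreMatrix(tbR)) + 1e-12))

  # fewer than 2 same/same columns: divisor defaults to 1
  one <- matrix(5, 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(scoreMatrix(sameSameNormalize(tb, one)), scoreMatrix(tb))
})
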
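# Fixtures are built in code; nothing is read from disk except round-trip
# temporaries written by the tests themselves.

makeScoreTable <- function(mat, contrast = "basal", region = "PFC") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("PS%04d", seq_len(nrow(mat)))
  new("SScoreTable", scores = mat, contrast = contrast, region = region)
}

makePanel <- function(exprs, genes = rownames(exprs), pheno = numeric(),
                      label = "test") {
  new("RIPanel", exprs = exprs,
      map = data.frame(probeset = rownames(exprs), gene = genes,
                       stringsAsFactors = FALSE),
      phenotype = pheno, label = label)
}

# Independent hypergeometric oracle: enumerate all C(N, n) query draws from a
# background whose first K elements form the set, and count draws with
# overlap >= k.
enumHyperP <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Independent Pearson p oracle: permutation null of the correlation.
permPearsonP <- function(x, y, B = 10000, seed = 1) {
  set.seed(seed)
  r0 <- abs(cor(x, y))
  hits <- 0L
  for (b in seq_len(B)) if (abs(cor(x, sample(y))) >= r0 - 1e-12) hits <- hits + 1L
  hits / B
}

# Adjusted Rand index between two partitions.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nc2 <- choose(sum(tab), 2)
  expected <- ai * bj / nc2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# Null S-score table: m probesets x n replicates of N(0, 1) scores.
nullScoreTable <- function(m, n = 3, seed = 1, ...) {
  set.seed(seed)
  makeScoreTable(matrix(rnorm(m * n), m, n), ...)
}
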
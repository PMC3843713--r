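## Shared internal helpers.

## Uppercase symbol normalization, applied wherever gene symbols from
## different sources are compared.
.normSym <- function(x) toupper(trimws(x))

## Two-sided p-value for a Pearson correlation via the t transform,
## vectorized over r (n may be scalar or vector).  |r| = 1 maps to p = 0.
.corP <- function(r, n) {
  p <- rep(NA_real_, length(r))
  df <- n - 2
  ok <- is.finite(r) & df > 0
  exact1 <- ok & abs(r) >= 1 - 1e-12
  p[exact1] <- 0
  mid <- ok & !exact1
  if (any(mid)) {
    tt <- abs(r[mid]) * sqrt(df[if (length(df) > 1) mid else 1] / (1 - r[mid]^2))
    p[mid] <- 2 * pt(-tt, df = if (length(df) > 1) df[mid] else df)
  }
  p
}

## Correlation of each row of `mat` (probesets x strains) against vector `y`
## (named by strain), pairwise-complete.  Returns data.frame(r, n, p).
.corScreen <- function(mat, y) {
  common <- intersect(colnames(mat), names(y))
  mat <- mat[, common, drop = FALSE]
  y <- y[common]
  keep <- is.finite(y)
  mat <- mat[, keep, drop = FALSE]
  y <- y[keep]
  finiteM <- is.finite(mat)
  n <- as.integer(rowSums(finiteM))
  if (all(finiteM)) {
    r <- as.vector(cor(t(mat), y))
  } else {
    r <- as.vector(cor(t(mat), y, use = "pairwise.complete.obs"))
  }
  data.frame(r = r, n = n, p = .corP(r, n), row.names = rownames(mat))
}

#' Smallest correlation magnitude significant at a given level
#'
#' Inverts the two-sided t test of a Pearson correlation: the smallest `|r|`
#' with `p <= alpha` at sample size `n`.  Useful for reporting the effective
#' effect-size floor of a p-value screen (e.g. `|r| ~ 0.47` for `alpha = 0.01`
#' at `n = 29` strains).
#'
#' @param n number of paired observations (`>= 3`).
#' @param alpha two-sided significance level.
#' @return the critical `|r|`.
#' @export
#' @examples
#' criticalR(29, 0.01)
criticalR <- function(n, alpha = 0.01) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

## Derive a per-stage substream seed from a master seed, kept within the
## 32-bit integer range R requires.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347) %% 2147483647)
}

## Message to stderr with a stage prefix; quiet-able.
.logMsg <- function(..., quiet = FALSE) {
  if (!quiet) message(sprintf(...))
}
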
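## SAM-style permutation tests on S-score tables.  The statistic is the
## moderated d = effect / (se + s0); the null is built by sign flips
## (one-class) or class-label permutations (two-class), enumerated completely
## when the atom count is small and sampled otherwise.  The FDR at a cut c is
## the median over permutations of the count of |d*| >= c, divided by the
## observed count of |d| >= c (pi0 fixed at 1 — conservative), capped at 1
## and monotonized across cuts in the Benjamini-Hochberg manner.  The
## composite filter requires both |mean| >= scoreFloor and FDR <= fdrCap.

## Vectorized per-row mean and SD (avoids apply() over large score tables).
.rowStats <- function(X) {
  n <- ncol(X)
  m <- rowMeans(X)
  v <- (rowSums(X^2) - n * m^2) / (n - 1)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

## d = eff / (den + s0) with a safe zero-denominator convention:
## a zero effect with zero spread is "no evidence", not NaN.
.modT <- function(eff, den, s0) {
  d <- eff / (den + s0)
  zero <- den + s0 == 0
  d[zero] <- sign(eff[zero]) * Inf
  d[zero & eff == 0] <- 0
  d
}

#' Default SAM fudge factor
#'
#' The 5th percentile (linear interpolation) of the per-probeset standard
#' errors; an explicit override (including 0) is honored verbatim wherever
#' `s0` is a parameter.
#'
#' @param se numeric vector of per-probeset standard errors.
#' @return the fudge factor.
#' @export
#' @examples
#' chooseS0(1:100)  # 5.95
chooseS0 <- function(se) {
  if (!length(se)) stop("empty score table")
  unname(quantile(se, 0.05, type = 7))
}

## Median-FDR machinery shared by the one- and two-class tests.
## d: observed statistics; dPerm: matrix probesets x permutations.
.samFDR <- function(d, dPerm) {
  ad <- abs(d)
  m <- length(ad)
  ord <- order(ad, decreasing = TRUE)
  cuts <- ad[ord]
  ## observed counts #{|d| >= cuts[i]}; at a tied cut every tied value counts
  sad <- sort(ad)
  R <- m - findInterval(cuts - 1e-12, sad)
  Vp <- apply(abs(dPerm), 2, function(x) {
    ## counts of |d*| >= each cut, via one sort per permutation
    sx <- sort(x)
    length(sx) - findInterval(cuts - 1e-12, sx)
  })
  if (is.null(dim(Vp))) Vp <- matrix(Vp, nrow = length(cuts))
  V <- apply(Vp, 1, median)
  fdr <- pmin(1, V / pmax(R, 1L))
  ## BH-style monotonization: the FDR assigned at a stricter cut is never
  ## larger than at any weaker cut
  fdr <- rev(cummin(rev(fdr)))
  out <- numeric(m)
  out[ord] <- fdr
  out
}

.samResult <- function(probesets, means, ses, d, fdr, scoreFloor, fdrCap,
                       s0, nPerm, complete, contrast, region) {
  pass <- abs(means) >= scoreFloor & fdr <= fdrCap
  if (nPerm < 50)
    warning(sprintf(
      "permutation null has only %d atoms; FDR granularity is coarse", nPerm))
  new("SamResult",
      table = data.frame(probeset = probesets, mean = means, se = ses,
                         d = d, fdr = fdr, pass = pass,
                         stringsAsFactors = FALSE, row.names = NULL),
      contrast = contrast, region = region, s0 = s0,
      nPerm = as.integer(nPerm), complete = complete,
      scoreFloor = scoreFloor, fdrCap = fdrCap)
}

#' One-class SAM on an S-score table
#'
#' Tests whether each probeset's replicate S-scores differ from 0 using
#' `d = mean / (se + s0)` with a sign-flip permutation null: all `2^n` sign
#' assignments are enumerated when `n <= 12` replicates, otherwise `nPerm`
#' random assignments are sampled.
#'
#' @param table an [SScoreTable-class] with at least 2 replicate columns.
#' @param s0 fudge factor; defaults to [chooseS0()] of the standard errors.
#' @param nPerm permutations to sample when enumeration is infeasible.
#' @param scoreFloor composite filter floor on `|mean|`.
#' @param fdrCap composite filter cap on the median FDR.
#' @param seed seed used only when permutations are sampled.
#' @return a [SamResult-class].
#' @export
oneClassSAM <- function(table, s0 = NULL, nPerm = 1000, scoreFloor = 1.5,
                        fdrCap = 0.05, seed = 1) {
  X <- scoreMatrix(table)
  n <- ncol(X)
  if (n < 2) stop("one-class SAM needs at least 2 replicate columns")
  st <- .rowStats(X)
  means <- st$mean
  ses <- st$sd / sqrt(n)
  if (is.null(s0)) s0 <- chooseS0(ses)
  d <- .modT(means, ses, s0)

  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    complete <- TRUE
  } else {
    set.seed(as.integer(seed))
    signs <- matrix(sample(c(1, -1), nPerm * n, replace = TRUE),
                    nrow = nPerm, ncol = n)
    complete <- FALSE
  }
  dPerm <- apply(signs, 1, function(sg) {
    Xp <- sweep(X, 2, sg, "*")
    sp <- .rowStats(Xp)
    .modT(sp$mean, sp$sd / sqrt(n), s0)
  })
  fdr <- .samFDR(d, dPerm)
  .samResult(rownames(X), means, ses, d, fdr, scoreFloor, fdrCap, s0,
             nrow(signs), complete, table@contrast, table@region)
}

#' Two-class SAM between two S-score tables
#'
#' Tests for a difference in mean S-score between two conditions (e.g.
#' knockout vs control ethanol responses) using
#' `d = (meanA - meanB) / (sePooled + s0)` with a class-label permutation
#' null: all distinct relabelings are enumerated when there are at most 500,
#' otherwise `nPerm` are sampled.  The composite floor applies to
#' `|meanA - meanB|`.
#'
#' @param tableA,tableB [SScoreTable-class] objects sharing a probeset
#'   universe, each with at least 2 replicate columns.
#' @inheritParams oneClassSAM
#' @return a [SamResult-class] (contrast label `"A.vs.B"` built from the two
#'   input contrasts).
#' @export
twoClassSAM <- function(tableA, tableB, s0 = NULL, nPerm = 1000,
                        scoreFloor = 1.5, fdrCap = 0.05, seed = 1) {
  XA <- scoreMatrix(tableA); XB <- scoreMatrix(tableB)
  if (!identical(rownames(XA), rownames(XB))) {
    if (!setequal(rownames(XA), rownames(XB)))
      stop("probeset universes of the two tables differ")
    XB <- XB[rownames(XA), , drop = FALSE]
  }
  nA <- ncol(XA); nB <- ncol(XB)
  if (nA < 2 || nB < 2) stop("two-class SAM needs >= 2 replicates per class")
  X <- cbind(XA, XB)
  n <- nA + nB

  stat <- function(idxA) {
    stA <- .rowStats(X[, idxA, drop = FALSE])
    stB <- .rowStats(X[, setdiff(seq_len(n), idxA), drop = FALSE])
    sp <- sqrt(((nA - 1) * stA$sd^2 + (nB - 1) * stB$sd^2) / (n - 2) *
                 (1 / nA + 1 / nB))
    list(diff = stA$mean - stB$mean, se = sp)
  }

  obs <- stat(seq_len(nA))
  if (is.null(s0)) s0 <- chooseS0(obs$se)
  d <- .modT(obs$diff, obs$se, s0)

  total <- choose(n, nA)
  if (total <= 500) {
    assigns <- combn(n, nA, simplify = FALSE)
    complete <- TRUE
  } else {
    set.seed(as.integer(seed))
    assigns <- lapply(seq_len(nPerm), function(i) sample.int(n, nA))
    complete <- FALSE
  }
  dPerm <- vapply(assigns, function(idxA) {
    st <- stat(idxA)
    .modT(st$diff, st$se, s0)
  }, numeric(nrow(X)))
  fdr <- .samFDR(d, dPerm)
  .samResult(rownames(X), obs$diff, obs$se, d, fdr, scoreFloor, fdrCap, s0,
             length(assigns), complete,
             paste0(tableA@contrast, ".vs.", tableB@contrast),
             tableA@region)
}
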
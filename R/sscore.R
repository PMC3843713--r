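## S-score stage: standardized pairwise difference scores between two arrays,
## calibrated on same-condition ("same/same") comparisons so that the null
## score distribution is approximately standard normal — |S| = 2 then
## corresponds to a two-sided p of 0.0455.  The scoring function works on
## probeset-level summaries under an additive-multiplicative error model; it
## is deliberately a small pluggable surface so a probe-level scorer could be
## swapped in.

#' Construct an array error model
#'
#' @param alpha multiplicative variance coefficient (`>= 0`).
#' @param beta additive noise floor, SD units (`> 0`).
#' @param gamma calibration scale (`> 0`); [calibrateErrorModel()] sets it so
#'   the pooled same/same score SD is 1.
#' @return an [ErrorModel-class] object.
#' @export
#' @examples
#' errorModel(alpha = 0, beta = sqrt(2))
errorModel <- function(alpha = 0, beta = 1, gamma = 1) {
  new("ErrorModel", alpha = alpha, beta = beta, gamma = gamma)
}

#' Pairwise S-score between two arrays
#'
#' For each probeset `g`,
#' `S_g = (a_g - b_g) / (gamma * sqrt(alpha * (a_g + b_g) + 2 * beta^2))`.
#' Under same-condition inputs and a calibrated model the scores have mean
#' ~0 and SD ~1.  Scores are antisymmetric in the two arrays.
#'
#' @param a,b named numeric vectors (same probeset universe) of probeset
#'   intensities for the two arrays.
#' @param model an [ErrorModel-class].
#' @return named numeric vector of scores.
#' @export
#' @examples
#' pairwiseSScore(c(g1 = 10), c(g1 = 6), errorModel(alpha = 0, beta = sqrt(2)))
pairwiseSScore <- function(a, b, model = errorModel()) {
  validObject(model)
  if (is.null(names(a)) || is.null(names(b)))
    stop("arrays must be named by probeset")
  if (length(a) != length(b) || !all(names(a) == names(b))) {
    if (!setequal(names(a), names(b)))
      stop("probeset universes of the two arrays differ")
    b <- b[names(a)]
  }
  v <- model@alpha * (a + b) + 2 * model@beta^2
  if (any(v <= 0)) stop("error model yields nonpositive variance")
  (a - b) / (model@gamma * sqrt(v))
}

#' Calibrate the error model from same-condition array pairs
#'
#' Fits `alpha` and `beta` by the method of moments — regressing squared
#' differences on intensity sums across all probesets of all same/same pairs
#' (slope -> `alpha`, intercept -> `2 * beta^2`) — and then sets `gamma` so
#' that the pooled SD of the resulting same/same scores is exactly 1.
#'
#' @param pairs list of same-condition pairs, each a `list(a = , b = )` of
#'   named intensity vectors.
#' @return a calibrated [ErrorModel-class].
#' @export
calibrateErrorModel <- function(pairs) {
  if (length(pairs) < 1) stop("need at least one same-condition pair")
  s <- unlist(lapply(pairs, function(p) p$a + p$b), use.names = FALSE)
  d2 <- unlist(lapply(pairs, function(p) (p$a - p$b)^2), use.names = FALSE)
  if (all(d2 == 0))
    stop("degenerate same/same pairs: arrays are identical, no spread to calibrate")
  fit <- coef(lm(d2 ~ s))
  alpha <- max(0, unname(fit[2]))
  beta2 <- unname(fit[1]) / 2
  if (!is.finite(beta2) || beta2 <= 0) {
    ## fall back to a pure additive model when the intercept collapses
    alpha <- 0
    beta2 <- mean(d2) / 2
  }
  m0 <- new("ErrorModel", alpha = alpha, beta = sqrt(beta2), gamma = 1)
  pooled <- unlist(lapply(pairs, function(p) pairwiseSScore(p$a, p$b, m0)),
                   use.names = FALSE)
  gamma <- sd(pooled)
  if (!is.finite(gamma) || gamma <= 0)
    stop("calibration failed: same/same scores have no spread")
  new("ErrorModel", alpha = alpha, beta = sqrt(beta2), gamma = gamma)
}

#' Average pairwise S-scores into biological-replicate scores
#'
#' All `nA x nB` pairwise comparisons between treated and control arrays are
#' grouped by treated array: replicate `j`'s score is the mean of the `nB`
#' comparisons sharing treated array `j`, yielding one column per treated
#' biological replicate.  The alternative reading — averaging all comparisons
#' into a single value — is available via `groupBy = "none"`, which returns a
#' single column (exposed for completeness, not endorsed).
#'
#' @param scores numeric matrix of pairwise score vectors, probesets x
#'   comparisons.
#' @param treated character vector (length `ncol(scores)`) naming the treated
#'   array of each comparison.
#' @param contrast,region labels for the resulting table.
#' @param groupBy `"treated"` (default) or `"none"`.
#' @return an [SScoreTable-class] with one column per treated array.
#' @export
replicateAverage <- function(scores, treated, contrast = "contrast",
                             region = "region",
                             groupBy = c("treated", "none")) {
  groupBy <- match.arg(groupBy)
  if (is.null(dim(scores)) || ncol(scores) < 1)
    stop("empty comparison set")
  if (length(treated) != ncol(scores))
    stop("'treated' must name the treated array of each comparison column")
  if (groupBy == "none") {
    out <- matrix(rowMeans(scores), ncol = 1,
                  dimnames = list(rownames(scores), "pooled"))
  } else {
    ids <- unique(treated)
    out <- vapply(ids, function(id) {
      rowMeans(scores[, treated == id, drop = FALSE])
    }, numeric(nrow(scores)))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(scores))
    dimnames(out) <- list(rownames(scores), ids)
  }
  new("SScoreTable", scores = out, contrast = contrast, region = region)
}

#' Normalize replicate S-scores by same/same variability
#'
#' Each probeset's replicate scores are divided by the greater of 1 and the
#' standard deviation of that probeset's same/same scores, damping probesets
#' whose technical noise exceeds the calibrated unit scale while never
#' inflating scores.  Probesets with fewer than 2 same/same comparisons get
#' divisor 1.
#'
#' @param table an [SScoreTable-class].
#' @param sameSameScores numeric matrix of same/same pairwise score vectors
#'   (probesets x comparisons), rows aligned with `table`.
#' @return the normalized [SScoreTable-class].
#' @export
sameSameNormalize <- function(table, sameSameScores) {
  sc <- scoreMatrix(table)
  if (is.null(dim(sameSameScores)) || ncol(sameSameScores) < 2) {
    divisor <- rep(1, nrow(sc))
  } else {
    ss <- sameSameScores[rownames(sc), , drop = FALSE]
    divisor <- pmax(1, apply(ss, 1, sd))
  }
  new("SScoreTable", scores = sc / divisor,
      contrast = table@contrast, region = table@region)
}

#' Replicate-averaged, normalized S-score table for one contrast
#'
#' Convenience wrapper running the full S-score stage for one contrast within
#' one region of a simulated (or imported) knockout experiment: calibrates
#' the error model on all within-group pairs of the two groups involved,
#' scores every treated-vs-control array pair, averages by treated array, and
#' normalizes by the per-probeset same/same SD.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] as produced by
#'   [simulateKOExperiment()] (assay `exprs`; colData `region`, `group`).
#' @param region region label to work in.
#' @param treatedGroup,controlGroup group labels of the contrast (treated
#'   minus control).
#' @param contrast label for the output table (defaults to
#'   `"treated.vs.control"`).
#' @param model optional pre-calibrated [ErrorModel-class]; calibrated from
#'   the same/same pairs when `NULL`.
#' @return an [SScoreTable-class].
#' @export
sscoreContrast <- function(se, region, treatedGroup, controlGroup,
                           contrast = paste0(treatedGroup, ".vs.", controlGroup),
                           model = NULL) {
  cd <- SummarizedExperiment::colData(se)
  ex <- SummarizedExperiment::assay(se, "exprs")
  trCols <- rownames(cd)[cd$region == region & cd$group == treatedGroup]
  ctCols <- rownames(cd)[cd$region == region & cd$group == controlGroup]
  if (!length(trCols) || !length(ctCols))
    stop("no arrays found for the requested region/groups")

  withinPairs <- function(cols) {
    if (length(cols) < 2) return(list())
    cmb <- combn(cols, 2, simplify = FALSE)
    lapply(cmb, function(p) list(a = ex[, p[1]], b = ex[, p[2]]))
  }
  ssPairs <- c(withinPairs(trCols), withinPairs(ctCols))
  if (is.null(model)) model <- calibrateErrorModel(ssPairs)

  pair <- expand.grid(treated = trCols, control = ctCols,
                      stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(pair)), function(i) {
    pairwiseSScore(ex[, pair$treated[i]], ex[, pair$control[i]], model)
  }, numeric(nrow(ex)))
  rownames(scores) <- rownames(ex)

  tab <- replicateAverage(scores, pair$treated, contrast = contrast,
                          region = region)
  ssScores <- vapply(ssPairs, function(p) pairwiseSScore(p$a, p$b, model),
                     numeric(nrow(ex)))
  rownames(ssScores) <- rownames(ex)
  sameSameNormalize(tab, ssScores)
}
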
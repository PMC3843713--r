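## Pattern assembly and k-means clustering: probesets significant anywhere
## are clustered on their mean normalized S-scores across every
## (region, contrast) column, so coordinately-regulated groups emerge across
## brain regions and treatments.  Rows are deliberately not re-standardized:
## S-scores already share a scale, and magnitude separates "no change" from
## regulated patterns.

#' Assemble per-probeset pattern vectors across regions and contrasts
#'
#' Rows are the union of the SAM pass sets; each column holds one table's
#' replicate-mean score, so a probeset significant in only one region still
#' carries its (non-significant) scores everywhere else.
#'
#' @param samResults list of [SamResult-class] objects (defines the union of
#'   pass sets).
#' @param tables list of [SScoreTable-class] objects sharing a probeset
#'   universe, one column each in the output.
#' @return a [PatternMatrix-class].
#' @export
assemblePatterns <- function(samResults, tables) {
  pass <- unique(unlist(lapply(samResults, passSet)))
  if (!length(pass)) stop("union of SAM pass sets is empty")
  cols <- vapply(tables, function(tb) {
    rowMeans(scoreMatrix(tb))[pass]
  }, numeric(length(pass)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = length(pass))
  region <- vapply(tables, regionLabel, character(1))
  contrast <- vapply(tables, contrastLabel, character(1))
  dimnames(cols) <- list(pass, paste(region, contrast, sep = ":"))
  new("PatternMatrix", values = cols, region = unname(region),
      contrast = unname(contrast))
}

#' k-means clustering of expression patterns
#'
#' Euclidean k-means on the pattern matrix, best of `nInit` restarts by
#' within-cluster sum of squares; clusters are relabeled `1..k` in
#' decreasing size so labels are stable across runs with the same seed.
#'
#' @param pattern a [PatternMatrix-class].
#' @param k number of clusters (`<=` number of rows).
#' @param nInit random restarts.
#' @param maxIter maximum Lloyd iterations.
#' @param seed integer seed (results are deterministic given it).
#' @return list with `cluster` (named integer vector), `sizes`, `wcss`
#'   (total within-cluster sum of squares), and `centers` (k x columns,
#'   rows ordered by the relabeled cluster ids).
#' @export
clusterPatterns <- function(pattern, k = 12, nInit = 50, maxIter = 500,
                            seed = 1) {
  X <- patternValues(pattern)
  if (k > nrow(X)) stop("k exceeds the number of probesets")
  set.seed(as.integer(seed))
  if (k == nrow(X)) {
    ## every probeset its own cluster; stats::kmeans requires k < n
    cl <- setNames(seq_len(nrow(X)), rownames(X))
    return(list(cluster = cl, sizes = rep(1L, k), wcss = 0, centers = X))
  }
  km <- kmeans(X, centers = k, nstart = nInit, iter.max = maxIter)
  sizes <- tabulate(km$cluster, nbins = k)
  relab <- order(sizes, decreasing = TRUE)      # old label in new order
  newOf <- integer(k); newOf[relab] <- seq_len(k)
  cl <- setNames(newOf[km$cluster], rownames(X))
  list(cluster = cl,
       sizes = sizes[relab],
       wcss = km$tot.withinss,
       centers = km$centers[relab, , drop = FALSE])
}
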
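## Anchor-gene and phenotype correlation screens across RI panels, multi-list
## intersection, and correlation-network assembly with probeset-to-gene
## collapsing.  Screens use raw Pearson p <= alpha with no multiplicity
## correction (the screen-wide expected false-positive count is recorded on
## the result so the cost is visible); gene collapsing is union-of-evidence:
## any significant probeset qualifies the gene.

#' Pearson correlation with exact t-based p-value
#'
#' Product-moment correlation over the complete pairs of `x` and `y`, with
#' the two-sided p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom; a correlation of exactly +/-1 yields `p = 0`.
#'
#' @param x,y numeric vectors (aligned by names when both are named,
#'   otherwise by position).
#' @return named vector `c(r = , n = , p = )`.
#' @export
#' @examples
#' pearsonWithP(1:4, c(2, 1, 4, 3))
pearsonWithP <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input")
  r <- cor(x, y)
  c(r = r, n = n, p = .corP(r, n))
}

.screen <- function(mat, target, map, alpha, exclude = character()) {
  keep <- setdiff(rownames(mat), exclude)
  res <- .corScreen(mat[keep, , drop = FALSE], target)
  hit <- which(res$p <= alpha)
  data.frame(probeset = keep[hit],
             gene = map$gene[match(keep[hit], map$probeset)],
             r = res$r[hit], n = res$n[hit], p = res$p[hit],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Anchor-gene correlation screen across an RI panel
#'
#' Correlates every probeset against each probeset of the anchor gene; a
#' probeset is retained when any pairing reaches `p <= alpha`, keeping the
#' smallest-p pairing.  The anchor's own probesets are excluded.
#'
#' @param panel an [RIPanel-class].
#' @param anchorGene anchor gene symbol (must map to >= 1 probeset).
#' @param alpha p-value cutoff of the screen.
#' @return a [CorrelationScreen-class].
#' @export
anchorScreen <- function(panel, anchorGene, alpha = 0.01) {
  map <- probeGeneMap(panel)
  ex <- panelExprs(panel)
  anchorPs <- map$probeset[.normSym(map$gene) == .normSym(anchorGene)]
  anchorPs <- intersect(anchorPs, rownames(ex))
  if (!length(anchorPs))
    stop("anchor gene '", anchorGene, "' has no probeset in the panel")
  recs <- NULL
  for (ap in anchorPs) {
    target <- setNames(ex[ap, ], colnames(ex))
    r1 <- .screen(ex, target, map, alpha, exclude = anchorPs)
    if (nrow(r1)) {
      r1$anchorProbeset <- ap
      recs <- rbind(recs, r1)
    }
  }
  if (is.null(recs)) {
    recs <- data.frame(probeset = character(), gene = character(),
                       r = numeric(), n = integer(), p = numeric(),
                       anchorProbeset = character(), stringsAsFactors = FALSE)
  } else {
    recs <- recs[order(recs$probeset, recs$p), , drop = FALSE]
    recs <- recs[!duplicated(recs$probeset), , drop = FALSE]
    recs <- recs[order(recs$p), , drop = FALSE]
    rownames(recs) <- NULL
  }
  new("CorrelationScreen", records = recs, type = "anchor",
      anchor = anchorGene, alpha = alpha,
      nTested = as.integer(nrow(ex) - length(anchorPs)))
}

#' Phenotype correlation screen across an RI panel
#'
#' As [anchorScreen()], but every probeset is correlated against the panel's
#' per-strain phenotype vector.
#'
#' @inheritParams anchorScreen
#' @return a [CorrelationScreen-class].
#' @export
phenotypeScreen <- function(panel, alpha = 0.01) {
  ph <- phenotype(panel)
  if (!length(ph)) stop("panel has no phenotype attached")
  recs <- .screen(panelExprs(panel), ph, probeGeneMap(panel), alpha)
  recs <- recs[order(recs$p), , drop = FALSE]
  rownames(recs) <- NULL
  new("CorrelationScreen", records = recs, type = "phenotype",
      anchor = NA_character_, alpha = alpha,
      nTested = as.integer(nrow(panelExprs(panel))))
}

#' Intersect gene lists into a core set
#'
#' `mode = "strict"` takes the intersection of all lists; `mode = "threshold"`
#' keeps genes present in at least `m` lists.  Symbols are
#' uppercase-normalized before comparison, and the anchor gene (when given)
#' is always appended to the core.
#'
#' @param lists list of >= 2 character vectors of gene symbols.
#' @param mode `"strict"` or `"threshold"`.
#' @param m minimum list count in threshold mode.
#' @param anchorGene optional anchor symbol to append.
#' @return character vector of core gene symbols (normalized).
#' @export
#' @examples
#' intersectLists(list(c("a", "b", "c"), c("b", "c", "d"), c("c", "e")))
intersectLists <- function(lists, mode = c("strict", "threshold"), m = 2,
                           anchorGene = NULL) {
  mode <- match.arg(mode)
  if (length(lists) < 2) stop("need at least 2 lists to intersect")
  lists <- lapply(lists, function(g) unique(.normSym(g)))
  if (mode == "strict") {
    core <- Reduce(intersect, lists)
  } else {
    counts <- table(unlist(lists))
    core <- names(counts)[counts >= m]
  }
  if (!is.null(anchorGene)) core <- union(core, .normSym(anchorGene))
  sort(core)
}

#' Build a gene correlation network over a core gene set
#'
#' For every unordered pair of core genes, correlations are computed across
#' all probeset pairings in the panel; one edge is created when any pairing
#' reaches `p <= alpha`, storing the smallest-p pairing.  Multiple probesets
#' of a gene collapse onto a single node, duplicate edges and self-loops are
#' removed, and isolated core genes stay in the network as nodes.  Core
#' genes without a panel probeset are retained as annotation-only nodes
#' (flag `inPanel = FALSE`).
#'
#' @param core character vector of core gene symbols.
#' @param panel an [RIPanel-class].
#' @param alpha p-value cutoff for edges.
#' @param anchorGene anchor gene symbol (added to the core if missing).
#' @param provenance optional named list of gene lists; each becomes a
#'   logical per-node flag recording which source lists contain the gene.
#' @return a [GeneNetwork-class].
#' @export
buildNetwork <- function(core, panel, alpha = 0.01, anchorGene = NA_character_,
                         provenance = NULL) {
  core <- unique(.normSym(core))
  if (!is.na(anchorGene)) core <- union(core, .normSym(anchorGene))
  map <- probeGeneMap(panel)
  map$geneN <- .normSym(map$gene)
  ex <- panelExprs(panel)
  sub <- map[map$geneN %in% core & map$probeset %in% rownames(ex), , drop = FALSE]
  unmapped <- setdiff(core, sub$geneN)
  if (length(unmapped))
    message(length(unmapped),
            " core genes without panel probesets kept as annotation-only nodes")

  edges <- data.frame(geneA = character(), geneB = character(), r = numeric(),
                      n = integer(), p = numeric(), probesetA = character(),
                      probesetB = character(), stringsAsFactors = FALSE)
  if (nrow(sub) >= 2) {
    M <- t(ex[sub$probeset, , drop = FALSE])
    C <- cor(M, use = "pairwise.complete.obs")
    nMat <- crossprod(!is.na(M))
    P <- matrix(.corP(as.vector(C), as.vector(nMat)), nrow = nrow(C))
    np <- nrow(sub)
    ii <- which(upper.tri(C), arr.ind = TRUE)
    gA <- sub$geneN[ii[, 1]]; gB <- sub$geneN[ii[, 2]]
    keep <- gA != gB & P[ii] <= alpha  # no self-loops across duplicate probesets
    if (any(keep)) {
      swap <- gA[keep] > gB[keep]
      pA <- sub$probeset[ii[, 1]][keep]; pB <- sub$probeset[ii[, 2]][keep]
      ed <- data.frame(
        geneA = ifelse(swap, gB[keep], gA[keep]),
        geneB = ifelse(swap, gA[keep], gB[keep]),
        r = C[ii][keep], n = as.integer(nMat[ii][keep]), p = P[ii][keep],
        probesetA = ifelse(swap, pB, pA),
        probesetB = ifelse(swap, pA, pB),
        stringsAsFactors = FALSE)
      ed <- ed[order(ed$geneA, ed$geneB, ed$p), , drop = FALSE]
      edges <- ed[!duplicated(ed[, c("geneA", "geneB")]), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  nodes <- data.frame(gene = sort(core), stringsAsFactors = FALSE)
  nodes$inPanel <- !nodes$gene %in% unmapped
  if (!is.null(provenance)) {
    for (nm in names(provenance))
      nodes[[nm]] <- nodes$gene %in% .normSym(provenance[[nm]])
  }
  new("GeneNetwork", nodes = nodes, edges = edges,
      anchor = if (is.na(anchorGene)) NA_character_ else .normSym(anchorGene))
}
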
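## Over-representation analysis in two dialects: set-based hypergeometric
## testing of an explicit query list, and score-threshold ORA that first
## collapses probesets to genes by the best-scoring replicate and thresholds
## on |score|.  Multiple testing is Benjamini-Hochberg in both.  The
## background defaults to the genes actually measured, not the genome, and
## is reported explicitly with every result.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols
#'   (uppercase-normalized on construction).
#' @param source source tag.
#' @return a [GeneSetList-class].
#' @export
geneSetList <- function(sets, source = "custom") {
  sets <- lapply(sets, function(g) unique(.normSym(g)))
  new("GeneSetList", sets = sets, source = source)
}

#' Hypergeometric over-representation analysis
#'
#' For each retained set, `p = P(X >= k)` with `X ~ hypergeometric(N, K, n)`:
#' `N` background genes of which `K` are in the set, `n` query genes of which
#' `k` overlap the set.  Sets are intersected with the background and kept
#' only when their size falls in `[minSize, maxSize]`.  BH correction runs
#' across the retained sets; results are sorted by q then p.
#'
#' @param query character vector of query gene symbols (must be a subset of
#'   the background).
#' @param sets a [GeneSetList-class] (or named list coerced to one).
#' @param background character vector: the gene universe.
#' @param minSize,maxSize retained set-size limits (after background
#'   intersection).
#' @param fdr FDR level for the `significant` flag.
#' @return an [OraResult-class].
#' @export
#' @examples
#' bg <- sprintf("g%02d", 1:20)
#' hypergeomORA(bg[1:10], list(hit = bg[1:5]), bg)
hypergeomORA <- function(query, sets, background, minSize = 3,
                         maxSize = 300, fdr = 0.05) {
  if (!is(sets, "GeneSetList")) sets <- geneSetList(sets)
  query <- unique(.normSym(query))
  background <- unique(.normSym(background))
  bad <- setdiff(query, background)
  if (length(bad))
    stop("query genes missing from background: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  N <- length(background)
  n <- length(query)
  inter <- lapply(geneSets(sets), intersect, background)
  K <- vapply(inter, length, 1L)
  keep <- K >= minSize & K <= maxSize
  inter <- inter[keep]; K <- K[keep]
  k <- vapply(inter, function(s) length(intersect(s, query)), 1L)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  tb <- data.frame(set = names(inter), k = k, n = n, K = K, N = N,
                   p = p, q = q, significant = q <= fdr,
                   stringsAsFactors = FALSE, row.names = NULL)
  tb <- tb[order(tb$q, tb$p, tb$set), , drop = FALSE]
  rownames(tb) <- NULL
  new("OraResult", table = tb, background = background, fdr = fdr,
      nUnmapped = 0L)
}

#' Score-threshold over-representation analysis
#'
#' Collapses probeset scores to genes by the best-scoring replicate (the
#' probeset with maximal `|score|`), takes as query the genes with
#' `|score| >= scoreThreshold`, and runs [hypergeomORA()] against the mapped
#' gene background at the given FDR (default 10%).  Probesets without a gene
#' mapping are dropped; their count is reported.
#'
#' @param scores named numeric vector of per-probeset scores (e.g. replicate
#'   mean S-scores).
#' @param map data.frame with columns `probeset`, `gene`.
#' @param sets a [GeneSetList-class] (or named list).
#' @param background optional gene universe; defaults to all mapped genes
#'   carrying a score.
#' @param scoreThreshold gene score threshold on `|score|`.
#' @param fdr FDR level for the `significant` flag.
#' @inheritParams hypergeomORA
#' @return an [OraResult-class]; the collapsed per-gene scores are attached
#'   as attribute `geneScores`.
#' @export
thresholdORA <- function(scores, map, sets, background = NULL,
                         scoreThreshold = 1.5, fdr = 0.10,
                         minSize = 3, maxSize = 300) {
  if (is.null(names(scores))) stop("'scores' must be named by probeset")
  gene <- map$gene[match(names(scores), map$probeset)]
  unmapped <- sum(is.na(gene))
  if (unmapped > 0) {
    message(unmapped, " probesets dropped: no gene mapping")
    scores <- scores[!is.na(gene)]
    gene <- gene[!is.na(gene)]
  }
  gene <- .normSym(gene)
  ## best-scoring replicate per gene: max |score|
  ord <- order(gene, -abs(scores))
  best <- !duplicated(gene[ord])
  geneScores <- setNames(scores[ord][best], gene[ord][best])
  if (is.null(background)) background <- names(geneScores)
  query <- names(geneScores)[abs(geneScores) >= scoreThreshold]
  res <- hypergeomORA(query, sets, background, minSize = minSize,
                      maxSize = maxSize, fdr = fdr)
  out <- new("OraResult", table = oraTable(res), background = res@background,
             fdr = fdr, nUnmapped = as.integer(unmapped))
  attr(out, "geneScores") <- geneScores
  out
}

#' Read a GMT gene-set file
#'
#' @param path path to a tab-delimited GMT file (set name, description,
#'   then gene symbols).
#' @return a [GeneSetList-class] tagged with the file name.
#' @export
readGMT <- function(path) {
  sets <- fgsea::gmtPathways(path)
  geneSetList(sets, source = basename(path))
}

#' Write a gene-set collection as GMT
#'
#' @param sets a [GeneSetList-class] or named list.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "na") {
  if (is(sets, "GeneSetList")) sets <- geneSets(sets)
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled extended myelin-associated gene set
#'
#' Loads the packaged stand-in for an extended myelin gene set: the five
#' genes annotated to GO:0019911 (structural constituent of myelin sheath:
#' Mal, Mbp, Plp1, Tspan2, Mobp) plus seven classic myelin-associated genes.
#' The exact membership of curated extended myelin sets varies between
#' laboratories; this fixture is a documented stand-in, suitable for testing
#' the ORA machinery, not a reference annotation.
#'
#' @return a [GeneSetList-class] with one set, `MYELIN_EXTENDED`.
#' @export
myelinGeneSet <- function() {
  readGMT(system.file("extdata", "myelin_extended_standin.gmt",
                      package = "anchornet", mustWork = TRUE))
}
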
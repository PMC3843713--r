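## Network eigengene: the first principal component of the standardized
## expression of a gene set across strains, and its correlation with a
## phenotype.  The PC1 sign is arbitrary; it is fixed so the sum of gene
## loadings is positive, and the phenotype correlation is reported both
## signed and in magnitude.

#' First principal component of a gene set across strains
#'
#' Collapses each gene to the mean of its standardized probesets (then
#' re-standardizes), drops constant genes with a warning and strains with
#' any missing value, and extracts PC1 from the singular value decomposition
#' of the strains x genes matrix (correlation PCA).
#'
#' @param panel an [RIPanel-class].
#' @param genes character vector of network gene symbols (>= 2 with panel
#'   data required).
#' @return an [EigengeneResult-class].
#' @export
networkPC1 <- function(panel, genes) {
  genes <- unique(.normSym(genes))
  map <- probeGeneMap(panel)
  map$geneN <- .normSym(map$gene)
  ex <- panelExprs(panel)
  sub <- map[map$geneN %in% genes & map$probeset %in% rownames(ex), ,
             drop = FALSE]
  if (length(unique(sub$geneN)) < 2)
    stop("need at least 2 network genes with panel data")

  strains <- colnames(ex)
  complete <- colSums(!is.finite(ex[sub$probeset, , drop = FALSE])) == 0
  droppedStrains <- strains[!complete]
  if (length(droppedStrains))
    message(length(droppedStrains), " strains dropped for missing values")
  exc <- ex[sub$probeset, complete, drop = FALSE]
  if (ncol(exc) < 3) stop("fewer than 3 complete strains")

  ## standardize probesets, average within gene, re-standardize genes
  geneIds <- sort(unique(sub$geneN))
  dropped <- character()
  cols <- list()
  for (g in geneIds) {
    ps <- sub$probeset[sub$geneN == g]
    vs <- lapply(ps, function(p) {
      v <- exc[p, ]
      s <- sd(v)
      if (s == 0) NULL else (v - mean(v)) / s
    })
    vs <- vs[!vapply(vs, is.null, TRUE)]
    if (!length(vs)) { dropped <- c(dropped, g); next }
    gv <- Reduce(`+`, vs) / length(vs)
    s <- sd(gv)
    if (s == 0) { dropped <- c(dropped, g); next }
    cols[[g]] <- (gv - mean(gv)) / s
  }
  if (length(dropped))
    warning(length(dropped), " constant genes dropped: ",
            paste(head(dropped, 5), collapse = ", "))
  if (length(cols) < 2) stop("degenerate input: fewer than 2 varying genes")

  X <- do.call(cbind, cols)           # strains x genes, standardized
  sv <- svd(X)
  scores <- sv$u[, 1] * sv$d[1]
  loadings <- sv$v[, 1]
  if (sum(loadings) < 0 ||
      (sum(loadings) == 0 && loadings[which.max(abs(loadings))] < 0)) {
    scores <- -scores
    loadings <- -loadings
  }
  new("EigengeneResult",
      scores = setNames(scores, rownames(X)),
      loadings = setNames(loadings, colnames(X)),
      varExplained = sv$d[1]^2 / sum(sv$d^2),
      droppedGenes = dropped,
      droppedStrains = droppedStrains)
}

#' Correlate a network eigengene with a phenotype
#'
#' Delegates to [pearsonWithP()] over the strains carrying both a PC1 score
#' and a phenotype value.  Because the PC1 sign is arbitrary, `|r|` is
#' reported alongside the signed correlation.
#'
#' @param eig an [EigengeneResult-class].
#' @param phenotype named per-strain phenotype vector.
#' @return list with `r`, `absR`, `n`, `p`.
#' @export
pc1PhenotypeCorr <- function(eig, phenotype) {
  res <- pearsonWithP(eigengeneScores(eig), phenotype)
  list(r = unname(res["r"]), absR = abs(unname(res["r"])),
       n = as.integer(res["n"]), p = unname(res["p"]))
}
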
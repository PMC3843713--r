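## File formats: tab-delimited expression matrices (probesets as rows, header
## row of sample/strain ids), S-score and SAM result TSVs, GMT gene sets,
## SIF + GraphML network exports, and JSON for ground truth and run
## manifests.  Everything is plain text and diff-able.

#' Read a tab-delimited expression matrix
#'
#' First column: probeset ids (unique); remaining columns: numeric sample or
#' strain values.  Malformed cells and duplicate ids raise errors naming the
#' offending lines (line 1 is the header).
#'
#' @param path input path.
#' @return numeric matrix with probeset rownames.
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2) stop("malformed header in ", path, ": need id + >= 1 sample column")
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate probeset ids in ", path, " at line(s) ",
         paste(head(dup + 1L, 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badRow <- which(apply(df[, -1, drop = FALSE], 1,
                          function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric cells in ", path, " at line(s) ",
         paste(head(badRow + 1L, 5), collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Write a tab-delimited expression matrix
#'
#' @param mat numeric matrix with rownames (probesets) and colnames.
#' @param path output path.
#' @param idColumn header of the id column.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(mat, path, idColumn = "probeset") {
  df <- data.frame(mat[, , drop = FALSE], check.names = FALSE)
  df <- cbind(setNames(data.frame(rownames(mat)), idColumn), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an S-score table as TSV
#'
#' Contrast and region travel in `#key=value` comment lines above the
#' header.
#'
#' @param table an [SScoreTable-class].
#' @param path file path.
#' @return `writeSScoreTable`: `path` invisibly; `readSScoreTable`: an
#'   [SScoreTable-class].
#' @export
writeSScoreTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#contrast=", table@contrast),
               paste0("#region=", table@region)), con)
  sc <- scoreMatrix(table)
  df <- cbind(data.frame(probeset = rownames(sc)),
              data.frame(sc, check.names = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSScoreTable
#' @export
readSScoreTable <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- sub("^#[a-z]+=", "", hdr)
  m <- readExpressionTSV(path)  # read.delim skips the leading comment lines
  new("SScoreTable", scores = m, contrast = meta[1], region = meta[2])
}

#' Write a SAM result as TSV
#'
#' @param result a [SamResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSamResult <- function(result, path) {
  write.table(samTable(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an RI panel from TSV files
#'
#' @param exprPath expression matrix TSV (probesets x strains).
#' @param mapPath probeset-to-gene mapping TSV with columns `probeset`,
#'   `gene`.
#' @param phenotypePath optional two-column TSV (`strain`, value); phenotype
#'   strains absent from the panel are dropped with a message.
#' @param label panel label.
#' @return an [RIPanel-class].
#' @export
readPanel <- function(exprPath, mapPath, phenotypePath = NULL,
                      label = basename(exprPath)) {
  ex <- readExpressionTSV(exprPath)
  map <- read.delim(mapPath, stringsAsFactors = FALSE)
  if (!all(c("probeset", "gene") %in% names(map)))
    stop("mapping file needs columns 'probeset' and 'gene'")
  pheno <- numeric()
  if (!is.null(phenotypePath)) {
    ph <- read.delim(phenotypePath, stringsAsFactors = FALSE)
    pheno <- setNames(as.numeric(ph[[2]]), as.character(ph[[1]]))
    extra <- setdiff(names(pheno), colnames(ex))
    if (length(extra)) {
      message(length(extra), " phenotyped strains absent from the panel dropped")
      pheno <- pheno[setdiff(names(pheno), extra)]
    }
    miss <- setdiff(colnames(ex), names(pheno))
    if (length(miss))
      message(length(miss), " panel strains lack a phenotype value")
  }
  new("RIPanel", exprs = ex, map = map[, c("probeset", "gene")],
      phenotype = pheno, label = label)
}

#' Write a phenotype vector as TSV
#'
#' @param pheno named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTSV <- function(pheno, path) {
  write.table(data.frame(strain = names(pheno), value = unname(pheno)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a gene network
#'
#' `writeSIF` writes the simple interaction format (`geneA cor geneB`, one
#' line per edge, isolated nodes on their own lines); `writeGraphML` writes
#' GraphML via igraph with `r`, `n`, `p` edge attributes and the node table
#' as vertex attributes.  Both load in Cytoscape.
#'
#' @param network a [GeneNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(network, path) {
  ed <- networkEdges(network)
  nd <- networkNodes(network)
  isolated <- setdiff(nd$gene, c(ed$geneA, ed$geneB))
  lines <- c(if (nrow(ed)) paste(ed$geneA, "cor", ed$geneB), isolated)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSIF
#' @export
writeGraphML <- function(network, path) {
  g <- asIgraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a gene network to an igraph object
#'
#' @param network a [GeneNetwork-class].
#' @return an [igraph::graph] with node provenance flags as vertex
#'   attributes and `r`, `n`, `p` as edge attributes.
#' @export
asIgraph <- function(network) {
  nd <- networkNodes(network)
  ed <- networkEdges(network)
  igraph::graph_from_data_frame(
    d = ed[, c("geneA", "geneB", "r", "n", "p"), drop = FALSE],
    directed = FALSE, vertices = nd)
}

#' Write planted ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(deProbesets = truth@deProbesets,
         moduleProbesets = truth@moduleProbesets,
         moduleGenes = truth@moduleGenes,
         anchorProbeset = truth@anchorProbeset,
         anchorGene = truth@anchorGene,
         latent = truth@latent,
         plantedRho = truth@plantedRho),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
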
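## Accessors and show methods.  Slot access from user code should go through
## these.

#' @name accessors
#' @title Accessors for anchornet S4 classes
#' @description Small accessor generics: slot access for user code.
#' @param x an anchornet S4 object
#' @return the requested component
NULL

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setMethod("scoreMatrix", "SScoreTable", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("contrastLabel", function(x) standardGeneric("contrastLabel"))
#' @rdname accessors
#' @export
setMethod("contrastLabel", "SScoreTable", function(x) x@contrast)
#' @rdname accessors
#' @export
setMethod("contrastLabel", "SamResult", function(x) x@contrast)

#' @rdname accessors
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))
#' @rdname accessors
#' @export
setMethod("regionLabel", "SScoreTable", function(x) x@region)
#' @rdname accessors
#' @export
setMethod("regionLabel", "SamResult", function(x) x@region)

#' @rdname accessors
#' @export
setGeneric("samTable", function(x) standardGeneric("samTable"))
#' @rdname accessors
#' @export
setMethod("samTable", "SamResult", function(x) x@table)

#' @rdname accessors
#' @param object a `SamResult`
#' @export
setGeneric("passSet", function(x) standardGeneric("passSet"))
#' @rdname accessors
#' @export
setMethod("passSet", "SamResult", function(x) x@table$probeset[x@table$pass])

#' @rdname accessors
#' @export
setGeneric("patternValues", function(x) standardGeneric("patternValues"))
#' @rdname accessors
#' @export
setMethod("patternValues", "PatternMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("oraTable", function(x) standardGeneric("oraTable"))
#' @rdname accessors
#' @export
setMethod("oraTable", "OraResult", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("panelExprs", function(x) standardGeneric("panelExprs"))
#' @rdname accessors
#' @export
setMethod("panelExprs", "RIPanel", function(x) x@exprs)

#' @rdname accessors
#' @export
setGeneric("probeGeneMap", function(x) standardGeneric("probeGeneMap"))
#' @rdname accessors
#' @export
setMethod("probeGeneMap", "RIPanel", function(x) x@map)

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname accessors
#' @export
setMethod("phenotype", "RIPanel", function(x) x@phenotype)

#' @rdname accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname accessors
#' @export
setMethod("strainNames", "RIPanel", function(x) colnames(x@exprs))

#' @rdname accessors
#' @export
setGeneric("screenRecords", function(x) standardGeneric("screenRecords"))
#' @rdname accessors
#' @export
setMethod("screenRecords", "CorrelationScreen", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("screenGenes", function(x) standardGeneric("screenGenes"))
#' @rdname accessors
#' @export
setMethod("screenGenes", "CorrelationScreen",
          function(x) unique(x@records$gene))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("anchorGene", function(x) standardGeneric("anchorGene"))
#' @rdname accessors
#' @export
setMethod("anchorGene", "GeneNetwork", function(x) x@anchor)
#' @rdname accessors
#' @export
setMethod("anchorGene", "GroundTruth", function(x) x@anchorGene)

#' @rdname accessors
#' @export
setGeneric("eigengeneScores", function(x) standardGeneric("eigengeneScores"))
#' @rdname accessors
#' @export
setMethod("eigengeneScores", "EigengeneResult", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("geneLoadings", function(x) standardGeneric("geneLoadings"))
#' @rdname accessors
#' @export
setMethod("geneLoadings", "EigengeneResult", function(x) x@loadings)

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setMethod("varianceExplained", "EigengeneResult", function(x) x@varExplained)

#' @rdname accessors
#' @export
setGeneric("moduleProbesets", function(x) standardGeneric("moduleProbesets"))
#' @rdname accessors
#' @export
setMethod("moduleProbesets", "GroundTruth", function(x) x@moduleProbesets)

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))
#' @rdname accessors
#' @export
setMethod("moduleGenes", "GroundTruth", function(x) x@moduleGenes)

#' @rdname accessors
#' @export
setGeneric("deProbesets", function(x) standardGeneric("deProbesets"))
#' @rdname accessors
#' @export
setMethod("deProbesets", "GroundTruth", function(x) x@deProbesets)

#' @rdname accessors
#' @export
setGeneric("latentFactor", function(x) standardGeneric("latentFactor"))
#' @rdname accessors
#' @export
setMethod("latentFactor", "GroundTruth", function(x) x@latent)

## ---- show methods -------------------------------------------------------

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf("ErrorModel: alpha=%.4g beta=%.4g gamma=%.4g\n",
              object@alpha, object@beta, object@gamma))
})

setMethod("show", "SScoreTable", function(object) {
  cat(sprintf("SScoreTable: %d probesets x %d replicates [%s, %s]\n",
              nrow(object@scores), ncol(object@scores),
              object@region, object@contrast))
})

setMethod("show", "SamResult", function(object) {
  cat(sprintf(
    "SamResult [%s, %s]: %d probesets, %d pass (floor %.2f, FDR cap %.2f)\n",
    object@region, object@contrast, nrow(object@table),
    sum(object@table$pass), object@scoreFloor, object@fdrCap))
  cat(sprintf("  s0 = %.4g; %d permutation atoms (%s enumeration)\n",
              object@s0, object@nPerm,
              if (object@complete) "complete" else "sampled"))
})

setMethod("show", "PatternMatrix", function(object) {
  cat(sprintf("PatternMatrix: %d probesets x %d (region, contrast) columns\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "GeneSetList", function(object) {
  sz <- vapply(object@sets, length, 1L)
  cat(sprintf("GeneSetList [%s]: %d sets, sizes %d-%d\n", object@source,
              length(object@sets), min(sz), max(sz)))
})

setMethod("show", "OraResult", function(object) {
  cat(sprintf("OraResult: %d sets tested against N=%d background; %d significant (FDR %.2f)\n",
              nrow(object@table), length(object@background),
              sum(object@table$significant), object@fdr))
  if (object@nUnmapped > 0L)
    cat(sprintf("  %d probesets dropped (no gene mapping)\n", object@nUnmapped))
})

setMethod("show", "RIPanel", function(object) {
  cat(sprintf("RIPanel '%s': %d probesets x %d strains (%d genes)%s\n",
              object@label, nrow(object@exprs), ncol(object@exprs),
              length(unique(object@map$gene)),
              if (length(object@phenotype))
                sprintf("; phenotype on %d strains", length(object@phenotype))
              else ""))
})

setMethod("show", "CorrelationScreen", function(object) {
  cat(sprintf(
    "CorrelationScreen (%s%s): %d/%d probesets retained at p <= %.3g\n",
    object@type,
    if (!is.na(object@anchor)) paste0(": ", object@anchor) else "",
    nrow(object@records), object@nTested, object@alpha))
  cat(sprintf("  expected false positives under the null: %.1f\n",
              object@alpha * object@nTested))
})

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork (anchor %s): %d gene nodes, %d edges\n",
              object@anchor, nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "EigengeneResult", function(object) {
  cat(sprintf("EigengeneResult: PC1 over %d genes, %d strains; %.1f%% variance\n",
              length(object@loadings), length(object@scores),
              100 * object@varExplained))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d module probesets (%d genes), anchor %s\n",
              length(object@moduleProbesets), length(object@moduleGenes),
              object@anchorGene))
  for (nm in names(object@deProbesets))
    cat(sprintf("  planted DE [%s]: %d probesets\n", nm,
                length(object@deProbesets[[nm]])))
})
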
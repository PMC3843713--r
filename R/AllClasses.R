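## Central S4 containers.  Expression matrices for the knockout experiment
## live in a SummarizedExperiment; the classes below hold the stage outputs.

#' ErrorModel: additive-multiplicative array error model
#'
#' Variance model for the difference between two arrays:
#' `Var(a - b) = gamma^2 * (alpha * (a + b) + 2 * beta^2)` per probeset, so the
#' standardized difference `S = (a - b) / (gamma * sqrt(alpha*(a+b) + 2*beta^2))`
#' has approximately unit variance under same-condition comparisons once
#' `gamma` has been calibrated empirically.
#'
#' @slot alpha multiplicative (intensity-proportional) variance coefficient,
#'   `>= 0`.
#' @slot beta additive noise floor (standard-deviation units), `> 0`.
#' @slot gamma positive calibration scale fixing the pooled same/same score
#'   standard deviation at 1.
#' @export
setClass("ErrorModel",
         representation(alpha = "numeric", beta = "numeric", gamma = "numeric"),
         prototype(alpha = 0, beta = 1, gamma = 1))

setValidity("ErrorModel", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || !is.finite(object@alpha) || object@alpha < 0)
    msg <- c(msg, "'alpha' must be a single finite number >= 0")
  if (length(object@beta) != 1L || !is.finite(object@beta) || object@beta <= 0)
    msg <- c(msg, "'beta' must be a single finite number > 0")
  if (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma <= 0)
    msg <- c(msg, "'gamma' must be a single finite number > 0")
  if (length(msg)) msg else TRUE
})

#' SScoreTable: per-replicate standardized difference scores
#'
#' Rows are probesets, columns are biological replicates of the treated group
#' of one contrast (e.g. knockout-saline vs control-saline) within one brain
#' region.  Scores are on the standardized S-score scale: same-condition
#' comparisons are approximately standard normal.
#'
#' @slot scores numeric matrix, probesets x replicates, finite values.
#' @slot contrast single contrast label.
#' @slot region single region label.
#' @export
setClass("SScoreTable",
         representation(scores = "matrix", contrast = "character",
                        region = "character"))

setValidity("SScoreTable", function(object) {
  msg <- character()
  if (!is.numeric(object@scores)) msg <- c(msg, "'scores' must be numeric")
  if (is.null(rownames(object@scores)))
    msg <- c(msg, "'scores' must have probeset rownames")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "'scores' must be finite")
  if (length(object@contrast) != 1L || length(object@region) != 1L)
    msg <- c(msg, "'contrast' and 'region' must be single labels")
  if (length(msg)) msg else TRUE
})

#' SamResult: SAM-style permutation test result
#'
#' One row per probeset with the replicate mean score, the moderated
#' `d = mean / (se + s0)` statistic, the permutation median-FDR at the
#' probeset's own cut, and the composite pass flag
#' (`|mean| >= scoreFloor` and `fdr <= fdrCap`).
#'
#' @slot table data.frame with columns `probeset`, `mean`, `se`, `d`, `fdr`,
#'   `pass`.
#' @slot contrast,region labels carried from the input table(s).
#' @slot s0 the fudge factor used.
#' @slot nPerm number of permutation atoms used for the null.
#' @slot complete TRUE when the permutation null was enumerated exhaustively.
#' @slot scoreFloor,fdrCap the composite filter thresholds.
#' @export
setClass("SamResult",
         representation(table = "data.frame", contrast = "character",
                        region = "character", s0 = "numeric",
                        nPerm = "integer", complete = "logical",
                        scoreFloor = "numeric", fdrCap = "numeric"))

setValidity("SamResult", function(object) {
  msg <- character()
  need <- c("probeset", "mean", "se", "d", "fdr", "pass")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("'table' must have columns", paste(need, collapse = ", ")))
  else {
    if (any(object@table$fdr < 0 | object@table$fdr > 1))
      msg <- c(msg, "FDR values must lie in [0, 1]")
    bad <- object@table$pass &
      !(abs(object@table$mean) >= object@scoreFloor &
          object@table$fdr <= object@fdrCap)
    if (any(bad))
      msg <- c(msg, "pass flag inconsistent with composite filter")
  }
  if (length(msg)) msg else TRUE
})

#' PatternMatrix: per-probeset pattern vectors across regions and contrasts
#'
#' Rows are probesets in the union of SAM pass sets; one column per
#' (region, contrast) pair holding the replicate-mean normalized S-score.
#'
#' @slot values numeric matrix with probeset rownames.
#' @slot region,contrast per-column labels.
#' @export
setClass("PatternMatrix",
         representation(values = "matrix", region = "character",
                        contrast = "character"))

setValidity("PatternMatrix", function(object) {
  msg <- character()
  if (length(object@region) != ncol(object@values) ||
      length(object@contrast) != ncol(object@values))
    msg <- c(msg, "per-column region/contrast labels must match ncol(values)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "pattern values must be finite")
  if (length(msg)) msg else TRUE
})

#' GeneSetList: named collection of gene-symbol sets
#'
#' Gene symbols are uppercase-normalized on construction so that membership
#' tests are case-insensitive across sources.
#'
#' @slot sets named list of character vectors (non-empty, unique symbols).
#' @slot source single source tag (e.g. file name or "planted").
#' @export
setClass("GeneSetList",
         representation(sets = "list", source = "character"))

setValidity("GeneSetList", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
    msg <- c(msg, "all sets must be named")
  if (any(vapply(object@sets, length, 1L) == 0L))
    msg <- c(msg, "sets must be non-empty")
  if (any(duplicated(names(object@sets))))
    msg <- c(msg, "set names must be unique")
  if (length(msg)) msg else TRUE
})

#' OraResult: over-representation analysis result
#'
#' @slot table data.frame with one row per retained set: `set`, `k` (overlap),
#'   `n` (query size), `K` (set size in background), `N` (background size),
#'   `p` (hypergeometric upper tail), `q` (BH-adjusted), `significant`.
#' @slot background character vector of (normalized) background symbols.
#' @slot fdr the FDR level used for the `significant` flag.
#' @slot nUnmapped number of probesets dropped for lacking a gene mapping
#'   (score-threshold dialect only; 0 otherwise).
#' @export
setClass("OraResult",
         representation(table = "data.frame", background = "character",
                        fdr = "numeric", nUnmapped = "integer"))

setValidity("OraResult", function(object) {
  tb <- object@table
  msg <- character()
  if (nrow(tb)) {
    if (any(tb$k > pmin(tb$n, tb$K)))
      msg <- c(msg, "overlap k cannot exceed min(query, set) size")
    if (any(tb$p <= 0 | tb$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
    if (any(tb$q + 1e-12 < tb$p)) msg <- c(msg, "q must be >= p")
  }
  if (length(msg)) msg else TRUE
})

#' RIPanel: recombinant inbred strain expression panel
#'
#' Probesets x strains expression with a probeset-to-gene map and an optional
#' per-strain phenotype (e.g. duration of ethanol loss of righting reflex).
#' Phenotyped strains must be a subset of the expression strains.
#'
#' @slot exprs numeric matrix, probesets (rows) x strains (columns).
#' @slot map data.frame with columns `probeset`, `gene`.
#' @slot phenotype named numeric vector (possibly length 0).
#' @slot label free-text panel label.
#' @export
setClass("RIPanel",
         representation(exprs = "matrix", map = "data.frame",
                        phenotype = "numeric", label = "character"))

setValidity("RIPanel", function(object) {
  msg <- character()
  if (ncol(object@exprs) < 5L)
    msg <- c(msg, "an RI panel needs at least 5 strains")
  if (is.null(rownames(object@exprs)) || is.null(colnames(object@exprs)))
    msg <- c(msg, "exprs must have probeset rownames and strain colnames")
  if (!all(c("probeset", "gene") %in% names(object@map)))
    msg <- c(msg, "map must have columns 'probeset' and 'gene'")
  else if (!all(rownames(object@exprs) %in% object@map$probeset))
    msg <- c(msg, "every probeset must appear in the gene map")
  if (length(object@phenotype) &&
      !all(names(object@phenotype) %in% colnames(object@exprs)))
    msg <- c(msg, "phenotype strains must be a subset of expression strains")
  if (length(msg)) msg else TRUE
})

#' CorrelationScreen: records retained by an anchor/phenotype screen
#'
#' @slot records data.frame with columns `probeset`, `gene`, `r`, `n`, `p`
#'   (and `anchorProbeset` for anchor screens), one row per retained probeset
#'   (smallest-p pairing when the anchor has several probesets).
#' @slot type `"anchor"` or `"phenotype"`.
#' @slot anchor anchor gene symbol (`NA` for phenotype screens).
#' @slot alpha p-value cutoff of the screen (no multiplicity correction; the
#'   expected screen-wide false-positive count `alpha * nTested` is recorded).
#' @slot nTested number of candidate probesets screened.
#' @export
setClass("CorrelationScreen",
         representation(records = "data.frame", type = "character",
                        anchor = "character", alpha = "numeric",
                        nTested = "integer"))

setValidity("CorrelationScreen", function(object) {
  rec <- object@records
  msg <- character()
  if (nrow(rec)) {
    if (any(abs(rec$r) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
    if (any(rec$p < 0 | rec$p > 1)) msg <- c(msg, "p must lie in [0, 1]")
    if (any(rec$n < 3)) msg <- c(msg, "each record needs n >= 3 strains")
  }
  if (length(msg)) msg else TRUE
})

#' GeneNetwork: gene-symbol correlation network
#'
#' Probesets are collapsed to gene nodes; at most one edge per unordered gene
#' pair (the smallest-p probeset pairing is kept) and no self-loops.
#'
#' @slot nodes data.frame with column `gene` plus logical provenance flags.
#' @slot edges data.frame with columns `geneA`, `geneB`, `r`, `n`, `p`,
#'   `probesetA`, `probesetB`.
#' @slot anchor the anchor gene symbol (always a node).
#' @export
setClass("GeneNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        anchor = "character"))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (nrow(ed)) {
    if (any(ed$geneA == ed$geneB)) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(ed$geneA, ed$geneB), pmax(ed$geneA, ed$geneB))
    if (anyDuplicated(key))
      msg <- c(msg, "at most one edge per unordered gene pair")
    if (!all(c(ed$geneA, ed$geneB) %in% object@nodes$gene))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(object@anchor) == 1L && !is.na(object@anchor) &&
      !object@anchor %in% object@nodes$gene)
    msg <- c(msg, "anchor gene must be a node")
  if (length(msg)) msg else TRUE
})

#' EigengeneResult: first principal component of a gene module
#'
#' @slot scores named per-strain PC1 scores (zero mean by construction).
#' @slot loadings named per-gene loadings (unit Euclidean norm), oriented so
#'   their sum is positive (sign of PC1 is otherwise arbitrary).
#' @slot varExplained fraction of total standardized variance carried by PC1.
#' @slot droppedGenes genes excluded for zero variance.
#' @slot droppedStrains strains excluded for missing values.
#' @export
setClass("EigengeneResult",
         representation(scores = "numeric", loadings = "numeric",
                        varExplained = "numeric", droppedGenes = "character",
                        droppedStrains = "character"))

setValidity("EigengeneResult", function(object) {
  msg <- character()
  if (abs(mean(object@scores)) > 1e-8 * max(1, sd(object@scores)))
    msg <- c(msg, "PC1 scores must have zero mean")
  if (abs(sum(object@loadings^2) - 1) > 1e-8)
    msg <- c(msg, "loadings must have unit norm")
  if (object@varExplained <= 0 || object@varExplained > 1 + 1e-12)
    msg <- c(msg, "variance explained must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot deProbesets named list of planted differential probeset sets, one per
#'   contrast.
#' @slot moduleProbesets probesets in the planted coherent module.
#' @slot moduleGenes gene symbols of the planted module.
#' @slot anchorProbeset,anchorGene the planted hub.
#' @slot latent named list of latent factor realizations (per region for the
#'   knockout design, per strain for RI panels).
#' @slot plantedRho target |correlation| between phenotype and module latent
#'   factor (RI panels; `NA` otherwise).
#' @export
setClass("GroundTruth",
         representation(deProbesets = "list", moduleProbesets = "character",
                        moduleGenes = "character", anchorProbeset = "character",
                        anchorGene = "character", latent = "list",
                        plantedRho = "numeric"))
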
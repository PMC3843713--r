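## Synthetic-data generators.  These emulate the statistical structure of a
## hub-gene knockout microarray study (4 genotype x treatment groups, 3 pooled
## biological replicates, 3 brain regions) and of recombinant inbred (RI)
## expression panels with a planted coherent module, a hub ("anchor") probeset
## loading on the same latent factor, and a phenotype linearly coupled to it.
## Ground truth for every planted feature is returned alongside the data so
## downstream stages can be tested for calibration and recovery.

.KO_GROUPS <- c("CTL.Sal", "CTL.EtOH", "KO.Sal", "KO.EtOH")

#' Simulate a knockout microarray experiment with planted structure
#'
#' Generates log-scale intensities for `length(regions)` brain regions, each
#' with the four genotype x treatment groups (control/knockout x
#' saline/ethanol) and `nReplicates` arrays per group.  Three kinds of signal
#' are planted on top of per-probeset baselines and Gaussian noise:
#'
#' * `nDE` *basal* differential probesets, shifted (random sign) in the
#'   knockout genotype in every region; the anchor gene is one of them,
#'   forced downward (it is deleted in the knockout).
#' * `nDE` *ethanol-response* differential probesets: ethanol shifts them in
#'   control animals but the response is absent in knockouts, so they carry
#'   the two-class (genotype difference in ethanol response) signal.
#' * a coherent module of `moduleSize` probesets sharing a per-sample latent
#'   factor in all regions and additionally shifted downward in knockouts
#'   within `moduleRegions` only (a myelin-like basal decrease confined to
#'   the affected regions).
#'
#' Intensity shifts are expressed in S-score units via
#' `delta = effectSize * sqrt(2) * noiseSd`, so that a planted probeset has a
#' replicate-mean S-score of about `effectSize` after calibration.
#'
#' @param nProbesets number of probesets on the synthetic array.
#' @param nReplicates arrays per group (pooled biological replicates).
#' @param regions character vector of region labels.
#' @param nDE planted differential probesets per contrast.
#' @param effectSize mean planted shift in S-score units.
#' @param moduleSize number of probesets in the planted coherent module.
#' @param moduleRegions regions in which the module is basally decreased in
#'   the knockout.
#' @param noiseSd within-group intensity standard deviation (log scale).
#' @param anchorGene symbol of the knocked-out hub gene.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list with elements `se` (a
#'   [SummarizedExperiment::SummarizedExperiment] of probesets x arrays with
#'   region/genotype/treatment/replicate column data and gene-symbol row
#'   data) and `truth` (a [GroundTruth-class] object).
#' @export
#' @examples
#' sim <- simulateKOExperiment(nProbesets = 500, nDE = 20, seed = 1)
#' sim$truth
simulateKOExperiment <- function(nProbesets = 4000,
                                 nReplicates = 3,
                                 regions = c("NAC", "PFC", "VMB"),
                                 nDE = 100,
                                 effectSize = 3,
                                 moduleSize = 50,
                                 moduleRegions = c("NAC", "PFC"),
                                 noiseSd = 0.25,
                                 anchorGene = "Fyn",
                                 seed = 1) {
  if (nReplicates < 2) stop("need at least 2 replicates per group")
  if (!is.finite(effectSize)) stop("'effectSize' must be finite")
  if (nDE < 0 || moduleSize < 0) stop("counts must be non-negative")
  if (2 * nDE + moduleSize > nProbesets)
    stop("planted probesets (2*nDE + moduleSize) exceed 'nProbesets'")
  if (!all(moduleRegions %in% regions))
    stop("'moduleRegions' must be a subset of 'regions'")

  set.seed(as.integer(seed))
  probesets <- sprintf("PS%05d", seq_len(nProbesets))
  genes <- sprintf("G%05d", seq_len(nProbesets))

  ## planted feature assignment (disjoint)
  idx <- sample.int(nProbesets, 2 * nDE + moduleSize)
  basalIdx <- if (nDE > 0) idx[seq_len(nDE)] else integer()
  etohIdx <- if (nDE > 0) idx[nDE + seq_len(nDE)] else integer()
  modIdx <- if (moduleSize > 0) idx[2 * nDE + seq_len(moduleSize)] else integer()
  anchorIdx <- if (nDE > 0) basalIdx[1] else NA_integer_
  if (!is.na(anchorIdx)) genes[anchorIdx] <- anchorGene

  delta <- effectSize * sqrt(2) * noiseSd
  basalSign <- if (nDE > 0) sample(c(-1, 1), nDE, replace = TRUE) else numeric()
  if (nDE > 0) basalSign[1] <- -1  # the anchor gene is deleted, hence down
  etohSign <- if (nDE > 0) sample(c(-1, 1), nDE, replace = TRUE) else numeric()
  modLoad <- if (moduleSize > 0) runif(moduleSize, 0.5, 1) else numeric()

  baseline <- runif(nProbesets, 6, 12)
  nPer <- nReplicates
  grp <- rep(.KO_GROUPS, each = nPer)
  genotype <- ifelse(grepl("^KO", grp), "KO", "CTL")
  treatment <- ifelse(grepl("EtOH$", grp), "EtOH", "Sal")
  repl <- rep(seq_len(nPer), times = 4)

  mats <- vector("list", length(regions))
  latents <- vector("list", length(regions))
  names(mats) <- names(latents) <- regions
  for (rg in regions) {
    nS <- length(grp)
    f <- rnorm(nS)  # per-sample latent factor driving module coherence
    m <- matrix(baseline, nrow = nProbesets, ncol = nS) +
      matrix(rnorm(nProbesets * nS, sd = noiseSd), nProbesets, nS)
    isKO <- genotype == "KO"
    isCtlEtoh <- grp == "CTL.EtOH"
    if (nDE > 0) {
      m[basalIdx, isKO] <- m[basalIdx, isKO] + basalSign * delta
      m[etohIdx, isCtlEtoh] <- m[etohIdx, isCtlEtoh] + etohSign * delta
    }
    if (moduleSize > 0) {
      m[modIdx, ] <- m[modIdx, ] + outer(modLoad * noiseSd, f)
      ## the latent factor inflates a module probeset's same/same SD by
      ## sqrt(1 + load^2); compensate the planted shift so the
      ## post-normalization replicate-mean S-score is effectSize as stated
      if (rg %in% moduleRegions)
        m[modIdx, isKO] <- m[modIdx, isKO] - delta * sqrt(1 + modLoad^2)
    }
    colnames(m) <- sprintf("%s_%s_%d", rg, grp, repl)
    rownames(m) <- probesets
    mats[[rg]] <- m
    latents[[rg]] <- setNames(f, colnames(m))
  }

  full <- do.call(cbind, mats)
  cd <- S4Vectors::DataFrame(
    region = rep(regions, each = length(grp)),
    group = rep(grp, times = length(regions)),
    genotype = rep(genotype, times = length(regions)),
    treatment = rep(treatment, times = length(regions)),
    replicate = rep(repl, times = length(regions)),
    row.names = colnames(full))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = full),
    colData = cd,
    rowData = S4Vectors::DataFrame(gene = genes, row.names = probesets),
    metadata = list(
      params = list(nProbesets = nProbesets, nReplicates = nReplicates,
                    regions = regions, nDE = nDE, effectSize = effectSize,
                    moduleSize = moduleSize, moduleRegions = moduleRegions,
                    noiseSd = noiseSd, anchorGene = anchorGene, seed = seed)))

  truth <- new("GroundTruth",
               deProbesets = list(basal = probesets[basalIdx],
                                  ethanol = probesets[etohIdx]),
               moduleProbesets = probesets[modIdx],
               moduleGenes = genes[modIdx],
               anchorProbeset = if (is.na(anchorIdx)) character()
                                else probesets[anchorIdx],
               anchorGene = anchorGene,
               latent = latents,
               plantedRho = NA_real_)
  list(se = se, truth = truth)
}

#' Simulate a recombinant inbred expression panel
#'
#' Generates a probesets x strains expression matrix in which `moduleSize`
#' module genes load on a standard-normal per-strain latent factor `z`
#' (per-probeset loadings uniform in `[0.5, 1]`, residual SD `moduleNoiseSd`),
#' the anchor gene's probeset is `anchorLoading * z` plus unit-completing
#' noise, and (optionally) a phenotype
#' `rho * standardize(z) + sqrt(1 - rho^2) * noise` so its planted
#' correlation with the module latent factor is `rho` and its variance is 1
#' up to sampling error.  A `duplicateRate` fraction of the probeset count is
#' used to give `floor(duplicateRate * nProbesets)` genes two probesets each
#' (independent noise, same loading), emulating array redundancy.
#'
#' @param nStrains number of strains (`>= 5`).
#' @param nProbesets number of probesets.
#' @param moduleSize number of module *genes* (their probesets may number a
#'   few more when duplicated genes fall in the module).
#' @param anchorLoading correlation of the anchor probeset with the latent
#'   factor.
#' @param phenoCoupling target |correlation| `rho` between phenotype and
#'   latent factor, in `[0, 1]`.
#' @param duplicateRate fraction of probesets used to duplicate genes.
#' @param moduleNoiseSd residual SD of module probesets around their latent
#'   component.
#' @param universe optional character vector of gene symbols to draw from
#'   (lets several panels share one gene universe); must contain at least
#'   the number of genes implied by `nProbesets` and `duplicateRate`.
#' @param moduleGenes optional fixed module gene symbols (must be in the
#'   universe and exclude the anchor); defaults to a random draw.
#' @param anchorGene anchor gene symbol.
#' @param withPhenotype attach the phenotype vector? (`FALSE` emulates a
#'   panel with expression only.)
#' @param label panel label.
#' @param seed integer seed.
#' @return list with elements `panel` (an [RIPanel-class]) and `truth`
#'   (a [GroundTruth-class]; `latentFactor(truth)$strain` holds `z`).
#' @export
#' @examples
#' sim <- simulateRIPanel(nStrains = 20, nProbesets = 300, seed = 1)
#' sim$panel
simulateRIPanel <- function(nStrains = 30,
                            nProbesets = 2000,
                            moduleSize = 50,
                            anchorLoading = 0.9,
                            phenoCoupling = 0.85,
                            duplicateRate = 0.05,
                            moduleNoiseSd = 0.5,
                            universe = NULL,
                            moduleGenes = NULL,
                            anchorGene = "Fyn",
                            withPhenotype = TRUE,
                            label = "synthetic RI panel",
                            seed = 1) {
  if (nStrains < 5) stop("an RI panel needs at least 5 strains")
  if (phenoCoupling < 0 || phenoCoupling > 1)
    stop("'phenoCoupling' must lie in [0, 1]")
  if (moduleSize >= nProbesets) stop("'moduleSize' must be < 'nProbesets'")
  if (anchorLoading < 0 || anchorLoading > 1)
    stop("'anchorLoading' must lie in [0, 1]")
  if (duplicateRate < 0 || duplicateRate >= 0.5)
    stop("'duplicateRate' must lie in [0, 0.5)")

  set.seed(as.integer(seed))
  nDup <- floor(duplicateRate * nProbesets)
  nGenes <- nProbesets - nDup
  if (is.null(universe)) {
    genes <- c(anchorGene, sprintf("G%05d", seq_len(nGenes - 1L)))
  } else {
    if (length(universe) < nGenes)
      stop("'universe' has fewer genes than this panel needs")
    ## anchor and any fixed module genes must make it onto the panel
    required <- unique(c(anchorGene, moduleGenes))
    if (length(required) > nGenes)
      stop("more required genes than the panel can carry")
    genes <- unique(c(required, setdiff(universe, required)))[seq_len(nGenes)]
  }
  dupGenes <- sample(setdiff(genes, anchorGene), nDup)
  geneOfProbe <- c(genes, dupGenes)
  probesets <- sprintf("RPS%05d", seq_along(geneOfProbe))
  map <- data.frame(probeset = probesets, gene = geneOfProbe,
                    stringsAsFactors = FALSE)

  if (is.null(moduleGenes)) {
    moduleGenes <- sample(setdiff(genes, anchorGene), moduleSize)
  } else {
    if (anchorGene %in% moduleGenes)
      stop("'moduleGenes' must not contain the anchor gene")
    if (!all(moduleGenes %in% genes))
      stop("'moduleGenes' must be drawn from the panel's gene universe")
  }

  strains <- sprintf("STR%03d", seq_len(nStrains))
  z <- rnorm(nStrains)
  baseline <- runif(length(probesets), 6, 12)

  expr <- matrix(rnorm(length(probesets) * nStrains, sd = 0.75),
                 nrow = length(probesets), ncol = nStrains,
                 dimnames = list(probesets, strains))
  isMod <- geneOfProbe %in% moduleGenes
  nModPs <- sum(isMod)
  if (nModPs > 0) {
    load <- runif(nModPs, 0.5, 1)
    expr[isMod, ] <- outer(load, z) +
      matrix(rnorm(nModPs * nStrains, sd = moduleNoiseSd), nModPs, nStrains)
  }
  anchorPs <- probesets[match(anchorGene, geneOfProbe)]
  expr[anchorPs, ] <- anchorLoading * z +
    sqrt(1 - anchorLoading^2) * rnorm(nStrains)
  expr <- expr + baseline

  pheno <- numeric()
  if (withPhenotype) {
    zs <- as.vector(scale(z))
    pheno <- setNames(
      phenoCoupling * zs + sqrt(1 - phenoCoupling^2) * rnorm(nStrains),
      strains)
  }

  panel <- new("RIPanel", exprs = expr, map = map, phenotype = pheno,
               label = label)
  truth <- new("GroundTruth",
               deProbesets = list(),
               moduleProbesets = probesets[isMod],
               moduleGenes = moduleGenes,
               anchorProbeset = anchorPs,
               anchorGene = anchorGene,
               latent = list(strain = setNames(z, strains)),
               plantedRho = phenoCoupling)
  list(panel = panel, truth = truth)
}
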
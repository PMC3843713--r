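## End-to-end pipeline on synthetic data: simulate -> S-scores -> SAM ->
## clustering -> ORA -> RI panels -> correlation screens -> strict
## intersection -> network -> eigengene -> manifest.  Every stage's outputs
## land on disk under `outdir`, and a JSON manifest records seeds,
## thresholds, headline numbers and md5 hashes of every artifact; the
## manifest contains no timestamps, so identical configurations produce
## bit-identical manifests.

#' Default pipeline configuration
#'
#' Returns the full configuration list for [runPipeline()], with every
#' threshold of the analysis chain (composite score floor 1.5, median-FDR
#' cap 5%, set-based ORA at 5% FDR with set sizes 3-300, score-threshold
#' ORA at 10% FDR, correlation screens at p <= 0.01, k = 12 clusters) and
#' the synthetic-data study conditions (3 replicates per group, 3 regions,
#' a 50-gene module, RI panels of 30 and 42 strains, phenotype coupling
#' 0.85).  Any element can be overridden via `...`.
#'
#' @param seed master seed; per-stage substreams are derived from it.
#' @param outdir output directory for all artifacts.
#' @param ... named overrides of any default element.
#' @return named configuration list.
#' @export
pipelineConfig <- function(seed = 1, outdir = tempfile("anchornet_run_"),
                           ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    quiet = FALSE,
    anchorGene = "Fyn",
    ## knockout experiment
    nProbesets = 4000, nReplicates = 3,
    regions = c("NAC", "PFC", "VMB"),
    nDE = 100, effectSize = 3, moduleSize = 50,
    moduleRegions = c("NAC", "PFC"), noiseSd = 0.25,
    ## RI panels
    nPanelProbesets = 2000, nStrainsA = 30, nStrainsB = 42,
    anchorLoading = 0.9, phenoCoupling = 0.85, duplicateRate = 0.05,
    ## thresholds
    scoreFloor = 1.5, fdrCap = 0.05,
    oraFdr = 0.05, thresholdOraFdr = 0.10,
    minSetSize = 3, maxSetSize = 300,
    alpha = 0.01, k = 12,
    networkRegion = "PFC")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$scoreFloor >= 0, cfg$fdrCap >= 0, cfg$fdrCap <= 1,
            cfg$alpha > 0, cfg$alpha <= 1, cfg$k >= 1,
            cfg$minSetSize <= cfg$maxSetSize,
            cfg$networkRegion %in% cfg$regions)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration overrides.
#' @param ... further overrides taking precedence over the file.
#' @return configuration list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, c(y, list(...)))
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate, sscore, sam, cluster, ora, panels, screen, intersect,
#' network and eigengene stages in order, writing each stage's artifacts
#' under `config$outdir` and a `manifest.json` that records the seed,
#' thresholds, per-stage status, headline numbers (core gene count, module
#' recovery, eigengene-phenotype correlation) and md5 hashes of every file.
#' A stage failure aborts with the stage name and cause.
#'
#' @param config configuration list from [pipelineConfig()] (or a path to a
#'   YAML file of overrides).
#' @return invisibly, a list with the key in-memory objects (`ko`, `panels`,
#'   `screens`, `core`, `network`, `eigengene`, `pc1Corr`) and the
#'   `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(cfg$outdir, ...)
  stages <- character()
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    .logMsg("[%s] starting", name, quiet = cfg$quiet)
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .logMsg("[%s] done (%.1fs elapsed)", name,
            proc.time()[["elapsed"]] - t0, quiet = cfg$quiet)
    stages <<- c(stages, name)
    res
  }

  ## -- simulate ------------------------------------------------------------
  ko <- stage("simulate", {
    sim <- simulateKOExperiment(
      nProbesets = cfg$nProbesets, nReplicates = cfg$nReplicates,
      regions = cfg$regions, nDE = cfg$nDE, effectSize = cfg$effectSize,
      moduleSize = cfg$moduleSize, moduleRegions = cfg$moduleRegions,
      noiseSd = cfg$noiseSd, anchorGene = cfg$anchorGene,
      seed = .subSeed(cfg$seed, 1))
    writeExpressionTSV(SummarizedExperiment::assay(sim$se, "exprs"),
                       outfile("ko_expression.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
    write.table(cbind(sample = rownames(cd), cd), outfile("ko_samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeGroundTruth(sim$truth, outfile("ko_truth.json"))
    sim
  })
  genes <- SummarizedExperiment::rowData(ko$se)$gene
  geneOf <- setNames(genes, rownames(ko$se))

  ## planted + decoy gene sets for the ORA stage
  gmt <- stage("genesets", {
    set.seed(.subSeed(cfg$seed, 2))
    decoys <- lapply(seq_len(20), function(i)
      sample(genes, sample(10:50, 1)))
    names(decoys) <- sprintf("DECOY_%02d", seq_along(decoys))
    planted <- if (length(ko$truth@moduleGenes))
      list(PLANTED_MODULE = ko$truth@moduleGenes) else list()
    gs <- geneSetList(c(planted, decoys), source = "planted")
    writeGMT(gs, outfile("planted_sets.gmt"))
    gs
  })

  ## -- sscore --------------------------------------------------------------
  contrasts <- list(basal = c("KO.Sal", "CTL.Sal"),
                    etohCTL = c("CTL.EtOH", "CTL.Sal"),
                    etohKO = c("KO.EtOH", "KO.Sal"))
  tables <- stage("sscore", {
    tl <- list()
    for (rg in cfg$regions) for (cn in names(contrasts)) {
      tb <- sscoreContrast(ko$se, rg, contrasts[[cn]][1], contrasts[[cn]][2],
                           contrast = cn)
      writeSScoreTable(tb, outfile(sprintf("sscore_%s_%s.tsv", rg, cn)))
      tl[[paste(rg, cn, sep = ".")]] <- tb
    }
    tl
  })

  ## -- sam -----------------------------------------------------------------
  sams <- stage("sam", {
    sl <- list()
    for (nm in names(tables)) {
      sr <- suppressWarnings(oneClassSAM(
        tables[[nm]], scoreFloor = cfg$scoreFloor, fdrCap = cfg$fdrCap,
        seed = .subSeed(cfg$seed, 3)))
      writeSamResult(sr, outfile(sprintf("sam_oneclass_%s.tsv", nm)))
      sl[[nm]] <- sr
    }
    for (rg in cfg$regions) {
      sr <- suppressWarnings(twoClassSAM(
        tables[[paste(rg, "etohKO", sep = ".")]],
        tables[[paste(rg, "etohCTL", sep = ".")]],
        scoreFloor = cfg$scoreFloor, fdrCap = cfg$fdrCap,
        seed = .subSeed(cfg$seed, 4)))
      writeSamResult(sr, outfile(sprintf("sam_twoclass_%s.tsv", rg)))
      sl[[paste(rg, "etoh2class", sep = ".")]] <- sr
    }
    sl
  })

  ## -- cluster -------------------------------------------------------------
  clusters <- stage("cluster", {
    if (!length(unique(unlist(lapply(sams, passSet))))) {
      ## nothing significant anywhere (e.g. a null configuration)
      write.table(data.frame(probeset = character(), cluster = integer()),
                  outfile("clusters.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      NULL
    } else {
      pm <- assemblePatterns(sams, tables)
      kEff <- min(cfg$k, nrow(patternValues(pm)))
      cl <- clusterPatterns(pm, k = kEff, seed = .subSeed(cfg$seed, 5))
      write.table(data.frame(probeset = names(cl$cluster),
                             cluster = unname(cl$cluster)),
                  outfile("clusters.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      cl
    }
  })

  ## -- ora -----------------------------------------------------------------
  ora <- stage("ora", {
    res <- list()
    for (rg in cfg$regions) {
      basal <- sams[[paste(rg, "basal", sep = ".")]]
      queryGenes <- unique(geneOf[passSet(basal)])
      hg <- hypergeomORA(queryGenes, gmt, genes, minSize = cfg$minSetSize,
                         maxSize = cfg$maxSetSize, fdr = cfg$oraFdr)
      write.table(oraTable(hg), outfile(sprintf("ora_hypergeom_%s.tsv", rg)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      meanScores <- rowMeans(scoreMatrix(tables[[paste(rg, "basal", sep = ".")]]))
      th <- thresholdORA(meanScores,
                         data.frame(probeset = names(geneOf),
                                    gene = unname(geneOf)),
                         gmt, scoreThreshold = cfg$scoreFloor,
                         fdr = cfg$thresholdOraFdr,
                         minSize = cfg$minSetSize, maxSize = cfg$maxSetSize)
      write.table(oraTable(th), outfile(sprintf("ora_threshold_%s.tsv", rg)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res[[rg]] <- list(hypergeom = hg, threshold = th)
    }
    res
  })

  ## -- panels --------------------------------------------------------------
  panels <- stage("panels", {
    pa <- simulateRIPanel(
      nStrains = cfg$nStrainsA, nProbesets = cfg$nPanelProbesets,
      moduleSize = cfg$moduleSize, anchorLoading = cfg$anchorLoading,
      phenoCoupling = cfg$phenoCoupling, duplicateRate = cfg$duplicateRate,
      universe = genes, moduleGenes = ko$truth@moduleGenes,
      anchorGene = cfg$anchorGene, withPhenotype = TRUE,
      label = "panelA", seed = .subSeed(cfg$seed, 6))
    pb <- simulateRIPanel(
      nStrains = cfg$nStrainsB, nProbesets = cfg$nPanelProbesets,
      moduleSize = cfg$moduleSize, anchorLoading = cfg$anchorLoading,
      phenoCoupling = cfg$phenoCoupling, duplicateRate = cfg$duplicateRate,
      universe = genes, moduleGenes = ko$truth@moduleGenes,
      anchorGene = cfg$anchorGene, withPhenotype = FALSE,
      label = "panelB", seed = .subSeed(cfg$seed, 7))
    for (p in list(pa, pb)) {
      lb <- p$panel@label
      writeExpressionTSV(panelExprs(p$panel),
                         outfile(sprintf("%s_expression.tsv", lb)))
      write.table(probeGeneMap(p$panel),
                  outfile(sprintf("%s_map.tsv", lb)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writePhenotypeTSV(phenotype(pa$panel), outfile("panelA_phenotype.tsv"))
    list(A = pa, B = pb)
  })

  ## -- screens -------------------------------------------------------------
  screens <- stage("screens", {
    sA <- anchorScreen(panels$A$panel, cfg$anchorGene, alpha = cfg$alpha)
    sB <- anchorScreen(panels$B$panel, cfg$anchorGene, alpha = cfg$alpha)
    sP <- phenotypeScreen(panels$A$panel, alpha = cfg$alpha)
    write.table(screenRecords(sA), outfile("screen_anchor_panelA.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(screenRecords(sB), outfile("screen_anchor_panelB.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(screenRecords(sP), outfile("screen_phenotype_panelA.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(anchorA = sA, anchorB = sB, phenoA = sP)
  })

  ## -- intersect -----------------------------------------------------------
  basalNet <- sams[[paste(cfg$networkRegion, "basal", sep = ".")]]
  sourceLists <- list(
    koBasal = unique(unname(geneOf[passSet(basalNet)])),
    anchorA = screenGenes(screens$anchorA),
    anchorB = screenGenes(screens$anchorB),
    phenoA = screenGenes(screens$phenoA))
  core <- stage("intersect", {
    co <- intersectLists(sourceLists, mode = "strict",
                         anchorGene = cfg$anchorGene)
    writeLines(co, outfile("core_genes.txt"))
    co
  })

  ## -- network -------------------------------------------------------------
  network <- stage("network", {
    nw <- buildNetwork(core, panels$A$panel, alpha = cfg$alpha,
                       anchorGene = cfg$anchorGene, provenance = sourceLists)
    writeSIF(nw, outfile("network.sif"))
    writeGraphML(nw, outfile("network.graphml"))
    write.table(networkNodes(nw), outfile("network_nodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    nw
  })

  ## -- eigengene -----------------------------------------------------------
  eigRes <- stage("eigengene", {
    nd <- networkNodes(network)
    if (sum(nd$inPanel) < 2) {
      ## degenerate core (null configuration): no eigengene to compute
      write.table(data.frame(strain = character(), pc1 = numeric()),
                  outfile("eigengene.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(eig = NULL, corr = list(r = NA_real_, absR = NA_real_,
                                   n = NA_integer_, p = NA_real_))
    } else {
      eig <- networkPC1(panels$A$panel, nd$gene[nd$inPanel])
      write.table(data.frame(strain = names(eigengeneScores(eig)),
                             pc1 = unname(eigengeneScores(eig))),
                  outfile("eigengene.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(eig = eig, corr = pc1PhenotypeCorr(eig, phenotype(panels$A$panel)))
    }
  })

  ## -- manifest ------------------------------------------------------------
  moduleRecovery <-
    length(intersect(.normSym(ko$truth@moduleGenes), core)) /
    max(1, length(ko$truth@moduleGenes))
  files <- sort(setdiff(list.files(cfg$outdir), "manifest.json"))
  hashes <- unname(tools::md5sum(file.path(cfg$outdir, files)))
  manifest <- list(
    package = "anchornet",
    version = as.character(utils::packageVersion("anchornet")),
    seed = cfg$seed,
    thresholds = cfg[c("scoreFloor", "fdrCap", "oraFdr", "thresholdOraFdr",
                       "minSetSize", "maxSetSize", "alpha", "k")],
    stages = setNames(as.list(rep("ok", length(stages))), stages),
    headline = list(
      coreGeneCount = length(core),
      networkEdges = nrow(networkEdges(network)),
      moduleRecovery = moduleRecovery,
      pc1VarianceExplained = if (is.null(eigRes$eig)) NA_real_
                             else varianceExplained(eigRes$eig),
      pc1PhenotypeR = eigRes$corr$r,
      pc1PhenotypeAbsR = eigRes$corr$absR,
      pc1PhenotypeP = eigRes$corr$p,
      pc1PhenotypeN = eigRes$corr$n),
    files = setNames(as.list(hashes), files))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .logMsg("pipeline complete: %d core genes, |r| = %.3f (p = %.3g)",
          length(core), eigRes$corr$absR, eigRes$corr$p, quiet = cfg$quiet)

  invisible(list(config = cfg, ko = ko, geneSets = gmt, tables = tables,
                 sams = sams, clusters = clusters, ora = ora,
                 panels = panels, screens = screens,
                 sourceLists = sourceLists, core = core, network = network,
                 eigengene = eigRes$eig, pc1Corr = eigRes$corr,
                 manifest = manifest))
}
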
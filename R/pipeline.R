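# End-to-end orchestration: synthetic data or TSV inputs -> normalization
# and DGE -> per-library-type modules (both presets) -> cliques ->
# within-module causal graphs -> edge-level GxE tests -> ASE.

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: RLE normalization and
#' the log2(count + 1) transform; expression filter at > 10 samples and
#' replicate-variance filter at 0.1; DGE FDR 0.05 (main effects) and 0.1
#' (GxE); soft power 5 with TOM scaling to the Bd21d reference at the 0.95
#' quantile; the moderate/conservative cut presets; clique cutoff 1e-12;
#' causal inference on conservative modules passing the
#' 70%-of-observational-samples gate with 100 half-subsamples (majority
#' retention; the 0.95/0.97 frequency-quantile rule is available as
#' `retention = "quantile"`); edge tests at R^2 > 0.5 and alpha 0.05
#' uncorrected; ASE at P < 0.1 uncorrected.
#'
#' @return Nested list of parameters, ready to edit or serialize as YAML.
#' @examples
#' str(defaultPipelineConfig(), max.level = 2)
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outputDir = "gxenet-run",
    simulate = list(scenario = "gxe", nReps = 48L),
    input = list(countsFile = NULL, designFile = NULL, traitFile = NULL,
                 aseCountsFile = NULL, aseDesignFile = NULL),
    preprocess = list(minSamplesExpressed = 10L, minVariance = 0.1,
                      fdrMain = 0.05, fdrGxe = 0.1),
    coexpression = list(softPower = 5L, referenceLibraryType = "Bd21d",
                        scaleQuantile = 0.95,
                        presets = c("moderate", "conservative")),
    cliques = list(pCutoff = 1e-12),
    causal = list(nSubsamples = 100L, subsampleFraction = 0.5,
                  retention = "fixed", fixedThreshold = 0.5,
                  freqQuantile = 0.95, freqQuantileLarge = 0.97,
                  largeModuleSize = 70L, alpha = 0.05, alphaInv = 0.05,
                  observational = "source", maxModules = NULL),
    edge = list(r2Threshold = 0.5, alpha = 0.05),
    ase = list(alpha = 0.1)
  )
}

# deep-merge user config over defaults
#' @keywords internal
#' @noRd
.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Executes, from one configuration: data acquisition (synthetic scenario
#' or TSV inputs), normalization and filtering, DGE with GxE response
#' classes, per-library-type coexpression modules under both cut presets
#' (TOMs quantile-scaled to the reference library type), cross-condition
#' clique construction and classification, DGE enrichment and trait
#' correlations, stability-selected causal graphs for eligible
#' conservative modules, edge-level GxE tests, and ASE classification when
#' allele data are present. Stage outputs are written as TSV under
#' `outputDir` together with a `manifest.json` recording every parameter
#' used; a rerun with the same configuration and seed is byte-identical.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]), or
#'   a path to a YAML file holding one; missing entries take defaults.
#' @return (Invisibly) a list with all in-memory stage results.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(cfg$outputDir, paste0(...))
  seed <- as.integer(cfg$seed)
  res <- list(config = cfg)

  # ---- data ----
  truth <- NULL
  if (!is.null(cfg$input$countsFile)) {
    x <- readCountsTsv(cfg$input$countsFile, cfg$input$designFile)
  } else {
    sc <- makeScenario(cfg$simulate$scenario,
                       nReps = cfg$simulate$nReps,
                       seed = .deriveSeed(seed, 1L))
    truth <- sc$truth
    x <- simulateCounts(truth, sc$design, seed = .deriveSeed(seed, 2L))
    writeCountsTsv(x, outfile("counts.tsv"), outfile("design.tsv"))
    writeGroundTruthJson(truth, outfile("ground_truth.json"))
  }

  # ---- preprocess ----
  x <- normalizeLog2(x)
  norm <- SummarizedExperiment::assay(x, "normalized")
  utils::write.table(
    data.frame(sample_id = colnames(x), size_factor = x$sizeFactor),
    outfile("size_factors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  filt <- filterGenes(x, cfg$preprocess$minSamplesExpressed,
                      cfg$preprocess$minVariance)
  dgeInt <- fitDge(x, "interaction", fdrMain = cfg$preprocess$fdrMain,
                   fdrGxe = cfg$preprocess$fdrGxe)
  dgeStrat <- fitDge(x, "stratified-by-genotype",
                     fdrMain = cfg$preprocess$fdrMain)
  classes <- classifyGxeResponse(dgeInt, dgeStrat)
  utils::write.table(dgeInt, outfile("dge_interaction.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(classes, outfile("gxe_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$experiment <- x
  res$filter <- filt
  res$dge <- list(interaction = dgeInt, stratified = dgeStrat,
                  classes = classes)

  # ---- coexpression ----
  universe <- filt$universe
  lts <- intersect(.libraryTypes(), unique(x$libraryType))
  refLt <- cfg$coexpression$referenceLibraryType
  modules <- list()
  toms <- list()
  for (lt in lts) {
    genes <- intersect(universe, rownames(norm))
    v <- norm[genes, x$libraryType == lt, drop = FALSE]
    toms[[lt]] <- buildTom(v, softPower = cfg$coexpression$softPower,
                           libraryType = lt)
  }
  if (refLt %in% lts)
    for (lt in setdiff(lts, refLt))
      toms[[lt]] <- scaleTom(toms[[lt]], toms[[refLt]],
                             cfg$coexpression$scaleQuantile)
  for (preset in cfg$coexpression$presets) {
    modules[[preset]] <- list()
    for (lt in lts) {
      v <- norm[rownames(toms[[lt]]$tom), x$libraryType == lt,
                drop = FALSE]
      ms <- detectModules(toms[[lt]], v, preset = preset)
      modules[[preset]][[lt]] <- ms
      writeModuleSetTsv(ms, outfile("modules_", preset, "_",
                                    gsub("-", "", lt), ".tsv"),
                        outfile("eigengenes_", preset, "_",
                                gsub("-", "", lt), ".tsv"))
    }
  }
  res$modules <- modules

  # ---- module comparison ----
  cliques <- NULL
  if (all(c("moderate", "conservative") %in% names(modules))) {
    cliques <- buildCliques(modules$moderate, modules$conservative,
                            universe, cfg$cliques$pCutoff)
    utils::write.table(cliqueTable(cliques), outfile("cliques.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cliques@edges, outfile("clique_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$cliques <- cliques
  }

  # DGE enrichment of conservative modules
  enrich <- NULL
  gxeGenes <- dgeInt$gene[dgeInt$sig_gxe]
  dgeClasses <- list(G = dgeInt$gene[dgeInt$sig_genotype],
                     E = dgeInt$gene[dgeInt$sig_treatment],
                     GxE = gxeGenes)
  for (lt in names(modules$conservative)) {
    sets <- moduleGeneSets(modules$conservative[[lt]])
    for (m in names(sets)) for (cl in names(dgeClasses)) {
      en <- tryCatch(dgeEnrichment(sets[[m]], dgeClasses[[cl]], universe),
                     error = function(e) NULL)
      if (is.null(en)) next
      enrich <- rbind(enrich, data.frame(
        library_type = lt, module = m, class = cl, p = en$p,
        fraction = en$fraction, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(enrich))
    utils::write.table(enrich, outfile("dge_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  res$enrichment <- enrich

  # ---- trait ----
  traits <- NULL
  if (!is.null(cfg$input$traitFile)) {
    traits <- utils::read.delim(cfg$input$traitFile,
                                stringsAsFactors = FALSE)
  } else if (!is.null(truth) && nrow(truth@traitLoadings)) {
    traits <- simulateTrait(truth, norm, seed = .deriveSeed(seed, 3L))
    utils::write.table(traits, outfile("traits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(traits)) {
    tcor <- NULL
    for (lt in names(modules$moderate)) {
      ms <- modules$moderate[[lt]]
      if (!ncol(eigengenes(ms))) next
      tc <- tryCatch(
        moduleTraitCorrelation(ms, traits[traits$sample_id %in%
                                            rownames(eigengenes(ms)), ]),
        error = function(e) NULL)
      tcor <- rbind(tcor, tc)
    }
    if (!is.null(tcor))
      utils::write.table(tcor, outfile("trait_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    res$traitCorrelations <- tcor
  }

  # ---- causal inference on eligible conservative modules ----
  graphs <- list()
  edgeResults <- NULL
  causalEdges <- NULL
  ccfg <- cfg$causal
  design <- data.frame(sample_id = colnames(x),
                       genotype = x$genotype, treatment = x$treatment,
                       library_type = x$libraryType,
                       stringsAsFactors = FALSE)
  fitted <- 0L
  for (lt in names(modules$conservative)) {
    sets <- moduleGeneSets(modules$conservative[[lt]])
    nLt <- sum(x$libraryType == lt)
    cap <- 0.7 * floor(ccfg$subsampleFraction * nLt)
    for (m in names(sets)) {
      if (!is.null(ccfg$maxModules) && fitted >= ccfg$maxModules) break
      genes <- sets[[m]]
      if (length(genes) > cap) next
      quant <- if (length(genes) > ccfg$largeModuleSize)
        ccfg$freqQuantileLarge else ccfg$freqQuantile
      obsLt <- if (identical(ccfg$observational, "pooled")) NULL else lt
      modId <- paste0(gsub("-", "", lt), m)
      cg <- tryCatch(stabilitySelect(
        norm[genes, , drop = FALSE], design, obsLt,
        nSubsamples = ccfg$nSubsamples,
        subsampleFraction = ccfg$subsampleFraction,
        retention = ccfg$retention,
        fixedThreshold = ccfg$fixedThreshold, freqQuantile = quant,
        alpha = ccfg$alpha, alphaInv = ccfg$alphaInv,
        moduleId = modId, seed = .deriveSeed(seed, 100L + fitted)),
        error = function(e) NULL)
      if (is.null(cg)) next
      fitted <- fitted + 1L
      graphs[[modId]] <- cg
      e <- graphEdges(cg)
      if (nrow(e))
        causalEdges <- rbind(causalEdges, cbind(
          module = modId, library_type = lt, e,
          stringsAsFactors = FALSE))
      # ---- edge-level GxE tests ----
      et <- tryCatch(edgeTests(cg, norm, design,
                               r2Threshold = cfg$edge$r2Threshold,
                               alpha = cfg$edge$alpha),
                     error = function(e) NULL)
      if (!is.null(et) && nrow(et))
        edgeResults <- rbind(edgeResults,
                             cbind(module = modId, et,
                                   stringsAsFactors = FALSE))
    }
  }
  if (!is.null(causalEdges))
    utils::write.table(causalEdges, outfile("causal_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(edgeResults))
    utils::write.table(edgeResults, outfile("edge_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  res$graphs <- graphs
  res$edgeTests <- edgeResults

  # ---- ASE (optional) ----
  if (!is.null(cfg$input$aseCountsFile)) {
    aseCounts <- utils::read.delim(cfg$input$aseCountsFile,
                                   stringsAsFactors = FALSE)
    aseDesign <- utils::read.delim(cfg$input$aseDesignFile,
                                   stringsAsFactors = FALSE)
    aseRes <- aseAnalysis(aseCounts, aseDesign, alpha = cfg$ase$alpha)
    utils::write.table(aseRes, outfile("ase_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$ase <- aseRes
  }

  # ---- manifest ----
  manifest <- list(
    package = "gxenet",
    version = as.character(utils::packageVersion("gxenet")),
    seed = seed,
    parameters = cfg[setdiff(names(cfg), "outputDir")],
    stages = c("preprocess", "coexpression", "module_comparison",
               if (length(graphs)) "causal_inference",
               if (!is.null(edgeResults)) "edge_gxe",
               if (!is.null(res$ase)) "ase"),
    outputs = sort(list.files(cfg$outputDir))
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
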
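# Synthetic-data generators with planted G/E/GxE structure.
#
# The generative model is a log2-scale linear Gaussian structural equation
# model (SEM) with a negative-binomial observation layer: every downstream
# method in the package (correlation modules, partial-correlation CI tests,
# OLS edge regressions on log2 counts) assumes approximately linear-Gaussian
# structure on that scale, so planted truth and fitted models share
# coordinates. Condition-dependent edge weights are parameterized as
# w0 + wg*g + we*e + wge*g*e, the same coordinates as the edge-level
# regression.

#' Balanced two-genotype x two-treatment design
#'
#' Creates a balanced design with `nRepsPerCondition` replicates in each of
#' the four library types (Bd21 control/drought, Bd3-1 control/drought).
#'
#' @param nRepsPerCondition replicates per library type; at least 2
#'   (downstream regressions need residual degrees of freedom).
#' @param seed integer seed; the design is deterministic given the seed.
#' @return data.frame with columns `sample_id`, `genotype` (0 = Bd21,
#'   1 = Bd3-1), `treatment` (0 = control, 1 = drought) and `library_type`.
#' @examples
#' d <- makeDesign(3, seed = 1)
#' table(d$library_type)
#' @export
makeDesign <- function(nRepsPerCondition, seed = 1L) {
  .assertScalarNumber(nRepsPerCondition, "nRepsPerCondition", min = 2)
  n <- as.integer(nRepsPerCondition)
  grid <- expand.grid(rep = seq_len(n), genotype = 0:1, treatment = 0:1,
                      KEEP.OUT.ATTRS = FALSE)
  lt <- libraryTypeLabel(grid$genotype, grid$treatment)
  data.frame(
    sample_id = sprintf("%s_r%02d", gsub("-", "", lt), grid$rep),
    genotype = grid$genotype,
    treatment = grid$treatment,
    library_type = lt,
    stringsAsFactors = FALSE
  )
}

#' Assemble a GroundTruth object
#'
#' @param moduleAssignment named integer vector, gene -> module id
#'   (0 = unassigned background gene).
#' @param dagEdges data.frame `parent`, `child`, `w0`, `wg`, `we`, `wge`
#'   (missing weight columns default to 0); must be acyclic and stay within
#'   modules.
#' @param meanEffects data.frame `gene`, `b0`, `bg`, `be`, `bge`, `sigma`;
#'   genes not listed get `b0 = baselineLog2`, zero shifts and
#'   `sigma = defaultSigma`.
#' @param sigmaOverride data.frame `gene`, `g`, `e`, `sigma`: per-condition
#'   residual-sd overrides (used to plant module absence by silencing a
#'   driver in some conditions).
#' @param traitLoadings data.frame `trait`, `module`, `coupling`, `noiseSd`.
#' @param aseMode named character vector, gene -> allelic architecture in
#'   `cis`, `trans`, `cisxE`, `transxE`, `none`.
#' @param aseEffect named numeric, log2 allelic effect sizes; genes in
#'   `aseMode` not listed get 1.
#' @param baselineLog2 default log2 expression level of an average gene.
#' @param defaultSigma default residual sd of the structural equations
#'   (log2 units).
#' @return A validated [GroundTruth-class] object.
#' @examples
#' ma <- c(gA = 1L, gB = 1L, gC = 0L)
#' tr <- makeGroundTruth(ma, dagEdges = data.frame(parent = "gA",
#'   child = "gB", w0 = 1))
#' tr
#' @export
makeGroundTruth <- function(moduleAssignment,
                            dagEdges = NULL,
                            meanEffects = NULL,
                            sigmaOverride = NULL,
                            traitLoadings = NULL,
                            aseMode = NULL,
                            aseEffect = NULL,
                            baselineLog2 = 7,
                            defaultSigma = 0.5) {
  stopifnot(!is.null(names(moduleAssignment)))
  genes <- names(moduleAssignment)
  if (is.null(dagEdges))
    dagEdges <- data.frame(parent = character(), child = character(),
                           w0 = numeric(), wg = numeric(), we = numeric(),
                           wge = numeric())
  for (w in c("w0", "wg", "we", "wge"))
    if (is.null(dagEdges[[w]])) dagEdges[[w]] <- 0
  me <- data.frame(gene = genes, b0 = baselineLog2, bg = 0, be = 0, bge = 0,
                   sigma = defaultSigma, stringsAsFactors = FALSE)
  rownames(me) <- genes
  if (!is.null(meanEffects)) {
    stopifnot(all(meanEffects$gene %in% genes))
    for (col in intersect(colnames(meanEffects),
                          c("b0", "bg", "be", "bge", "sigma")))
      me[meanEffects$gene, col] <- meanEffects[[col]]
  }
  if (is.null(sigmaOverride))
    sigmaOverride <- data.frame(gene = character(), g = integer(),
                                e = integer(), sigma = numeric())
  if (is.null(traitLoadings))
    traitLoadings <- data.frame(trait = character(), module = integer(),
                                coupling = numeric(), noiseSd = numeric())
  if (is.null(aseMode)) aseMode <- stats::setNames(character(), character())
  ae <- stats::setNames(rep(1, length(aseMode)), names(aseMode))
  if (!is.null(aseEffect)) ae[names(aseEffect)] <- aseEffect
  methods::new("GroundTruth",
               moduleAssignment = stats::setNames(
                 as.integer(moduleAssignment), genes),
               dagEdges = dagEdges,
               meanEffects = me,
               sigmaOverride = sigmaOverride,
               traitLoadings = traitLoadings,
               aseMode = aseMode,
               aseEffect = ae)
}

# residual sd per gene per sample given condition overrides
#' @keywords internal
#' @noRd
.sigmaMatrix <- function(truth, design) {
  genes <- names(truth@moduleAssignment)
  sig <- matrix(truth@meanEffects[genes, "sigma"],
                nrow = length(genes), ncol = nrow(design),
                dimnames = list(genes, design$sample_id))
  ov <- truth@sigmaOverride
  if (nrow(ov)) {
    for (k in seq_len(nrow(ov))) {
      j <- design$genotype == ov$g[k] & design$treatment == ov$e[k]
      sig[ov$gene[k], j] <- ov$sigma[k]
    }
  }
  sig
}

#' Simulate counts from the planted structural equation model
#'
#' Latent log2 expression is drawn per sample from the linear SEM
#' `x_child = intercept(g, e) + sum_parents (w0 + wg g + we e + wge g e)
#' x_parent + noise`, evaluated in topological order; counts are drawn
#' negative-binomial with mean `2^x` scaled by a per-sample log-normal size
#' factor. Noise is drawn per gene in lexicographic gene order, so the
#' result is invariant to the order in which genes or edges are listed in
#' the truth object.
#'
#' @param truth a [GroundTruth-class] object.
#' @param design a design from [makeDesign()].
#' @param nbDispersion negative-binomial dispersion (1/size); 0.05 models
#'   moderate biological noise.
#' @param libSizeCv coefficient of variation of the log-normal per-sample
#'   size factors.
#' @param seed integer seed; output is bit-reproducible given
#'   (parameters, seed).
#' @return A [GxEExperiment-class] with assay `"counts"`; the truth object
#'   is stored in `metadata(x)$groundTruth` and the latent log2 matrix in
#'   `metadata(x)$latent`.
#' @examples
#' sc <- makeScenario("null", nReps = 3, nGenes = 20, seed = 1)
#' x <- simulateCounts(sc$truth, sc$design, seed = 1)
#' dim(x)
#' @export
simulateCounts <- function(truth, design, nbDispersion = 0.05,
                           libSizeCv = 0.2, seed = 1L) {
  methods::validObject(truth)
  .assertScalarNumber(nbDispersion, "nbDispersion", min = 0, strict = TRUE)
  .assertScalarNumber(libSizeCv, "libSizeCv", min = 0)
  genes <- names(truth@moduleAssignment)
  ord <- order(genes)
  n <- nrow(design)
  g <- design$genotype
  e <- design$treatment

  set.seed(seed)
  # per-variable standard-normal noise, drawn in sorted gene order
  noise <- matrix(NA_real_, length(genes), n,
                  dimnames = list(genes, design$sample_id))
  for (gn in genes[ord]) noise[gn, ] <- stats::rnorm(n)
  sf <- if (libSizeCv > 0) {
    s <- stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + libSizeCv^2)))
    s / exp(mean(log(s)))
  } else rep(1, n)

  sig <- .sigmaMatrix(truth, design)
  me <- truth@meanEffects[genes, ]
  intercept <- outer(me$b0, rep(1, n)) + outer(me$bg, g) + outer(me$be, e) +
    outer(me$bge, g * e)
  dimnames(intercept) <- list(genes, design$sample_id)

  x <- intercept + sig * noise
  ed <- truth@dagEdges
  if (nrow(ed)) {
    dg <- igraph::graph_from_data_frame(ed[, c("parent", "child")],
                                        directed = TRUE,
                                        vertices = genes)
    topo <- names(igraph::topo_sort(dg))
    for (gn in topo) {
      pe <- ed[ed$child == gn, , drop = FALSE]
      if (!nrow(pe)) next
      pe <- pe[order(pe$parent), , drop = FALSE]  # edge-order invariance
      # parent contributions are centered at the parent's condition mean,
      # so edge weights shape the covariance while every gene's mean stays
      # at its planted baseline (uncentered propagation would push
      # strongly regulated genes to unrealistic expression levels)
      contrib <- 0
      for (k in seq_len(nrow(pe))) {
        w <- pe$w0[k] + pe$wg[k] * g + pe$we[k] * e + pe$wge[k] * g * e
        contrib <- contrib + w * (x[pe$parent[k], ] -
                                    intercept[pe$parent[k], ])
      }
      x[gn, ] <- intercept[gn, ] + contrib + sig[gn, ] * noise[gn, ]
    }
  }

  counts <- matrix(NA_integer_, length(genes), n,
                   dimnames = list(genes, design$sample_id))
  size <- 1 / nbDispersion
  for (gn in genes[ord]) {
    mu <- pmax(sf * 2^x[gn, ], 1e-8)
    counts[gn, ] <- stats::rnbinom(n, mu = mu, size = size)
  }
  res <- GxEExperiment(counts, design)
  S4Vectors::metadata(res)$groundTruth <- truth
  S4Vectors::metadata(res)$latent <- x
  S4Vectors::metadata(res)$trueSizeFactors <- sf
  res
}

#' Simulate quantitative traits coupled to module eigengenes
#'
#' Each trait in `traitLoadings(truth)` is `coupling * eigengene + noise`,
#' where the module eigengene is computed from the supplied normalized
#' expression and standardized to unit variance before coupling (so
#' `coupling` is in trait-sd-per-eigengene-sd units and the expected
#' trait-eigengene correlation is `coupling / sqrt(coupling^2 + noiseSd^2)`).
#'
#' @param truth a [GroundTruth-class] with at least one `traitLoadings` row.
#' @param expression normalized log2 matrix (genes x samples) or a
#'   [GxEExperiment-class] carrying a `"normalized"` assay.
#' @param seed integer seed.
#' @return data.frame with `sample_id` and one column per trait.
#' @export
simulateTrait <- function(truth, expression, seed = 1L) {
  if (methods::is(expression, "SummarizedExperiment"))
    expression <- SummarizedExperiment::assay(expression, "normalized")
  tl <- truth@traitLoadings
  if (!nrow(tl)) stop("truth has no trait loadings")
  ma <- truth@moduleAssignment
  set.seed(seed)
  out <- data.frame(sample_id = colnames(expression),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tl))) {
    mod <- tl$module[k]
    genes <- names(ma)[ma == mod]
    if (length(genes) < 2)
      stop("trait '", tl$trait[k], "' references module ", mod,
           " which is absent or has < 2 genes")
    eig <- computeEigengene(expression[genes, , drop = FALSE])$eigengene
    eig <- as.numeric(scale(eig))
    out[[tl$trait[k]]] <- tl$coupling[k] * eig +
      stats::rnorm(length(eig), 0, tl$noiseSd[k])
  }
  out
}

#' Design for an allele-specific-expression experiment
#'
#' F1 hybrid samples (generation 0, both alleles measured per sample) plus
#' parental samples of both accessions (generation 1), each under both
#' treatments.
#'
#' @param nRepsPerStratum replicates per (generation/accession x treatment)
#'   stratum.
#' @param seed integer seed (the design is deterministic).
#' @return data.frame with `sample_id`, `generation` (0 = F1, 1 = parent),
#'   `genotype` (parental accession; NA for F1) and `treatment`.
#' @examples
#' table(makeAseDesign(3)$generation)
#' @export
makeAseDesign <- function(nRepsPerStratum, seed = 1L) {
  .assertScalarNumber(nRepsPerStratum, "nRepsPerStratum", min = 2)
  n <- as.integer(nRepsPerStratum)
  f1 <- expand.grid(rep = seq_len(n), treatment = 0:1,
                    KEEP.OUT.ATTRS = FALSE)
  par <- expand.grid(rep = seq_len(n), genotype = 0:1, treatment = 0:1,
                     KEEP.OUT.ATTRS = FALSE)
  rbind(
    data.frame(sample_id = sprintf("F1_%s_r%02d",
                                   ifelse(f1$treatment == 0, "c", "d"),
                                   f1$rep),
               generation = 0L, genotype = NA_integer_,
               treatment = f1$treatment, stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("P%s_%s_r%02d",
                                   ifelse(par$genotype == 0, "Bd21", "Bd31"),
                                   ifelse(par$treatment == 0, "c", "d"),
                                   par$rep),
               generation = 1L, genotype = par$genotype,
               treatment = par$treatment, stringsAsFactors = FALSE)
  )
}

#' Simulate allele-resolved counts under planted cis/trans architectures
#'
#' Per gene and sample, allele-level log2 abundance follows the planted
#' architecture: `cis` adds `delta * A` in every generation (the allelic
#' imbalance persists in the shared F1 nucleus), `trans` adds
#' `delta * A * G` (parental accessions differ but F1 allele ratios are
#' balanced), `cisxE`/`transxE` gate the respective effect on drought
#' (`T = 1`), and `none` genes have no allelic effect. Counts are
#' negative-binomial around `2^q` with per-sample size factors; F1 samples
#' contribute both alleles, parental samples only their own allele.
#'
#' @param design an ASE design from [makeAseDesign()].
#' @param truth a [GroundTruth-class] with `aseMode` set for the
#'   allele-informative genes. Genes of the truth object without an
#'   `aseMode` entry are simulated as allele-indistinguishable background
#'   genes (one total-count row per sample, `allele = NA`); they carry no
#'   allelic signal but anchor the size-factor estimation, as in a real
#'   experiment where most genes have no diagnostic variant.
#' @param noiseSd residual sd of log2 allele abundance.
#' @param nbDispersion,libSizeCv observation-layer parameters as in
#'   [simulateCounts()].
#' @param seed integer seed.
#' @return Long-format data.frame: `gene`, `sample_id`, `allele` (0 = Bd21
#'   allele, 1 = Bd3-1 allele), `count`.
#' @export
simulateAse <- function(design, truth, noiseSd = 0.3, nbDispersion = 0.05,
                        libSizeCv = 0.2, seed = 1L) {
  modes <- truth@aseMode
  if (!length(modes)) stop("truth has no aseMode entries")
  hasF1 <- any(design$generation == 0 & design$treatment == 0) &&
    any(design$generation == 0 & design$treatment == 1)
  hasPar <- all(vapply(0:1, function(gg) {
    all(vapply(0:1, function(tt) {
      any(design$generation == 1 & design$genotype == gg &
            design$treatment == tt)
    }, logical(1)))
  }, logical(1)))
  if (!hasF1 || !hasPar)
    stop("design must contain F1 samples under both treatments and ",
         "parental samples of both accessions under both treatments: ",
         "the full ASE model is inestimable otherwise")

  genes <- names(modes)
  background <- setdiff(names(truth@moduleAssignment), genes)
  allGenes <- c(genes, background)
  ord <- order(allGenes)
  # one row per (sample, allele) observation
  obs <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    al <- if (design$generation[i] == 0L) 0:1 else design$genotype[i]
    data.frame(sample_id = design$sample_id[i],
               generation = design$generation[i],
               treatment = design$treatment[i], allele = al,
               stringsAsFactors = FALSE)
  }))
  me <- truth@meanEffects
  set.seed(seed)
  sfs <- if (libSizeCv > 0) {
    s <- stats::rlnorm(nrow(design), 0, sqrt(log(1 + libSizeCv^2)))
    stats::setNames(s / exp(mean(log(s))), design$sample_id)
  } else stats::setNames(rep(1, nrow(design)), design$sample_id)

  A <- obs$allele
  Tt <- obs$treatment
  G <- obs$generation
  size <- 1 / nbDispersion
  out <- vector("list", length(allGenes))
  names(out) <- allGenes
  for (gn in allGenes[ord]) {
    base <- (if (gn %in% rownames(me)) me[gn, "b0"] else 7) - 1
    bT <- if (gn %in% rownames(me)) me[gn, "be"] else 0
    if (gn %in% genes) {
      delta <- truth@aseEffect[[gn]]
      effect <- switch(modes[[gn]],
                       cis = delta * A,
                       trans = delta * A * G,
                       cisxE = delta * A * Tt,
                       transxE = delta * A * G * Tt,
                       none = 0)
      q <- base + bT * Tt + effect + stats::rnorm(nrow(obs), 0, noiseSd)
      mu <- pmax(sfs[obs$sample_id] * 2^q, 1e-8)
      out[[gn]] <- data.frame(gene = gn, sample_id = obs$sample_id,
                              allele = A,
                              count = stats::rnbinom(nrow(obs), mu = mu,
                                                     size = size),
                              stringsAsFactors = FALSE)
    } else {
      # allele-indistinguishable background gene: one total-count row per
      # sample (per-allele base + 1 restores the gene-level total)
      q <- base + 1 + bT * design$treatment +
        stats::rnorm(nrow(design), 0, noiseSd)
      mu <- pmax(sfs[design$sample_id] * 2^q, 1e-8)
      out[[gn]] <- data.frame(gene = gn, sample_id = design$sample_id,
                              allele = NA_integer_,
                              count = stats::rnbinom(nrow(design),
                                                     mu = mu, size = size),
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[allGenes])
  rownames(res) <- NULL
  res
}

#' Ready-made simulation scenarios
#'
#' Bundles a [GroundTruth-class] and design for the study conditions the
#' package is validated on:
#' \describe{
#'   \item{`gxe`}{Four planted 30-gene modules driven by shared latent
#'     drivers whose variance is silenced outside their active conditions:
#'     one conserved module, one Bd3-1-specific, one drought-specific, one
#'     present only in Bd21 drought. Background genes include planted
#'     G/E/GxE mean-shift genes, and a `glucose` trait is coupled to the
#'     drought-specific module.}
#'   \item{`null`}{Independent genes, no planted structure.}
#'   \item{`blocks`}{`nBlocks` independent driver-based modules of
#'     `blockSize` genes plus noise genes (planted-partition benchmark).}
#'   \item{`dag`}{One module holding a random `nNodes`-gene DAG with strong
#'     condition-independent weights (causal-recovery benchmark).}
#'   \item{`ase`}{100 allele-informative genes: 25 cis, 25 trans,
#'     25 cisxE, 25 none, effect 1 log2 unit.}
#' }
#'
#' @param name scenario name.
#' @param nReps replicates per library type (48 reproduces the study's
#'   subsampled depth).
#' @param nGenes,nNoise,nBlocks,blockSize,nNodes,edgeProb scenario-specific
#'   size knobs (see details above).
#' @param driverSigma sd of module driver genes when active; default 1 for
#'   the 50-gene `blocks` modules and 1.5 for the 30-gene `gxe` modules
#'   (smaller modules need a stronger shared factor for a comparable
#'   topological-overlap signature).
#' @param seed integer seed for the scenario's randomized parts (DAG
#'   topology, loadings).
#' @return list with elements `truth` ([GroundTruth-class]) and `design`
#'   (data.frame); the `ase` scenario instead returns `truth` and an ASE
#'   design from [makeAseDesign()].
#' @examples
#' sc <- makeScenario("blocks", nReps = 4, nBlocks = 2, blockSize = 10,
#'                    seed = 1)
#' table(sc$truth@moduleAssignment)
#' @export
makeScenario <- function(name = c("gxe", "null", "blocks", "dag", "ase"),
                         nReps = 48, nGenes = 200, nNoise = 80,
                         nBlocks = 4, blockSize = 50, nNodes = 8,
                         edgeProb = 0.3, driverSigma = NULL, seed = 1L) {
  name <- match.arg(name)
  if (is.null(driverSigma))
    driverSigma <- if (name == "gxe") 1.5 else 1
  set.seed(.deriveSeed(seed, 77L))
  if (name == "null") {
    genes <- sprintf("gene%04d", seq_len(nGenes))
    truth <- makeGroundTruth(stats::setNames(rep(0L, nGenes), genes))
    return(list(truth = truth, design = makeDesign(nReps, seed)))
  }
  if (name == "blocks") {
    perBlock <- blockSize
    genes <- c(sprintf("drv%02d", seq_len(nBlocks)),
               sprintf("blk%02d_g%03d",
                       rep(seq_len(nBlocks), each = perBlock - 1),
                       sequence(rep(perBlock - 1, nBlocks))),
               if (nNoise > 0) sprintf("noise%04d", seq_len(nNoise)))
    ma <- stats::setNames(c(seq_len(nBlocks),
                            rep(seq_len(nBlocks), each = perBlock - 1),
                            rep(0L, nNoise)), genes)
    members <- genes[grepl("^blk", genes)]
    ed <- data.frame(parent = sprintf("drv%02d",
                                      ma[members]),
                     child = members,
                     w0 = stats::rnorm(length(members), 1, 0.1),
                     wg = 0, we = 0, wge = 0, stringsAsFactors = FALSE)
    me <- data.frame(gene = sprintf("drv%02d", seq_len(nBlocks)),
                     sigma = driverSigma)
    truth <- makeGroundTruth(ma, dagEdges = ed, meanEffects = me)
    return(list(truth = truth, design = makeDesign(nReps, seed)))
  }
  if (name == "dag") {
    genes <- c(sprintf("node%02d", seq_len(nNodes)),
               if (nNoise > 0) sprintf("noise%04d", seq_len(nNoise)))
    ma <- stats::setNames(c(rep(1L, nNodes), rep(0L, nNoise)), genes)
    ed <- NULL
    # random DAG on a random topological order; ensure it is connected
    # enough to be interesting
    repeat {
      pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
      keep <- stats::runif(nrow(pairs)) < edgeProb
      if (sum(keep) >= 1) break
    }
    ord <- sample(nNodes)
    ed <- data.frame(parent = genes[ord[pairs[keep, 1]]],
                     child = genes[ord[pairs[keep, 2]]],
                     w0 = sample(c(-1, 1), sum(keep), replace = TRUE) *
                       stats::runif(sum(keep), 0.8, 1.2),
                     wg = 0, we = 0, wge = 0, stringsAsFactors = FALSE)
    # module genes are high-variance by construction (they pass the
    # replicate-variance filter); structural sd 1 matches the planted
    # module drivers
    nodeGenes <- genes[seq_len(nNodes)]
    truth <- makeGroundTruth(ma, dagEdges = ed,
                             meanEffects = data.frame(gene = nodeGenes,
                                                      sigma = 1))
    return(list(truth = truth, design = makeDesign(nReps, seed)))
  }
  if (name == "ase") {
    n <- 100
    genes <- c(sprintf("ase%03d", seq_len(n)),
               sprintf("bg%04d", seq_len(3 * n)))
    modes <- stats::setNames(rep(c("cis", "trans", "cisxE", "none"),
                                 each = 25), genes[seq_len(n)])
    ma <- stats::setNames(rep(0L, length(genes)), genes)
    truth <- makeGroundTruth(ma, aseMode = modes)
    return(list(truth = truth, design = makeAseDesign(10, seed)))
  }

  # "gxe": four driver-based modules with condition-dependent presence
  modSize <- 30L
  conds <- list(conserved = NULL,
                genotypeSpecific = cbind(g = c(0, 0), e = c(0, 1)),
                environmentSpecific = cbind(g = c(0, 1), e = c(0, 0)),
                gxeSpecific = cbind(g = c(0, 1, 1), e = c(0, 0, 1)))
  # rows above are the conditions where each module's driver is SILENCED:
  # module 2 active only in Bd3-1, module 3 only under drought, module 4
  # only in Bd21 drought.
  genes <- character(); ma <- integer(); ed <- NULL; ov <- NULL
  for (m in seq_along(conds)) {
    drv <- sprintf("mod%d_drv", m)
    mem <- sprintf("mod%d_g%03d", m, seq_len(modSize - 1))
    genes <- c(genes, drv, mem)
    ma <- c(ma, stats::setNames(rep(m, modSize), c(drv, mem)))
    ed <- rbind(ed, data.frame(parent = drv, child = mem,
                               w0 = stats::rnorm(length(mem), 1, 0.1),
                               wg = 0, we = 0, wge = 0,
                               stringsAsFactors = FALSE))
    sil <- conds[[m]]
    if (!is.null(sil))
      ov <- rbind(ov, data.frame(gene = drv, g = sil[, "g"],
                                 e = sil[, "e"], sigma = 0.02))
  }
  # a small fifth module carrying a planted regulatory DAG (conservative
  # preset size, eligible for causal inference under the sample-size gate)
  caus <- sprintf("mod5_g%02d", seq_len(16))
  genes <- c(genes, caus)
  ma <- c(ma, stats::setNames(rep(5L, 16), caus))
  chain <- data.frame(parent = caus[c(1, 1, 2, 3, 4, 4, 5, 6, 7, 8,
                                      9, 10, 11, 12)],
                      child = caus[c(2, 3, 4, 4, 5, 6, 7, 8, 9, 10,
                                     11, 12, 13, 14)],
                      w0 = 1, wg = 0, we = 0, wge = 0,
                      stringsAsFactors = FALSE)
  chain <- chain[!duplicated(paste(chain$parent, chain$child)), ]
  chain$wge[1] <- 1                       # one GxE-modified edge
  ed <- rbind(ed, chain,
              data.frame(parent = caus[14], child = caus[15:16],
                         w0 = 1, wg = 0, we = 0, wge = 0))
  bg <- sprintf("bg%04d", seq_len(nNoise))
  genes <- c(genes, bg)
  ma <- c(ma, stats::setNames(rep(0L, nNoise), bg))
  nShift <- min(20L, nNoise %/% 4)
  me <- rbind(
    data.frame(gene = sprintf("mod%d_drv", seq_along(conds)),
               b0 = 7, bg = 0, be = 0, bge = 0, sigma = driverSigma),
    data.frame(gene = caus, b0 = 7, bg = 0, be = 0, bge = 0, sigma = 1),
    if (nShift > 0) data.frame(gene = bg[seq_len(nShift)], b0 = 7, bg = 1,
                               be = 0, bge = 0, sigma = 0.5),
    if (nShift > 0) data.frame(gene = bg[nShift + seq_len(nShift)], b0 = 7,
                               bg = 0, be = 1, bge = 0, sigma = 0.5),
    if (nShift > 0) data.frame(gene = bg[2 * nShift + seq_len(nShift)],
                               b0 = 7, bg = 0, be = 0, bge = 1, sigma = 0.5)
  )
  tl <- data.frame(trait = "glucose", module = 3, coupling = 1, noiseSd = 1,
                   stringsAsFactors = FALSE)
  truth <- makeGroundTruth(stats::setNames(as.integer(ma), genes),
                           dagEdges = ed, meanEffects = me,
                           sigmaOverride = ov, traitLoadings = tl)
  list(truth = truth, design = makeDesign(nReps, seed))
}
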
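#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GxEExperiment: counts plus a two-factor genotype x treatment design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' gene-by-sample count matrix (assay `"counts"`, optionally a `"normalized"`
#' log2 assay added by [normalizeLog2()]) together with the per-sample design:
#' `colData` columns `genotype` (0 = Bd21, 1 = Bd3-1), `treatment`
#' (0 = control, 1 = drought) and the derived `libraryType` label.
#'
#' @seealso [GxEExperiment()], [makeDesign()], [simulateCounts()]
#' @export
setClass("GxEExperiment", contains = "SummarizedExperiment")

setValidity("GxEExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("genotype", "treatment", "libraryType") %in% colnames(cd)))
    msg <- c(msg, "colData must have genotype, treatment and libraryType")
  else {
    if (!all(cd$genotype %in% c(0L, 1L)))
      msg <- c(msg, "genotype codes must be 0 (Bd21) or 1 (Bd3-1)")
    if (!all(cd$treatment %in% c(0L, 1L)))
      msg <- c(msg, "treatment codes must be 0 (control) or 1 (drought)")
  }
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct a GxEExperiment
#'
#' @param counts nonnegative integer matrix, genes x samples, with rownames.
#' @param design data.frame with columns `sample_id`, `genotype`, `treatment`
#'   (codes in 0/1), one row per column of `counts`.
#' @return A [GxEExperiment-class] object.
#' @examples
#' d <- makeDesign(2, seed = 1)
#' m <- matrix(rpois(40, 20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), d$sample_id))
#' GxEExperiment(m, d)
#' @export
GxEExperiment <- function(counts, design) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (ncol(counts) != nrow(design))
    stop("number of count columns must equal number of design rows")
  cd <- S4Vectors::DataFrame(
    genotype = as.integer(design$genotype),
    treatment = as.integer(design$treatment),
    libraryType = libraryTypeLabel(design$genotype, design$treatment),
    row.names = design$sample_id
  )
  if ("generation" %in% colnames(design))
    cd$generation <- as.integer(design$generation)
  colnames(counts) <- design$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  methods::new("GxEExperiment", se)
}

#' ModuleSet: a coexpression module partition for one library type
#'
#' @slot assignment named integer vector, gene -> module id (0 = unassigned).
#' @slot eigengenes numeric matrix, samples x modules; each column is the
#'   first principal component of the module's standardized expression,
#'   unit norm, oriented to correlate positively with the module mean.
#' @slot varExplained numeric, proportion of module variance carried by each
#'   eigengene.
#' @slot libraryType character label, e.g. `"Bd21d"`.
#' @slot preset character, the cut preset used (`"moderate"`,
#'   `"conservative"` or `"custom"`).
#' @slot parameters list of the cut parameters actually used.
#' @seealso [detectModules()]
#' @export
setClass("ModuleSet", representation(
  assignment = "integer",
  eigengenes = "matrix",
  varExplained = "numeric",
  libraryType = "character",
  preset = "character",
  parameters = "list"
))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by gene id")
  if (any(object@assignment < 0))
    msg <- c(msg, "module ids must be >= 0")
  ids <- sort(unique(object@assignment[object@assignment > 0]))
  if (length(ids) && ncol(object@eigengenes) != length(ids))
    msg <- c(msg, "one eigengene column per non-zero module is required")
  if (length(msg)) msg else TRUE
})

#' CliqueReport: groups of overlapping modules across library types
#'
#' @slot cliques data.frame with one row per clique: `clique`, `pattern`,
#'   `n_members`, `n_library_types`, `members` (comma-separated
#'   `libraryType:module` labels), `min_p` (smallest pairwise overlap
#'   P-value) and `multiway_p` (exact m-way intersection P across members,
#'   NA for singletons).
#' @slot edges data.frame of the significant pairwise overlaps that formed
#'   the cliques (both-preset rule applied).
#' @slot pCutoff numeric, the pairwise significance cutoff used.
#' @slot universeSize integer, number of genes in the test universe.
#' @seealso [buildCliques()]
#' @export
setClass("CliqueReport", representation(
  cliques = "data.frame",
  edges = "data.frame",
  pCutoff = "numeric",
  universeSize = "integer"
))

#' CausalGraph: a stability-selected DAG over one module's genes
#'
#' @slot nodes character, genes (and optionally one trait node) retained in
#'   the graph; singletons are dropped.
#' @slot edges data.frame with columns `from`, `to`, `frequency` (stability
#'   selection frequency in [0,1]) and `ambiguous` (TRUE when both
#'   directions were retained).
#' @slot moduleId character label of the module the graph was fitted on.
#' @slot libraryType character, the observational library type.
#' @slot threshold numeric, the retention frequency threshold actually used.
#' @slot nSubsamples integer, number of successful stability subsamples.
#' @seealso [stabilitySelect()]
#' @export
setClass("CausalGraph", representation(
  nodes = "character",
  edges = "data.frame",
  moduleId = "character",
  libraryType = "character",
  threshold = "numeric",
  nSubsamples = "integer"
))

setValidity("CausalGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$frequency < 0 | e$frequency > 1))
      msg <- c(msg, "edge frequencies must lie in [0,1]")
    un <- e[!e$ambiguous, , drop = FALSE]
    if (nrow(un)) {
      g <- igraph::graph_from_data_frame(un[, c("from", "to")],
                                         directed = TRUE)
      if (!igraph::is_dag(g))
        msg <- c(msg, "unambiguous edges must form an acyclic graph")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure for the synthetic-data generator
#'
#' Describes the generative model used by [simulateCounts()],
#' [simulateTrait()] and [simulateAse()]: module membership, within-module
#' condition-dependent DAG edges, per-gene mean shifts, trait couplings and
#' allelic architectures. Edge weights use the same (w0, wg, we, wge)
#' coordinates as the edge-level GxE regression so planted truth and fitted
#' models are directly comparable.
#'
#' @slot moduleAssignment named integer, gene -> module id (0 = unassigned
#'   background gene).
#' @slot dagEdges data.frame `parent`, `child`, `w0`, `wg`, `we`, `wge`;
#'   the realized weight in condition (g, e) is `w0 + wg g + we e + wge g e`.
#'   Edges must stay within one module and form a DAG.
#' @slot meanEffects data.frame `gene`, `b0`, `bg`, `be`, `bge`, `sigma`
#'   (log2-scale intercept shifts and residual sd of the structural
#'   equation).
#' @slot sigmaOverride data.frame `gene`, `g`, `e`, `sigma`: per-condition
#'   residual-sd overrides; setting a module driver's sd near zero in one
#'   condition plants module "absence" there without deleting genes.
#' @slot traitLoadings data.frame `trait`, `module`, `coupling`, `noiseSd`.
#' @slot aseMode named character, gene -> one of `cis`, `trans`, `cisxE`,
#'   `transxE`, `none`.
#' @slot aseEffect named numeric, log2 allelic effect size per gene.
#' @seealso [makeGroundTruth()], [makeScenario()]
#' @export
setClass("GroundTruth", representation(
  moduleAssignment = "integer",
  dagEdges = "data.frame",
  meanEffects = "data.frame",
  sigmaOverride = "data.frame",
  traitLoadings = "data.frame",
  aseMode = "character",
  aseEffect = "numeric"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  genes <- names(object@moduleAssignment)
  ed <- object@dagEdges
  if (nrow(ed)) {
    if (!all(c(ed$parent, ed$child) %in% genes))
      msg <- c(msg, "dag edges must reference known genes")
    else {
      ma <- object@moduleAssignment
      if (any(ma[ed$parent] != ma[ed$child]))
        msg <- c(msg, "dag edges must connect genes of the same module")
      g <- igraph::graph_from_data_frame(ed[, c("parent", "child")],
                                         directed = TRUE)
      if (!igraph::is_dag(g)) {
        comp <- igraph::components(g, mode = "strong")
        cyc <- names(comp$membership)[comp$membership %in%
                                        which(comp$csize > 1)]
        msg <- c(msg, paste0("dag edges contain a cycle through: ",
                             paste(cyc, collapse = ", ")))
      }
    }
  }
  if (length(object@aseMode) &&
      !all(object@aseMode %in% c("cis", "trans", "cisxE", "transxE", "none")))
    msg <- c(msg, "unknown ase mode")
  if (length(msg)) msg else TRUE
})
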
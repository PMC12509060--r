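# Cross-library-type module preservation: overlap tests, cliques, pattern
# classification, DGE enrichment and trait correlations.

# best-Jaccard counterpart of a gene set among another ModuleSet's modules
#' @keywords internal
#' @noRd
.bestJaccardModule <- function(genes, moduleSet) {
  sets <- moduleGeneSets(moduleSet)
  if (!length(sets)) return(NULL)
  jac <- vapply(sets, function(s) {
    length(intersect(genes, s)) / length(union(genes, s))
  }, numeric(1))
  if (max(jac) == 0) return(NULL)
  sets[[which.max(jac)]]
}

#' Module-overlap cliques across library types
#'
#' Tests, for every pair of modules from different library types, whether
#' their gene overlap is larger than expected by chance (exact
#' [multisetIntersectionTest()] against the filtered gene universe). A pair
#' is accepted only when the moderate-preset overlap passes `pCutoff` and
#' the corresponding conservative-preset module pair (matched by best
#' Jaccard similarity) also passes. Cliques are the connected components of
#' the accepted overlap graph; each clique is annotated with its m-way
#' intersection P-value and classified with [classifyClique()].
#'
#' @param moderate named list of [ModuleSet-class] objects (one per library
#'   type), moderate preset.
#' @param conservative named list of ModuleSet objects, conservative
#'   preset, same library types.
#' @param universe character vector of genes that entered module detection.
#' @param pCutoff pairwise significance cutoff (1e-12 keeps the familywise
#'   error below 0.05 after Bonferroni correction over all pairs at
#'   genome-scale module counts).
#' @return A [CliqueReport-class].
#' @export
buildCliques <- function(moderate, conservative, universe,
                         pCutoff = 1e-12) {
  lts <- names(moderate)
  stopifnot(!is.null(lts), setequal(lts, names(conservative)))
  N <- length(universe)
  sets <- lapply(moderate, moduleGeneSets)
  nodeIds <- unlist(lapply(lts, function(lt)
    if (length(sets[[lt]])) paste0(lt, ":", names(sets[[lt]]))), use.names = FALSE)

  edges <- NULL
  for (i in seq_along(lts)) for (j in seq_along(lts)) {
    if (i >= j) next
    ltA <- lts[i]; ltB <- lts[j]
    for (a in names(sets[[ltA]])) for (b in names(sets[[ltB]])) {
      gA <- intersect(sets[[ltA]][[a]], universe)
      gB <- intersect(sets[[ltB]][[b]], universe)
      if (!length(gA) || !length(gB)) next
      tst <- multisetIntersectionTest(list(gA, gB), N)
      if (tst$p >= pCutoff) next
      # support in the conservative preset via best-Jaccard counterparts
      cA <- .bestJaccardModule(gA, conservative[[ltA]])
      cB <- .bestJaccardModule(gB, conservative[[ltB]])
      if (is.null(cA) || is.null(cB)) next
      tstC <- multisetIntersectionTest(list(intersect(cA, universe),
                                            intersect(cB, universe)), N)
      if (tstC$p >= pCutoff) next
      edges <- rbind(edges, data.frame(
        from = paste0(ltA, ":", a), to = paste0(ltB, ":", b),
        p = tst$p, p_conservative = tstC$p, overlap = tst$observed,
        stringsAsFactors = FALSE))
    }
  }

  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(nodeIds))
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(as.matrix(edges[, c("from", "to")])))
  comp <- igraph::components(g)
  cliques <- NULL
  memb <- split(names(comp$membership), comp$membership)
  # singletons (modules with no significant overlap) are reported as
  # single-member cliques only when they exist in just that library type,
  # i.e. every module is either in a multi-module clique or a singleton
  cid <- 0L
  for (k in seq_along(memb)) {
    mods <- sort(memb[[k]])
    cid <- cid + 1L
    ltsIn <- sub(":.*$", "", mods)
    pat <- classifyClique(mods)
    mw <- NA_real_
    if (length(mods) >= 3) {
      gs <- lapply(mods, function(m) {
        lt <- sub(":.*$", "", m); id <- sub("^.*:", "", m)
        intersect(sets[[lt]][[id]], universe)
      })
      mw <- multisetIntersectionTest(gs, N)$p
    }
    minp <- if (is.null(edges)) NA_real_ else {
      sel <- edges$from %in% mods & edges$to %in% mods
      if (any(sel)) min(edges$p[sel]) else NA_real_
    }
    cliques <- rbind(cliques, data.frame(
      clique = cid, pattern = pat, n_members = length(mods),
      n_library_types = length(unique(ltsIn)),
      members = paste(mods, collapse = ","),
      min_p = minp, multiway_p = mw, stringsAsFactors = FALSE))
  }
  if (is.null(cliques))
    cliques <- data.frame(clique = integer(), pattern = character(),
                          n_members = integer(),
                          n_library_types = integer(),
                          members = character(), min_p = numeric(),
                          multiway_p = numeric())
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(), p = numeric(),
                        p_conservative = numeric(), overlap = integer())
  methods::new("CliqueReport", cliques = cliques, edges = edges,
               pCutoff = pCutoff, universeSize = as.integer(N))
}

#' Classify a clique's conservation pattern
#'
#' Library types are counted once each: all four present = `conserved`;
#' exactly two sharing the genotype = `genotype-specific`; exactly two
#' sharing the treatment = `environment-specific`; one or three library
#' types (or two sharing neither factor) = `GxE-specific`.
#'
#' @param members character vector of `libraryType:module` labels (or bare
#'   library-type labels).
#' @return One of `"conserved"`, `"genotype-specific"`,
#'   `"environment-specific"`, `"GxE-specific"`.
#' @examples
#' classifyClique(c("Bd21d:1", "Bd3-1d:4"))
#' @export
classifyClique <- function(members) {
  stopifnot(length(members) >= 1)
  lts <- unique(sub(":.*$", "", members))
  stopifnot(all(lts %in% .libraryTypes()))
  if (length(lts) == 4) return("conserved")
  if (length(lts) == 2) {
    codes <- lapply(lts, .codesForLibraryType)
    if (codes[[1]]$genotype == codes[[2]]$genotype)
      return("genotype-specific")
    if (codes[[1]]$treatment == codes[[2]]$treatment)
      return("environment-specific")
  }
  "GxE-specific"
}

#' Fisher test for DGE-class enrichment in a module
#'
#' One-sided Fisher's exact test for over-representation of a gene class
#' (e.g. significant treatment-effect genes) among a module's genes,
#' against the filtered gene universe. Also reports the fraction of module
#' genes in the class.
#'
#' @param module character vector of module genes.
#' @param geneClass character vector of class genes (e.g. significant-E).
#' @param universe character vector of background genes.
#' @return list: `p` (one-sided), `fraction`, `table` (the 2x2 table).
#' @export
dgeEnrichment <- function(module, geneClass, universe) {
  if (!length(module)) stop("empty module")
  module <- intersect(module, universe)
  geneClass <- intersect(geneClass, universe)
  inBoth <- length(intersect(module, geneClass))
  tab <- matrix(c(inBoth,
                  length(module) - inBoth,
                  length(geneClass) - inBoth,
                  length(universe) - length(module) - length(geneClass) +
                    inBoth), 2, 2)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p = ft$p.value, fraction = inBoth / length(module), table = tab)
}

#' Module eigengene-trait correlations within a library type
#'
#' Pearson correlation, with the two-sided t-test P-value, between each
#' module eigengene of a [ModuleSet-class] and each trait column, computed
#' on that library type's samples.
#'
#' @param moduleSet a [ModuleSet-class] (eigengene rows named by sample).
#' @param traits data.frame with `sample_id` and one numeric column per
#'   trait.
#' @return data.frame: `library_type`, `module`, `trait`, `r`, `p`, `n`.
#' @export
moduleTraitCorrelation <- function(moduleSet, traits) {
  eg <- eigengenes(moduleSet)
  if (!nrow(eg)) stop("module set has no eigengenes")
  idx <- match(rownames(eg), traits$sample_id)
  if (anyNA(idx)) stop("traits are missing for some samples")
  if (nrow(eg) < 3) stop("at least 3 samples are required")
  traitCols <- setdiff(colnames(traits), "sample_id")
  out <- NULL
  for (m in colnames(eg)) for (tr in traitCols) {
    ct <- stats::cor.test(eg[, m], traits[[tr]][idx])
    out <- rbind(out, data.frame(
      library_type = libraryType(moduleSet), module = m, trait = tr,
      r = unname(ct$estimate), p = ct$p.value, n = nrow(eg),
      stringsAsFactors = FALSE))
  }
  out
}
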
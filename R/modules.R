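# Module detection: adaptive dynamic branch cut of the TOM dendrogram,
# eigengene computation and eigengene-based module merging.

#' Module eigengene (first principal component)
#'
#' The eigengene of a gene set is the first right singular vector of the
#' gene-standardized expression submatrix: a unit-norm per-sample score.
#' Its sign is oriented so that it correlates positively with the module's
#' mean standardized expression (with a deterministic fallback to the first
#' gene's profile when the mean is degenerate, e.g. two perfectly
#' anti-correlated genes).
#'
#' @param values normalized expression, genes x samples.
#' @param genes optional subset of rownames to use.
#' @return list with `eigengene` (unit-norm numeric, one value per sample)
#'   and `varExplained` (fraction of standardized variance carried).
#' @examples
#' v <- matrix(rnorm(30), 3, 10, dimnames = list(letters[1:3], NULL))
#' computeEigengene(v)$varExplained
#' @export
computeEigengene <- function(values, genes = NULL) {
  if (!is.null(genes)) values <- values[genes, , drop = FALSE]
  stopifnot(nrow(values) >= 2, ncol(values) >= 2)
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s) from ",
            "eigengene computation")
    values <- values[sds > 0, , drop = FALSE]
    if (nrow(values) < 2) stop("fewer than 2 variable genes in module")
  }
  X <- t(scale(t(values)))
  sv <- svd(X)
  v <- sv$v[, 1]
  ref <- colMeans(X)
  ornt <- sum(v * ref)
  if (abs(ornt) < 1e-10) ornt <- sum(v * X[1, ])
  if (abs(ornt) < 1e-10) ornt <- v[which(v != 0)[1]]
  if (ornt < 0) v <- -v
  list(eigengene = v, varExplained = sv$d[1]^2 / sum(sv$d^2))
}

# deepSplit (0..4) -> minimum branch separation gap on the 1-TOM scale;
# higher deepSplit = laxer criterion = more, smaller modules
#' @keywords internal
#' @noRd
.deepSplitGap <- function(deepSplit) {
  gaps <- c(0.05, 0.035, 0.025, 0.015, 0.010)
  stopifnot(deepSplit %in% 0:4)
  gaps[deepSplit + 1]
}

# Recursive adaptive branch cut of an hclust tree.
# Returns a list of integer leaf-index vectors (candidate modules).
#' @keywords internal
#' @noRd
.cutBranches <- function(hc, cutHeight, minClusterSize, minGap) {
  n <- length(hc$order)
  members <- vector("list", n - 1)
  leaves <- function(k) if (k < 0) -k else members[[k]]
  for (k in seq_len(n - 1))
    members[[k]] <- c(leaves(hc$merge[k, 1]), leaves(hc$merge[k, 2]))
  hgt <- hc$height
  out <- list()
  descend <- function(k, parentHeight) {
    if (k < 0) return(invisible(NULL))        # singleton: unassigned
    h <- hgt[k]
    c1 <- hc$merge[k, 1]; c2 <- hc$merge[k, 2]
    if (h > cutHeight) {                      # cut: children are separate
      descend(c1, h); descend(c2, h)
      return(invisible(NULL))
    }
    s1 <- if (c1 < 0) 1L else length(members[[c1]])
    s2 <- if (c2 < 0) 1L else length(members[[c2]])
    h1 <- if (c1 < 0) 0 else hgt[c1]
    h2 <- if (c2 < 0) 0 else hgt[c2]
    if (s1 >= minClusterSize && s2 >= minClusterSize &&
        (h - max(h1, h2)) >= minGap) {        # deep split
      descend(c1, h); descend(c2, h)
      return(invisible(NULL))
    }
    if (length(members[[k]]) >= minClusterSize &&
        (parentHeight - h) >= minGap) {
      out[[length(out) + 1L]] <<- members[[k]]
      return(invisible(NULL))
    }
    # branch not separated from its surroundings (e.g. stragglers joined
    # just below the cut): look for separated sub-branches instead
    descend(c1, h); descend(c2, h)
    invisible(NULL)
  }
  # the root has no surroundings to be separated from, so it can never
  # itself be a module; its children are examined instead
  if (n >= 2) descend(n - 1L, hgt[n - 1L])
  out
}

#' Cut a TOM dendrogram into coexpression modules
#'
#' Genes are clustered by average-linkage hierarchical clustering of the
#' dissimilarity `1 - TOM` and modules are obtained with an adaptive
#' dynamic branch cut (no PAM re-assignment stage): merges above
#' `cutHeight` never bind modules; a branch below the cut is split further
#' when both halves hold at least `minClusterSize` genes and are separated
#' from their join by a gap controlled by `deepSplit` (0..4, progressively
#' laxer); a branch becomes a module when it has at least `minClusterSize`
#' genes and is separated from its surroundings by the same gap. Remaining
#' genes are unassigned (module 0). Modules whose eigengenes have
#' dissimilarity `1 - cor` below `mergeHeight` are merged iteratively.
#' Gene input order does not affect the result (genes are sorted before
#' clustering).
#'
#' Presets: `moderate` (cutHeight 0.99, minClusterSize 30, deepSplit 2) and
#' `conservative` (cutHeight 0.984, minClusterSize 15, deepSplit 3), both
#' with mergeHeight 0.25.
#'
#' @param tom a `"TomMatrix"` from [buildTom()] (possibly rescaled by
#'   [scaleTom()]).
#' @param values the normalized expression matrix the TOM was built from
#'   (genes x samples), used for eigengenes and merging.
#' @param preset `"moderate"`, `"conservative"`, or `"custom"` (then supply
#'   the individual parameters).
#' @param cutHeight,minClusterSize,deepSplit,mergeHeight override the
#'   preset's parameters.
#' @return A [ModuleSet-class]; module ids are 1..K in decreasing size
#'   order, 0 marks unassigned genes.
#' @export
detectModules <- function(tom, values,
                          preset = c("moderate", "conservative", "custom"),
                          cutHeight = NULL, minClusterSize = NULL,
                          deepSplit = NULL, mergeHeight = 0.25) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    moderate = list(cutHeight = 0.99, minClusterSize = 30, deepSplit = 2),
    conservative = list(cutHeight = 0.984, minClusterSize = 15,
                        deepSplit = 3),
    custom = list(cutHeight = 0.99, minClusterSize = 30, deepSplit = 2))
  if (is.null(cutHeight)) cutHeight <- defaults$cutHeight
  if (is.null(minClusterSize)) minClusterSize <- defaults$minClusterSize
  if (is.null(deepSplit)) deepSplit <- defaults$deepSplit
  minGap <- .deepSplitGap(deepSplit)

  tm <- tom$tom
  genes <- rownames(tm)
  stopifnot(!is.null(genes), identical(rownames(values), genes) ||
              all(genes %in% rownames(values)))
  ord <- order(genes)
  tm <- tm[ord, ord]
  vals <- values[genes[ord], , drop = FALSE]
  n <- length(genes)
  assignment <- stats::setNames(rep(0L, n), genes[ord])

  if (n >= max(2, minClusterSize)) {
    hc <- stats::hclust(stats::as.dist(1 - tm), method = "average")
    branches <- .cutBranches(hc, cutHeight, minClusterSize, minGap)
    for (b in seq_along(branches))
      assignment[branches[[b]]] <- b
  }

  # eigengene-based merging
  relabel <- function(a) {
    ids <- sort(unique(a[a > 0]))
    match(a, ids, nomatch = 0L)
  }
  assignment[] <- relabel(assignment)
  repeat {
    ids <- sort(unique(assignment[assignment > 0]))
    if (length(ids) < 2) break
    eg <- vapply(ids, function(id)
      computeEigengene(vals, names(assignment)[assignment == id])$eigengene,
      numeric(ncol(vals)))
    dd <- 1 - stats::cor(eg)
    diag(dd) <- Inf
    mn <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    if (dd[mn[1], mn[2]] >= mergeHeight) break
    assignment[assignment == ids[max(mn)]] <- ids[min(mn)]
    assignment[] <- relabel(assignment)
  }

  # final labels by decreasing size
  ids <- sort(unique(assignment[assignment > 0]))
  if (length(ids)) {
    sizes <- vapply(ids, function(id) sum(assignment == id), integer(1))
    newIds <- ids[order(-sizes, ids)]
    assignment[] <- ifelse(assignment == 0, 0L,
                           match(assignment, newIds))
    ids <- seq_along(newIds)
    egList <- lapply(ids, function(id)
      computeEigengene(vals, names(assignment)[assignment == id]))
    eg <- vapply(egList, function(z) z$eigengene, numeric(ncol(vals)))
    colnames(eg) <- paste0("M", ids)
    rownames(eg) <- colnames(vals)
    ve <- vapply(egList, function(z) z$varExplained, numeric(1))
  } else {
    eg <- matrix(numeric(0), nrow = ncol(vals), ncol = 0,
                 dimnames = list(colnames(vals), NULL))
    ve <- numeric(0)
  }

  # report in the caller's gene order
  assignment <- assignment[genes]
  methods::new("ModuleSet",
               assignment = assignment,
               eigengenes = eg,
               varExplained = ve,
               libraryType = if (is.null(tom$libraryType)) NA_character_
                             else tom$libraryType,
               preset = preset,
               parameters = list(cutHeight = cutHeight,
                                 minClusterSize = minClusterSize,
                                 deepSplit = deepSplit,
                                 mergeHeight = mergeHeight,
                                 softPower = tom$softPower))
}

#' Gene sets of a ModuleSet
#'
#' @param moduleSet a [ModuleSet-class].
#' @param dropUnassigned omit module 0.
#' @return Named list of character vectors, one per module.
#' @export
moduleGeneSets <- function(moduleSet, dropUnassigned = TRUE) {
  a <- moduleAssignments(moduleSet)
  ids <- sort(unique(a))
  if (dropUnassigned) ids <- ids[ids > 0]
  sets <- lapply(ids, function(id) names(a)[a == id])
  names(sets) <- ids
  sets
}
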
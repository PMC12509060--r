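# Stability selection for causal edges and trait-node augmentation.

#' Stability-selected causal graph for one module
#'
#' Runs the interventional sparsest-permutation search ([utigspFit()]) on
#' repeated half-subsamples, drawn without replacement within each library
#' type so the interventional groups survive subsampling. Per directed
#' edge, the selection frequency is the fraction of successful fits
#' containing it; a gene pair's skeleton frequency is the sum over both
#' directions (so a real interaction whose orientation is not identifiable
#' is not penalized for flipping direction between subsamples). Pairs
#' whose skeleton frequency reaches the retention threshold are kept: with
#' `retention = "fixed"` (default) the threshold is the absolute
#' majority-vote frequency `fixedThreshold`; with `retention = "quantile"`
#' it is the `freqQuantile` empirical quantile of the positive skeleton
#' frequencies (the sparser rule suited to large modules). A retained
#' pair is oriented in its dominant direction when that direction carries
#' at least two thirds of the pair's frequency mass, and flagged ambiguous
#' (both directions reported) otherwise. Genes not connected to any
#' retained edge are dropped from the graph.
#'
#' @param values normalized expression, module genes x samples.
#' @param design data.frame aligned with the columns of `values`, with a
#'   `library_type` column.
#' @param obsLibraryType the library type whose samples are observational
#'   (the module's source); all other library types enter as separate
#'   unknown-target interventional groups. `NULL` pools every sample as
#'   observational with no interventional groups (appropriate when the
#'   mechanism is assumed identical across library types).
#' @param nSubsamples number of subsamples.
#' @param subsampleFraction fraction of each library type drawn per
#'   subsample.
#' @param retention `"fixed"` (absolute threshold) or `"quantile"`.
#' @param fixedThreshold majority-vote skeleton-frequency threshold for
#'   `retention = "fixed"`.
#' @param freqQuantile quantile of the positive skeleton-frequency
#'   distribution for `retention = "quantile"` (0.95; 0.97 for larger
#'   conserved modules to keep edges sparse).
#' @param alpha,alphaInv CI and invariance test levels (see [utigspFit()]).
#' @param nRestarts,maxDepth search effort per subsample fit.
#' @param moduleId label stored in the result.
#' @param seed integer seed.
#' @return A [CausalGraph-class].
#' @export
stabilitySelect <- function(values, design, obsLibraryType,
                            nSubsamples = 100L, subsampleFraction = 0.5,
                            retention = c("fixed", "quantile"),
                            fixedThreshold = 0.5, freqQuantile = 0.95,
                            alpha = 0.05, alphaInv = 0.05,
                            nRestarts = 3L, maxDepth = 3L,
                            moduleId = NA_character_, seed = 1L) {
  retention <- match.arg(retention)
  stopifnot(nSubsamples >= 2, ncol(values) == nrow(design))
  nodes <- rownames(values)
  p <- length(nodes)
  lts <- unique(design$library_type)
  pooled <- is.null(obsLibraryType)
  if (!pooled) stopifnot(obsLibraryType %in% lts)
  nObsFull <- if (pooled) nrow(design)
              else sum(design$library_type == obsLibraryType)
  if (p > 0.7 * floor(subsampleFraction * nObsFull))
    stop("module has ", p, " genes but subsample fits would see only ",
         floor(subsampleFraction * nObsFull), " observational samples; ",
         "the search requires the gene count to be fewer than 70% of ",
         "the observational samples")
  X <- t(values)

  counts <- matrix(0, p, p, dimnames = list(nodes, nodes))
  nOk <- 0L
  nFail <- 0L
  set.seed(.deriveSeed(seed, 53L))
  for (b in seq_len(nSubsamples)) {
    idx <- unlist(lapply(lts, function(lt) {
      w <- which(design$library_type == lt)
      sample(w, max(2L, floor(length(w) * subsampleFraction)))
    }), use.names = FALSE)
    sub <- design$library_type[idx]
    if (pooled) {
      obs <- X[idx, , drop = FALSE]
      ints <- list()
    } else {
      obs <- X[idx[sub == obsLibraryType], , drop = FALSE]
      ints <- lapply(setdiff(lts, obsLibraryType), function(lt)
        X[idx[sub == lt], , drop = FALSE])
    }
    fit <- tryCatch(
      utigspFit(obs, ints, alpha = alpha, alphaInv = alphaInv,
                seed = .deriveSeed(seed, 1000L + b),
                nRestarts = nRestarts, maxDepth = maxDepth,
                checkSize = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) { nFail <- nFail + 1L; next }
    counts <- counts + fit$adjacency
    nOk <- nOk + 1L
  }
  if (nOk == 0L) stop("every subsample fit failed")
  if (nFail > 0.2 * nSubsamples)
    warning(nFail, " of ", nSubsamples, " subsample fits failed")
  freq <- counts / nOk

  skelFreq <- freq + t(freq)
  posSkel <- skelFreq[upper.tri(skelFreq)]
  posSkel <- posSkel[posSkel > 0]
  threshold <- if (retention == "fixed") fixedThreshold
  else if (length(posSkel))
    stats::quantile(posSkel, freqQuantile, names = FALSE)
  else 1
  pairs <- which(upper.tri(skelFreq) & skelFreq >= threshold,
                 arr.ind = TRUE)
  edges <- NULL
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    fij <- freq[i, j]; fji <- freq[j, i]
    tot <- fij + fji
    if (max(fij, fji) >= 2 / 3 * tot) {      # dominant orientation
      if (fij >= fji)
        edges <- rbind(edges, data.frame(from = nodes[i], to = nodes[j],
                                         frequency = fij,
                                         ambiguous = FALSE))
      else
        edges <- rbind(edges, data.frame(from = nodes[j], to = nodes[i],
                                         frequency = fji,
                                         ambiguous = FALSE))
    } else {
      edges <- rbind(edges,
                     data.frame(from = nodes[c(i, j)], to = nodes[c(j, i)],
                                frequency = c(fij, fji), ambiguous = TRUE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        frequency = numeric(), ambiguous = logical())
  # an (unlikely) directed cycle among unambiguous edges is demoted to
  # ambiguous, weakest edges first, so the retained DAG is well defined
  repeat {
    un <- edges[!edges$ambiguous, , drop = FALSE]
    if (!nrow(un)) break
    g <- igraph::graph_from_data_frame(un[, c("from", "to")],
                                       directed = TRUE)
    if (igraph::is_dag(g)) break
    cyc <- which(!edges$ambiguous)
    weakest <- cyc[which.min(edges$frequency[cyc])]
    edges$ambiguous[weakest] <- TRUE
  }
  connected <- sort(unique(c(edges$from, edges$to)))
  edges <- edges[order(-edges$frequency, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  methods::new("CausalGraph", nodes = connected, edges = edges,
               moduleId = moduleId,
               libraryType = if (pooled) "pooled" else obsLibraryType,
               threshold = threshold, nSubsamples = nOk)
}

#' Attach a quantitative trait as a node of a module
#'
#' Appends the trait as one extra row of the module's expression matrix so
#' the same causal machinery applies to gene-trait edges. Samples with
#' missing trait values are dropped with a warning.
#'
#' @param values module expression, genes x samples.
#' @param trait numeric trait vector aligned with the columns of `values`.
#' @param traitName row name of the trait node.
#' @return list: `values` (augmented matrix), `design_keep` (logical,
#'   samples retained).
#' @export
attachTraitNode <- function(values, trait, traitName = "trait") {
  stopifnot(length(trait) == ncol(values))
  keep <- !is.na(trait)
  if (!all(keep))
    warning("dropping ", sum(!keep), " samples with missing trait values")
  aug <- rbind(values[, keep, drop = FALSE],
               matrix(trait[keep], 1,
                      dimnames = list(traitName, colnames(values)[keep])))
  list(values = aug, keep = keep)
}

#' Export a CausalGraph in DOT format
#'
#' @param graph a [CausalGraph-class].
#' @param file path of the `.dot` file to write.
#' @return The file path, invisibly.
#' @export
writeGraphDot <- function(graph, file) {
  e <- graphEdges(graph)
  lines <- c("digraph causal {",
             paste0("  \"", graph@nodes, "\";"),
             vapply(seq_len(nrow(e)), function(k) {
               paste0("  \"", e$from[k], "\" -> \"", e$to[k],
                      "\" [label=\"", sprintf("%.2f", e$frequency[k]),
                      "\"", if (e$ambiguous[k]) ", dir=both" else "", "];")
             }, character(1)),
             "}")
  writeLines(lines, file)
  invisible(file)
}
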
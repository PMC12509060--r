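# Interventional greedy sparsest-permutation search with unknown
# intervention targets.
#
# Given observational samples and one or more groups of samples whose
# interventions have unknown targets, the search scores a node permutation
# by the number of edges of its minimal I-MAP (edge i -> j present, for i
# preceding j, when i and j are dependent given the other predecessors of
# j) plus the number of intervention targets implied by invariance tests
# of each node's conditional given its permutation parents. Depth-first
# traversal over covered-edge transpositions accepts permutations whose
# score is no worse; the sparsest graph found is returned.

# invariance test of node j given parents P between observational
# sufficient statistics and one interventional group; Bonferroni over a
# residual mean-shift t-test and a residual variance-ratio F-test
#' @keywords internal
#' @noRd
.invarianceChanged <- function(stats0, statsK, j, P, alphaInv) {
  C0 <- stats0$cov; m0 <- stats0$mean; n0 <- stats0$n
  Ck <- statsK$cov; mk <- statsK$mean; nk <- statsK$n
  if (length(P)) {
    b <- tryCatch(solve(C0[P, P, drop = FALSE], C0[P, j]),
                  error = function(e) NULL)
    if (is.null(b)) return(TRUE)
    a <- m0[j] - sum(b * m0[P])
    s2o <- C0[j, j] - sum(C0[j, P] * b)
    rk <- mk[j] - a - sum(b * mk[P])
    s2k <- Ck[j, j] - 2 * sum(b * Ck[P, j]) +
      sum(b * (Ck[P, P, drop = FALSE] %*% b))
  } else {
    a <- m0[j]
    s2o <- C0[j, j]
    rk <- mk[j] - a
    s2k <- Ck[j, j]
  }
  s2o <- max(s2o, 1e-12); s2k <- max(s2k, 1e-12)
  tstat <- rk / sqrt(s2k / nk)
  pMean <- 2 * stats::pt(-abs(tstat), nk - 1)
  f <- s2k / s2o
  dfo <- n0 - length(P) - 1
  pVar <- 2 * min(stats::pf(f, nk - 1, dfo),
                  stats::pf(f, nk - 1, dfo, lower.tail = FALSE))
  min(pMean, pVar) < alphaInv / 2
}

#' Greedy sparsest-permutation causal search with unknown-target
#' interventions
#'
#' Estimates a DAG over a module's genes from observational samples plus
#' interventional-style sample groups (samples from the other library
#' types, assuming most of the regulatory structure is shared), without
#' knowing which genes each "intervention" perturbed. See the package
#' vignette for the scoring and search details.
#'
#' @param obs matrix of observational samples x nodes (ignored when a
#'   `ciTest` oracle is supplied together with `nNodes`).
#' @param interventions list of interventional sample matrices with the
#'   same columns as `obs` (may be empty).
#' @param alpha significance level of the Fisher-z CI tests deciding edge
#'   presence.
#' @param alphaInv significance level of the invariance tests deciding
#'   intervention targets (Bonferroni over a mean-shift and a
#'   variance-shift test).
#' @param seed integer seed for the restart permutations.
#' @param nRestarts number of search restarts.
#' @param maxDepth depth limit of the depth-first traversal over
#'   score-neutral covered-edge transpositions.
#' @param ciTest optional oracle `function(i, j, S)` returning TRUE for
#'   independence (e.g. [dsepOracle()]); replaces the Fisher-z kernel.
#' @param nNodes number of nodes when `obs` is NULL (oracle mode).
#' @param checkSize enforce the gene-count-below-70%-of-samples gate
#'   (disabled by [stabilitySelect()], which applies the gate at the
#'   module level before subsampling).
#' @return list: `adjacency` (logical, edge i -> j), `edges` (data.frame),
#'   `targets` (list, per interventional group, of nodes whose
#'   conditionals changed), `score`, `nodes`.
#' @examples
#' adj <- matrix(FALSE, 3, 3); adj[1, 3] <- adj[2, 3] <- TRUE
#' utigspFit(ciTest = dsepOracle(adj), nNodes = 3)$score
#' @export
utigspFit <- function(obs = NULL, interventions = list(), alpha = 0.01,
                      alphaInv = 0.05, seed = 1L, nRestarts = 2L,
                      maxDepth = 3L, ciTest = NULL, nNodes = NULL,
                      checkSize = TRUE) {
  oracleMode <- !is.null(ciTest)
  if (oracleMode) {
    stopifnot(!is.null(nNodes) || !is.null(obs))
    p <- if (is.null(nNodes)) ncol(obs) else nNodes
    nodes <- if (!is.null(obs) && !is.null(colnames(obs))) colnames(obs)
             else paste0("V", seq_len(p))
    statsObs <- NULL; statsInt <- list()
  } else {
    stopifnot(is.matrix(obs))
    p <- ncol(obs)
    if (checkSize && p > 0.7 * nrow(obs))
      stop("module has ", p, " genes but only ", nrow(obs),
           " observational samples; the search requires the gene count ",
           "to be fewer than 70% of samples")
    nodes <- if (!is.null(colnames(obs))) colnames(obs)
             else paste0("V", seq_len(p))
    statsObs <- list(cov = stats::cov(obs), mean = colMeans(obs),
                     n = nrow(obs))
    statsInt <- lapply(interventions, function(m) {
      stopifnot(ncol(m) == p)
      list(cov = stats::cov(m), mean = colMeans(m), n = nrow(m))
    })
    nObs <- nrow(obs)
    ciTest <- local({
      cache <- new.env(parent = emptyenv(), hash = TRUE)
      function(i, j, S) {
        key <- paste(min(i, j), max(i, j), paste(sort(S), collapse = "."),
                     sep = "|")
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
        r <- .partialCorFromCov(statsObs$cov, i, j, S)
        ans <- if (is.na(r)) FALSE else {
          r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
          stat <- sqrt(nObs - length(S) - 3) * abs(atanh(r))
          2 * stats::pnorm(-stat) > alpha
        }
        cache[[key]] <- ans
        ans
      }
    })
  }

  imapFor <- function(perm) {
    adj <- matrix(FALSE, p, p)
    for (k in seq_len(p)[-1]) {
      j <- perm[k]
      pre <- perm[seq_len(k - 1)]
      for (i in pre)
        adj[i, j] <- !ciTest(i, j, setdiff(pre, i))
    }
    adj
  }
  scoreFor <- function(adj) {
    sc <- sum(adj)
    targets <- lapply(statsInt, function(sk) {
      hit <- vapply(seq_len(p), function(j)
        .invarianceChanged(statsObs, sk, j, which(adj[, j]), alphaInv),
        logical(1))
      which(hit)
    })
    list(score = sc + sum(lengths(targets)), targets = targets)
  }

  permCache <- new.env(parent = emptyenv(), hash = TRUE)
  evalPerm <- function(perm) {
    key <- paste(perm, collapse = ",")
    hit <- permCache[[key]]
    if (!is.null(hit)) return(hit)
    adj <- imapFor(perm)
    sc <- scoreFor(adj)
    res <- list(perm = perm, adj = adj, score = sc$score,
                targets = sc$targets)
    permCache[[key]] <- res
    res
  }
  coveredEdges <- function(adj) {
    out <- NULL
    for (j in seq_len(p)) {
      pa <- which(adj[, j])
      for (i in pa)
        if (identical(sort(c(setdiff(pa, i))), sort(which(adj[, i]))))
          out <- rbind(out, c(i, j))
    }
    out
  }

  set.seed(.deriveSeed(seed, 31L))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    perm <- if (r == 1L) seq_len(p) else sample.int(p)
    visited <- new.env(parent = emptyenv(), hash = TRUE)
    cur <- evalPerm(perm)
    repeat {
      improved <- FALSE
      stack <- list(list(node = cur, depth = 0L))
      visited[[paste(cur$perm, collapse = ",")]] <- TRUE
      while (length(stack)) {
        top <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        ce <- coveredEdges(top$node$adj)
        if (is.null(ce)) next
        for (k in seq_len(nrow(ce))) {
          i <- ce[k, 1]; j <- ce[k, 2]
          np <- top$node$perm
          pi <- which(np == i); pj <- which(np == j)
          np[c(pi, pj)] <- np[c(pj, pi)]
          key <- paste(np, collapse = ",")
          if (!is.null(visited[[key]])) next
          visited[[key]] <- TRUE
          cand <- evalPerm(np)
          if (cand$score < cur$score) {
            cur <- cand
            improved <- TRUE
            break
          } else if (cand$score == cur$score &&
                     top$depth < maxDepth) {
            stack[[length(stack) + 1]] <- list(node = cand,
                                               depth = top$depth + 1L)
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    if (is.null(best) || cur$score < best$score) best <- cur
  }

  adj <- best$adj
  dimnames(adj) <- list(nodes, nodes)
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  targets <- lapply(best$targets, function(tt) nodes[tt])
  list(adjacency = adj, edges = edges, targets = targets,
       score = best$score, nodes = nodes, permutation = best$perm)
}
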
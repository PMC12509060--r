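# Conditional-independence kernel and d-separation oracle.

# partial correlation of variables i, j given set S from a covariance
#' @keywords internal
#' @noRd
.partialCorFromCov <- function(C, i, j, S) {
  idx <- c(i, j, S)
  P <- tryCatch(solve(C[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(P)) return(NA_real_)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

#' Fisher-z test of zero partial correlation
#'
#' Tests whether variables `x` and `y` are conditionally independent given
#' the set `S` under a linear-Gaussian model, via the Fisher
#' z-transformed sample partial correlation. A singular conditioning
#' covariance is treated as dependence (with a warning), the conservative
#' choice for a sparsity-seeking search.
#'
#' @param x,y column indices (or names) in `data`.
#' @param S vector of conditioning column indices (possibly empty),
#'   excluding `x` and `y`.
#' @param data numeric matrix, samples x variables.
#' @param alpha significance level.
#' @return list: `p`, `statistic` (z-scale), `independent` (logical at
#'   `alpha`), `estimate` (the partial correlation).
#' @examples
#' d <- matrix(rnorm(300), 100, 3)
#' ciTestFisherZ(1, 2, 3, d)$independent
#' @export
ciTestFisherZ <- function(x, y, S = integer(), data, alpha = 0.01) {
  if (is.character(x)) x <- match(x, colnames(data))
  if (is.character(y)) y <- match(y, colnames(data))
  if (is.character(S)) S <- match(S, colnames(data))
  stopifnot(!x %in% S, !y %in% S, x != y)
  n <- nrow(data)
  if (n <= length(S) + 3)
    stop("need n > |S| + 3 samples for the Fisher-z test")
  C <- stats::cov(data[, c(x, y, S), drop = FALSE])
  r <- .partialCorFromCov(C, 1, 2, if (length(S)) 3:(2 + length(S))
                          else integer())
  if (is.na(r)) {
    warning("singular conditioning covariance; treating as dependent")
    return(list(p = 0, statistic = Inf, independent = FALSE,
                estimate = NA_real_))
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  stat <- sqrt(n - length(S) - 3) * abs(atanh(r))
  p <- 2 * stats::pnorm(-stat)
  list(p = p, statistic = stat, independent = p > alpha, estimate = r)
}

#' d-separation in a DAG
#'
#' Tests whether nodes `x` and `y` are d-separated by the set `S` in the
#' DAG with logical adjacency matrix `adj` (`adj[i, j]` TRUE for edge
#' i -> j), via the moralized ancestral graph: restrict to ancestors of
#' `{x, y} U S`, marry co-parents, drop `S`, and check whether `x` and `y`
#' are disconnected. Used as the infinite-data oracle for the causal
#' search.
#'
#' @param adj logical adjacency matrix of a DAG.
#' @param x,y node indices.
#' @param S conditioning node indices (may be empty).
#' @return TRUE when `x` and `y` are d-separated given `S`.
#' @examples
#' adj <- matrix(FALSE, 3, 3); adj[1, 2] <- adj[2, 3] <- TRUE  # chain
#' dSeparated(adj, 1, 3, 2)
#' @export
dSeparated <- function(adj, x, y, S = integer()) {
  p <- nrow(adj)
  keep <- rep(FALSE, p)
  frontier <- unique(c(x, y, S))
  while (length(frontier)) {             # ancestors of {x, y} U S
    keep[frontier] <- TRUE
    frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0),
                        which(keep))
  }
  idx <- which(keep)
  sub <- adj[idx, idx, drop = FALSE]
  moral <- sub | t(sub)
  for (j in seq_along(idx)) {            # marry co-parents
    pa <- which(sub[, j])
    if (length(pa) > 1)
      for (a in pa) for (b in pa) if (a != b) moral[a, b] <- TRUE
  }
  drop <- match(S, idx)
  moral[drop[!is.na(drop)], ] <- FALSE
  moral[, drop[!is.na(drop)]] <- FALSE
  xs <- match(x, idx); ys <- match(y, idx)
  reach <- rep(FALSE, length(idx))
  frontier <- xs
  while (length(frontier)) {
    reach[frontier] <- TRUE
    nxt <- which(rowSums(moral[, frontier, drop = FALSE] |
                           t(moral[frontier, , drop = FALSE])) > 0)
    frontier <- setdiff(nxt, which(reach))
  }
  !reach[ys]
}

#' CI oracle backed by d-separation on a known DAG
#'
#' Returns a conditional-independence test function (same interface as the
#' internal kernel of [utigspFit()]) that answers from d-separation on the
#' true DAG instead of data: the infinite-data limit of any consistent CI
#' test.
#'
#' @param adj logical adjacency matrix of the true DAG.
#' @return function(i, j, S) returning TRUE when i and j are independent
#'   given S.
#' @export
dsepOracle <- function(adj) {
  force(adj)
  function(i, j, S = integer()) dSeparated(adj, i, j, S)
}
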
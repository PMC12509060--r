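# Exact multi-set intersection test (high-dimensional Fisher's exact
# test): distribution of the m-way intersection size of independent
# uniformly drawn subsets of a finite universe.

#' Exact multi-set intersection test
#'
#' Computes the exact upper-tail probability `P(X >= t)` of the m-way
#' intersection size `X` of `m` sets drawn independently and uniformly at
#' random (without replacement) with the observed sizes from a universe of
#' `universeSize` elements. The distribution is built by iterated
#' hypergeometric mixing: conditional on the running intersection having
#' size `s`, intersecting the next set of size `n` gives a
#' hypergeometric(`s`, `N - s`, `n`) count. All mixing is done in log
#' space. For `m = 2` this reduces exactly to the hypergeometric upper
#' tail.
#'
#' @param sets either a list of character vectors (the observed sets) or an
#'   integer vector of set sizes (then `observed` must be given).
#' @param universeSize number of elements in the universe.
#' @param observed observed intersection size; computed from `sets` when
#'   they are given explicitly.
#' @return list of class `"IntersectionTest"`: `setSizes`, `universeSize`,
#'   `observed`, `p` and `logP` (natural log).
#' @examples
#' # two sets of 5 in a universe of 10, perfect overlap: P = 1/choose(10,5)
#' multisetIntersectionTest(c(5, 5), universeSize = 10, observed = 5)$p
#' @export
multisetIntersectionTest <- function(sets, universeSize, observed = NULL) {
  if (is.list(sets)) {
    if (any(lengths(sets) > universeSize))
      stop("a set is larger than the universe")
    if (is.null(observed))
      observed <- length(Reduce(intersect, sets))
    sizes <- lengths(sets)
  } else {
    sizes <- as.integer(sets)
    if (is.null(observed))
      stop("'observed' is required when only set sizes are given")
  }
  if (length(sizes) < 2) stop("at least two sets are required")
  if (any(sizes > universeSize)) stop("a set is larger than the universe")
  if (observed > min(sizes)) stop("observed intersection exceeds min size")
  N <- universeSize

  # log P(X_2 = t): hypergeometric
  supp <- 0:min(sizes[1], sizes[2])
  logp <- stats::dhyper(supp, sizes[1], N - sizes[1], sizes[2], log = TRUE)
  for (k in seq_along(sizes)[-(1:2)]) {
    nk <- sizes[k]
    newSupp <- 0:min(max(supp), nk)
    newLogp <- vapply(newSupp, function(t) {
      ok <- supp >= t
      .logSumExp(logp[ok] +
                   stats::dhyper(t, supp[ok], N - supp[ok], nk, log = TRUE))
    }, numeric(1))
    supp <- newSupp
    logp <- newLogp
  }
  logTail <- .logSumExp(logp[supp >= observed])
  logTail <- min(logTail, 0)
  structure(list(setSizes = sizes, universeSize = N, observed = observed,
                 p = exp(logTail), logP = logTail),
            class = "IntersectionTest")
}

#' @export
print.IntersectionTest <- function(x, ...) {
  cat("Exact multi-set intersection test: m = ", length(x$setSizes),
      ", sizes (", paste(x$setSizes, collapse = ", "), ") in universe ",
      x$universeSize, "\n  observed intersection ", x$observed,
      ", P(X >= t) = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}
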
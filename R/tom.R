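# Weighted coexpression network: adjacency and topological overlap.

#' Topological overlap matrix for one library type
#'
#' Builds the unsigned soft-threshold adjacency `a_ij = |cor(x_i, x_j)|^p`
#' and its topological overlap
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`, where `k_i` is the connectivity `sum_{u != i} a_iu` and the
#' shared-neighbour sum runs over `u != i, j`.
#'
#' @param values normalized log2 expression, genes x samples, for a single
#'   library type.
#' @param softPower soft-threshold exponent applied to `|cor|` (5 gives an
#'   approximately scale-free adjacency at this replication depth).
#' @param signed use signed correlations (`((1 + r)/2)^p`); the default
#'   unsigned network treats negative and positive correlation alike.
#' @param libraryType optional label stored with the matrix.
#' @return list of class `"TomMatrix"`: `tom` (symmetric, unit diagonal,
#'   values in [0,1]), `adjacency`, `softPower`, `libraryType`.
#' @examples
#' v <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), NULL))
#' round(buildTom(v)$tom, 3)
#' @export
buildTom <- function(values, softPower = 5, signed = FALSE,
                     libraryType = NA_character_) {
  stopifnot(nrow(values) >= 2, ncol(values) >= 3)
  v <- apply(values, 1, stats::var)
  if (any(v == 0))
    stop("constant gene(s): ",
         paste(utils::head(rownames(values)[v == 0], 5), collapse = ", "),
         "; apply the variance filter first")
  r <- stats::cor(t(values))
  a <- if (signed) ((1 + r) / 2)^softPower else abs(r)^softPower
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a                      # diag(a)=0 => sum over u != i, j
  minK <- outer(k, k, pmin)
  tom <- (shared + a) / (minK + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2              # symmetrize numerical noise
  structure(list(tom = tom, adjacency = a, softPower = softPower,
                 signed = signed, libraryType = libraryType),
            class = "TomMatrix")
}

#' @export
print.TomMatrix <- function(x, ...) {
  cat("TomMatrix: ", nrow(x$tom), " genes, soft power ", x$softPower,
      if (!is.na(x$libraryType)) paste0(", library type ", x$libraryType),
      "\n", sep = "")
  invisible(x)
}

#' Quantile-match a TOM to a reference library type
#'
#' Raises the off-diagonal entries of `target` to the power `p` solving
#' `q(target)^p = q(reference)` at the chosen quantile, aligning the
#' overall TOM distribution of the two library types while preserving
#' ranks (the transform is monotone).
#'
#' @param target,reference `"TomMatrix"` objects over the same genes.
#' @param quantile the matching quantile of the off-diagonal values.
#' @return The rescaled target `"TomMatrix"`.
#' @export
scaleTom <- function(target, reference, quantile = 0.95) {
  tt <- target$tom; rr <- reference$tom
  stopifnot(identical(dim(tt), dim(rr)))
  off <- upper.tri(tt)
  qT <- stats::quantile(tt[off], quantile, names = FALSE)
  qR <- stats::quantile(rr[off], quantile, names = FALSE)
  if (qR <= 0 || qR >= 1 || qT <= 0 || qT >= 1) {
    warning("degenerate matching quantile (", signif(qT, 3), " vs ",
            signif(qR, 3), "); TOM left unscaled")
    return(target)
  }
  p <- log(qR) / log(qT)
  out <- tt
  out[off] <- tt[off]^p
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  target$tom <- out
  target$scalePower <- p
  target
}
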
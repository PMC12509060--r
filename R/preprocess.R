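# Normalization, gene filtering and per-gene G/E/GxE differential
# expression.

#' Relative-log-expression (median-of-ratios) size factors
#'
#' For every gene with positive counts in all samples, the ratio of its
#' count to its geometric mean across samples is formed; a sample's size
#' factor is the median of these ratios. Size factors are scale-equivariant:
#' multiplying one sample's counts by c multiplies its factor by c.
#'
#' @param counts nonnegative count matrix (genes x samples) or a
#'   [GxEExperiment-class].
#' @return Positive numeric vector of per-sample size factors.
#' @examples
#' m <- rbind(a = c(2, 4), b = c(2, 4), c = c(2, 4))
#' rleSizeFactors(m)  # 1/sqrt(2), sqrt(2)
#' @export
rleSizeFactors <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  allPos <- rowSums(counts <= 0) == 0
  if (!any(allPos))
    stop("no gene has positive counts in every sample; ",
         "filter to well-expressed genes before normalization")
  lc <- log(counts[allPos, , drop = FALSE])
  logGeo <- rowMeans(lc)
  sf <- apply(lc - logGeo, 2, stats::median)
  exp(sf)
}

#' Log2 normalization by size factors
#'
#' Computes `log2(count / sizeFactor + 1)`. When given a
#' [GxEExperiment-class], size factors are estimated with
#' [rleSizeFactors()] (unless supplied), the normalized matrix is attached
#' as assay `"normalized"` and the factors as `colData(x)$sizeFactor`.
#'
#' @param counts count matrix or [GxEExperiment-class].
#' @param sizeFactors positive per-sample factors; estimated if `NULL` and
#'   a GxEExperiment is given.
#' @return Matrix of normalized values, or the augmented GxEExperiment.
#' @examples
#' normalizeLog2(rbind(g = c(0, 7, 6)), sizeFactors = c(1, 1, 2))
#' @export
normalizeLog2 <- function(counts, sizeFactors = NULL) {
  if (methods::is(counts, "SummarizedExperiment")) {
    obj <- counts
    cts <- SummarizedExperiment::assay(obj, "counts")
    if (is.null(sizeFactors)) sizeFactors <- rleSizeFactors(cts)
    SummarizedExperiment::assay(obj, "normalized") <-
      normalizeLog2(cts, sizeFactors)
    obj$sizeFactor <- sizeFactors
    return(obj)
  }
  if (is.null(sizeFactors))
    stop("sizeFactors are required when normalizing a plain matrix")
  if (length(sizeFactors) != ncol(counts))
    stop("length(sizeFactors) must equal ncol(counts)")
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, sizeFactors, "/") + 1)
}

#' Expression and replicate-variance gene filters
#'
#' Two filters are applied: (a) genes with `> 0` counts in strictly more
#' than `minSamplesExpressed` samples are "expressed"; (b) within each
#' library type, genes whose variance of normalized values across that
#' library type's replicates is at least `minVariance` pass the variance
#' filter. The `universe` slot of the result (expressed genes passing the
#' variance filter in every library type) is the gene universe used for
#' module detection and overlap testing.
#'
#' @param x a [GxEExperiment-class] carrying assays `"counts"` and
#'   `"normalized"`.
#' @param minSamplesExpressed strict lower bound on the number of samples
#'   with a nonzero count.
#' @param minVariance minimum within-library-type variance of normalized
#'   values.
#' @return list with `expressed` (character), `variancePass` (named list of
#'   character vectors, one per library type) and `universe` (character).
#' @export
filterGenes <- function(x, minSamplesExpressed = 10, minVariance = 0.1) {
  stopifnot(minSamplesExpressed >= 0, minVariance >= 0)
  cts <- SummarizedExperiment::assay(x, "counts")
  norm <- SummarizedExperiment::assay(x, "normalized")
  expressed <- rownames(cts)[rowSums(cts > 0) > minSamplesExpressed]
  lts <- unique(x$libraryType)
  vp <- lapply(lts, function(lt) {
    sub <- norm[, x$libraryType == lt, drop = FALSE]
    v <- apply(sub, 1, stats::var)
    rownames(norm)[v >= minVariance]
  })
  names(vp) <- lts
  universe <- Reduce(intersect, c(list(expressed), vp))
  list(expressed = expressed, variancePass = vp, universe = universe)
}

# vectorized per-gene OLS: Y genes x samples, X samples x p
#' @keywords internal
#' @noRd
.lmMatrix <- function(Y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design: a genotype x treatment cell is missing")
  n <- nrow(X); p <- ncol(X)
  coef <- t(qr.coef(qrX, t(Y)))
  fitted <- coef %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  xtxInv <- solve(crossprod(X))
  se <- sqrt(outer(sigma2, diag(xtxInv)))
  tstat <- coef / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  list(coef = coef, se = se, t = tstat, p = pval, df = df,
       sigma2 = sigma2, rss = rss)
}

#' Per-gene genotype/treatment/GxE differential-expression models
#'
#' Fits, for every gene, a linear model of log2-normalized expression on the
#' genotype and treatment codes. The default Gaussian fit on log2 values is
#' calibrated on negative-binomial simulated counts by the package's test
#' suite; an optional negative-binomial GLM backend (`method = "nb"`,
#' fitted on raw counts with a size-factor offset) is available for users
#' who prefer a count likelihood. P-values are Benjamini-Hochberg adjusted
#' within each coefficient family (main effects at `fdrMain`, the
#' interaction at `fdrGxe`).
#'
#' @param x [GxEExperiment-class] with a `"normalized"` assay (and
#'   `"counts"` for `method = "nb"`).
#' @param model `"interaction"` (`~ genotype * treatment`), `"additive"`
#'   (`~ genotype + treatment`), or `"stratified-by-genotype"` /
#'   `"stratified-by-treatment"` (the other factor's effect fitted within
#'   each level).
#' @param fdrMain,fdrGxe FDR levels attached to the significance calls for
#'   main effects and the interaction term.
#' @param method `"lm"` (default) or `"nb"`.
#' @return data.frame, one row per gene, with `estimate_*`, `p_*` and `q_*`
#'   columns per term, plus `sig_*` calls at the configured FDR levels.
#'   For stratified models, columns are suffixed by stratum
#'   (e.g. `_Bd21`, `_Bd3.1`).
#' @export
fitDge <- function(x, model = c("interaction", "additive",
                                "stratified-by-genotype",
                                "stratified-by-treatment"),
                   fdrMain = 0.05, fdrGxe = 0.1,
                   method = c("lm", "nb")) {
  model <- match.arg(model)
  method <- match.arg(method)
  g <- x$genotype
  e <- x$treatment
  tab <- table(factor(g, 0:1), factor(e, 0:1))
  if (model == "interaction" && any(tab == 0))
    stop("interaction model needs all four genotype x treatment cells")
  if (any(tab[tab > 0] < 2))
    stop("at least 2 replicates per design cell are required")
  Y <- SummarizedExperiment::assay(x, "normalized")

  strat <- function(keep, X, terms, suffix) {
    fit <- if (method == "lm") .lmMatrix(Y[, keep, drop = FALSE], X)
    else .nbMatrix(SummarizedExperiment::assay(x, "counts")[, keep,
                                                            drop = FALSE],
                   X, x$sizeFactor[keep])
    out <- data.frame(row.names = rownames(Y))
    for (k in seq_along(terms)) {
      tm <- terms[k]
      p <- fit$p[, k + 1]
      q <- stats::p.adjust(p, "BH")
      fdr <- if (tm == "gxe") fdrGxe else fdrMain
      out[[paste0("estimate_", tm, suffix)]] <- fit$coef[, k + 1]
      out[[paste0("se_", tm, suffix)]] <- fit$se[, k + 1]
      out[[paste0("p_", tm, suffix)]] <- p
      out[[paste0("q_", tm, suffix)]] <- q
      out[[paste0("sig_", tm, suffix)]] <- q < fdr
    }
    out
  }

  res <- switch(model,
    interaction = strat(rep(TRUE, ncol(Y)), cbind(1, g, e, g * e),
                        c("genotype", "treatment", "gxe"), ""),
    additive = strat(rep(TRUE, ncol(Y)), cbind(1, g, e)[, , drop = FALSE],
                     c("genotype", "treatment"), ""),
    `stratified-by-genotype` = {
      cbind(strat(g == 0, cbind(1, e[g == 0]), "treatment", "_Bd21"),
            strat(g == 1, cbind(1, e[g == 1]), "treatment", "_Bd3.1"))
    },
    `stratified-by-treatment` = {
      cbind(strat(e == 0, cbind(1, g[e == 0]), "genotype", "_control"),
            strat(e == 1, cbind(1, g[e == 1]), "genotype", "_drought"))
    })
  res <- cbind(gene = rownames(Y), res)
  attr(res, "model") <- model
  attr(res, "fdrMain") <- fdrMain
  attr(res, "fdrGxe") <- fdrGxe
  res
}

# negative-binomial GLM backend, per gene (slow; optional)
#' @keywords internal
#' @noRd
.nbMatrix <- function(counts, X, sizeFactors) {
  if (is.null(sizeFactors)) sizeFactors <- rleSizeFactors(counts)
  off <- log(sizeFactors)
  p <- ncol(X)
  coef <- se <- pv <- matrix(NA_real_, nrow(counts), p,
                             dimnames = list(rownames(counts), NULL))
  for (i in seq_len(nrow(counts))) {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(counts[i, ] ~ X - 1 + offset(off))),
      error = function(err) NULL)
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    coef[i, ] <- sm[, 1]; se[i, ] <- sm[, 2]; pv[i, ] <- sm[, 4]
  }
  list(coef = coef, se = se, t = coef / se, p = pv,
       df = ncol(counts) - p)
}

#' Classify the shape of a gene's GxE expression response
#'
#' For genes with a significant interaction term, the per-genotype
#' treatment contrasts (stratified fits at `fdrStrat`) determine the
#' response class: up/down in both genotypes with different strengths,
#' up/down in only one genotype, or opposite directions. When neither
#' stratified contrast reaches significance the gene is assigned to the
#' genotype with the larger absolute fold change (a convention; such genes
#' are rare because the interaction is itself significant).
#'
#' @param dgeInteraction result of `fitDge(x, model = "interaction")`.
#' @param dgeStratified result of
#'   `fitDge(x, model = "stratified-by-genotype")`.
#' @param fdrStrat FDR level for the per-genotype treatment contrasts.
#' @return data.frame with one row per significant-GxE gene: `gene`,
#'   `lfc_Bd21`, `lfc_Bd3.1` and `class`.
#' @export
classifyGxeResponse <- function(dgeInteraction, dgeStratified,
                                fdrStrat = 0.05) {
  gxe <- dgeInteraction$gene[dgeInteraction$sig_gxe]
  if (!length(gxe))
    return(data.frame(gene = character(), lfc_Bd21 = numeric(),
                      lfc_Bd3.1 = numeric(), class = character()))
  st <- dgeStratified[match(gxe, dgeStratified$gene), ]
  l0 <- st$estimate_treatment_Bd21
  l1 <- st$estimate_treatment_Bd3.1
  s0 <- stats::p.adjust(st$p_treatment_Bd21, "BH") < fdrStrat
  s1 <- stats::p.adjust(st$p_treatment_Bd3.1, "BH") < fdrStrat
  cls <- character(length(gxe))
  for (i in seq_along(gxe)) {
    cls[i] <- if (s0[i] && s1[i]) {
      if (sign(l0[i]) == sign(l1[i])) {
        if (l0[i] > 0) "both-up-different-strength"
        else "both-down-different-strength"
      } else "opposite"
    } else if (s1[i]) {
      if (l1[i] > 0) "Bd3-1-only-up" else "Bd3-1-only-down"
    } else if (s0[i]) {
      if (l0[i] > 0) "Bd21-only-up" else "Bd21-only-down"
    } else {
      # convention: attribute to the genotype with the larger response
      if (abs(l1[i]) >= abs(l0[i])) {
        if (l1[i] > 0) "Bd3-1-only-up" else "Bd3-1-only-down"
      } else {
        if (l0[i] > 0) "Bd21-only-up" else "Bd21-only-down"
      }
    }
  }
  data.frame(gene = gxe, lfc_Bd21 = l0, lfc_Bd3.1 = l1, class = cls,
             stringsAsFactors = FALSE)
}
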
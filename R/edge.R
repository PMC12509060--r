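# Edge-level G/E/GxE regression: does genotype, environment or their
# interaction change the slope or intercept of a regulator -> target
# relationship?

# full interaction design for n regulators:
# y = g0 + gg*g + ge*e + gge*g*e + sum_i (b0 + bg*g + be*e + bge*g*e) x_i
#' @keywords internal
#' @noRd
.edgeDesign <- function(X, g, e) {
  n <- length(g)
  D <- cbind(gamma0 = rep(1, n), gammaG = g, gammaE = e, gammaGE = g * e)
  for (i in seq_len(ncol(X))) {
    nm <- colnames(X)[i]
    if (is.null(nm)) nm <- paste0("x", i)
    xi <- X[, i]
    block <- cbind(xi, xi * g, xi * e, xi * g * e)
    colnames(block) <- paste0(c("beta0", "betaG", "betaE", "betaGE"),
                              ".", nm)
    D <- cbind(D, block)
  }
  D
}

#' Fit the edge-level genotype x environment interaction regression
#'
#' Regresses a target gene's log2 expression on its inferred regulator(s)
#' with a full set of genotype/treatment modifiers:
#' `y = g0 + gg g + ge e + gge g e + sum_i (b0i + bgi g + bei e +
#' bgei g e) x_i`, with the condition codes g, e in \{0, 1\} (0,0 = Bd21
#' control ... 1,1 = Bd3-1 drought). A significant `betaG`/`betaE`/`betaGE`
#' indicates a genotype/environment/GxE effect on the regulatory slope; the
#' corresponding `gamma` terms capture intercept (baseline expression)
#' effects. Per-coefficient t-tests are reported uncorrected at `alpha`;
#' edges with `R^2 <= r2Threshold` are flagged excluded. A multivariate fit
#' is used when several regulators are supplied.
#'
#' @param y numeric target expression (log2 normalized), one value per
#'   sample. A log-transformed molecular trait may be used as target.
#' @param X numeric matrix of regulator expression, samples x regulators
#'   (a vector is treated as a single regulator).
#' @param genotype,treatment 0/1 condition codes per sample.
#' @param r2Threshold minimum model R^2 for an edge to be interpreted.
#' @param alpha per-coefficient significance level (uncorrected).
#' @return list of class `"EdgeTestResult"`: `coefficients` (data.frame
#'   with estimate, se, t, p per term), `r2`, `excluded`, `nRegulators`,
#'   `conditionSlopes` (per-library-type slope of each regulator implied by
#'   the pooled fit), `alpha`.
#' @export
fitEdgeModel <- function(y, X, genotype, treatment, r2Threshold = 0.5,
                         alpha = 0.05) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(NULL, "x1"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  g <- as.numeric(genotype); e <- as.numeric(treatment)
  stopifnot(length(y) == nrow(X), length(g) == length(y),
            length(e) == length(y))
  if (length(unique(paste(g, e))) < 4)
    stop("all four genotype x treatment cells must be represented")
  if (length(y) <= 4 * (ncol(X) + 1))
    stop("need more than 4 * (nRegulators + 1) samples")
  D <- .edgeDesign(X, g, e)
  if (kappa(crossprod(D)) > 1e10)
    stop("collinear regulators (condition number ",
         format(kappa(crossprod(D)), digits = 3), "); drop one")
  fit <- stats::lm.fit(D, y)
  p <- ncol(D); n <- length(y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  sigma2 <- rss / (n - p)
  vc <- sigma2 * solve(crossprod(D))
  se <- sqrt(diag(vc))
  tstat <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tstat), n - p)
  coefs <- data.frame(term = colnames(D), estimate = fit$coefficients,
                      se = se, t = tstat, p = pval,
                      significant = pval < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  # per-condition slope implied by the pooled fit (algebraic identity with
  # a stratified fit on the same samples)
  cs <- NULL
  for (i in colnames(X)) {
    b <- coefs$estimate[match(paste0(c("beta0", "betaG", "betaE",
                                       "betaGE"), ".", i), coefs$term)]
    for (gg in 0:1) for (ee in 0:1)
      cs <- rbind(cs, data.frame(
        regulator = i, library_type = libraryTypeLabel(gg, ee),
        slope = b[1] + b[2] * gg + b[3] * ee + b[4] * gg * ee,
        stringsAsFactors = FALSE))
  }
  structure(list(coefficients = coefs, r2 = r2,
                 excluded = r2 <= r2Threshold,
                 nRegulators = ncol(X), regulators = colnames(X),
                 conditionSlopes = cs, alpha = alpha, n = n),
            class = "EdgeTestResult")
}

#' @export
print.EdgeTestResult <- function(x, ...) {
  cat("Edge GxE regression: ", x$nRegulators, " regulator(s), n = ", x$n,
      ", R^2 = ", round(x$r2, 3),
      if (x$excluded) " (excluded by R^2 filter)", "\n", sep = "")
  sig <- x$coefficients[x$coefficients$significant, "term"]
  cat("  significant terms (P < ", x$alpha, "): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Classify the regulatory pattern of a fitted edge
#'
#' Assigns non-exclusive flags from the modifier tests of a single-
#' regulator [fitEdgeModel()] fit, plus per-condition slope significance
#' from stratified fits on the same samples: `GXE_SLOPE` (betaGE
#' significant), `ENV_SLOPE`/`GENO_SLOPE` (betaE/betaG significant),
#' `STRENGTH_CHANGE` (slope significant with the same sign in all four
#' library types while some slope modifier is significant),
#' `INTERCEPT_CHANGE` (a gamma modifier significant), `CONSERVED` (no
#' modifier significant; with both genes individually GxE this is the
#' transmission pattern). The primary label takes the highest-precedence
#' flag: GXE_SLOPE, then STRENGTH_CHANGE (a conserved-direction
#' interaction whose strength shifts), then ENV_SLOPE/GENO_SLOPE (by
#' smaller P when both), then INTERCEPT_CHANGE, then CONSERVED.
#'
#' @param fit an `"EdgeTestResult"` from a single-regulator
#'   [fitEdgeModel()].
#' @param y,x,genotype,treatment the data the edge was fitted on (used for
#'   the per-condition stratified slope tests).
#' @param alpha significance level.
#' @return list: `flags` (character vector), `primary` (single label),
#'   `conditionSlopes` (data.frame with per-condition slope, P).
#' @export
classifyEdgePattern <- function(fit, y, x, genotype, treatment,
                                alpha = 0.05) {
  if (fit$excluded)
    stop("edge was excluded by the R^2 filter; no pattern is assigned")
  stopifnot(fit$nRegulators == 1)
  cf <- fit$coefficients
  pOf <- function(term) cf$p[match(term, cf$term)]
  reg <- fit$regulators[1]
  sigBG <- pOf(paste0("betaG.", reg)) < alpha
  sigBE <- pOf(paste0("betaE.", reg)) < alpha
  sigBGE <- pOf(paste0("betaGE.", reg)) < alpha
  sigGamma <- any(cf$p[match(c("gammaG", "gammaE", "gammaGE"),
                             cf$term)] < alpha)

  cs <- NULL
  for (gg in 0:1) for (ee in 0:1) {
    sel <- genotype == gg & treatment == ee
    sf <- summary(stats::lm(y[sel] ~ x[sel]))$coefficients
    cs <- rbind(cs, data.frame(
      library_type = libraryTypeLabel(gg, ee), slope = sf[2, 1],
      p = sf[2, 4], stringsAsFactors = FALSE))
  }
  allSig <- all(cs$p < alpha)
  sameSign <- length(unique(sign(cs$slope))) == 1
  anySlopeMod <- sigBG || sigBE || sigBGE

  flags <- character()
  if (sigBGE) flags <- c(flags, "GXE_SLOPE")
  if (sigBE) flags <- c(flags, "ENV_SLOPE")
  if (sigBG) flags <- c(flags, "GENO_SLOPE")
  if (allSig && sameSign && anySlopeMod)
    flags <- c(flags, "STRENGTH_CHANGE")
  if (sigGamma) flags <- c(flags, "INTERCEPT_CHANGE")
  if (!anySlopeMod && !sigGamma) flags <- c(flags, "CONSERVED")

  primary <- if ("GXE_SLOPE" %in% flags) "GXE_SLOPE"
  else if ("STRENGTH_CHANGE" %in% flags) "STRENGTH_CHANGE"
  else if (sigBE && sigBG) {
    if (pOf(paste0("betaE.", reg)) <= pOf(paste0("betaG.", reg)))
      "ENV_SLOPE" else "GENO_SLOPE"
  }
  else if (sigBE) "ENV_SLOPE"
  else if (sigBG) "GENO_SLOPE"
  else if (sigGamma) "INTERCEPT_CHANGE"
  else "CONSERVED"

  list(flags = flags, primary = primary, conditionSlopes = cs)
}

#' Slope-differentiation test on standardized data (CILP-style)
#'
#' Standardizes target and regulator to zero mean and unit variance over
#' the analysis set and refits the single-regulator edge model, so the
#' slope-modifier tests become tests of correlation differences between
#' conditions (the correlated-individual-level-pairs formulation). The
#' standardized test statistics are invariant to the measurement scale of
#' either gene.
#'
#' @param y,x target and regulator expression.
#' @param genotype,treatment 0/1 condition codes.
#' @param alpha significance level.
#' @return An `"EdgeTestResult"` on the standardized variables.
#' @export
cilpStandardized <- function(y, x, genotype, treatment, alpha = 0.05) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("zero variance in target or regulator")
  fitEdgeModel(as.numeric(scale(y)),
               matrix(as.numeric(scale(x)), ncol = 1,
                      dimnames = list(NULL, "x1")),
               genotype, treatment, r2Threshold = -Inf, alpha = alpha)
}

#' Are GxE targets preferentially regulated by GxE genes?
#'
#' For each target gene with at least one parent in the module graph,
#' computes the fraction of its parents that are GxE genes, and compares
#' this fraction between GxE targets and non-GxE targets with a
#' two-sample t-test (the "transmission" enrichment: GxE expression
#' propagating along conserved regulatory edges).
#'
#' @param graph a [CausalGraph-class] or an edge data.frame with `from`,
#'   `to`.
#' @param gxeGenes character vector of genes with significant GxE
#'   expression.
#' @return list: `statistic`, `p`, `meanFractionGxe`,
#'   `meanFractionNonGxe`, `nGxe`, `nNonGxe`.
#' @export
transmissionEnrichment <- function(graph, gxeGenes) {
  e <- if (methods::is(graph, "CausalGraph")) graphEdges(graph) else graph
  targets <- unique(e$to)
  frac <- vapply(targets, function(tg) {
    pa <- e$from[e$to == tg]
    mean(pa %in% gxeGenes)
  }, numeric(1))
  isGxe <- targets %in% gxeGenes
  if (sum(isGxe) < 2 || sum(!isGxe) < 2)
    stop("need at least 2 GxE and 2 non-GxE targets with parents")
  tt <- if (stats::sd(frac[isGxe]) == 0 && stats::sd(frac[!isGxe]) == 0) {
    # degenerate (constant fractions in both groups): identical means are
    # indistinguishable (p = 1), different means are perfectly separated
    sep <- mean(frac[isGxe]) != mean(frac[!isGxe])
    list(statistic = c(t = if (sep) Inf else 0),
         p.value = if (sep) 0 else 1)
  } else stats::t.test(frac[isGxe], frac[!isGxe])
  list(statistic = unname(tt$statistic), p = tt$p.value,
       meanFractionGxe = mean(frac[isGxe]),
       meanFractionNonGxe = mean(frac[!isGxe]),
       nGxe = sum(isGxe), nNonGxe = sum(!isGxe))
}

#' Edge tests for every retained edge of a causal graph
#'
#' Convenience wrapper running [fitEdgeModel()] (and, for edges passing the
#' R^2 filter, [classifyEdgePattern()]) for each target of a
#' [CausalGraph-class], using all of a target's retained parents as
#' regulators for the fit and each single parent for the pattern label.
#'
#' @param graph a [CausalGraph-class].
#' @param values normalized expression (genes x samples) holding all graph
#'   nodes.
#' @param design design data.frame with `genotype`, `treatment` aligned to
#'   the columns of `values`.
#' @param r2Threshold,alpha see [fitEdgeModel()].
#' @return data.frame with one row per edge: coefficient estimates and
#'   P-values of the slope family, R^2, `excluded`, and the pattern label.
#' @export
edgeTests <- function(graph, values, design, r2Threshold = 0.5,
                      alpha = 0.05) {
  e <- graphEdges(graph)
  e <- e[!duplicated(paste(e$from, e$to)), , drop = FALSE]
  out <- NULL
  g <- design$genotype; tr <- design$treatment
  for (tg in unique(e$to)) {
    parents <- unique(e$from[e$to == tg])
    y <- values[tg, ]
    X <- t(values[parents, , drop = FALSE])
    fit <- tryCatch(fitEdgeModel(y, X, g, tr, r2Threshold, alpha),
                    error = function(err) NULL)
    if (is.null(fit)) next
    for (pa in parents) {
      cf <- fit$coefficients
      pick <- function(w) {
        i <- match(paste0(w, ".", pa), cf$term)
        c(cf$estimate[i], cf$p[i])
      }
      b0 <- pick("beta0"); bg <- pick("betaG"); be <- pick("betaE")
      bge <- pick("betaGE")
      lab <- NA_character_
      if (!fit$excluded) {
        cls <- classifyEdgePattern(
          fitEdgeModel(y, X[, pa], g, tr, r2Threshold = -Inf,
                       alpha = alpha),
          y, X[, pa], g, tr, alpha)
        lab <- cls$primary
      }
      out <- rbind(out, data.frame(
        from = pa, to = tg, n_regulators = length(parents),
        beta0 = b0[1], p_beta0 = b0[2], betaG = bg[1], p_betaG = bg[2],
        betaE = be[1], p_betaE = be[2], betaGE = bge[1],
        p_betaGE = bge[2], r2 = fit$r2, excluded = fit$excluded,
        pattern = lab, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(from = character(), to = character())
  out
}
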
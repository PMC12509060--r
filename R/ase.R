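# Allele-specific expression: cis/trans classification from F1 hybrids
# and parents.
#
# Coding (fixed): T = treatment (0 control, 1 drought), A = allele
# (0 Bd21, 1 Bd3-1), G = generation (0 F1, 1 parents). In the full model
# log2 q = b0 + bT*T + bA*A + bG*G + bAG*A*G + bTG*T*G + bAT*T*A +
# bAGT*A*T*G, the allele term bA tests cis-acting regulation (allelic
# imbalance shared by F1 and parents), bAG tests trans-acting regulation
# (parental divergence absent from F1 allelic ratios), and bAT / bAGT the
# corresponding environment-dependent versions.

#' Filter to allele-informative genes
#'
#' Keeps genes whose alleles can be distinguished reliably: in every
#' parental sample, the own-accession allele has more than `minOwnCount`
#' counts and the opposing accession's allele carries less than
#' `maxOpposingFraction` of that sample's total for the gene. The filter is
#' monotone: lowering `maxOpposingFraction` never adds genes.
#'
#' @param aseCounts long-format allele counts: `gene`, `sample_id`,
#'   `allele`, `count` (see [simulateAse()]).
#' @param design ASE design with `generation` and `genotype` columns.
#' @param minOwnCount strict lower bound on the own-allele count.
#' @param maxOpposingFraction strict upper bound on the opposing allele's
#'   share.
#' @return Character vector of informative gene ids.
#' @export
filterAllelicGenes <- function(aseCounts, design, minOwnCount = 1,
                               maxOpposingFraction = 0.2) {
  par <- design[design$generation == 1, , drop = FALSE]
  if (!nrow(par)) stop("no parental samples in design")
  # allele-indistinguishable genes (NA allele) are never informative
  naGenes <- unique(aseCounts$gene[is.na(aseCounts$allele)])
  d <- aseCounts[aseCounts$sample_id %in% par$sample_id &
                   !aseCounts$gene %in% naGenes, , drop = FALSE]
  if (!nrow(d)) return(character())
  d$own <- d$allele == par$genotype[match(d$sample_id, par$sample_id)]
  keep <- vapply(split(d, d$gene), function(dg) {
    tot <- tapply(dg$count, dg$sample_id, sum)
    ownOk <- all(dg$count[dg$own] > minOwnCount)
    opp <- dg[!dg$own, , drop = FALSE]
    oppOk <- if (!nrow(opp)) TRUE else
      all(opp$count / tot[opp$sample_id] < maxOpposingFraction)
    ownOk && oppOk
  }, logical(1))
  names(keep)[keep]
}

#' Normalize allele-resolved counts
#'
#' Size factors are estimated by RLE on the per-sample gene totals
#' (alleles summed, so allele-indistinguishable genes could be included on
#' the same footing), and both alleles of a sample share that sample's
#' factor. Returns the input with a normalized log2 abundance column
#' `q = log2(count / sizeFactor + 1)`.
#'
#' @param aseCounts long-format allele counts.
#' @param sizeFactors optional named per-sample factors; estimated when
#'   NULL.
#' @return The input data.frame with a `q` column added.
#' @export
normalizeAse <- function(aseCounts, sizeFactors = NULL) {
  if (is.null(sizeFactors)) {
    tot <- tapply(aseCounts$count,
                  list(aseCounts$gene, aseCounts$sample_id), sum)
    tot[is.na(tot)] <- 0
    sizeFactors <- rleSizeFactors(tot)
  }
  aseCounts$q <- log2(aseCounts$count /
                        sizeFactors[aseCounts$sample_id] + 1)
  aseCounts
}

# assemble the per-observation model frame for one gene
#' @keywords internal
#' @noRd
.aseFrame <- function(obs, design) {
  i <- match(obs$sample_id, design$sample_id)
  data.frame(q = obs$q, A = obs$allele, T = design$treatment[i],
             G = design$generation[i])
}

#' Full 8-term allele-specific-expression model
#'
#' Fits `q ~ T * A * G` on the log2 normalized allele abundances of one
#' gene (both generations, both treatments, both alleles), testing each
#' coefficient at `alpha` uncorrected. Falls back to the per-condition
#' half models (with a warning) when a stratum is missing.
#'
#' @param obs long-format observations of one gene with a `q` column (see
#'   [normalizeAse()]).
#' @param design ASE design table.
#' @param alpha per-coefficient significance level.
#' @return data.frame with one row per coefficient: `term` (`bA`, `bAG`,
#'   `bAT`, `bAGT`, ...), `estimate`, `p`, `significant`.
#' @export
fitAseFull <- function(obs, design, alpha = 0.1) {
  mf <- .aseFrame(obs, design)
  cells <- unique(mf[, c("A", "T", "G")])
  if (nrow(cells) < 8) {
    warning("missing stratum for gene; falling back to half models")
    halves <- lapply(0:1, function(tr)
      tryCatch(fitAseHalf(obs, design, treatment = tr, alpha = alpha),
               error = function(e) NULL))
    halves <- halves[!vapply(halves, is.null, logical(1))]
    if (!length(halves))
      stop("no treatment stratum retains both generations")
    return(do.call(rbind, halves))
  }
  fit <- stats::lm(q ~ T * A * G, data = mf)
  sm <- summary(fit)$coefficients
  map <- c("(Intercept)" = "b0", "T" = "bT", "A" = "bA", "G" = "bG",
           "T:A" = "bAT", "T:G" = "bTG", "A:G" = "bAG", "T:A:G" = "bAGT")
  data.frame(term = unname(map[rownames(sm)]), estimate = sm[, 1],
             se = sm[, 2], p = sm[, 4], significant = sm[, 4] < alpha,
             model = "full", row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-condition ("half") allele-specific-expression model
#'
#' Fits `q ~ A * G` within one treatment stratum: `bA` flags cis and `bAG`
#' trans regulation detected in that condition. Interaction-with-
#' environment modes cannot be tested here; they come from the full model.
#'
#' @param obs long-format observations of one gene with `q`.
#' @param design ASE design table.
#' @param treatment which stratum (0 control, 1 drought).
#' @param alpha per-coefficient significance level.
#' @return data.frame as in [fitAseFull()], with `model` set to
#'   `"half-control"` or `"half-drought"`.
#' @export
fitAseHalf <- function(obs, design, treatment, alpha = 0.1) {
  mf <- .aseFrame(obs, design)
  mf <- mf[mf$T == treatment, , drop = FALSE]
  if (length(unique(mf$G)) < 2)
    stop("both generations are required within the stratum")
  fit <- stats::lm(q ~ A * G, data = mf)
  sm <- summary(fit)$coefficients
  map <- c("(Intercept)" = "b0", "A" = "bA", "G" = "bG", "A:G" = "bAG")
  data.frame(term = unname(map[rownames(sm)]), estimate = sm[, 1],
             se = sm[, 2], p = sm[, 4], significant = sm[, 4] < alpha,
             model = paste0("half-", if (treatment == 0) "control"
                            else "drought"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map significant allele coefficients to regulatory modes
#'
#' Full-model flags: `bA` -> cis, `bAG` -> trans, `bAT` -> cisxE,
#' `bAGT` -> transxE. Half-model flags are suffixed by the condition
#' (`cis-control`, `trans-drought`, ...).
#'
#' @param fullResult result of [fitAseFull()] (may be NULL).
#' @param halfResults optional list of [fitAseHalf()] results.
#' @return Character vector of mode labels (possibly empty).
#' @export
classifyRegulatoryMode <- function(fullResult = NULL, halfResults = NULL) {
  modes <- character()
  if (!is.null(fullResult)) {
    full <- fullResult[fullResult$model == "full", , drop = FALSE]
    map <- c(bA = "cis", bAG = "trans", bAT = "cisxE", bAGT = "transxE")
    hit <- full$term %in% names(map) & full$significant
    modes <- c(modes, unname(map[full$term[hit]]))
  }
  for (hr in halfResults) {
    cond <- sub("^half-", "", hr$model[1])
    map <- c(bA = "cis", bAG = "trans")
    hit <- hr$term %in% names(map) & hr$significant
    modes <- c(modes, paste0(unname(map[hr$term[hit]]), "-", cond))
  }
  unique(modes)
}

#' Run the full ASE analysis for a set of genes
#'
#' Filters to allele-informative genes, normalizes, and fits the full and
#' both half models per gene; assigns mode labels and a primary mode (the
#' significant full-model allele term with the smallest P-value, or
#' `"none"`).
#'
#' @param aseCounts long-format allele counts.
#' @param design ASE design table.
#' @param alpha per-coefficient significance level (0.1, uncorrected).
#' @param filter apply [filterAllelicGenes()] first.
#' @return data.frame with one row per tested gene: estimates and P-values
#'   of the four allele terms, `modes` (comma-separated label set) and
#'   `primary_mode`.
#' @export
aseAnalysis <- function(aseCounts, design, alpha = 0.1, filter = TRUE) {
  genes <- if (filter) filterAllelicGenes(aseCounts, design)
           else unique(aseCounts$gene)
  norm <- normalizeAse(aseCounts)
  out <- NULL
  for (gn in genes) {
    obs <- norm[norm$gene == gn, , drop = FALSE]
    full <- fitAseFull(obs, design, alpha = alpha)
    halves <- list(fitAseHalf(obs, design, 0, alpha = alpha),
                   fitAseHalf(obs, design, 1, alpha = alpha))
    modes <- classifyRegulatoryMode(full, halves)
    fullOnly <- full[full$model == "full", , drop = FALSE]
    terms <- c("bA", "bAG", "bAT", "bAGT")
    est <- fullOnly$estimate[match(terms, fullOnly$term)]
    pv <- fullOnly$p[match(terms, fullOnly$term)]
    sig <- which(fullOnly$significant[match(terms, fullOnly$term)])
    primary <- if (!length(sig)) "none" else {
      modeMap <- c("cis", "trans", "cisxE", "transxE")
      modeMap[sig[which.min(pv[sig])]]
    }
    out <- rbind(out, data.frame(
      gene = gn, bA = est[1], p_bA = pv[1], bAG = est[2], p_bAG = pv[2],
      bAT = est[3], p_bAT = pv[3], bAGT = est[4], p_bAGT = pv[4],
      modes = paste(modes, collapse = ","), primary_mode = primary,
      stringsAsFactors = FALSE))
  }
  out
}
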
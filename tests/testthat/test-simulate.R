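# Synthetic-data generator: design, SEM counts, traits, allele counts.

test_that("makeDesign builds balanced four-cell designs deterministically", {
  d <- makeDesign(48, seed = 1)
  expect_equal(nrow(d), 192)
  expect_equal(unname(table(d$library_type)),
               as.array(rep(48L, 4)), ignore_attr = TRUE)
  expect_equal(nrow(makeDesign(2)), 8)
  expect_identical(makeDesign(5, seed = 3), makeDesign(5, seed = 3))
  expect_error(makeDesign(1), "nRepsPerCondition")
})

test_that("null truth yields mutually independent genes", {
  sc <- makeScenario("null", nReps = 48, nGenes = 100, seed = 1)
  x <- simulateCounts(sc$truth, sc$design, seed = 2)
  cts <- SummarizedExperiment::assay(x, "counts")
  expect_true(all(cts >= 0))
  expect_true(all(cts == round(cts)))
  expect_equal(dim(cts), c(100L, 192L))
  # depth-normalized values (raw log counts share the library-size factor)
  norm <- SummarizedExperiment::assay(normalizeLog2(x), "normalized")
  set.seed(3)
  pairs <- cbind(sample(100, 1000, replace = TRUE),
                 sample(100, 1000, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  rs <- vapply(seq_len(nrow(pairs)), function(k)
    cor(norm[pairs[k, 1], ], norm[pairs[k, 2], ]), numeric(1))
  # the exact-null expectation of |r| at n = 192 is sqrt(2/pi)/sqrt(191)
  # ~ 0.058; anything close to it indicates no residual structure
  expect_lt(mean(abs(rs)), 0.07)
})

test_that("a single planted edge is recovered by latent-scale regression", {
  ma <- c(parentG = 0L, childG = 0L)
  ma[] <- c(1L, 1L)
  truth <- makeGroundTruth(ma,
                           dagEdges = data.frame(parent = "parentG",
                                                 child = "childG",
                                                 w0 = 1))
  d <- makeDesign(48, 1)
  x <- simulateCounts(truth, d, seed = 5)
  lat <- S4Vectors::metadata(x)$latent
  # oracle: OLS on the latent matrix before count noise
  fit <- summary(lm(lat["childG", ] ~ lat["parentG", ]))$coefficients
  expect_lt(abs(fit[2, 1] - 1), 3 * fit[2, 2])
})

test_that("a planted shared-parent module is internally correlated", {
  sc <- makeScenario("blocks", nReps = 48, nBlocks = 2, blockSize = 50,
                     nNoise = 50, seed = 2)
  x <- simulateCounts(sc$truth, sc$design, seed = 3)
  norm <- log2(SummarizedExperiment::assay(x, "counts") + 1)
  ma <- sc$truth@moduleAssignment[rownames(norm)]
  within <- abs(cor(t(norm[ma == 1, ])))
  between <- abs(cor(t(norm[ma == 1, ]), t(norm[ma == 2, ])))
  expect_gt(mean(within[upper.tri(within)]), mean(between))
})

test_that("simulation is bit-reproducible and gene-order invariant", {
  sc <- makeScenario("blocks", nReps = 4, nBlocks = 2, blockSize = 10,
                     nNoise = 5, seed = 1)
  x1 <- simulateCounts(sc$truth, sc$design, seed = 9)
  x2 <- simulateCounts(sc$truth, sc$design, seed = 9)
  expect_identical(SummarizedExperiment::assay(x1, "counts"),
                   SummarizedExperiment::assay(x2, "counts"))

  # permute gene order and edge order in the truth object
  tr <- sc$truth
  perm <- rev(seq_along(tr@moduleAssignment))
  tr2 <- makeGroundTruth(tr@moduleAssignment[perm],
                         dagEdges = tr@dagEdges[rev(seq_len(
                           nrow(tr@dagEdges))), ],
                         meanEffects = tr@meanEffects)
  x3 <- simulateCounts(tr2, sc$design, seed = 9)
  g <- rownames(x1)
  expect_identical(S4Vectors::metadata(x1)$latent[g, ],
                   S4Vectors::metadata(x3)$latent[g, ])
  expect_identical(SummarizedExperiment::assay(x1, "counts")[g, ],
                   SummarizedExperiment::assay(x3, "counts")[g, ])
})

test_that("cyclic dag edges are rejected with a diagnostic", {
  ma <- stats::setNames(rep(1L, 3), c("a", "b", "c"))
  expect_error(
    makeGroundTruth(ma, dagEdges = data.frame(
      parent = c("a", "b", "c"), child = c("b", "c", "a"), w0 = 1)),
    "cycle")
})

test_that("simulateTrait obeys the coupling/noise closed form", {
  sc <- makeScenario("blocks", nReps = 12, nBlocks = 1, blockSize = 20,
                     nNoise = 0, seed = 1)
  x <- normalizeLog2(simulateCounts(sc$truth, sc$design, seed = 2))
  norm <- SummarizedExperiment::assay(x, "normalized")

  tr <- sc$truth
  tr@traitLoadings <- data.frame(trait = "t", module = 1, coupling = 1,
                                 noiseSd = 0)
  t0 <- simulateTrait(tr, norm, seed = 3)
  eig <- computeEigengene(norm)$eigengene
  expect_equal(abs(cor(t0$t, eig)), 1, tolerance = 1e-10)

  tr@traitLoadings$noiseSd <- 1
  tr@traitLoadings$coupling <- 0
  tnull <- simulateTrait(tr, norm, seed = 4)
  expect_lt(abs(cor(tnull$t, eig)), 3 / sqrt(length(eig)))

  # closed form: E[r] ~ coupling / sqrt(coupling^2 + noiseSd^2) for a
  # unit-variance eigengene
  tr@traitLoadings$coupling <- 1
  rs <- vapply(1:50, function(s)
    cor(simulateTrait(tr, norm, seed = s)$t, eig), numeric(1))
  expect_lt(abs(mean(rs) - 1 / sqrt(2)), 0.15)

  tr@traitLoadings$module <- 99
  expect_error(simulateTrait(tr, norm, seed = 1), "absent")
})

test_that("simulateAse plants the four allelic architectures", {
  genes <- c(cisG = "cis", transG = "trans", noneG = "none")
  ma <- stats::setNames(rep(0L, 3), names(genes))
  truth <- makeGroundTruth(ma, aseMode = stats::setNames(unname(genes),
                                                         names(genes)))
  d <- makeAseDesign(12, 1)
  # average fitted coefficients over seeds against the noiseless
  # expectation (per-seed estimates have sd ~0.1 at 12 reps/stratum)
  est <- function(f, term) f$estimate[f$term == term]
  sums <- c(cis_bA = 0, cis_bAG = 0, trans_bA = 0, trans_bAG = 0,
            none_bA = 0, none_bAG = 0, none_bAT = 0, none_bAGT = 0)
  f1p <- c()
  nSeeds <- 20
  for (s in seq_len(nSeeds)) {
    ac <- simulateAse(d, truth, noiseSd = 0.05, libSizeCv = 0,
                      nbDispersion = 0.005, seed = s)
    # unit factors isolate the model from normalization (three structured
    # genes cannot anchor an RLE fit)
    norm <- normalizeAse(ac, sizeFactors = stats::setNames(
      rep(1, nrow(d)), d$sample_id))
    fc <- fitAseFull(norm[norm$gene == "cisG", ], d)
    ft <- fitAseFull(norm[norm$gene == "transG", ], d)
    fn <- fitAseFull(norm[norm$gene == "noneG", ], d)
    sums <- sums + c(est(fc, "bA"), est(fc, "bAG"),
                     est(ft, "bA"), est(ft, "bAG"),
                     est(fn, "bA"), est(fn, "bAG"),
                     est(fn, "bAT"), est(fn, "bAGT"))
    # F1-only subset shows no allelic effect for a trans gene
    f1 <- d$sample_id[d$generation == 0]
    sub <- norm[norm$gene == "transG" & norm$sample_id %in% f1, ]
    sub$treatment <- d$treatment[match(sub$sample_id, d$sample_id)]
    f1fit <- summary(lm(q ~ allele * treatment, data = sub))$coefficients
    f1p <- c(f1p, f1fit["allele", 4])
  }
  m <- sums / nSeeds
  expect_lt(abs(m["cis_bA"] - 1), 0.1)
  expect_lt(abs(m["cis_bAG"]), 0.1)
  expect_lt(abs(m["trans_bA"]), 0.1)
  expect_lt(abs(m["trans_bAG"] - 1), 0.1)
  for (nm in c("none_bA", "none_bAG", "none_bAT", "none_bAGT"))
    expect_lt(abs(m[nm]), 0.1)
  expect_gt(mean(f1p > 0.05), 0.8)

  # missing parental stratum is rejected
  dBad <- d[!(d$generation == 1 & d$genotype == 1), ]
  expect_error(simulateAse(dBad, truth, seed = 1), "inestimable")
})
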
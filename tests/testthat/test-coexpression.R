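# TOM construction, scaling, eigengenes and module detection.

test_that("TOM matches the brute-force definition and limit cases", {
  set.seed(1)
  for (p in c(4, 7, 10)) {
    v <- matrix(rnorm(p * 20), p, 20,
                dimnames = list(paste0("g", seq_len(p)), NULL))
    tm <- buildTom(v)$tom
    expect_equal(tm, bruteTom(v), tolerance = 1e-12)
    expect_true(isSymmetric(tm))
    expect_true(all(tm >= -1e-12 & tm <= 1 + 1e-12))
    expect_equal(unname(diag(tm)), rep(1, p))
  }

  # two perfectly correlated genes: adjacency 1, overlap 1
  z <- rnorm(10)
  v2 <- rbind(g1 = z, g2 = 2 * z + 1)
  expect_equal(unname(buildTom(v2)$tom[1, 2]), 1, tolerance = 1e-10)

  # the spec'd 3-gene system with exact correlations 0.9 / 0.9 / 0.81
  R <- matrix(c(1, .9, .9, .9, 1, .81, .9, .81, 1), 3, 3)
  v3 <- exactCorMatrix(R, n = 30, seed = 2)
  expect_equal(cor(t(v3)), R, tolerance = 1e-10, ignore_attr = TRUE)
  a12 <- 0.9^5; a13 <- 0.9^5; a23 <- 0.81^5
  k <- c(a12 + a13, a12 + a23, a13 + a23)
  hand12 <- (a13 * a23 + a12) / (min(k[1], k[2]) + 1 - a12)
  expect_equal(unname(buildTom(v3)$tom[1, 2]), hand12, tolerance = 1e-10)

  expect_error(buildTom(rbind(g1 = rep(1, 5), g2 = rnorm(5))), "constant")
})

test_that("TOM scaling solves the quantile power equation", {
  mk <- function(val) {
    m <- matrix(val, 4, 4); diag(m) <- 1
    list(tom = m, softPower = 5, libraryType = NA)
  }
  target <- mk(0.25); reference <- mk(0.5)
  out <- scaleTom(target, reference, quantile = 0.95)
  expect_equal(out$scalePower, log(0.5) / log(0.25))   # = 0.5
  expect_equal(out$tom[1, 2], 0.5)

  # identity: scaling a TOM to itself changes nothing
  set.seed(3)
  v <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("g", 1:10), NULL))
  tm <- buildTom(v)
  expect_equal(scaleTom(tm, tm)$tom, tm$tom, tolerance = 1e-12)

  # monotone: ranks preserved
  v2 <- matrix(rnorm(200), 10, 20,
               dimnames = list(paste0("g", 1:10), NULL))
  tm2 <- buildTom(v2)
  sc <- scaleTom(tm, tm2)
  off <- upper.tri(tm$tom)
  expect_equal(cor(tm$tom[off], sc$tom[off], method = "spearman"), 1)

  # degenerate reference quantile: warn, leave unscaled
  degRef <- tm
  degRef$tom[] <- 1
  expect_warning(out2 <- scaleTom(tm, degRef), "unscaled")
  expect_equal(out2$tom, tm$tom)
})

test_that("eigengenes are unit-norm, oriented first principal components", {
  z <- rnorm(12)
  v <- rbind(g1 = z, g2 = 2 * z + 3, g3 = 0.5 * z - 1)
  eg <- computeEigengene(v)
  expect_equal(eg$varExplained, 1, tolerance = 1e-10)
  expect_equal(sum(eg$eigengene^2), 1, tolerance = 1e-10)
  expect_gt(cor(eg$eigengene, z), 0.999)

  # two anti-correlated genes: still rank 1; orientation deterministic
  v2 <- rbind(g1 = z, g2 = -z)
  eg2 <- computeEigengene(v2)
  expect_equal(eg2$varExplained, 1, tolerance = 1e-10)
  eg2b <- computeEigengene(v2)
  expect_identical(eg2$eigengene, eg2b$eigengene)
  expect_gt(cor(eg2$eigengene, z), 0.999)   # oriented to the first gene

  # factor recovery: loadings ~ N(1, 0.1)
  set.seed(4)
  f <- rnorm(48)
  loads <- rnorm(40, 1, 0.1)
  vm <- sapply(f, function(fs) loads * fs) +
    matrix(rnorm(40 * 48, 0, 0.5), 40)
  rownames(vm) <- paste0("g", 1:40)
  expect_gt(abs(cor(computeEigengene(vm)$eigengene, f)), 0.95)

  expect_warning(computeEigengene(rbind(g1 = z, g2 = z,
                                        g3 = rep(1, 12))), "zero-variance")
})

test_that("planted blocks are recovered and noise stays unassigned", {
  aris <- c()
  for (s in 1:3) {
    sc <- makeScenario("blocks", nReps = 48, nBlocks = 4, blockSize = 50,
                       nNoise = 40, seed = s)
    x <- normalizeLog2(simulateCounts(sc$truth, sc$design, seed = s + 100))
    norm <- SummarizedExperiment::assay(x, "normalized")
    v <- norm[, x$libraryType == "Bd21d"]
    ms <- detectModules(buildTom(v), v, preset = "moderate")
    a <- moduleAssignments(ms)
    aris <- c(aris, mclust::adjustedRandIndex(
      sc$truth@moduleAssignment[names(a)], a))
  }
  expect_gt(mean(aris), 0.9)

  sc <- makeScenario("null", nReps = 48, nGenes = 200, seed = 5)
  x <- normalizeLog2(simulateCounts(sc$truth, sc$design, seed = 105))
  norm <- SummarizedExperiment::assay(x, "normalized")
  v <- norm[, x$libraryType == "Bd21c"]
  ms <- detectModules(buildTom(v), v, preset = "moderate")
  expect_gte(mean(moduleAssignments(ms) == 0), 0.9)
})

test_that("modules driven by one shared factor are merged", {
  set.seed(6)
  d <- makeDesign(48, 1)
  f <- rnorm(192)
  # two 40-gene blocks riding the same driver, plus an independent block
  mk <- function(driver, n, sd) {
    m <- sapply(driver, function(fs) rnorm(n, 1, 0.1) * fs) +
      matrix(rnorm(n * length(driver), 0, sd), n)
    m
  }
  g <- rnorm(192)
  vm <- rbind(mk(f, 40, 0.6), mk(f, 40, 1.2), mk(g, 40, 0.6))
  rownames(vm) <- sprintf("g%03d", 1:120)
  v <- vm[, d$library_type == "Bd21c"]
  ms <- detectModules(buildTom(v), v, preset = "moderate")
  a <- moduleAssignments(ms)
  # the two shared-driver blocks end up in one module
  expect_equal(length(unique(a[1:80])), 1)
  expect_false(a[1] == a[101])
})

test_that("detection is invariant to gene order and monotone in size", {
  sc <- makeScenario("blocks", nReps = 48, nBlocks = 3, blockSize = 40,
                     nNoise = 30, seed = 9)
  x <- normalizeLog2(simulateCounts(sc$truth, sc$design, seed = 109))
  norm <- SummarizedExperiment::assay(x, "normalized")
  v <- norm[, x$libraryType == "Bd3-1c"]
  tm <- buildTom(v)
  a1 <- moduleAssignments(detectModules(tm, v, preset = "moderate"))

  set.seed(10)
  perm <- sample(nrow(v))
  tmP <- tm; tmP$tom <- tm$tom[perm, perm]
  a2 <- moduleAssignments(detectModules(tmP, v[perm, ],
                                        preset = "moderate"))
  expect_identical(a1[sort(names(a1))], a2[sort(names(a2))])

  nMods <- sapply(c(15, 30, 60), function(mcs)
    max(moduleAssignments(detectModules(tm, v, preset = "custom",
                                        minClusterSize = mcs))))
  expect_true(all(diff(nMods) <= 0))
})
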
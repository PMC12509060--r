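# Multi-set intersection test, cliques, enrichment, trait correlations.

test_that("the two-set case is exactly the hypergeometric upper tail", {
  set.seed(1)
  for (k in 1:50) {
    N <- sample(20:2000, 1)
    n1 <- sample(1:(N - 1), 1); n2 <- sample(1:(N - 1), 1)
    t <- sample(max(0, n1 + n2 - N):min(n1, n2), 1)
    got <- multisetIntersectionTest(c(n1, n2), N, t)$logP
    want <- phyper(t - 1, n1, N - n1, n2, lower.tail = FALSE,
                   log.p = TRUE)
    expect_lt(abs(got - want), 1e-12)    # absolute agreement in log-P
  }
  # closed form: both sets of 5 in a 10-universe, full overlap
  expect_equal(multisetIntersectionTest(c(5, 5), 10, 5)$p, 1 / choose(10, 5))
})

test_that("higher-order intersections match a Monte-Carlo oracle", {
  set.seed(2)
  cases <- list(list(N = 50, sizes = c(20, 25, 15), t = 4),
                list(N = 30, sizes = c(10, 12, 15, 9), t = 2))
  for (cs in cases) {
    nDraw <- 2e4
    hits <- replicate(nDraw, {
      s <- Reduce(intersect,
                  lapply(cs$sizes, function(n) sample.int(cs$N, n)))
      length(s) >= cs$t
    })
    pMc <- mean(hits)
    pEx <- multisetIntersectionTest(cs$sizes, cs$N, cs$t)$p
    expect_lt(abs(pEx - pMc), 3 * sqrt(pMc * (1 - pMc) / nDraw))
  }
})

test_that("intersection-test edge cases and monotonicity hold", {
  # all sets equal to the universe force t = N and P = 1
  u <- paste0("g", 1:12)
  tst <- multisetIntersectionTest(list(u, u, u), 12)
  expect_equal(tst$observed, 12)
  expect_equal(tst$p, 1)

  expect_error(multisetIntersectionTest(c(60, 5), 50, 2), "larger")

  ps <- sapply(0:10, function(t)
    multisetIntersectionTest(c(10, 15, 12), 40, t)$p)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("clique patterns follow the four-way taxonomy", {
  expect_equal(classifyClique(c("Bd21c:1", "Bd21d:2", "Bd3-1c:3",
                                "Bd3-1d:1")), "conserved")
  expect_equal(classifyClique(c("Bd3-1c:1", "Bd3-1d:4")),
               "genotype-specific")
  expect_equal(classifyClique(c("Bd21d:1", "Bd3-1d:4")),
               "environment-specific")
  expect_equal(classifyClique("Bd21d:7"), "GxE-specific")
  expect_equal(classifyClique(c("Bd21c:1", "Bd21d:1", "Bd3-1d:2")),
               "GxE-specific")
  # two library types sharing neither factor
  expect_equal(classifyClique(c("Bd21c:1", "Bd3-1d:2")), "GxE-specific")
})

test_that("buildCliques links planted identical modules across types", {
  universe <- sprintf("g%05d", 1:2000)
  shared <- universe[1:50]
  droughtOnly <- universe[101:150]
  lts <- c("Bd21c", "Bd21d", "Bd3-1c", "Bd3-1d")
  mkAssign <- function(lt) {
    a <- stats::setNames(rep(0L, 2000), universe)
    a[shared] <- 1L
    if (grepl("d$", lt)) a[droughtOnly] <- 2L
    a
  }
  moderate <- lapply(lts, function(lt) fakeModuleSet(mkAssign(lt), lt))
  conservative <- lapply(lts, function(lt)
    fakeModuleSet(mkAssign(lt), lt, preset = "conservative"))
  names(moderate) <- names(conservative) <- lts
  cr <- buildCliques(moderate, conservative, universe)
  ct <- cliqueTable(cr)
  expect_true("conserved" %in% ct$pattern)
  expect_true("environment-specific" %in% ct$pattern)
  cons <- ct[ct$pattern == "conserved", ]
  expect_equal(cons$n_library_types, 4)
  expect_lt(cons$multiway_p, 1e-12)

  # disjoint modules: no edges, singleton cliques only
  disj <- lapply(seq_along(lts), function(i) {
    a <- stats::setNames(rep(0L, 2000), universe)
    a[universe[(i - 1) * 100 + 1:50]] <- 1L
    fakeModuleSet(a, lts[i])
  })
  names(disj) <- lts
  cr0 <- buildCliques(disj, disj, universe)
  expect_equal(nrow(cr0@edges), 0)
  expect_true(all(cliqueTable(cr0)$n_members == 1))
})

test_that("enrichment matches hypergeometric enumeration", {
  universe <- paste0("g", 1:100)
  module <- universe[1:10]
  cls <- universe[c(1:8, 51:92)]          # 8 of 10 in class, class = 50
  en <- dgeEnrichment(module, cls, universe)
  # brute force over the hypergeometric support
  pBrute <- sum(dhyper(8:10, 50, 50, 10))
  expect_equal(en$p, pBrute, tolerance = 1e-12)
  expect_equal(en$fraction, 0.8)

  full <- dgeEnrichment(universe[1:20], universe[1:20], universe)
  expect_equal(full$fraction, 1)
  expect_lt(full$p, 1e-20)
  expect_error(dgeEnrichment(character(), cls, universe), "empty")
})

test_that("eigengene-trait correlations are exact and calibrated", {
  ms <- fakeModuleSet(stats::setNames(c(1L, 1L, 1L), paste0("g", 1:3)),
                      "Bd21d", nSamples = 48)
  eg <- eigengenes(ms)[, 1]
  traits <- data.frame(sample_id = rownames(eigengenes(ms)), tr = eg)
  out <- moduleTraitCorrelation(ms, traits)
  expect_equal(out$r, 1, tolerance = 1e-10)

  # null: 0.29 is the ~95.4% two-sided point of r at n = 48, so the hit
  # count is Binomial(1000, 0.954); 930 is a > 4-sigma floor
  hits <- 0
  for (s in 1:1000) {
    set.seed(s)
    traits$tr <- rnorm(48)
    hits <- hits + (abs(moduleTraitCorrelation(ms, traits)$r) < 0.29)
  }
  expect_gte(hits, 930)

  expect_error(moduleTraitCorrelation(
    fakeModuleSet(stats::setNames(c(1L, 1L), c("a", "b")), "Bd21c",
                  nSamples = 2),
    data.frame(sample_id = c("s1", "s2"), tr = 1:2)), "3 samples")
})

test_that("a planted trait coupling is recovered through the pipeline path", {
  # background genes outnumber the block so the RLE factors track depth,
  # not the module signal
  sc <- makeScenario("blocks", nReps = 48, nBlocks = 1, blockSize = 40,
                     nNoise = 100, driverSigma = 1.5, seed = 3)
  x <- normalizeLog2(simulateCounts(sc$truth, sc$design, seed = 33))
  norm <- SummarizedExperiment::assay(x, "normalized")
  tr <- sc$truth
  tr@traitLoadings <- data.frame(trait = "glu", module = 1, coupling = 1,
                                 noiseSd = 1)
  lt <- x$libraryType == "Bd21d"
  v <- norm[, lt]
  ms <- detectModules(buildTom(v, libraryType = "Bd21d"), v,
                      preset = "moderate")
  traits <- simulateTrait(tr, norm, seed = 4)
  out <- moduleTraitCorrelation(ms, traits[match(rownames(eigengenes(ms)),
                                                 traits$sample_id), ])
  expect_lt(out$p[out$module == "M1"], 0.001)
})
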
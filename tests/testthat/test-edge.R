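# Edge-level G/E/GxE regression, pattern classification, CILP test,
# transmission enrichment.

test_that("modifier coefficients are null-calibrated and recover truth", {
  d <- makeDesign(48, 1)
  g <- d$genotype; e <- d$treatment

  # identical mechanism in all four conditions: modifiers quiet
  mods <- c("gammaG", "gammaE", "gammaGE", "betaG.x1", "betaE.x1",
            "betaGE.x1")
  quiet <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(192); y <- 1 + 2 * x + rnorm(192, 0, 0.1)
    fit <- fitEdgeModel(y, x, g, e)
    cf <- fit$coefficients
    quiet <- quiet + !any(cf$significant[cf$term %in% mods])
  }
  expect_gte(quiet / 100, 0.7)   # ~ (1 - 0.05)^6 with correlated tests

  # environment-modified slope: 1 under control, 2 under drought
  set.seed(5)
  x <- rnorm(192); y <- (1 + e) * x + rnorm(192, 0, 0.5)
  fit <- fitEdgeModel(y, x, g, e)
  cf <- fit$coefficients
  bE <- cf[cf$term == "betaE.x1", ]
  expect_true(bE$significant)
  expect_lt(abs(bE$estimate - 1), 3 * bE$se)

  # GxE-only slope modifier
  set.seed(6)
  y2 <- (1 + g * e) * x + rnorm(192, 0, 0.5)
  cf2 <- fitEdgeModel(y2, x, g, e)$coefficients
  expect_true(cf2$significant[cf2$term == "betaGE.x1"])
  expect_false(cf2$significant[cf2$term == "betaE.x1"])
  expect_false(cf2$significant[cf2$term == "betaG.x1"])
})

test_that("stratified slopes equal the pooled-fit identity exactly", {
  d <- makeDesign(12, 1)
  set.seed(7)
  x <- rnorm(48)
  y <- (0.5 + d$genotype - 0.3 * d$treatment +
          0.8 * d$genotype * d$treatment) * x + rnorm(48, 0, 0.3)
  fit <- fitEdgeModel(y, x, d$genotype, d$treatment, r2Threshold = -Inf)
  for (gg in 0:1) for (ee in 0:1) {
    sel <- d$genotype == gg & d$treatment == ee
    strat <- unname(coef(lm(y[sel] ~ x[sel]))[2])
    pooled <- fit$conditionSlopes$slope[
      fit$conditionSlopes$library_type == libraryTypeLabel(gg, ee)]
    expect_equal(strat, pooled, tolerance = 1e-12)
  }
})

test_that("the R^2 filter separates real edges from noise pairs", {
  d <- makeDesign(48, 1)
  set.seed(8)
  x <- rnorm(192)
  y <- 2 * x                                   # deterministic edge
  expect_false(fitEdgeModel(y, x, d$genotype, d$treatment)$excluded)
  fails <- 0
  for (s in 1:100) {
    set.seed(s)
    fit <- fitEdgeModel(rnorm(192), rnorm(192), d$genotype, d$treatment)
    fails <- fails + fit$excluded
  }
  expect_gte(fails, 99)
})

test_that("edge precondition and collinearity checks fire", {
  d <- makeDesign(12, 1)
  x <- rnorm(48)
  expect_error(fitEdgeModel(rnorm(48), x, rep(0, 48), d$treatment),
               "four")
  expect_error(fitEdgeModel(rnorm(48), cbind(a = x, b = x), d$genotype,
                            d$treatment), "collinear")
  expect_error(fitEdgeModel(rnorm(8), rnorm(8), rep(0:1, 4),
                            rep(0:1, each = 4)), "samples")
})

test_that("pattern labels follow the case taxonomy", {
  d <- makeDesign(48, 1)
  g <- d$genotype; e <- d$treatment
  set.seed(9)
  x <- rnorm(192)

  # slope only under drought
  y <- e * x + rnorm(192, 0, 0.3)
  fit <- fitEdgeModel(y, x, g, e, r2Threshold = -Inf)
  cls <- classifyEdgePattern(fit, y, x, g, e)
  expect_equal(cls$primary, "ENV_SLOPE")

  # slope 1 vs 2 by genotype, same direction everywhere
  y2 <- (1 + g) * x + rnorm(192, 0, 0.3)
  fit2 <- fitEdgeModel(y2, x, g, e, r2Threshold = -Inf)
  cls2 <- classifyEdgePattern(fit2, y2, x, g, e)
  expect_equal(cls2$primary, "STRENGTH_CHANGE")
  expect_true("GENO_SLOPE" %in% cls2$flags)

  # stable slope, genotype-shifted baseline
  set.seed(14)
  y3 <- 2 + g + x + rnorm(192, 0, 0.3)
  fit3 <- fitEdgeModel(y3, x, g, e, r2Threshold = -Inf)
  cls3 <- classifyEdgePattern(fit3, y3, x, g, e)
  expect_equal(cls3$primary, "INTERCEPT_CHANGE")

  # nothing modified: conserved transmission
  y4 <- 1 + x + rnorm(192, 0, 0.3)
  fit4 <- fitEdgeModel(y4, x, g, e, r2Threshold = -Inf)
  cls4 <- classifyEdgePattern(fit4, y4, x, g, e)
  expect_equal(cls4$primary, "CONSERVED")

  expect_error(classifyEdgePattern(
    fitEdgeModel(rnorm(192), rnorm(192), g, e), rnorm(192), rnorm(192),
    g, e), "excluded")
})

test_that("the standardized (CILP-style) test is scale-invariant and powered", {
  d <- makeDesign(48, 1)
  g <- d$genotype; e <- d$treatment
  set.seed(10)
  x <- rnorm(192); y <- (1 + e) * x + rnorm(192, 0, 0.5)
  t1 <- cilpStandardized(y, x, g, e)$coefficients
  t2 <- cilpStandardized(y, 10 * x, g, e)$coefficients
  expect_equal(t1$t[t1$term == "betaE.x1"], t2$t[t2$term == "betaE.x1"],
               tolerance = 1e-10)

  # null calibration
  rej <- 0
  for (s in 1:500) {
    set.seed(s)
    xs <- rnorm(192); ys <- xs + rnorm(192, 0, 1)
    cf <- cilpStandardized(ys, xs, g, e)$coefficients
    rej <- rej + cf$significant[cf$term == "betaE.x1"]
  }
  expect_gt(rej / 500, 0.02)
  expect_lt(rej / 500, 0.09)

  # power for a correlation difference 0.2 vs 0.8 between treatments
  hit <- 0
  for (s in 1:100) {
    set.seed(s)
    rho <- ifelse(e == 1, 0.8, 0.2)
    xs <- rnorm(192)
    ys <- rho * xs + sqrt(1 - rho^2) * rnorm(192)
    cf <- cilpStandardized(ys, xs, g, e)$coefficients
    hit <- hit + cf$significant[cf$term == "betaE.x1"]
  }
  expect_gte(hit / 100, 0.8)

  expect_error(cilpStandardized(rep(1, 192), rnorm(192), g, e),
               "variance")
})

test_that("transmission enrichment distinguishes propagated GxE", {
  # maximal separation: GxE targets fed only by GxE parents
  edges <- data.frame(
    from = c("p1", "p2", "p1", "p2", "q1", "q2", "q1", "q2"),
    to = c("t1", "t1", "t2", "t2", "u1", "u1", "u2", "u2"))
  gxe <- c("p1", "p2", "t1", "t2")
  res <- transmissionEnrichment(edges, gxe)
  expect_lt(res$p, 0.05)
  expect_equal(res$meanFractionGxe, 1)
  expect_equal(res$meanFractionNonGxe, 0)

  # random labels: rejection near nominal
  set.seed(11)
  targets <- paste0("t", 1:20)
  parents <- paste0("p", 1:30)
  e2 <- do.call(rbind, lapply(targets, function(tg)
    data.frame(from = sample(parents, 3), to = tg)))
  rej <- 0
  for (k in 1:500) {
    lab <- sample(c(targets, parents), 25)
    ok <- tryCatch(transmissionEnrichment(e2, lab)$p < 0.05,
                   error = function(err) NA)
    if (!is.na(ok)) rej <- rej + ok
  }
  expect_lt(rej / 500, 0.09)

  expect_error(transmissionEnrichment(e2, c(targets, parents)), "2 GxE")
})

test_that("partial transmission enrichment is detected with power", {
  # GxE targets draw 80% of parents from the GxE pool, others 20%
  set.seed(12)
  gxePool <- paste0("G", 1:30); plainPool <- paste0("P", 1:30)
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    edges <- NULL
    for (i in 1:10) {
      pa <- c(sample(gxePool, 4), sample(plainPool, 1))
      edges <- rbind(edges, data.frame(from = pa,
                                       to = paste0("gt", i)))
      pb <- c(sample(gxePool, 1), sample(plainPool, 4))
      edges <- rbind(edges, data.frame(from = pb,
                                       to = paste0("pt", i)))
    }
    lab <- c(gxePool, paste0("gt", 1:10))
    hits <- hits + (transmissionEnrichment(edges, lab)$p < 0.05)
  }
  expect_gte(hits / 20, 0.8)
})
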
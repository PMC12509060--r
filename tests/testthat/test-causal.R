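# CI kernel, d-separation oracle, sparsest-permutation search,
# stability selection.

test_that("the Fisher-z CI test is calibrated and detects dependence", {
  set.seed(1)
  rej <- 0
  for (k in 1:1000) {
    d <- matrix(rnorm(1000), 500, 2)
    rej <- rej + !ciTestFisherZ(1, 2, integer(), d, alpha = 0.05)$independent
  }
  expect_gt(rej / 1000, 0.03)
  expect_lt(rej / 1000, 0.07)

  # chain x -> z -> y: conditioning on z restores independence
  acc <- 0
  for (k in 1:200) {
    set.seed(k)
    x <- rnorm(300); z <- x + rnorm(300, 0, 0.5)
    y <- z + rnorm(300, 0, 0.5)
    d <- cbind(x, y, z)
    acc <- acc + ciTestFisherZ(1, 2, 3, d, alpha = 0.05)$independent
  }
  expect_gt(acc / 200, 0.85)

  # (near-)identical variables are maximally dependent
  x <- rnorm(100)
  expect_lt(ciTestFisherZ(1, 2, integer(),
                          cbind(x, x + rnorm(100, 0, 0.01)))$p, 1e-10)
  # an exactly singular covariance is treated as dependence, with warning
  expect_warning(res <- ciTestFisherZ(1, 2, integer(), cbind(x, x)),
                 "singular")
  expect_false(res$independent)
})

test_that("d-separation answers match textbook cases", {
  chain <- matrix(FALSE, 3, 3); chain[1, 2] <- chain[2, 3] <- TRUE
  expect_false(dSeparated(chain, 1, 3))
  expect_true(dSeparated(chain, 1, 3, 2))

  collider <- matrix(FALSE, 3, 3); collider[1, 3] <- collider[2, 3] <- TRUE
  expect_true(dSeparated(collider, 1, 2))
  expect_false(dSeparated(collider, 1, 2, 3))    # conditioning opens it

  fork <- matrix(FALSE, 3, 3); fork[3, 1] <- fork[3, 2] <- TRUE
  expect_false(dSeparated(fork, 1, 2))
  expect_true(dSeparated(fork, 1, 2, 3))
})

test_that("with oracle CI answers the search attains the true edge count", {
  set.seed(7)
  for (rep in 1:15) {
    p <- sample(3:5, 1)
    adj <- matrix(FALSE, p, p)
    ord <- sample(p)
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      if (runif(1) < 0.4) adj[ord[i], ord[j]] <- TRUE
    orc <- dsepOracle(adj)
    # brute force: minimal I-MAP edge count over all permutations
    imapEdges <- function(perm) {
      cnt <- 0
      for (k in seq_len(p)[-1]) {
        j <- perm[k]; pre <- perm[seq_len(k - 1)]
        for (i in pre) if (!orc(i, j, setdiff(pre, i))) cnt <- cnt + 1
      }
      cnt
    }
    brute <- min(vapply(allPermutations(p), imapEdges, numeric(1)))
    fit <- utigspFit(ciTest = orc, nNodes = p, seed = rep,
                     nRestarts = 10, maxDepth = 20)
    expect_equal(brute, sum(adj))          # faithfulness of the oracle
    expect_equal(fit$score, sum(adj))      # search reaches the optimum
    # the returned graph is acyclic
    g <- igraph::graph_from_adjacency_matrix(fit$adjacency)
    expect_true(igraph::is_dag(g))
  }
})

test_that("a v-structure is oriented from observational data alone", {
  set.seed(2)
  n <- 2000
  x <- rnorm(n); y <- rnorm(n); z <- x + y + rnorm(n, 0, 0.5)
  fit <- utigspFit(cbind(x = x, y = y, z = z), alpha = 0.01, seed = 1)
  expect_setequal(paste(fit$edges$from, fit$edges$to),
                  c("x z", "y z"))
})

test_that("interventions resolve orientation and reveal their targets", {
  hit <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 300
    x <- rnorm(n); y <- x + rnorm(n, 0, 0.7)
    obs <- cbind(x = x, y = y)
    xi <- rnorm(n); yi <- xi + 2 + rnorm(n, 0, 0.7)
    int <- cbind(x = xi, y = yi)
    fit <- utigspFit(obs, list(int), seed = s, nRestarts = 2)
    if ("y" %in% fit$targets[[1]] && nrow(fit$edges) == 1 &&
        fit$edges$from == "x")
      hit <- hit + 1
  }
  expect_gte(hit / 20, 0.8)
})

test_that("the sample-size gate rejects oversized modules", {
  d <- matrix(rnorm(20 * 20), 20, 20)
  expect_error(utigspFit(d), "70%")
})

test_that("stability selection retains strong edges and drops noise", {
  d <- makeDesign(24, 1)
  design <- data.frame(library_type = d$library_type)
  set.seed(3)
  x <- rnorm(96)
  strong <- rbind(a = x, b = x + rnorm(96, 0, 0.05),
                  c = rnorm(96), d = rnorm(96))
  cg <- stabilitySelect(strong, design, NULL, nSubsamples = 25, seed = 4)
  e <- graphEdges(cg)
  expect_true("a~b" %in% skeletonOf(e))
  expect_gte(max(e$frequency[paste(e$from, e$to) %in%
                               c("a b", "b a")]), 0.5)
  expect_false("c~d" %in% skeletonOf(e))

  # pure-noise pairs fall below the retention threshold in most runs
  miss <- 0
  for (s in 1:10) {
    set.seed(s)
    noise <- matrix(rnorm(4 * 96), 4,
                    dimnames = list(letters[1:4], NULL))
    cgN <- stabilitySelect(noise, design, NULL, nSubsamples = 25,
                           seed = s)
    miss <- miss + (nrow(graphEdges(cgN)) == 0)
  }
  expect_gte(miss, 9)
})

test_that("a trait node is linked to its parents and not to noise", {
  d <- makeDesign(48, 1)
  design <- data.frame(library_type = d$library_type)
  linked <- 0; nullLinked <- 0
  for (s in 1:5) {
    set.seed(s)
    g1 <- rnorm(192); g2 <- rnorm(192); g3 <- rnorm(192)
    vals <- rbind(g1 = g1, g2 = g2, g3 = g3)
    trait <- g1 + g2 + g3 + rnorm(192, 0, 0.5)
    aug <- attachTraitNode(vals, trait, "glucose")
    cg <- stabilitySelect(aug$values, design, NULL, nSubsamples = 25,
                          seed = s, moduleId = "m")
    e <- graphEdges(cg)
    adjacent <- unique(c(e$to[e$from == "glucose"],
                         e$from[e$to == "glucose"]))
    linked <- linked + (length(adjacent) >= 2)

    # independent trait: no retained trait edges
    augN <- attachTraitNode(vals, rnorm(192), "null_trait")
    cgN <- stabilitySelect(augN$values, design, NULL, nSubsamples = 25,
                           seed = s + 50, moduleId = "m")
    eN <- graphEdges(cgN)
    nullLinked <- nullLinked +
      any(c(eN$from, eN$to) == "null_trait")
  }
  expect_gte(linked, 4)
  expect_lte(nullLinked, 1)

  expect_warning(attachTraitNode(rbind(a = 1:5), c(1, NA, 3, 4, 5)),
                 "missing")
})

test_that("planted dense edges reach frequency ~1 and graphs stay acyclic", {
  sc <- makeScenario("dag", nReps = 24, nNodes = 6, edgeProb = 0.4,
                     seed = 11)
  x <- normalizeLog2(simulateCounts(sc$truth, sc$design, seed = 12))
  norm <- SummarizedExperiment::assay(x, "normalized")
  mod <- norm[grep("^node", rownames(norm)), ]
  design <- data.frame(library_type = x$libraryType)
  cg <- stabilitySelect(mod, design, NULL, nSubsamples = 30, seed = 13)
  e <- graphEdges(cg)
  un <- e[!e$ambiguous, ]
  if (nrow(un)) {
    g <- igraph::graph_from_data_frame(un[, 1:2], directed = TRUE)
    expect_true(igraph::is_dag(g))
  }
  expect_true(all(e$frequency >= 0 & e$frequency <= 1))
})
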
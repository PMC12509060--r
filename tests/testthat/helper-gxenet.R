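# Shared test utilities: independent oracles and small fixture builders.

# undirected skeleton of an edge table
skeletonOf <- function(df, from = "from", to = "to") {
  if (!nrow(df)) return(character())
  unique(apply(df[, c(from, to)], 1, function(z)
    paste(sort(z), collapse = "~")))
}

skeletonF1 <- function(trueSk, estSk) {
  tp <- length(intersect(trueSk, estSk))
  if (length(trueSk) + length(estSk) == 0) return(1)
  2 * tp / (length(trueSk) + length(estSk))
}

# all permutations of 1..n (brute-force oracle helper)
allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (pp in allPermutations(n - 1))
    for (k in 0:(n - 1))
      out[[length(out) + 1L]] <- append(pp, n, after = k)
  out
}

# brute-force TOM: triple loop straight from the definition
bruteTom <- function(values, power = 5) {
  r <- cor(t(values))
  a <- abs(r)^power
  p <- nrow(a)
  tom <- matrix(0, p, p, dimnames = dimnames(a))
  k <- sapply(seq_len(p), function(i) sum(a[i, -i]))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# matrix with exactly the requested correlation structure (n > p):
# L %*% Z where Z has orthonormal, centered rows
exactCorMatrix <- function(R, n, seed = 1) {
  set.seed(seed)
  p <- nrow(R)
  Z <- matrix(rnorm(p * n), p, n)
  Z <- Z - rowMeans(Z)
  Z <- qr.Q(qr(t(Z)))[, seq_len(p)]        # orthonormal centered columns
  out <- t(chol(R)) %*% t(Z)
  rownames(out) <- paste0("g", seq_len(p))
  out * sqrt(n - 1)
}

# minimal ModuleSet construction for comparison tests
fakeModuleSet <- function(assignment, libraryType, preset = "moderate",
                          nSamples = 6) {
  ids <- sort(unique(assignment[assignment > 0]))
  eg <- matrix(rnorm(nSamples * length(ids)), nSamples, length(ids),
               dimnames = list(paste0("s", seq_len(nSamples)),
                               paste0("M", ids)))
  eg <- apply(eg, 2, function(v) v / sqrt(sum(v^2)))
  if (is.null(dim(eg))) eg <- matrix(eg, ncol = length(ids))
  methods::new("ModuleSet",
               assignment = stats::setNames(as.integer(assignment),
                                            names(assignment)),
               eigengenes = eg,
               varExplained = rep(0.5, length(ids)),
               libraryType = libraryType, preset = preset,
               parameters = list(minClusterSize = 2))
}
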
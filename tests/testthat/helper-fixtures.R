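# Shared fixtures and independent brute-force oracles.

# Small two-cycle trial dataset plus derived kernels.
smallTrial <- function(seed = 3, nLines = 60, nMi = 200, trialsPerEnv = 1,
                       ...) {
  cfg <- simConfig(nLines = nLines, nSnps = 300, nCycles = 2,
                   locations = "LocA", trialsPerEnv = trialsPerEnv,
                   plotsGrid = c(6, 8), nMiFeatures = nMi,
                   nNirWavelengths = 141, seed = seed, ...)
  ds <- generateDataset(cfg)
  geno <- imputeMeanDosage(snpQC(ds$genotypes))
  ph <- ds$phenotypes
  list(ds = ds, geno = geno, ph = ph,
       G = vanRadenG(geno),
       S = spatialKernel(data.frame(
         plot_id = ph$plot_id,
         trial = paste(ph$year, ph$location, ph$trial, sep = "_"),
         row = ph$row, col = ph$col)))
}

# Random raw dosage matrix with missing calls.
randomGeno <- function(nLines, nSnps, missingRate = 0.05, seed = 1) {
  set.seed(seed)
  p <- runif(nSnps, 0.05, 0.5)
  d <- matrix(rbinom(nLines * nSnps, 2, rep(p, each = nLines)), nLines,
              dimnames = list(sprintf("L%03d", 1:nLines),
                              sprintf("S%03d", 1:nSnps)))
  storage.mode(d) <- "double"
  d[sample(length(d), round(missingRate * length(d)))] <- NA
  genotypeData(d)
}

# Double-loop VanRaden G, independent of the vectorized implementation.
bruteForceG <- function(d) {
  p <- colMeans(d) / 2
  Q <- d
  for (j in seq_len(ncol(d))) Q[, j] <- d[, j] - 2 * p[j]
  G <- matrix(0, nrow(d), nrow(d))
  for (i in seq_len(nrow(d))) for (k in seq_len(nrow(d))) {
    G[i, k] <- sum(Q[i, ] * Q[k, ])
  }
  G / (2 * sum(p * (1 - p)))
}

# Neighbour enumeration over all plot pairs.
bruteForceS <- function(layout) {
  n <- nrow(layout)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && layout$trial[i] == layout$trial[j] &&
        abs(layout$row[i] - layout$row[j]) <= 1 &&
        abs(layout$col[i] - layout$col[j]) <= 1) {
      W[i, j] <- 1
    }
  }
  WWt <- W %*% t(W)
  WWt / (sum(diag(WWt)) / n)
}

# Per-SNP QC filter recomputed with explicit loops.
bruteForceQCKeep <- function(d, mafMin, callrateMin) {
  keep <- logical(ncol(d))
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    obs <- x[!is.na(x)]
    cr <- length(obs) / length(x)
    p <- if (length(obs)) mean(obs) / 2 else 0
    keep[j] <- min(p, 1 - p) >= mafMin && cr >= callrateMin
  }
  keep
}
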
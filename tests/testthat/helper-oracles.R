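# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the code paths they check.

# O(P*N) pairwise AUC with ties counting one half.
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Sliding-window k-mer counts by explicit loop.
oracleKmerCounts <- function(s, k, alphabet) {
  lev <- gruf::allKmers(alphabet, k)
  counts <- stats::setNames(rep(0, length(lev)), lev)
  for (i in seq_len(nchar(s) - k + 1)) {
    w <- substr(s, i, i + k - 1)
    counts[w] <- counts[w] + 1
  }
  counts / (nchar(s) - k + 1)
}

# Double-loop 1/(1+Euclidean distance) similarity.
oracleSimilarity <- function(F) {
  n <- nrow(F)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- 1 / (1 + sqrt(sum((F[i, ] - F[j, ])^2)))
  S
}

# A valid SimilarityMatrix from random points (1/(1+dist) kernel).
randomSimilarity <- function(n, d = 3, seed = 1, prefix = "e") {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  rownames(X) <- paste0(prefix, seq_len(n))
  gruf::similarityFromFeatures(X)
}

# Random DiseaseDag over an explicit random hierarchy, for property tests.
randomDagPair <- function(seed) {
  set.seed(seed)
  nodes <- paste0("n", 1:12)
  hier <- data.frame(child = nodes[2:12],
                     parent = nodes[sapply(2:12, function(i) sample(i - 1, 1))])
  mk <- function(id) {
    desc <- sample(nodes, sample(1:3, 1))
    gruf::buildDiseaseDag(id, desc, hier)
  }
  list(a = mk("A"), b = mk("B"), hier = hier)
}

# Small planted dataset shared by fast tests.
smallPlanted <- function(noiseSd = 0, seed = 5) {
  gruf::generatePlantedDataset(m = 25, g = 15, n = 30, latentDim = 3,
                               noiseSd = noiseSd, interactionDensity = 0.06,
                               seed = seed)
}
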
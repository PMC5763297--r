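test_that("k-mer frequencies match sliding-window counts and sum to one", {
  expect_equal(unname(kmerFrequency("AAAA", 1)), c(1, 0, 0, 0))
  expect_equal(unname(kmerFrequency("ACGU", 1)), rep(0.25, 4))

  f <- kmerFrequency("ACGUACG", 2)
  expect_length(f, 16)
  expect_equal(f[["AC"]], 2 / 6)
  expect_equal(f[["CG"]], 2 / 6)
  expect_equal(f[["GU"]], 1 / 6)
  expect_equal(f[["UA"]], 1 / 6)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(f, oracleKmerCounts("ACGUACG", 2, c("A", "C", "G", "U")))

  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(10:60, 1), replace = TRUE),
               collapse = "")
    k <- sample(1:3, 1)
    f <- kmerFrequency(s, k)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_equal(f, oracleKmerCounts(s, k, c("A", "C", "G", "U")))
  }
  expect_error(kmerFrequency("ACG", 4), "shorter than k")
})

test_that("segmented features concatenate per-segment frequencies deterministically", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "U"), 200, replace = TRUE), collapse = "")
  v <- segmentedKmerFeatures(s, k = 4, nSegments = 35)
  expect_length(v, 8960)

  expect_equal(unname(segmentedKmerFeatures(s, k = 2, nSegments = 1)),
               unname(kmerFrequency(s, 2)))

  # length 10, 3 segments -> lengths (4, 3, 3), left to right
  s10 <- "ACGUACGUAC"
  v10 <- segmentedKmerFeatures(s10, k = 1, nSegments = 3)
  expect_equal(unname(v10[1:4]), unname(kmerFrequency("ACGU", 1)))
  expect_equal(unname(v10[5:8]), unname(kmerFrequency("ACG", 1)))
  expect_equal(unname(v10[9:12]), unname(kmerFrequency("UAC", 1)))

  expect_error(segmentedKmerFeatures("ACGUACGU", k = 4, nSegments = 3, id = "x1"),
               "x1")
  # T mapped to U, lowercase accepted
  expect_equal(segmentedKmerFeatures("acgtacgtac", k = 1, nSegments = 3),
               v10)
})

test_that("protein encoding maps the 20 residues onto exactly 7 groups", {
  expect_equal(encodeProteinSequence("AGV"), "111")
  expect_equal(encodeProteinSequence("CRKDE"), "75566")
  expect_error(encodeProteinSequence("XAA"), "position 1")
  aa20 <- "AGVILFPYMTSHNQWRKDEC"
  enc <- encodeProteinSequence(aa20)
  expect_equal(nchar(enc), 20)
  expect_setequal(strsplit(enc, "")[[1]], as.character(1:7))
})

test_that("protein 3-mer features live on the encoded 7-letter alphabet", {
  f <- proteinKmerFeatures("AAA")
  expect_length(f, 343)
  expect_equal(f[["111"]], 1)
  expect_equal(sum(f), 1)

  f2 <- proteinKmerFeatures("AGVIL")  # encodes to "11122"
  expect_equal(f2[["111"]], 1 / 3)
  expect_equal(f2[["112"]], 1 / 3)
  expect_equal(f2[["122"]], 1 / 3)
  expect_equal(sum(f2 != 0), 3)
})

test_that("z-score normalisation centres and scales columns, zero-variance to zero", {
  Z <- zscoreColumns(cbind(a = c(1, 3), b = c(5, 5)))
  expect_equal(Z[, "a"], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(Z[, "b"], c(0, 0))

  set.seed(3)
  F <- matrix(rnorm(40), 8, 5)
  Z <- zscoreColumns(F)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
  expect_equal(zscoreColumns(Z), Z, tolerance = 1e-10)

  expect_error(zscoreColumns(matrix(1:3, 1)), "2 rows")
})

test_that("PCA projection keeps informative components and preserves distances", {
  set.seed(4)
  X <- matrix(rnorm(12), 6, 2) %*% matrix(rnorm(10), 2, 5)
  X <- sweep(X, 2, colMeans(X))          # centred rank-2 matrix
  P <- pcaReduce(X)
  expect_equal(ncol(P), 2)
  expect_equal(as.matrix(dist(P)), as.matrix(dist(X)), tolerance = 1e-8,
               ignore_attr = TRUE)

  Xdup <- cbind(X, X[, 1])               # exact collinearity
  expect_lt(ncol(pcaReduce(Xdup)), ncol(Xdup))

  O <- qr.Q(qr(matrix(rnorm(25), 5)))    # orthogonal rows: pure rotation
  expect_equal(as.matrix(dist(pcaReduce(O))), as.matrix(dist(O)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("1/(1+dist) similarity matches the double-loop oracle", {
  F <- rbind(x = c(0, 0), y = c(0, 0), z = c(3, 4))
  S <- as.matrix(similarityFromFeatures(F))
  expect_equal(S["x", "y"], 1)
  expect_equal(S["x", "z"], 1 / 6)
  F2 <- rbind(a = 0, b = 1)
  expect_equal(as.matrix(similarityFromFeatures(F2))["a", "b"], 0.5)

  set.seed(9)
  F <- matrix(rnorm(50 * 4), 50, 4)
  rownames(F) <- paste0("s", 1:50)
  expect_equal(unname(as.matrix(similarityFromFeatures(F))),
               oracleSimilarity(F), tolerance = 1e-12)

  # permutation of rows permutes the similarity consistently
  perm <- sample(50)
  S1 <- as.matrix(similarityFromFeatures(F))
  S2 <- as.matrix(similarityFromFeatures(F[perm, ]))
  expect_equal(S2, S1[perm, perm])
})

test_that("similarity pipelines produce valid similarity objects", {
  seqs <- generateSequences(6, lengthRange = c(150L, 220L), seed = 2)
  S <- lncrnaSimilarity(seqs)
  expect_s4_class(S, "SimilarityMatrix")
  expect_true(validObject(S))
  expect_equal(entityIds(S), names(seqs))

  prot <- generateSequences(5, lengthRange = c(40L, 80L),
                            alphabet = strsplit("AGVILFPYMTSHNQWRKDEC", "")[[1]],
                            seed = 3, prefix = "p", minLength = 3L)
  Sp <- proteinSimilarity(prot)
  expect_s4_class(Sp, "SimilarityMatrix")
  expect_equal(dim(Sp), c(5L, 5L))
})
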
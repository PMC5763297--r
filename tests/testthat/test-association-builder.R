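mkBip <- function(values, rids, cids) {
  dimnames(values) <- list(rids, cids)
  BipartiteMatrix(values)
}

test_that("binary associations flag shared genes", {
  Arp <- mkBip(matrix(c(1, 0), 1), "r1", c("g1", "g2"))
  AgdYes <- mkBip(matrix(c(1, 0), 2), c("g1", "g2"), "d1")
  AgdNo <- mkBip(matrix(c(0, 1), 2), c("g1", "g2"), "d1")
  expect_equal(unname(as.matrix(buildBinary(Arp, AgdYes))), matrix(1))
  expect_equal(unname(as.matrix(buildBinary(Arp, AgdNo))), matrix(0))

  set.seed(11)
  Arp3 <- mkBip(matrix(rbinom(15, 1, 0.4), 3, 5), paste0("r", 1:3),
                paste0("g", 1:5))
  Agd3 <- mkBip(matrix(rbinom(20, 1, 0.4), 5, 4), paste0("g", 1:5),
                paste0("d", 1:4))
  B <- buildBinary(Arp3, Agd3)
  expect_equal(dim(B), c(3L, 4L))
  expect_equal(variant(B), "binary")

  # disjoint gene namespaces
  AgdAlien <- mkBip(matrix(1, 1), "gX", "d1")
  expect_error(buildBinary(Arp, AgdAlien), "shared gene")
})

test_that("discrete associations count shared genes (brute-force oracle)", {
  Arp <- mkBip(matrix(c(1, 1), 1), "r1", c("g1", "g2"))
  Agd <- mkBip(matrix(c(1, 1), 2), c("g1", "g2"), "d1")
  expect_equal(unname(as.matrix(buildDiscrete(Arp, Agd))), matrix(2))

  zero <- mkBip(matrix(0, 1, 2), "r1", c("g1", "g2"))
  expect_true(all(as.matrix(buildDiscrete(zero, Agd)) == 0))

  set.seed(12)
  for (rep in 1:5) {
    Arp <- mkBip(matrix(rbinom(48, 1, 0.35), 6, 8), paste0("r", 1:6),
                 paste0("g", 1:8))
    Agd <- mkBip(matrix(rbinom(40, 1, 0.35), 8, 5), paste0("g", 1:8),
                 paste0("d", 1:5))
    D <- as.matrix(buildDiscrete(Arp, Agd))
    oracle <- matrix(0, 6, 5)
    for (i in 1:6) for (j in 1:5) for (g in 1:8)
      oracle[i, j] <- oracle[i, j] +
        (as.matrix(Arp)[i, g] > 0 && as.matrix(Agd)[g, j] > 0)
    expect_equal(unname(D), oracle)
    # binarising the counts reproduces the binary builder exactly
    expect_identical(unname(as.matrix(binarizeLda(buildDiscrete(Arp, Agd)))),
                     unname(as.matrix(buildBinary(Arp, Agd))))
  }
})

test_that("continued associations are the similarity-weighted product", {
  Arp <- mkBip(matrix(c(1, 1), 1), "r1", c("g1", "g2"))
  Agd <- mkBip(matrix(c(1, 0), 2), c("g1", "g2"), "d1")
  Sp <- SimilarityMatrix(matrix(c(1, 0.5, 0.5, 1), 2,
                                dimnames = list(c("g1", "g2"), c("g1", "g2"))))
  C <- buildContinued(Arp, Sp, Agd)
  expect_equal(unname(as.matrix(C)), matrix(1.5))
  expect_equal(variant(C), "continued")

  # S_P = identity collapses the product to the discrete count, exactly
  set.seed(13)
  Arp <- mkBip(matrix(rbinom(30, 1, 0.4), 5, 6), paste0("r", 1:5),
               paste0("g", 1:6))
  Agd <- mkBip(matrix(rbinom(42, 1, 0.4), 6, 7), paste0("g", 1:6),
               paste0("d", 1:7))
  I6 <- diag(6); dimnames(I6) <- list(paste0("g", 1:6), paste0("g", 1:6))
  expect_identical(unname(as.matrix(buildContinued(Arp, SimilarityMatrix(I6), Agd))),
                   unname(as.matrix(buildDiscrete(Arp, Agd))))

  # raising a similarity entry never decreases any intensity
  Sp6 <- randomSimilarity(6, seed = 2, prefix = "g")
  C1 <- as.matrix(buildContinued(Arp, Sp6, Agd))
  M <- as.matrix(Sp6); M["g2", "g3"] <- M["g3", "g2"] <- min(1, M["g2", "g3"] + 0.3)
  C2 <- as.matrix(buildContinued(Arp, SimilarityMatrix(M), Agd))
  expect_true(all(C2 - C1 >= -1e-12))

  expect_error(buildContinued(Arp, randomSimilarity(3, prefix = "q"), Agd),
               "missing shared gene")
})

test_that("builders are permutation-equivariant", {
  set.seed(14)
  Arp <- mkBip(matrix(rbinom(24, 1, 0.4), 4, 6), paste0("r", 1:4),
               paste0("g", 1:6))
  Agd <- mkBip(matrix(rbinom(30, 1, 0.4), 6, 5), paste0("g", 1:6),
               paste0("d", 1:5))
  pr <- sample(4); pd <- sample(5)
  B <- as.matrix(buildBinary(Arp, Agd))
  Bp <- as.matrix(buildBinary(
    BipartiteMatrix(as.matrix(Arp)[pr, , drop = FALSE]),
    BipartiteMatrix(as.matrix(Agd)[, pd, drop = FALSE])))
  expect_equal(Bp, B[pr, pd])
})

test_that("binary labels transfer to enriched matrices with matching ids", {
  set.seed(15)
  Arp <- mkBip(matrix(rbinom(20, 1, 0.5), 4, 5), paste0("r", 1:4),
               paste0("g", 1:5))
  Agd <- mkBip(matrix(rbinom(15, 1, 0.5), 5, 3), paste0("g", 1:5),
               paste0("d", 1:3))
  bam <- buildBinary(Arp, Agd)
  dam <- buildDiscrete(Arp, Agd)
  lab <- labelsFromBinary(dam, bam)
  expect_identical(lab, as.matrix(bam))
  expect_true(all((as.matrix(dam) > 0) == (lab == 1)))

  bad <- LdaMatrix(matrix(0, 2, 3, dimnames = list(paste0("r", 1:2),
                                                   paste0("d", 1:3))),
                   variant = "binary")
  expect_error(labelsFromBinary(dam, bad), "differ")
  expect_error(binarizeLda(buildContinued(Arp, randomSimilarity(5, prefix = "g"),
                                          Agd)),
               "explicitly")
})
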
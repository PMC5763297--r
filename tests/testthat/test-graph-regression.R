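test_that("truncated SVD embedding satisfies the Eckart-Young identity", {
  e <- svdEmbed(diag(2), rank = 2)
  expect_equal(latentFactors(e$L) %*% t(latentFactors(e$R)), diag(2),
               tolerance = 1e-10, ignore_attr = TRUE)

  e2 <- svdEmbed(matrix(c(4, 0, 0, 0), 2), rank = 1)
  expect_equal(unname(latentFactors(e2$L)), matrix(c(2, 0)), tolerance = 1e-12)
  expect_equal(latentFactors(e2$L) %*% t(latentFactors(e2$R)),
               matrix(c(4, 0, 0, 0), 2), tolerance = 1e-12, ignore_attr = TRUE)

  set.seed(21)
  for (i in 1:10) {
    M <- matrix(rnorm(30), 6, 5)
    d <- svd(M)$d                              # independent full-SVD oracle
    emb <- svdEmbed(M, rank = 3)
    err <- sqrt(sum((M - latentFactors(emb$L) %*% t(latentFactors(emb$R)))^2))
    expect_equal(err, sqrt(sum(d[4:5]^2)), tolerance = 1e-9)
  }
  expect_error(svdEmbed(diag(3), rank = 5), "out of range")
})

test_that("symmetric embedding reconstructs the PSD part of a similarity", {
  f <- symmetricEmbed(diag(3), rank = 3)
  expect_equal(latentFactors(f) %*% t(latentFactors(f)), diag(3),
               tolerance = 1e-10, ignore_attr = TRUE)

  ones <- matrix(1, 2, 2)
  f1 <- symmetricEmbed(ones, rank = 1)
  expect_equal(unname(latentFactors(f1)), matrix(c(1, 1)), tolerance = 1e-10)

  set.seed(22)
  X <- matrix(rnorm(40), 8, 5)
  G <- X %*% t(X)                              # Gram: PSD by construction
  fG <- symmetricEmbed(G, rank = 8)
  expect_lt(sqrt(sum((G - latentFactors(fG) %*% t(latentFactors(fG)))^2)), 1e-8)

  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(symmetricEmbed(asym), "not symmetric")
})

test_that("uncentered PLS recovers exact linear maps and the rank-1 fit", {
  set.seed(23)
  X <- matrix(rnorm(24), 8, 3)
  expect_equal(plsRegress(X, matrix(0, 8, 2)), matrix(0, 3, 2),
               ignore_attr = TRUE)

  Btrue <- matrix(rnorm(6), 3, 2)
  Y <- X %*% Btrue
  B <- plsRegress(X, Y, nComponents = 3)
  expect_lt(sqrt(sum((X %*% B - Y)^2)), 1e-8)

  # full-component fit agrees with the least-squares oracle (no intercept)
  Ynoisy <- Y + matrix(rnorm(16, sd = 0.1), 8, 2)
  Bpls <- plsRegress(X, Ynoisy, nComponents = 3)
  Bols <- qr.coef(qr(X), Ynoisy)
  expect_equal(Bpls, Bols, tolerance = 1e-8, ignore_attr = TRUE)

  # one component: matches the explicit rank-1 NIPALS oracle
  B1 <- plsRegress(X, Ynoisy, nComponents = 1)
  w <- eigen(t(X) %*% Ynoisy %*% t(Ynoisy) %*% X)$vectors[, 1]
  tv <- X %*% w
  cv <- t(Ynoisy) %*% tv / sum(tv^2)
  pred1 <- tv %*% t(cv)
  expect_equal(X %*% B1, pred1, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(plsRegress(matrix(0, 4, 2), matrix(1, 4, 1)), "degenerate")
})

test_that("fitting planted bilinear data reproduces the association matrix", {
  set.seed(24)
  Sr <- randomSimilarity(10, seed = 31, prefix = "r")
  Sd <- randomSimilarity(12, seed = 32, prefix = "d")
  Fr <- latentFactors(symmetricEmbed(Sr))
  Fd <- latentFactors(symmetricEmbed(Sd))
  Theta <- matrix(rnorm(ncol(Fr) * ncol(Fd)), ncol(Fr), ncol(Fd))
  A <- Fr %*% Theta %*% t(Fd)
  dimnames(A) <- list(entityIds(Sr), entityIds(Sd))

  fit <- grufFit(A, Sr, Sd, nComponents = 50)   # capped at the full rank
  expect_lt(max(abs(thetaMatrix(fit) - fit@br %*% t(fit@bd))), 1e-12)
  expect_equal(as.matrix(predictT1(fit)), A, tolerance = 1e-6)

  # all-zero associations give a zero bi-regression and zero scores
  A0 <- matrix(0, 10, 12, dimnames = dimnames(A))
  fit0 <- grufFit(A0, Sr, Sd)
  expect_true(all(thetaMatrix(fit0) == 0))
  expect_true(all(as.matrix(predictT1(fit0)) == 0))

  # permuting lncRNA order permutes prediction rows identically
  perm <- sample(10)
  SrP <- SimilarityMatrix(as.matrix(Sr)[perm, perm])
  fitP <- grufFit(A[perm, ], SrP, Sd, nComponents = 50)
  expect_equal(as.matrix(predictT1(fitP)), as.matrix(predictT1(fit))[perm, ],
               tolerance = 1e-6)

  expect_error(grufFit(A, randomSimilarity(4, prefix = "x"), Sd), "missing")
})

test_that("Nystrom projection maps training similarity rows onto their latent rows", {
  Sr <- randomSimilarity(9, seed = 33, prefix = "r")
  emb <- symmetricEmbed(Sr)                    # full retained rank
  M <- as.matrix(Sr)
  for (i in c(1, 5, 9))
    expect_equal(as.vector(projectNewEntity(M[i, ], emb)),
                 unname(latentFactors(emb)[i, ]), tolerance = 1e-8)
  expect_equal(as.vector(projectNewEntity(rep(0, 9), emb)),
               rep(0, ncol(latentFactors(emb))))
  # identical similarity rows give identical latent vectors
  dup <- projectNewEntity(rbind(M[3, ], M[3, ]), emb)
  expect_equal(dup[1, ], dup[2, ])
  expect_error(projectNewEntity(rep(0.5, 4), emb), "training entities")
})

test_that("cold-start predictors agree with the warm path on training entities", {
  set.seed(25)
  Sr <- randomSimilarity(10, seed = 34, prefix = "r")
  Sd <- randomSimilarity(8, seed = 35, prefix = "d")
  A <- matrix(rbinom(80, 1, 0.3), 10, 8,
              dimnames = list(entityIds(Sr), entityIds(Sd)))
  fit <- grufFit(A, Sr, Sd)

  t1 <- as.matrix(predictT1(fit))
  t2 <- as.matrix(predictT2(fit, as.matrix(Sr)[c(2, 7), , drop = FALSE]))
  expect_equal(unname(t2), unname(t1[c(2, 7), ]), tolerance = 1e-6)
  t3 <- as.matrix(predictT3(fit, as.matrix(Sd)[3, , drop = FALSE]))
  expect_equal(unname(t3), unname(t1[, 3, drop = FALSE]), tolerance = 1e-6)

  # T4 with zero similarity evidence scores zero
  t4 <- predictT4(fit, rep(0, 10), rep(0, 8))
  expect_equal(unname(as.matrix(t4)), matrix(0))

  # transposing the whole problem swaps the two cold-start predictors
  fitT <- grufFit(t(A), Sd, Sr)
  sx <- as.matrix(Sr)[4, , drop = FALSE]
  expect_equal(unname(as.matrix(predictT2(fit, sx))),
               unname(t(as.matrix(predictT3(fitT, sx)))), tolerance = 1e-6)
})
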
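test_that("fold plans partition the task units exactly", {
  for (task in c("T1", "T2", "T3")) for (K in c(2, 5, 10)) {
    plan <- makeCvPlan(task, 10, 12, K, seed = 7)
    units <- lapply(plan@folds, function(f) switch(task,
      T1 = paste(f$testEntries[, 1], f$testEntries[, 2]),
      T2 = f$testRows, T3 = f$testCols))
    all <- unlist(units)
    expect_equal(length(all), length(unique(all)))          # disjoint
    expect_equal(length(all), switch(task, T1 = 120, T2 = 10, T3 = 12))
    sizes <- lengths(units)
    expect_lte(max(sizes) - min(sizes), 1)                  # balanced
  }

  plan2 <- makeCvPlan("T2", 10, 5, 5, seed = 1)
  expect_true(all(lengths(lapply(plan2@folds, `[[`, "testRows")) == 2))
  expect_error(makeCvPlan("T2", 4, 5, 9), "out of range")
})

test_that("T4 plans exclude every mixed train/test row-column block", {
  plan <- makeCvPlan("T4", 10, 10, 10, seed = 3)
  expect_length(plan@folds, 100)
  f <- plan@folds[[1]]
  expect_equal(nrow(f$testEntries), 1)
  expect_equal(nrow(f$trainEntries), 81)
  expect_equal(nrow(f$excludedEntries), 18)
  for (f in plan@folds[1:10]) {
    expect_false(any(f$trainEntries[, "row"] %in% f$testRows))
    expect_false(any(f$trainEntries[, "col"] %in% f$testCols))
    expect_equal(nrow(f$testEntries) + nrow(f$trainEntries) +
                 nrow(f$excludedEntries), 100)
  }

  # determinism: same seed identical, different seed differs
  expect_identical(makeCvPlan("T4", 10, 10, 5, seed = 3),
                   makeCvPlan("T4", 10, 10, 5, seed = 3))
  expect_false(identical(makeCvPlan("T1", 6, 6, 3, seed = 1)@folds,
                         makeCvPlan("T1", 6, 6, 3, seed = 2)@folds))
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(aucScore(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(aucScore(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(aucScore(c(0.8, 0.8, 0.6, 0.4), c(1, 0, 1, 0)), 0.625)

  set.seed(31)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))   # rounding forces ties
    expect_equal(aucScore(scores, labels), oracleAuc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(aucScore(c(1, 2), c(1, 1)), "undefined")

  # null behaviour: random scores against random labels hover at 1/2
  set.seed(32)
  expect_lt(abs(aucScore(rnorm(500), rbinom(500, 1, 0.3)) - 0.5), 0.1)
})

test_that("AUPR follows the tie-blocked step curve", {
  expect_equal(auprScore(c(0.9, 0.1), c(1, 0)), 1)          # perfect, 1 of 2
  expect_equal(auprScore(c(0.5, 0.5), c(1, 0)), 0.5)        # tie block
  expect_equal(auprScore(rep(0.7, 4), c(1, 1, 0, 0)), 0.5)  # all tied baseline
  # hand-derived curve: scores 0.9, 0.8, 0.7, 0.6 labels 1,0,1,0
  # thresholds: prec 1, 1/2, 2/3, 1/2; recall 1/2, 1/2, 1, 1
  expect_equal(auprScore(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * 2 / 3)
})

test_that("intensity correlation is Pearson with a Spearman option", {
  expect_equal(intensityCorrelation(1:5, 1:5), 1)
  expect_equal(intensityCorrelation(1:5, -(1:5)), -1)
  expect_equal(intensityCorrelation(c(1, 2, 4), c(1, 2, 3)),
               9 / (2 * sqrt(21)), tolerance = 1e-10)
  expect_equal(intensityCorrelation(c(1, 2, 10), c(1, 2, 3),
                                    method = "spearman"), 1)
  expect_error(intensityCorrelation(c(1, 1, 1), 1:3), "constant")
  expect_error(intensityCorrelation(1:2, 1:2), "3 paired")
})

test_that("cross-validation is reproducible and recovers signal on planted data", {
  ds <- smallPlanted()
  A <- ds$lda$binary
  plan <- makeCvPlan("T2", 25, 30, 5, seed = 9)
  r1 <- suppressWarnings(runCv(A, ds$Sr, ds$Sd, plan, ranks = c(8, 10, 10),
                               nComponents = 6))
  r2 <- suppressWarnings(runCv(A, ds$Sr, ds$Sd, plan, ranks = c(8, 10, 10),
                               nComponents = 6))
  expect_identical(r1@perFold, r2@perFold)                  # bit-reproducible
  expect_gt(r1@auc, 0.8)
  expect_equal(r1@auc, mean(r1@perFold$auc))

  # pooled aggregation concatenates entries instead of averaging folds
  rp <- suppressWarnings(runCv(A, ds$Sr, ds$Sd, plan, ranks = c(8, 10, 10),
                               nComponents = 6, aggregate = "pooled"))
  expect_gt(rp@auc, 0.8)

  expect_error(runCv(ds$lda$continued, ds$Sr, ds$Sd, plan), "bam")
  expect_error(runCv(A, ds$Sr, ds$Sd, makeCvPlan("T1", 4, 4, 2)), "dimensions")
})
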
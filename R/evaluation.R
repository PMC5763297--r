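#' @include AllClasses.R
NULL

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Shuffle nUnits units into K folds whose sizes differ by at most 1.
.foldAssignment <- function(nUnits, K) {
  perm <- sample.int(nUnits)
  sizes <- rep(nUnits %/% K, K)
  extra <- nUnits %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(K), times = sizes))
}

.entryMatrix <- function(idx, m) {
  cbind(row = (idx - 1L) %% m + 1L, col = (idx - 1L) %/% m + 1L)
}

#' Build a task-specific cross-validation plan
#'
#' The shufflable unit depends on the scenario: T1 partitions the m x n
#' entries, T2 the rows (lncRNAs), T3 the columns (diseases). T4 partitions
#' rows and columns independently into K folds each and crosses them into
#' K^2 fold pairs; within a pair only the test-row x test-column block is
#' tested, only the train-row x train-column block is trained, and the mixed
#' blocks are excluded from both, so the training matrix contains none of
#' the test rows or columns.
#'
#' @param task one of "T1", "T2", "T3", "T4".
#' @param m,n association matrix dimensions.
#' @param K fold count (per axis for T4). Set K to the unit count for
#'   leave-one-out.
#' @param seed integer seed; plans are deterministic given the seed.
#' @return a \linkS4class{CvPlan}.
#' @export
makeCvPlan <- function(task = c("T1", "T2", "T3", "T4"), m, n, K, seed = 1L) {
  task <- match.arg(task)
  m <- as.integer(m); n <- as.integer(n); K <- as.integer(K)
  nUnits <- switch(task, T1 = m * n, T2 = m, T3 = n, T4 = min(m, n))
  if (K < 2 || K > nUnits)
    stop(sprintf("K = %d out of range for task %s (%d units)", K, task, nUnits))
  allEntries <- .entryMatrix(seq_len(m * n), m)
  folds <- .withSeed(seed, {
    if (task == "T1") {
      lapply(.foldAssignment(m * n, K), function(idx) {
        test <- .entryMatrix(sort(idx), m)
        train <- .entryMatrix(sort(setdiff(seq_len(m * n), idx)), m)
        list(testEntries = test, trainEntries = train,
             excludedEntries = allEntries[0, , drop = FALSE])
      })
    } else if (task == "T2") {
      lapply(.foldAssignment(m, K), function(rows) {
        rows <- sort(rows)
        list(testRows = rows, trainRows = setdiff(seq_len(m), rows),
             testEntries = allEntries[allEntries[, "row"] %in% rows, ,
                                      drop = FALSE],
             trainEntries = allEntries[!allEntries[, "row"] %in% rows, ,
                                       drop = FALSE],
             excludedEntries = allEntries[0, , drop = FALSE])
      })
    } else if (task == "T3") {
      lapply(.foldAssignment(n, K), function(cols) {
        cols <- sort(cols)
        list(testCols = cols, trainCols = setdiff(seq_len(n), cols),
             testEntries = allEntries[allEntries[, "col"] %in% cols, ,
                                      drop = FALSE],
             trainEntries = allEntries[!allEntries[, "col"] %in% cols, ,
                                       drop = FALSE],
             excludedEntries = allEntries[0, , drop = FALSE])
      })
    } else {
      rowFolds <- .foldAssignment(m, K)
      colFolds <- .foldAssignment(n, K)
      out <- list()
      for (i in seq_len(K)) for (j in seq_len(K)) {
        tstR <- sort(rowFolds[[i]]); tstC <- sort(colFolds[[j]])
        trnR <- setdiff(seq_len(m), tstR); trnC <- setdiff(seq_len(n), tstC)
        isTestR <- allEntries[, "row"] %in% tstR
        isTestC <- allEntries[, "col"] %in% tstC
        out[[length(out) + 1L]] <- list(
          testRows = tstR, testCols = tstC,
          trainRows = trnR, trainCols = trnC,
          testEntries = allEntries[isTestR & isTestC, , drop = FALSE],
          trainEntries = allEntries[!isTestR & !isTestC, , drop = FALSE],
          excludedEntries = allEntries[xor(isTestR, isTestC), , drop = FALSE])
      }
      out
    }
  })
  new("CvPlan", task = task, K = K, m = m, n = n, seed = as.integer(seed),
      folds = unname(folds))
}

#' Area under the ROC curve
#'
#' Rank-based Mann-Whitney statistic with midranks: the probability that a
#' random positive outranks a random negative, ties counting one half.
#'
#' @param scores numeric confidence scores.
#' @param labels binary labels (0/1), same length.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("AUC undefined: need at least one positive and one negative label")
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Step-curve summation without interpolation, thresholds descending by
#' score; equal-scored items form a single threshold block (so the curve
#' never splits ties).
#'
#' @inheritParams aucScore
#' @return AUPR in (0, 1].
#' @export
auprScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  P <- sum(labels == 1)
  if (P == 0 || sum(labels == 0) == 0)
    stop("AUPR undefined: need at least one positive and one negative label")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  ends <- cumsum(rle(s)$lengths)    # tie blocks collapse to one threshold
  tp <- cumsum(l)[ends]
  prec <- tp / ends
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Correlation between predicted scores and association intensity
#'
#' Measures the consistency between the predicted confidence scores and the
#' discrete/continued association values of the same entries (the higher,
#' the better); Pearson by default, Spearman behind the flag.
#'
#' @param scores predicted confidence scores.
#' @param truth association values of the same entries.
#' @param method "pearson" (default) or "spearman".
#' @return correlation in [-1, 1].
#' @export
intensityCorrelation <- function(scores, truth,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (length(scores) < 3) stop("need at least 3 paired values")
  if (stats::sd(scores) == 0 || stats::sd(truth) == 0)
    stop("correlation undefined for constant input")
  stats::cor(scores, truth, method = method)
}

.scoreEntries <- function(scores, entries) scores[entries]

#' Run task-specific cross-validation of the graph-regression model
#'
#' Per fold the test units are blinded according to the task semantics:
#' T1 sets the test entries to 0 ("no known association") in the training
#' matrix; T2/T3 drop the test rows/columns entirely and predict them via
#' Nystrom projection of their similarity rows; T4 fits on the
#' train-row x train-column block only and predicts the test block via the
#' double projection. Test entries are scored with AUC and AUPR against
#' binary labels (taken from the binary association matrix) and with the
#' intensity correlation against the evaluated variant's values; folds whose
#' test labels are single-class are skipped with a warning.
#'
#' @param A \linkS4class{LdaMatrix} to evaluate (any variant).
#' @param Sr,Sd lncRNA/disease \linkS4class{SimilarityMatrix}.
#' @param plan a \linkS4class{CvPlan} matching \code{dim(A)}.
#' @param bam binary \linkS4class{LdaMatrix} supplying the labels; defaults
#'   to \code{A} (binary) or its binarisation (discrete); required for the
#'   continued variant.
#' @param ranks,nComponents,ridge passed to \code{\link{grufFit}}.
#' @param aggregate "fold" (default) averages per-fold metrics; "pooled"
#'   concatenates all test entries before computing metrics once.
#' @param correlationMethod passed to \code{\link{intensityCorrelation}}.
#' @param intensityTruth matrix of association intensities the correlation is
#'   computed against (e.g. the shared-protein counts); defaults to
#'   \code{A}'s own values. Passing a common intensity matrix makes
#'   correlations comparable across variants.
#' @return a \linkS4class{MetricReport}.
#' @export
runCv <- function(A, Sr, Sd, plan, bam = NULL, ranks = NULL,
                  nComponents = NULL, ridge = 0,
                  aggregate = c("fold", "pooled"),
                  correlationMethod = "pearson", intensityTruth = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(A, "LdaMatrix"), is(plan, "CvPlan"))
  if (plan@m != nrow(A@values) || plan@n != ncol(A@values))
    stop("CvPlan dimensions do not match the association matrix")
  if (is.null(bam)) {
    if (variant(A) == "continued")
      stop("the continued variant needs an explicit binary label matrix 'bam'")
    bam <- binarizeLda(A)
  }
  labelsAll <- labelsFromBinary(A, bam)
  Av <- as.matrix(A)
  truthAll <- if (is.null(intensityTruth)) Av else as.matrix(intensityTruth)
  if (!identical(dim(truthAll), dim(Av)))
    stop("'intensityTruth' dimensions do not match the association matrix")
  Srm <- if (is(Sr, "SimilarityMatrix")) Sr else SimilarityMatrix(as.matrix(Sr))
  Sdm <- if (is(Sd, "SimilarityMatrix")) Sd else SimilarityMatrix(as.matrix(Sd))
  SrFull <- as.matrix(Srm)[A@lncrnaIds, A@lncrnaIds, drop = FALSE]
  SdFull <- as.matrix(Sdm)[A@diseaseIds, A@diseaseIds, drop = FALSE]

  perFold <- data.frame()
  pooledScores <- numeric(); pooledLabels <- numeric(); pooledTruth <- numeric()
  for (f in seq_along(plan@folds)) {
    fold <- plan@folds[[f]]
    test <- fold$testEntries
    if (nrow(test) == 0) next
    if (plan@task == "T1") {
      Atr <- Av
      Atr[test] <- 0
      fit <- grufFit(LdaMatrix(Atr, variant = variant(A)),
                     SimilarityMatrix(SrFull), SimilarityMatrix(SdFull),
                     ranks = ranks, nComponents = nComponents, ridge = ridge)
      scores <- as.matrix(predictT1(fit))
      sc <- scores[test]
    } else if (plan@task == "T2") {
      rows <- fold$trainRows
      fit <- grufFit(LdaMatrix(Av[rows, , drop = FALSE], variant = variant(A)),
                     SimilarityMatrix(SrFull[rows, rows, drop = FALSE]),
                     SimilarityMatrix(SdFull),
                     ranks = ranks, nComponents = nComponents, ridge = ridge)
      sx <- SrFull[fold$testRows, rows, drop = FALSE]
      scores <- as.matrix(predictT2(fit, sx))
      sc <- scores[cbind(match(test[, "row"], fold$testRows), test[, "col"])]
    } else if (plan@task == "T3") {
      cols <- fold$trainCols
      fit <- grufFit(LdaMatrix(Av[, cols, drop = FALSE], variant = variant(A)),
                     SimilarityMatrix(SrFull),
                     SimilarityMatrix(SdFull[cols, cols, drop = FALSE]),
                     ranks = ranks, nComponents = nComponents, ridge = ridge)
      sy <- SdFull[fold$testCols, cols, drop = FALSE]
      scores <- as.matrix(predictT3(fit, sy))
      sc <- scores[cbind(test[, "row"], match(test[, "col"], fold$testCols))]
    } else {
      trnR <- fold$trainRows; trnC <- fold$trainCols
      fit <- grufFit(LdaMatrix(Av[trnR, trnC, drop = FALSE],
                               variant = variant(A)),
                     SimilarityMatrix(SrFull[trnR, trnR, drop = FALSE]),
                     SimilarityMatrix(SdFull[trnC, trnC, drop = FALSE]),
                     ranks = ranks, nComponents = nComponents, ridge = ridge)
      sx <- SrFull[fold$testRows, trnR, drop = FALSE]
      sy <- SdFull[fold$testCols, trnC, drop = FALSE]
      scores <- as.matrix(predictT4(fit, sx, sy))
      sc <- scores[cbind(match(test[, "row"], fold$testRows),
                         match(test[, "col"], fold$testCols))]
    }
    lab <- labelsAll[test]
    tru <- truthAll[test]
    pooledScores <- c(pooledScores, sc)
    pooledLabels <- c(pooledLabels, lab)
    pooledTruth <- c(pooledTruth, tru)
    if (length(unique(lab)) < 2) {
      warning(sprintf("fold %d skipped: single-class test labels", f))
      next
    }
    corr <- if (stats::sd(sc) > 0 && stats::sd(tru) > 0 && length(sc) >= 3)
      intensityCorrelation(sc, tru, method = correlationMethod) else NA_real_
    perFold <- rbind(perFold, data.frame(
      fold = f, nTest = nrow(test),
      auc = aucScore(sc, lab), aupr = auprScore(sc, lab),
      correlation = corr))
  }
  if (nrow(perFold) == 0) stop("no evaluable fold (all single-class)")
  if (aggregate == "fold") {
    auc <- mean(perFold$auc); aupr <- mean(perFold$aupr)
    corr <- mean(perFold$correlation, na.rm = TRUE)
  } else {
    auc <- aucScore(pooledScores, pooledLabels)
    aupr <- auprScore(pooledScores, pooledLabels)
    corr <- intensityCorrelation(pooledScores, pooledTruth,
                                 method = correlationMethod)
  }
  new("MetricReport", task = plan@task, variant = variant(A),
      auc = auc, aupr = aupr, correlation = if (is.nan(corr)) NA_real_ else corr,
      perFold = perFold)
}
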
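#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn entityIds ids of a similarity matrix
#' @export
setMethod("entityIds", "SimilarityMatrix", function(x) x@ids)

#' @describeIn entityIds ids of an embedding
#' @export
setMethod("entityIds", "Embedding", function(x) x@ids)

#' @describeIn entityIds descriptor codes of a disease DAG
#' @export
setMethod("entityIds", "DiseaseDag", function(x) x@nodes)

#' @describeIn lncrnaIds lncRNA ids of an association matrix
#' @export
setMethod("lncrnaIds", "LdaMatrix", function(x) x@lncrnaIds)

#' @describeIn lncrnaIds row ids of a bipartite matrix
#' @export
setMethod("lncrnaIds", "BipartiteMatrix", function(x) x@rowIds)

#' @describeIn lncrnaIds lncRNA ids of a score matrix
#' @export
setMethod("lncrnaIds", "ScoreMatrix", function(x) x@lncrnaIds)

#' @describeIn diseaseIds disease ids of an association matrix
#' @export
setMethod("diseaseIds", "LdaMatrix", function(x) x@diseaseIds)

#' @describeIn diseaseIds disease ids of a score matrix
#' @export
setMethod("diseaseIds", "ScoreMatrix", function(x) x@diseaseIds)

#' @describeIn variant variant of an association matrix
#' @export
setMethod("variant", "LdaMatrix", function(x) x@variant)

#' @describeIn latentFactors factors of an embedding
#' @export
setMethod("latentFactors", "Embedding", function(x) x@factors)

#' @describeIn singularValues spectrum of an embedding
#' @export
setMethod("singularValues", "Embedding", function(x) x@singularValues)

#' @describeIn thetaMatrix bi-regression matrix of a fitted model
#' @export
setMethod("thetaMatrix", "GrufModel", function(x) x@theta)

#' Extract the underlying labelled matrix
#'
#' @param x a gruf matrix-like object.
#' @param ... ignored.
#' @return the labelled base matrix.
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "BipartiteMatrix", function(x, ...) x@values)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "LdaMatrix", function(x, ...) x@values)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@scores)

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "Embedding", function(x, ...) x@factors)

setMethod("dim", "LdaMatrix", function(x) dim(x@values))
setMethod("dim", "ScoreMatrix", function(x) dim(x@scores))
setMethod("dim", "BipartiteMatrix", function(x) dim(x@values))
setMethod("dim", "SimilarityMatrix", function(x) dim(x@values))

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d entities\n", length(object@ids)))
  if (length(object@values))
    cat(sprintf("  off-diagonal range [%.4g, %.4g]\n",
                min(object@values[row(object@values) != col(object@values)],
                    Inf),
                max(object@values[row(object@values) != col(object@values)],
                    -Inf)))
  invisible(object)
})

setMethod("show", "LdaMatrix", function(object) {
  known <- if (object@variant == "continued") sum(object@values >= 1)
           else sum(object@values > 0)
  cat(sprintf("LdaMatrix (%s): %d lncRNAs x %d diseases, %d known associations\n",
              object@variant, nrow(object@values), ncol(object@values), known))
  invisible(object)
})

setMethod("show", "BipartiteMatrix", function(object) {
  cat(sprintf("BipartiteMatrix: %d x %d, %d non-zero entries\n",
              nrow(object@values), ncol(object@values),
              sum(object@values > 0)))
  invisible(object)
})

setMethod("show", "Embedding", function(object) {
  cat(sprintf("Embedding: %d entities, %d latent dimensions\n",
              length(object@ids), ncol(object@factors)))
  if (length(object@singularValues))
    cat("  spectrum:", paste(signif(utils::head(object@singularValues, 6), 4),
                             collapse = ", "),
        if (length(object@singularValues) > 6) "..." else "", "\n")
  invisible(object)
})

setMethod("show", "GrufModel", function(object) {
  r <- object@ranks
  cat("GrufModel (graph-regression, SVD + PLS bi-regression)\n")
  cat(sprintf("  %d lncRNAs, %d diseases\n", length(object@fr@ids),
              length(object@fd@ids)))
  cat(sprintf("  ranks: r = %d (associating), p = %d (lncRNA), q = %d (disease); %d PLS components\n",
              r[1], r[2], r[3], object@nComponents))
  invisible(object)
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d lncRNAs x %d diseases, score range [%.4g, %.4g]\n",
              nrow(object@scores), ncol(object@scores),
              min(object@scores), max(object@scores)))
  invisible(object)
})

setMethod("show", "DiseaseDag", function(object) {
  cat(sprintf("DiseaseDag '%s': %d descriptors (max depth %d)\n",
              object@diseaseId, length(object@nodes), max(object@depth)))
  invisible(object)
})

setMethod("show", "CvPlan", function(object) {
  cat(sprintf("CvPlan: task %s, K = %d, %d folds on a %d x %d matrix (seed %d)\n",
              object@task, object@K, length(object@folds), object@m,
              object@n, object@seed))
  invisible(object)
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: task %s, %s associations, %d folds\n",
              object@task, object@variant, nrow(object@perFold)))
  cat(sprintf("  AUC %.4f  AUPR %.4f  Correlation %.4f\n",
              object@auc, object@aupr, object@correlation))
  invisible(object)
})
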
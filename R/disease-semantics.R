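#' @include AllClasses.R
NULL

# Parent lookup: explicit hierarchy edges when given, otherwise MeSH tree
# numbers encode their own ancestry by dot-prefix truncation
# (C04.588.180 -> C04.588 -> C04).
.parentFun <- function(hierarchy) {
  if (is.null(hierarchy)) {
    function(code) {
      if (!grepl(".", code, fixed = TRUE)) return(character())
      sub("\\.[^.]+$", "", code)
    }
  } else {
    if (!all(c("child", "parent") %in% colnames(hierarchy)))
      stop("hierarchy must have columns 'child' and 'parent'")
    byChild <- split(as.character(hierarchy$parent),
                     as.character(hierarchy$child))
    function(code) unique(byChild[[code]] %||% character())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the MeSH DAG of one disease
#'
#' A disease is represented by the DAG spanned by its MeSH descriptors and
#' all their ancestors in the descriptor hierarchy. Each node gets the
#' minimum hop count to any of the disease's own descriptors (those have
#' depth 0); with multiple parents the smallest depth wins.
#'
#' @param diseaseId disease identifier.
#' @param descriptors character vector of MeSH descriptor codes
#'   (e.g. "C04.588.180"); a disease may belong to several categories.
#' @param hierarchy optional data.frame with columns \code{child},
#'   \code{parent}. When NULL, ancestry is derived from dot-prefix
#'   truncation of the tree numbers themselves.
#' @return a \linkS4class{DiseaseDag}.
#' @export
buildDiseaseDag <- function(diseaseId, descriptors, hierarchy = NULL) {
  descriptors <- unique(as.character(descriptors))
  if (length(descriptors) == 0) stop("disease has no descriptors")
  if (!is.null(hierarchy)) {
    known <- unique(c(as.character(hierarchy$child),
                      as.character(hierarchy$parent)))
    missing <- setdiff(descriptors, known)
    if (length(missing))
      stop(sprintf("unknown descriptor code(s) for disease '%s': %s",
                   diseaseId, paste(missing, collapse = ", ")))
  }
  parentsOf <- .parentFun(hierarchy)
  depth <- stats::setNames(rep(0L, length(descriptors)), descriptors)
  frontier <- descriptors
  d <- 0L
  while (length(frontier)) {       # level-wise BFS child -> parent: min depth
    d <- d + 1L
    parents <- unique(unlist(lapply(frontier, parentsOf)))
    parents <- setdiff(parents, names(depth))
    if (length(parents) == 0) break
    depth[parents] <- d
    frontier <- parents
    if (d > 10000L) stop("hierarchy appears cyclic")
  }
  new("DiseaseDag", diseaseId = as.character(diseaseId),
      nodes = names(depth), depth = depth)
}

#' Semantic similarity of two disease DAGs
#'
#' Each node t of DAG X contributes D_X(t) = decay^depth_X(t); the semantic
#' value of the DAG is DV(X) = sum of contributions. Similarity is the shared
#' contribution relative to the total,
#' sim(A, B) = sum_{t in A&B} (D_A(t) + D_B(t)) / (DV(A) + DV(B)):
#' 1 for identical DAGs (with identical depths), 0 for disjoint node sets —
#' the more of their DAGs two diseases share, the more similar they are.
#'
#' @param a,b \linkS4class{DiseaseDag} objects.
#' @param decay semantic decay factor per hop, in (0, 1); default 0.5.
#' @return similarity in [0, 1].
#' @export
meshSemanticSimilarity <- function(a, b, decay = 0.5) {
  stopifnot(is(a, "DiseaseDag"), is(b, "DiseaseDag"))
  if (decay <= 0 || decay >= 1) stop("decay must lie in (0, 1)")
  if (length(a@nodes) == 0 || length(b@nodes) == 0) stop("empty DiseaseDag")
  da <- decay^a@depth
  db <- decay^b@depth
  shared <- intersect(a@nodes, b@nodes)
  (sum(da[shared]) + sum(db[shared])) / (sum(da) + sum(db))
}

#' Pairwise MeSH semantic similarity matrix
#'
#' @param dags list of \linkS4class{DiseaseDag} objects with unique disease
#'   ids.
#' @param decay semantic decay factor, in (0, 1).
#' @return a \linkS4class{SimilarityMatrix} over the disease ids (entries in
#'   [0, 1], exact zeros possible for disjoint DAGs).
#' @export
meshSimilarityMatrix <- function(dags, decay = 0.5) {
  ids <- vapply(dags, function(d) d@diseaseId, character(1))
  if (anyDuplicated(ids)) stop("duplicated disease ids")
  n <- length(dags)
  S <- diag(1, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- meshSemanticSimilarity(dags[[i]], dags[[j]], decay)
  }
  dimnames(S) <- list(ids, ids)
  SimilarityMatrix(S, ids = ids)
}

#' ICD same-category disease similarity
#'
#' Fallback used when MeSH codes are unavailable but ICD category labels
#' are: similarity 1 if two diseases share the category, 0 otherwise.
#'
#' @param labels named character vector mapping disease id to its single
#'   ICD category.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
icdCategorySimilarity <- function(labels) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be named uniquely by disease id")
  if (anyNA(labels) || any(labels == ""))
    stop(sprintf("missing category label for: %s",
                 paste(names(labels)[is.na(labels) | labels == ""],
                       collapse = ", ")))
  S <- outer(labels, labels, "==") * 1
  diag(S) <- 1
  dimnames(S) <- list(names(labels), names(labels))
  SimilarityMatrix(S, ids = names(labels))
}
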
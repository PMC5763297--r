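#' @import methods
NULL

.checkLabelledMatrix <- function(values, rowIds, colIds) {
  msg <- character()
  if (!is.matrix(values) || !is.numeric(values))
    msg <- c(msg, "'values' must be a numeric matrix")
  else {
    if (nrow(values) != length(rowIds))
      msg <- c(msg, "row id count does not match matrix rows")
    if (ncol(values) != length(colIds))
      msg <- c(msg, "column id count does not match matrix columns")
    if (anyNA(values)) msg <- c(msg, "matrix contains missing values")
  }
  if (anyDuplicated(rowIds)) msg <- c(msg, "duplicated row ids")
  if (anyDuplicated(colIds)) msg <- c(msg, "duplicated column ids")
  msg
}

#' SimilarityMatrix: labelled symmetric similarity matrix
#'
#' Houses the lncRNA similarity S_r, the disease similarity S_d and the
#' protein similarity S_P. Entries lie in [0, 1] with a unit diagonal;
#' sequence-derived similarities of the form 1/(1 + dist) are strictly
#' positive, while MeSH/ICD disease similarities may contain exact zeros, so
#' the class-wide invariant is the relaxed [0, 1].
#'
#' @slot ids ordered entity identifiers.
#' @slot values square numeric matrix.
#' @export
setClass("SimilarityMatrix",
  representation(ids = "character", values = "matrix"),
  validity = function(object) {
    msg <- .checkLabelledMatrix(object@values, object@ids, object@ids)
    if (length(msg)) return(msg)
    v <- object@values
    if (nrow(v) != ncol(v)) return("similarity matrix must be square")
    if (nrow(v) > 0) {
      if (max(abs(v - t(v))) > 1e-8) return("similarity matrix not symmetric")
      if (max(abs(diag(v) - 1)) > 1e-8) return("diagonal must equal 1")
      if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
        return("similarity entries must lie in [0, 1]")
    }
    TRUE
  }
)

#' Construct a SimilarityMatrix
#'
#' Symmetrises tiny numerical asymmetry (up to 1e-8) and forces the diagonal
#' to exactly 1 before validation.
#'
#' @param values square numeric matrix; row/column names are used as ids when
#'   \code{ids} is missing.
#' @param ids entity identifiers.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(ids)) stop("similarity matrix needs entity ids (row names)")
  ids <- as.character(ids)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (nrow(values) > 0) {
    if (max(abs(values - t(values))) > 1e-8)
      stop("similarity matrix asymmetric beyond 1e-8")
    values <- (values + t(values)) / 2
    diag(values) <- 1
  }
  dimnames(values) <- list(ids, ids)
  new("SimilarityMatrix", ids = ids, values = values)
}

#' BipartiteMatrix: labelled non-negative bipartite relation
#'
#' Houses the lncRNA x protein interaction matrix A_rp and the gene x disease
#' association matrix A_gd.
#'
#' @slot rowIds,colIds ordered identifiers.
#' @slot values non-negative numeric matrix.
#' @export
setClass("BipartiteMatrix",
  representation(rowIds = "character", colIds = "character", values = "matrix"),
  validity = function(object) {
    msg <- .checkLabelledMatrix(object@values, object@rowIds, object@colIds)
    if (length(msg)) return(msg)
    if (length(object@values) && min(object@values) < 0)
      return("bipartite matrix entries must be non-negative")
    TRUE
  }
)

#' Construct a BipartiteMatrix
#'
#' @param values non-negative numeric matrix with dimnames, or explicit ids.
#' @param rowIds,colIds identifiers; default taken from dimnames.
#' @param binary if TRUE, additionally require entries in {0, 1}.
#' @return a \linkS4class{BipartiteMatrix}.
#' @export
BipartiteMatrix <- function(values, rowIds = rownames(values),
                            colIds = colnames(values), binary = FALSE) {
  values <- as.matrix(values)
  if (is.null(rowIds) || is.null(colIds))
    stop("bipartite matrix needs row and column ids")
  if (binary && length(values) && !all(values %in% c(0, 1)))
    stop("binary bipartite matrix has entries outside {0, 1}")
  rowIds <- as.character(rowIds); colIds <- as.character(colIds)
  dimnames(values) <- list(rowIds, colIds)
  new("BipartiteMatrix", rowIds = rowIds, colIds = colIds, values = values)
}

#' LdaMatrix: lncRNA x disease association matrix
#'
#' The object being predicted, in one of three variants: \code{binary}
#' (association exists or not), \code{discrete} (count of shared
#' proteins/genes, non-negative integers) or \code{continued} (real-valued
#' intensity, entries >= 1 marking known associations by convention).
#'
#' @slot lncrnaIds,diseaseIds ordered identifiers.
#' @slot values m x n numeric matrix.
#' @slot variant one of "binary", "discrete", "continued".
#' @export
setClass("LdaMatrix",
  representation(lncrnaIds = "character", diseaseIds = "character",
                 values = "matrix", variant = "character"),
  validity = function(object) {
    msg <- .checkLabelledMatrix(object@values, object@lncrnaIds,
                                object@diseaseIds)
    if (length(msg)) return(msg)
    if (length(object@variant) != 1 ||
        !object@variant %in% c("binary", "discrete", "continued"))
      return("variant must be one of binary/discrete/continued")
    v <- object@values
    if (length(v)) {
      if (object@variant == "binary" && !all(v %in% c(0, 1)))
        return("binary LdaMatrix has entries outside {0, 1}")
      if (object@variant == "discrete" &&
          (min(v) < 0 || max(abs(v - round(v))) > 0))
        return("discrete LdaMatrix entries must be non-negative integers")
      if (object@variant == "continued" && min(v) < 0)
        return("continued LdaMatrix entries must be non-negative")
    }
    TRUE
  }
)

#' Construct an LdaMatrix
#'
#' @param values numeric matrix (lncRNAs x diseases).
#' @param variant association type.
#' @param lncrnaIds,diseaseIds identifiers; default from dimnames.
#' @return an \linkS4class{LdaMatrix}.
#' @export
LdaMatrix <- function(values, variant = c("binary", "discrete", "continued"),
                      lncrnaIds = rownames(values),
                      diseaseIds = colnames(values)) {
  variant <- match.arg(variant)
  values <- as.matrix(values)
  if (is.null(lncrnaIds) || is.null(diseaseIds))
    stop("LdaMatrix needs lncRNA and disease ids")
  lncrnaIds <- as.character(lncrnaIds); diseaseIds <- as.character(diseaseIds)
  dimnames(values) <- list(lncrnaIds, diseaseIds)
  new("LdaMatrix", lncrnaIds = lncrnaIds, diseaseIds = diseaseIds,
      values = values, variant = variant)
}

#' Embedding: low-rank latent factors of a graph
#'
#' Factors are U * sqrt(Sigma) for the retained spectrum, so the bilinear
#' products of Eq.-style predictors reconstruct the embedded matrix.
#'
#' @slot ids ordered entity identifiers (rows of \code{factors}).
#' @slot factors entities x latent-dimensions matrix.
#' @slot singularValues non-increasing, non-negative retained spectrum.
#' @export
setClass("Embedding",
  representation(ids = "character", factors = "matrix",
                 singularValues = "numeric"),
  validity = function(object) {
    msg <- .checkLabelledMatrix(object@factors, object@ids,
                                as.character(seq_len(ncol(object@factors))))
    msg <- msg[!grepl("column id", msg)]
    if (length(msg)) return(msg)
    sv <- object@singularValues
    if (ncol(object@factors) != length(sv))
      return("latent dimension count must match spectrum length")
    if (length(sv)) {
      if (min(sv) < 0) return("singular values must be non-negative")
      if (is.unsorted(rev(sv), strictly = FALSE))
        return("singular values must be non-increasing")
    }
    TRUE
  }
)

Embedding <- function(ids, factors, singularValues) {
  factors <- as.matrix(factors)
  rownames(factors) <- ids
  new("Embedding", ids = as.character(ids), factors = factors,
      singularValues = as.numeric(singularValues))
}

#' GrufModel: fitted graph-regression model
#'
#' Holds the SVD embeddings of the association matrix (lncRNA associating
#' matrix \code{ra}, disease associating matrix \code{da}), the symmetric
#' embeddings of the similarity matrices (lncRNA latent feature matrix
#' \code{fr}, disease latent feature matrix \code{fd}), the PLS regression
#' coefficients \code{br} (p x r) and \code{bd} (q x r), and the bi-regression
#' matrix \code{theta} = br bd^T that the four task predictors share.
#'
#' @slot ra,da,fr,fd \linkS4class{Embedding} objects.
#' @slot br,bd,theta numeric matrices.
#' @slot ranks integer triple (r, p, q).
#' @slot nComponents PLS component count used.
#' @export
setClass("GrufModel",
  representation(ra = "Embedding", da = "Embedding", fr = "Embedding",
                 fd = "Embedding", br = "matrix", bd = "matrix",
                 theta = "matrix", ranks = "integer",
                 nComponents = "integer"),
  validity = function(object) {
    r <- object@ranks
    if (length(r) != 3) return("ranks must be the triple (r, p, q)")
    if (ncol(object@br) != r[1] || nrow(object@br) != r[2])
      return("br must be p x r")
    if (ncol(object@bd) != r[1] || nrow(object@bd) != r[3])
      return("bd must be q x r")
    d <- object@theta - object@br %*% t(object@bd)
    if (length(d) && max(abs(d)) > 1e-12)
      return("theta must equal br %*% t(bd)")
    TRUE
  }
)

#' ScoreMatrix: predicted confidence scores
#'
#' @slot lncrnaIds,diseaseIds ordered identifiers.
#' @slot scores numeric matrix of confidence scores (finite).
#' @export
setClass("ScoreMatrix",
  representation(lncrnaIds = "character", diseaseIds = "character",
                 scores = "matrix"),
  validity = function(object) {
    msg <- .checkLabelledMatrix(object@scores, object@lncrnaIds,
                                object@diseaseIds)
    if (length(msg)) return(msg)
    if (length(object@scores) && !all(is.finite(object@scores)))
      return("scores must be finite")
    TRUE
  }
)

ScoreMatrix <- function(scores, lncrnaIds = rownames(scores),
                        diseaseIds = colnames(scores)) {
  scores <- as.matrix(scores)
  dimnames(scores) <- list(lncrnaIds, diseaseIds)
  new("ScoreMatrix", lncrnaIds = as.character(lncrnaIds),
      diseaseIds = as.character(diseaseIds), scores = scores)
}

#' DiseaseDag: ancestor closure of a disease's MeSH descriptors
#'
#' @slot diseaseId disease identifier.
#' @slot nodes descriptor codes: the disease's own descriptors plus all
#'   ancestors.
#' @slot depth named integer vector, minimum hop count from any of the
#'   disease's own descriptors (0 for the descriptors themselves).
#' @export
setClass("DiseaseDag",
  representation(diseaseId = "character", nodes = "character",
                 depth = "integer"),
  validity = function(object) {
    if (length(object@nodes) == 0) return("DiseaseDag must be non-empty")
    if (anyDuplicated(object@nodes)) return("duplicated descriptor codes")
    if (!identical(sort(names(object@depth)), sort(object@nodes)))
      return("depth must be named by exactly the DAG's nodes")
    if (min(object@depth) != 0)
      return("the disease's own descriptors must have depth 0")
    TRUE
  }
)

#' CvPlan: task-specific cross-validation partition
#'
#' For T1 the units are matrix entries, for T2 rows (lncRNAs), for T3 columns
#' (diseases); T4 crosses K row-folds with K column-folds into K^2 fold
#' pairs whose excluded entries (test row x train column and vice versa)
#' attend neither training nor testing.
#'
#' @slot task one of "T1".."T4".
#' @slot K fold count per axis.
#' @slot m,n association matrix dimensions the plan was built for.
#' @slot seed RNG seed the plan was drawn with.
#' @slot folds list of fold specifications (test/train/excluded index sets).
#' @export
setClass("CvPlan",
  representation(task = "character", K = "integer", m = "integer",
                 n = "integer", seed = "integer", folds = "list"))

#' MetricReport: aggregated cross-validation metrics
#'
#' @slot task,variant what was evaluated.
#' @slot auc,aupr,correlation fold-averaged metrics.
#' @slot perFold data.frame with one row per evaluated fold.
#' @export
setClass("MetricReport",
  representation(task = "character", variant = "character", auc = "numeric",
                 aupr = "numeric", correlation = "numeric",
                 perFold = "data.frame"))
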
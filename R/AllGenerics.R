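#' @include AllClasses.R
NULL

#' Entity identifiers of a gruf object
#'
#' @param x a \linkS4class{SimilarityMatrix}, \linkS4class{Embedding} or
#'   \linkS4class{DiseaseDag}.
#' @return character vector of identifiers.
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' Row (lncRNA) identifiers
#'
#' @param x an \linkS4class{LdaMatrix}, \linkS4class{BipartiteMatrix} or
#'   \linkS4class{ScoreMatrix}.
#' @return character vector.
#' @export
setGeneric("lncrnaIds", function(x) standardGeneric("lncrnaIds"))

#' Column (disease) identifiers
#'
#' @param x an \linkS4class{LdaMatrix} or \linkS4class{ScoreMatrix}.
#' @return character vector.
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' Association variant of an LdaMatrix
#'
#' @param x an \linkS4class{LdaMatrix}.
#' @return one of \code{"binary"}, \code{"discrete"}, \code{"continued"}.
#' @export
setGeneric("variant", function(x) standardGeneric("variant"))

#' Latent factor matrix of an Embedding
#'
#' @param x an \linkS4class{Embedding}.
#' @return numeric matrix, entities in rows, latent dimensions in columns.
#' @export
setGeneric("latentFactors", function(x) standardGeneric("latentFactors"))

#' Retained spectrum of an Embedding
#'
#' @param x an \linkS4class{Embedding}.
#' @return non-increasing numeric vector of singular values (or clipped
#'   eigenvalues for symmetric embeddings).
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' Bi-regression coefficient matrix of a fitted model
#'
#' @param x a \linkS4class{GrufModel}.
#' @return the p x q matrix linking the lncRNA and disease latent feature
#'   spaces.
#' @export
setGeneric("thetaMatrix", function(x) standardGeneric("thetaMatrix"))
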
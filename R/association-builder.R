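#' @include AllClasses.R
NULL

# Resolve the shared gene/protein namespace between the lncRNA-protein
# interaction columns and the gene-disease association rows; genes outside
# the intersection are dropped with a warning (gene and protein name the
# same object here).
.sharedGenes <- function(Arp, Agd) {
  gr <- Arp@colIds
  gd <- Agd@rowIds
  shared <- intersect(gr, gd)
  if (length(shared) == 0)
    stop("no shared gene/protein ids between the interaction and association matrices")
  dropped <- length(gr) + length(gd) - 2 * length(shared)
  if (dropped > 0)
    warning(sprintf("dropping %d gene id(s) outside the shared namespace",
                    dropped))
  shared
}

.asBipartite <- function(x, what) {
  if (is(x, "BipartiteMatrix")) return(x)
  if (is.matrix(x)) return(BipartiteMatrix(x))
  stop(sprintf("'%s' must be a BipartiteMatrix or labelled matrix", what))
}

#' Binary lncRNA-disease associations from shared genes
#'
#' An lncRNA and a disease are associated (entry 1) exactly when they share
#' at least one gene/protein: some gene both interacts with the lncRNA
#' (A_rp) and is associated with the disease (A_gd).
#'
#' @param Arp lncRNA x protein interaction matrix
#'   (\linkS4class{BipartiteMatrix} or labelled matrix).
#' @param Agd gene x disease association matrix.
#' @return an \linkS4class{LdaMatrix} with variant \code{"binary"}.
#' @export
buildBinary <- function(Arp, Agd) {
  Arp <- .asBipartite(Arp, "Arp"); Agd <- .asBipartite(Agd, "Agd")
  g <- .sharedGenes(Arp, Agd)
  cnt <- (as.matrix(Arp)[, g, drop = FALSE] > 0) %*%
         (as.matrix(Agd)[g, , drop = FALSE] > 0)
  LdaMatrix((cnt > 0) * 1, variant = "binary",
            lncrnaIds = Arp@rowIds, diseaseIds = Agd@colIds)
}

#' Discrete lncRNA-disease associations: shared-gene counts
#'
#' Entry (i, j) is the number of genes/proteins shared by lncRNA i and
#' disease j; binarising this matrix reproduces \code{\link{buildBinary}}
#' exactly.
#'
#' @inheritParams buildBinary
#' @return an \linkS4class{LdaMatrix} with variant \code{"discrete"}.
#' @export
buildDiscrete <- function(Arp, Agd) {
  Arp <- .asBipartite(Arp, "Arp"); Agd <- .asBipartite(Agd, "Agd")
  g <- .sharedGenes(Arp, Agd)
  cnt <- (as.matrix(Arp)[, g, drop = FALSE] > 0) %*%
         (as.matrix(Agd)[g, , drop = FALSE] > 0)
  LdaMatrix(cnt, variant = "discrete",
            lncrnaIds = Arp@rowIds, diseaseIds = Agd@colIds)
}

#' Continued lncRNA-disease associations: intensity via protein similarity
#'
#' The association intensity A^c = A_rp S_P A_gd weights every shared-gene
#' path by the protein similarity: the more shared genes and the more
#' similar they are, the stronger the association. With S_P the identity
#' this reduces exactly to the discrete count. Entries are reported as the
#' raw product (no rescaling); entries >= 1 mark known associations by the
#' matrix-product construction.
#'
#' @inheritParams buildBinary
#' @param Sp \linkS4class{SimilarityMatrix} over the shared gene/protein
#'   namespace.
#' @return an \linkS4class{LdaMatrix} with variant \code{"continued"}.
#' @export
buildContinued <- function(Arp, Sp, Agd) {
  Arp <- .asBipartite(Arp, "Arp"); Agd <- .asBipartite(Agd, "Agd")
  if (!is(Sp, "SimilarityMatrix")) Sp <- SimilarityMatrix(Sp)
  g <- .sharedGenes(Arp, Agd)
  missing <- setdiff(g, Sp@ids)
  if (length(missing))
    stop(sprintf("protein similarity is missing shared gene(s): %s",
                 paste(missing, collapse = ", ")))
  vals <- as.matrix(Arp)[, g, drop = FALSE] %*%
          as.matrix(Sp)[g, g, drop = FALSE] %*%
          as.matrix(Agd)[g, , drop = FALSE]
  LdaMatrix(vals, variant = "continued",
            lncrnaIds = Arp@rowIds, diseaseIds = Agd@colIds)
}

#' Binary labels for scoring discrete/continued predictions
#'
#' There is a one-to-one correspondence between the entries of the binary
#' association matrix and the enriched entries of the discrete or continued
#' matrix, so the binary values serve as AUC labels for non-binary
#' predictions.
#'
#' @param lda the \linkS4class{LdaMatrix} whose entries are being scored.
#' @param bam the binary \linkS4class{LdaMatrix} over the same ids in the
#'   same order.
#' @return binary label matrix with the shared dimnames.
#' @export
labelsFromBinary <- function(lda, bam) {
  stopifnot(is(lda, "LdaMatrix"), is(bam, "LdaMatrix"))
  if (variant(bam) != "binary") stop("'bam' must be the binary variant")
  if (!identical(lda@lncrnaIds, bam@lncrnaIds) ||
      !identical(lda@diseaseIds, bam@diseaseIds))
    stop("id sets/order of 'lda' and 'bam' differ")
  as.matrix(bam)
}

#' Binarise an association matrix
#'
#' @param lda an \linkS4class{LdaMatrix}. Binary and discrete variants
#'   binarise by > 0; for the continued variant the product construction
#'   does not determine the binary matrix, so an explicit one is required.
#' @return an \linkS4class{LdaMatrix}, variant binary.
#' @export
binarizeLda <- function(lda) {
  stopifnot(is(lda, "LdaMatrix"))
  if (variant(lda) == "continued")
    stop("continued intensities do not determine the binary matrix; supply it explicitly")
  LdaMatrix((as.matrix(lda) > 0) * 1, variant = "binary",
            lncrnaIds = lda@lncrnaIds, diseaseIds = lda@diseaseIds)
}
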
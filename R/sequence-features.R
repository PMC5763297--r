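#' @include AllClasses.R
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")
PROTEIN_GROUP_ALPHABET <- as.character(1:7)

# Dipole-moment / side-chain-volume grouping of the 20 standard amino acids
# into 7 classes; group index is the position in this list.
AA_GROUPS <- list(c("A", "G", "V"),
                  c("I", "L", "F", "P"),
                  c("Y", "M", "T", "S"),
                  c("H", "N", "Q", "W"),
                  c("R", "K"),
                  c("D", "E"),
                  c("C"))

.seqToString <- function(seq) {
  if (methods::is(seq, "XString") || methods::is(seq, "XStringSet"))
    seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1)
    stop("expected a single sequence (character scalar or XString)")
  seq
}

#' Normalise an RNA residue string
#'
#' Uppercases and maps the DNA convention T to U; any symbol outside
#' {A, C, G, U} is an error.
#'
#' @param seq character scalar or Biostrings sequence.
#' @param id optional identifier used in error messages.
#' @return normalised character scalar over {A, C, G, U}.
#' @export
normalizeRnaSequence <- function(seq, id = NULL) {
  s <- chartr("T", "U", toupper(.seqToString(seq)))
  if (nchar(s) == 0)
    stop(sprintf("empty RNA sequence%s", if (is.null(id)) "" else paste0(" '", id, "'")))
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad))
    stop(sprintf("invalid RNA residue '%s' in sequence%s", bad,
                 if (is.null(id)) "" else paste0(" '", id, "'")))
  s
}

#' All k-mers over an ordered alphabet, in lexicographic order
#'
#' @param alphabet ordered character vector of single symbols.
#' @param k word length.
#' @return character vector of length \code{length(alphabet)^k}.
#' @export
allKmers <- function(alphabet, k) {
  stopifnot(k >= 1)
  out <- alphabet
  if (k > 1) for (i in 2:k)
    out <- paste0(rep(alphabet, each = length(out)), out)
  out
}

#' Overlapping k-mer frequency vector
#'
#' Counts every overlapping window of length \code{k} (step 1) and divides by
#' the window count \code{len - k + 1}, so the vector sums to 1. Entries are
#' indexed lexicographically by k-mer over the given ordered alphabet.
#'
#' @param seq character scalar (or Biostrings sequence) over \code{alphabet}.
#' @param k word length; the sequence must be at least this long.
#' @param alphabet ordered symbol set; defaults to the RNA alphabet.
#' @param id optional identifier for error messages.
#' @return named numeric vector of length \code{length(alphabet)^k}.
#' @examples
#' kmerFrequency("ACGUACG", 2)
#' @export
kmerFrequency <- function(seq, k, alphabet = RNA_ALPHABET, id = NULL) {
  s <- .seqToString(seq)
  L <- nchar(s)
  if (L < k)
    stop(sprintf("sequence%s of length %d is shorter than k = %d",
                 if (is.null(id)) "" else paste0(" '", id, "'"), L, k))
  n <- L - k + 1L
  words <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  lev <- allKmers(alphabet, k)
  cnt <- table(factor(words, levels = lev))
  if (sum(cnt) < n)
    stop("sequence contains symbols outside the alphabet")
  out <- as.numeric(cnt) / n
  names(out) <- lev
  out
}

# Deterministic balanced segment lengths: the first (L mod s) segments get
# ceiling(L/s) residues, the rest floor(L/s).
.segmentLengths <- function(L, nSegments) {
  base <- L %/% nSegments
  extra <- L %% nSegments
  c(rep(base + 1L, extra), rep(base, nSegments - extra))
}

#' Segmented k-mer features of an lncRNA sequence
#'
#' Splits the sequence left-to-right into \code{nSegments} contiguous
#' segments of approximately equal length (the first \code{L mod nSegments}
#' segments one residue longer), computes the k-mer frequency vector of each
#' segment separately and concatenates them. Captures local composition,
#' reflecting that RNA-protein binding acts on local sequence zones. With
#' k = 4 and 35 segments an RNA sequence yields 35 * 4^4 = 8960 dimensions.
#'
#' @param seq RNA sequence (character or Biostrings); T is mapped to U.
#' @param k word length (default 4).
#' @param nSegments segment count (default 35).
#' @param id optional identifier for error messages.
#' @return numeric vector of length \code{nSegments * 4^k}; each segment's
#'   block sums to 1.
#' @export
segmentedKmerFeatures <- function(seq, k = 4, nSegments = 35, id = NULL) {
  s <- normalizeRnaSequence(seq, id = id)
  L <- nchar(s)
  if (L < nSegments * k)
    stop(sprintf("sequence%s of length %d too short for %d segments of >= %d residues",
                 if (is.null(id)) "" else paste0(" '", id, "'"),
                 L, nSegments, k))
  lens <- .segmentLengths(L, nSegments)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  blocks <- lapply(seq_len(nSegments), function(i) {
    f <- kmerFrequency(substr(s, starts[i], ends[i]), k, RNA_ALPHABET, id = id)
    names(f) <- paste0("seg", i, "_", names(f))
    f
  })
  unlist(blocks, use.names = TRUE)
}

#' Encode a protein sequence into the reduced 7-letter alphabet
#'
#' Each residue is replaced by the index of its physico-chemical group:
#' 1 = {A,G,V}, 2 = {I,L,F,P}, 3 = {Y,M,T,S}, 4 = {H,N,Q,W}, 5 = {R,K},
#' 6 = {D,E}, 7 = {C}.
#'
#' @param seq amino-acid sequence over the 20 one-letter codes.
#' @param id optional identifier for error messages.
#' @return character scalar over "1".."7", same length as the input.
#' @examples
#' encodeProteinSequence("AGV")   # "111"
#' encodeProteinSequence("CRKDE") # "75566"
#' @export
encodeProteinSequence <- function(seq, id = NULL) {
  s <- toupper(.seqToString(seq))
  if (nchar(s) == 0) stop("empty protein sequence")
  map <- character()
  for (g in seq_along(AA_GROUPS)) map[AA_GROUPS[[g]]] <- as.character(g)
  res <- strsplit(s, "", fixed = TRUE)[[1]]
  enc <- map[res]
  if (anyNA(enc)) {
    pos <- which(is.na(enc))[1]
    stop(sprintf("unknown amino acid '%s' at position %d%s", res[pos], pos,
                 if (is.null(id)) "" else paste0(" in sequence '", id, "'")))
  }
  paste(enc, collapse = "")
}

#' 3-mer features of a protein on the reduced alphabet
#'
#' The sequence is first encoded into the 7 amino-acid groups, then the
#' overlapping k-mer frequency is taken on the encoded sequence, giving
#' 7^k dimensions (343 for the default k = 3).
#'
#' @param seq amino-acid sequence.
#' @param k word length on the encoded sequence (default 3).
#' @param id optional identifier for error messages.
#' @return named numeric vector of length \code{7^k}.
#' @export
proteinKmerFeatures <- function(seq, k = 3, id = NULL) {
  enc <- encodeProteinSequence(seq, id = id)
  kmerFrequency(enc, k, PROTEIN_GROUP_ALPHABET, id = id)
}

#' Column-wise z-score normalisation
#'
#' Centres every column to sample mean 0 and scales to sample standard
#' deviation 1 (n - 1 denominator). Zero-variance columns are mapped to
#' all-zero rather than NaN so downstream distances stay finite.
#'
#' @param F numeric matrix (rows = entities) with at least 2 rows.
#' @return matrix of the same shape.
#' @export
zscoreColumns <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) < 2)
    stop("z-score needs at least 2 rows (sample sd undefined)")
  mu <- colMeans(F)
  sdv <- apply(F, 2, stats::sd)
  const <- sdv <= 1e-12 * pmax(1, abs(mu))
  sdv[const] <- 1
  Z <- sweep(sweep(F, 2, mu, "-"), 2, sdv, "/")
  Z[, const] <- 0
  Z
}

#' Project features onto their informative principal components
#'
#' Intended for already column-centred (z-scored) features: rows are
#' projected onto the principal axes via SVD, and components whose singular
#' value is at most \code{tol} times the largest are dropped — a relative
#' test for dimensions that are zero within numerical accuracy. When no
#' component is dropped the projection is a rotation, so pairwise Euclidean
#' distances are preserved.
#'
#' @param F numeric matrix, columns centred.
#' @param tol relative singular-value cutoff (default 1e-10).
#' @return matrix of PCA scores with the retained components as columns.
#' @export
pcaReduce <- function(F, tol = 1e-10) {
  F <- as.matrix(F)
  sv <- svd(F)
  keep <- sv$d > tol * sv$d[1]
  if (!any(keep)) keep[1] <- TRUE  # all-zero input: keep one null component
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                                nrow = sum(keep))
  rownames(scores) <- rownames(F)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Similarity matrix from feature vectors
#'
#' Pairwise similarity s_ij = 1 / (1 + ||f_i - f_j||_2), the reciprocal
#' Euclidean-distance kernel: 1 on the diagonal, strictly positive
#' everywhere.
#'
#' @param F numeric feature matrix with row names as entity ids.
#' @param ids entity identifiers (default row names).
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
similarityFromFeatures <- function(F, ids = rownames(F)) {
  F <- as.matrix(F)
  if (anyNA(F)) stop("feature matrix contains missing values")
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(F)))
  D <- as.matrix(stats::dist(F))
  S <- 1 / (1 + D)
  dimnames(S) <- list(ids, ids)
  SimilarityMatrix(S, ids = ids)
}

#' Sequence-based lncRNA similarity pipeline
#'
#' Runs the fixed feature pipeline: segmented k-mer features, z-score
#' normalisation, PCA projection (dropping numerically zero dimensions),
#' then the 1/(1 + dist) similarity.
#'
#' @param seqs named character vector or Biostrings RNAStringSet.
#' @param k k-mer length (default 4).
#' @param nSegments segment count (default 35).
#' @param pcaTol relative singular-value cutoff for \code{\link{pcaReduce}}.
#' @return a \linkS4class{SimilarityMatrix} over the sequence ids.
#' @export
lncrnaSimilarity <- function(seqs, k = 4, nSegments = 35, pcaTol = 1e-10) {
  seqs <- .asNamedStrings(seqs)
  feats <- t(vapply(names(seqs),
                    function(id) segmentedKmerFeatures(seqs[[id]], k = k,
                                                       nSegments = nSegments,
                                                       id = id),
                    numeric(nSegments * length(RNA_ALPHABET)^k)))
  similarityFromFeatures(pcaReduce(zscoreColumns(feats), tol = pcaTol),
                         ids = names(seqs))
}

#' Sequence-based protein similarity pipeline
#'
#' Reduced-alphabet k-mer features, z-score, PCA, then 1/(1 + dist).
#'
#' @param seqs named character vector or Biostrings AAStringSet.
#' @param k k-mer length on the encoded sequence (default 3).
#' @param pcaTol relative singular-value cutoff.
#' @return a \linkS4class{SimilarityMatrix} over the sequence ids.
#' @export
proteinSimilarity <- function(seqs, k = 3, pcaTol = 1e-10) {
  seqs <- .asNamedStrings(seqs)
  feats <- t(vapply(names(seqs),
                    function(id) proteinKmerFeatures(seqs[[id]], k = k, id = id),
                    numeric(7^k)))
  similarityFromFeatures(pcaReduce(zscoreColumns(feats), tol = pcaTol),
                         ids = names(seqs))
}

.asNamedStrings <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("expected a character vector or XStringSet")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  as.list(seqs)
}
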
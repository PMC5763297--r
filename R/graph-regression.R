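#' @include AllClasses.R
NULL

# Deterministic sign convention: flip each column of U (and the matching
# column of V) so its largest-magnitude entry is non-negative. Makes
# factorisations reproducible across linear-algebra backends.
.fixSigns <- function(U, V = NULL) {
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      if (!is.null(V)) V[, j] <- -V[, j]
    }
  }
  if (is.null(V)) U else list(U = U, V = V)
}

.defaultRank <- function(d, tol = 1e-10) {
  if (length(d) == 0 || max(d) <= 0) return(1L)
  max(1L, sum(d > tol * max(d)))
}

#' Truncated SVD embedding of a rectangular matrix
#'
#' Factorises M = U Sigma V^T and returns the rank-truncated left and right
#' embeddings L = U sqrt(Sigma), R = V sqrt(Sigma), so that L R^T is the
#' best rank-\code{rank} approximation of M (Frobenius error equal to the
#' discarded spectrum).
#'
#' @param M numeric matrix; row/column names become the embedding ids.
#' @param rank retained rank; default keeps the spectrum above
#'   \code{1e-10 * max(singular value)}.
#' @return list with elements \code{L} and \code{R}
#'   (\linkS4class{Embedding} objects).
#' @export
svdEmbed <- function(M, rank = NULL) {
  M <- as.matrix(M)
  sv <- svd(M)
  if (is.null(rank)) rank <- .defaultRank(sv$d)
  if (rank < 1 || rank > min(dim(M)))
    stop(sprintf("rank %d out of range [1, %d]", rank, min(dim(M))))
  fix <- .fixSigns(sv$u[, seq_len(rank), drop = FALSE],
                   sv$v[, seq_len(rank), drop = FALSE])
  d <- sv$d[seq_len(rank)]
  sq <- sqrt(d)
  rowIds <- rownames(M) %||% paste0("r", seq_len(nrow(M)))
  colIds <- colnames(M) %||% paste0("c", seq_len(ncol(M)))
  list(L = Embedding(rowIds, sweep(fix$U, 2, sq, "*"), d),
       R = Embedding(colIds, sweep(fix$V, 2, sq, "*"), d))
}

#' Symmetric embedding of a similarity matrix
#'
#' Eigen-decomposes a symmetric similarity matrix and returns
#' F = U sqrt(lambda+) over the top \code{rank} eigenvalues, so F F^T
#' reconstructs the positive semi-definite part of S. Negative eigenvalues
#' (possible for 1/(1 + dist) similarities, which are not guaranteed PSD)
#' are clipped to zero before the square root.
#'
#' @param S \linkS4class{SimilarityMatrix} or symmetric matrix (asymmetry
#'   beyond 1e-8 is an error).
#' @param rank retained dimensions; default keeps eigenvalues above
#'   \code{1e-10 * max}.
#' @return an \linkS4class{Embedding}.
#' @export
symmetricEmbed <- function(S, rank = NULL) {
  ids <- if (is(S, "SimilarityMatrix")) S@ids else
    rownames(S) %||% paste0("e", seq_len(nrow(as.matrix(S))))
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("matrix is not symmetric (beyond 1e-8)")
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (is.null(rank)) rank <- .defaultRank(lam)
  if (rank < 1 || rank > nrow(S))
    stop(sprintf("rank %d out of range [1, %d]", rank, nrow(S)))
  U <- .fixSigns(eg$vectors[, seq_len(rank), drop = FALSE])
  lam <- lam[seq_len(rank)]
  Embedding(ids, sweep(U, 2, sqrt(lam), "*"), lam)
}

#' Uncentered multi-response partial least squares
#'
#' NIPALS PLS2 without centring or scaling of X or Y: the bilinear
#' predictors have no intercept term, so the regression is carried out on
#' the raw latent factors. Returns the p x r coefficient matrix B with
#' X B approximating Y; with \code{nComponents >= rank(X)} and Y exactly in
#' the column space of X the recovery is exact.
#'
#' @param X n x p predictor matrix.
#' @param Y n x r response matrix (a vector is treated as one column).
#' @param nComponents latent components, at most \code{min(n, p)}; extraction
#'   stops early if X deflates to numerical zero.
#' @param tol convergence tolerance of the NIPALS inner loop.
#' @param maxIter iteration cap of the inner loop.
#' @return p x r coefficient matrix.
#' @export
plsRegress <- function(X, Y, nComponents = min(nrow(X), ncol(X)),
                       tol = 1e-12, maxIter = 500L) {
  X <- as.matrix(X)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same row count")
  if (nComponents < 1 || nComponents > min(nrow(X), ncol(X)))
    stop("nComponents out of range")
  normX0 <- sqrt(sum(X^2))
  if (normX0 < 1e-300) stop("degenerate predictor matrix X (all zeros)")
  p <- ncol(X); r <- ncol(Y)
  B0 <- matrix(0, p, r, dimnames = list(colnames(X), colnames(Y)))
  if (sqrt(sum(Y^2)) == 0) return(B0)
  W <- P <- matrix(0, p, 0)
  C <- matrix(0, r, 0)
  Xk <- X; Yk <- Y
  for (a in seq_len(nComponents)) {
    if (sqrt(sum(Xk^2)) < 1e-12 * normX0) break
    if (sqrt(sum(Yk^2)) < 1e-14) break
    u <- Yk[, which.max(colSums(Yk^2))]
    tOld <- rep(0, nrow(X))
    nw <- tt <- 0; cc <- NULL
    for (it in seq_len(maxIter)) {
      w <- crossprod(Xk, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      tvec <- Xk %*% w
      tt <- sum(tvec^2)
      if (tt < 1e-300) break
      cc <- crossprod(Yk, tvec) / tt
      if (sum(cc^2) < 1e-300) break
      u <- Yk %*% cc / sum(cc^2)
      if (sqrt(sum((tvec - tOld)^2)) <= tol * sqrt(tt)) break
      tOld <- tvec
    }
    if (nw < 1e-300 || tt < 1e-300 || is.null(cc)) break
    pvec <- crossprod(Xk, tvec) / tt
    Xk <- Xk - tvec %*% t(pvec)
    Yk <- Yk - tvec %*% t(cc)
    W <- cbind(W, w); P <- cbind(P, pvec); C <- cbind(C, cc)
  }
  if (ncol(W) == 0) return(B0)
  PW <- crossprod(P, W)
  B <- W %*% solve(PW, t(C))
  dimnames(B) <- list(colnames(X), colnames(Y))
  B
}

.ridgeRegress <- function(X, Y, ridge) {
  XtX <- crossprod(X) + diag(ridge, ncol(X))
  solve(XtX, crossprod(X, Y))
}

#' Fit the unified graph-regression model
#'
#' Solves the five-term objective item by item, exactly in the printed
#' order of the method: (1) truncated SVD of the association matrix A into
#' the lncRNA/disease associating matrices A_r, A_d; (2, 3) symmetric
#' embeddings of the similarity matrices S_r, S_d into the latent feature
#' matrices F_r, F_d; (4, 5) uncentered PLS regressions A_r ~ F_r B_r and
#' A_d ~ F_d B_d. The bi-regression matrix Theta = B_r B_d^T then drives
#' all four task predictors.
#'
#' @param A \linkS4class{LdaMatrix} (any variant) or labelled matrix.
#' @param Sr,Sd lncRNA / disease \linkS4class{SimilarityMatrix}; ids must
#'   cover A's rows / columns.
#' @param ranks optional integer triple (r, p, q); defaults retain each
#'   spectrum above \code{1e-10 * max}.
#' @param nComponents PLS components; default \code{min(p, r)}.
#' @param ridge optional ridge penalty replacing PLS (default 0 = off), an
#'   escape hatch for degenerate spectra.
#' @return a \linkS4class{GrufModel}.
#' @export
grufFit <- function(A, Sr, Sd, ranks = NULL, nComponents = NULL, ridge = 0) {
  Am <- as.matrix(A)
  Srm <- if (is(Sr, "SimilarityMatrix")) Sr else SimilarityMatrix(as.matrix(Sr))
  Sdm <- if (is(Sd, "SimilarityMatrix")) Sd else SimilarityMatrix(as.matrix(Sd))
  rids <- rownames(Am) %||% paste0("r", seq_len(nrow(Am)))
  dids <- colnames(Am) %||% paste0("d", seq_len(ncol(Am)))
  rownames(Am) <- rids; colnames(Am) <- dids
  missR <- setdiff(rids, Srm@ids); missD <- setdiff(dids, Sdm@ids)
  if (length(missR) || length(missD))
    stop(sprintf("ids missing from similarity matrices: %s",
                 paste(c(missR, missD), collapse = ", ")))
  SrA <- SimilarityMatrix(as.matrix(Srm)[rids, rids, drop = FALSE], ids = rids)
  SdA <- SimilarityMatrix(as.matrix(Sdm)[dids, dids, drop = FALSE], ids = dids)

  # ranks may be a triple with NA entries meaning "default retained spectrum";
  # a single value sets the associating rank r only.
  if (!is.null(ranks)) {
    ranks <- as.integer(ranks)
    if (length(ranks) == 1) ranks <- c(ranks, NA_integer_, NA_integer_)
    if (length(ranks) != 3) stop("ranks must be (r, p, q) or a single r")
  }
  pick <- function(i) if (!is.null(ranks) && !is.na(ranks[i])) ranks[i] else NULL
  rRank <- pick(1); pRank <- pick(2); qRank <- pick(3)
  assoc <- svdEmbed(Am, rank = rRank)
  fr <- symmetricEmbed(SrA, rank = pRank)
  fd <- symmetricEmbed(SdA, rank = qRank)
  r <- ncol(assoc$L@factors); p <- ncol(fr@factors); q <- ncol(fd@factors)
  if (is.null(nComponents)) nComponents <- min(p, r)
  nComponents <- as.integer(nComponents)

  regress <- function(X, Y) {
    if (ridge > 0) return(.ridgeRegress(X, Y, ridge))
    if (sqrt(sum(X^2)) < 1e-300) return(matrix(0, ncol(X), ncol(Y)))
    plsRegress(X, Y, nComponents = min(nComponents, nrow(X), ncol(X)))
  }
  br <- regress(fr@factors, assoc$L@factors)
  bd <- regress(fd@factors, assoc$R@factors)
  new("GrufModel", ra = assoc$L, da = assoc$R, fr = fr, fd = fd,
      br = br, bd = bd, theta = br %*% t(bd),
      ranks = c(r = r, p = p, q = q), nComponents = nComponents)
}

#' Confidence scores for known lncRNAs x known diseases (T1)
#'
#' Scores = F_r Theta F_d^T over the training entities.
#'
#' @param model a fitted \linkS4class{GrufModel}.
#' @return a \linkS4class{ScoreMatrix}.
#' @export
predictT1 <- function(model) {
  stopifnot(is(model, "GrufModel"))
  ScoreMatrix(model@fr@factors %*% model@theta %*% t(model@fd@factors),
              lncrnaIds = model@fr@ids, diseaseIds = model@fd@ids)
}

#' Nystrom projection of new entities into a latent feature space
#'
#' Given similarity rows s_x of new entities to the training entities, the
#' out-of-sample latent vectors are F_x = s_x U Sigma^(-1/2) over the
#' retained spectrum (equivalently s_x F Sigma^(-1)). Projecting a training
#' entity's own similarity row reproduces its latent row exactly at full
#' rank.
#'
#' @param sx numeric vector (one new entity) or matrix with one row per new
#'   entity; columns ordered as the embedding's training entities.
#' @param embedding the training \linkS4class{Embedding} (F_r or F_d).
#' @return matrix of latent rows (new entities x latent dims).
#' @export
projectNewEntity <- function(sx, embedding) {
  stopifnot(is(embedding, "Embedding"))
  if (is.vector(sx)) sx <- matrix(sx, nrow = 1)
  sx <- as.matrix(sx)
  if (ncol(sx) != nrow(embedding@factors))
    stop(sprintf("similarity rows have %d columns but embedding has %d training entities",
                 ncol(sx), nrow(embedding@factors)))
  lam <- embedding@singularValues
  inv <- ifelse(lam > 1e-12 * max(lam, 1e-300), 1 / lam, 0)
  out <- sx %*% embedding@factors %*% diag(inv, nrow = length(inv))
  rownames(out) <- rownames(sx)
  out
}

#' Confidence scores for new lncRNAs (T2)
#'
#' Scores = F_rx Theta F_d^T where F_rx is the Nystrom projection of the
#' new lncRNAs' similarity rows to the training lncRNAs.
#'
#' @param model a fitted \linkS4class{GrufModel}.
#' @param sx similarity rows (new lncRNAs x training lncRNAs).
#' @return a \linkS4class{ScoreMatrix}.
#' @export
predictT2 <- function(model, sx) {
  stopifnot(is(model, "GrufModel"))
  frx <- projectNewEntity(sx, model@fr)
  ScoreMatrix(frx %*% model@theta %*% t(model@fd@factors),
              lncrnaIds = rownames(frx) %||% paste0("new_r", seq_len(nrow(frx))),
              diseaseIds = model@fd@ids)
}

#' Confidence scores for new diseases (T3)
#'
#' Scores = F_r Theta F_dy^T with F_dy the projection of the new diseases'
#' similarity rows to the training diseases.
#'
#' @param model a fitted \linkS4class{GrufModel}.
#' @param sy similarity rows (new diseases x training diseases).
#' @return a \linkS4class{ScoreMatrix}.
#' @export
predictT3 <- function(model, sy) {
  stopifnot(is(model, "GrufModel"))
  fdy <- projectNewEntity(sy, model@fd)
  ScoreMatrix(model@fr@factors %*% model@theta %*% t(fdy),
              lncrnaIds = model@fr@ids,
              diseaseIds = rownames(fdy) %||% paste0("new_d", seq_len(nrow(fdy))))
}

#' Confidence scores for the double cold start (T4)
#'
#' Scores = F_rx Theta F_dy^T for new lncRNAs against new diseases; one new
#' lncRNA and one new disease yield a single score.
#'
#' @param model a fitted \linkS4class{GrufModel}.
#' @param sx similarity rows of new lncRNAs to training lncRNAs.
#' @param sy similarity rows of new diseases to training diseases.
#' @return a \linkS4class{ScoreMatrix}.
#' @export
predictT4 <- function(model, sx, sy) {
  stopifnot(is(model, "GrufModel"))
  frx <- projectNewEntity(sx, model@fr)
  fdy <- projectNewEntity(sy, model@fd)
  ScoreMatrix(frx %*% model@theta %*% t(fdy),
              lncrnaIds = rownames(frx) %||% paste0("new_r", seq_len(nrow(frx))),
              diseaseIds = rownames(fdy) %||% paste0("new_d", seq_len(nrow(fdy))))
}
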
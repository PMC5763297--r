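#' @include AllClasses.R
NULL

#' Read an RNA FASTA file
#'
#' Multi-record FASTA with wrapped lines; the id is the first
#' whitespace-delimited token of the header. Residues are uppercased, the
#' DNA convention T is mapped to U, and any symbol outside {A, C, G, U} is
#' an error. Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @return a named \code{RNAStringSet}.
#' @export
readRnaFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  strs <- vapply(seq_along(raw),
                 function(i) normalizeRnaSequence(as.character(raw[[i]]),
                                                  id = ids[i]),
                 character(1))
  names(strs) <- ids
  Biostrings::RNAStringSet(strs)
}

#' Read a protein FASTA file
#'
#' @param path FASTA file; residues must be among the 20 standard one-letter
#'   amino-acid codes.
#' @return a named \code{AAStringSet}.
#' @export
readProteinFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", ")))
  strs <- toupper(as.character(raw))
  for (i in seq_along(strs)) encodeProteinSequence(strs[i], id = ids[i])
  names(strs) <- ids
  Biostrings::AAStringSet(strs)
}

#' Write sequences to FASTA
#'
#' @param seqs an \code{XStringSet} or named character vector.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

.formatFull <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  sub("^(-?\\d+)\\.0*$", "\\1", out)
}

#' Write a labelled matrix as TSV
#'
#' First row holds column labels (leading cell "id"), first column row
#' labels; numbers are rendered at full double precision so write/read
#' round-trips are exact.
#'
#' @param x a gruf matrix object or labelled base matrix.
#' @param path output file.
#' @export
writeMatrixTsv <- function(x, path) {
  M <- as.matrix(x)
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop("matrix must carry row and column labels")
  body <- apply(M, 1, function(row) paste(.formatFull(row), collapse = "\t"))
  lines <- c(paste(c("id", colnames(M)), collapse = "\t"),
             paste(rownames(M), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled TSV matrix with type checking
#'
#' The invariants of the target type are enforced on load: similarity
#' matrices must be square, symmetric (within 1e-8) with a unit diagonal
#' and entries in [0, 1]; binary matrices must contain only {0, 1}; ragged
#' rows are an error.
#'
#' @param path TSV file written by \code{\link{writeMatrixTsv}} (or
#'   equivalent: labelled rows/columns).
#' @param expect one of "matrix" (no checks), "bipartite", "similarity",
#'   "lda".
#' @param variant association variant when \code{expect = "lda"}.
#' @return the corresponding typed object.
#' @export
readMatrixTsv <- function(path, expect = c("matrix", "bipartite",
                                           "similarity", "lda"),
                          variant = "binary") {
  expect <- match.arg(expect)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, fill = FALSE,
                          blank.lines.skip = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop(sprintf("non-numeric entries in %s", path))
  switch(expect,
         matrix = M,
         bipartite = BipartiteMatrix(M),
         similarity = SimilarityMatrix(M),
         lda = LdaMatrix(M, variant = variant))
}

#' Read a MeSH hierarchy TSV (columns child, parent)
#'
#' @param path two-column TSV with a header line.
#' @return data.frame with character columns \code{child}, \code{parent}.
#' @export
readHierarchyTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", fill = FALSE)
  if (!all(c("child", "parent") %in% colnames(df)))
    stop("hierarchy TSV must have columns 'child' and 'parent'")
  df[, c("child", "parent")]
}

#' Read disease descriptor assignments
#'
#' Two-column TSV: disease id, comma-separated descriptor codes.
#'
#' @param path TSV file with a header line.
#' @return named list of descriptor code vectors.
#' @export
readDescriptorTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", fill = FALSE)
  if (ncol(df) < 2) stop("descriptor TSV needs two columns")
  out <- strsplit(df[[2]], ",", fixed = TRUE)
  out <- lapply(out, trimws)
  names(out) <- df[[1]]
  out
}

#' Serialise a fitted model to a directory
#'
#' Writes the four embeddings, the regression coefficients and the
#' bi-regression matrix as labelled full-precision TSVs plus a JSON
#' manifest (ranks, component count, spectra, package version).
#'
#' @param model a \linkS4class{GrufModel}.
#' @param dir output directory (created if needed).
#' @export
writeGrufModel <- function(model, dir) {
  stopifnot(is(model, "GrufModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- list(ra = model@ra, da = model@da, fr = model@fr, fd = model@fd)
  for (nm in names(emb)) {
    F <- emb[[nm]]@factors
    colnames(F) <- paste0("dim", seq_len(ncol(F)))
    writeMatrixTsv(F, file.path(dir, paste0(nm, ".tsv")))
  }
  named <- function(M) {
    dimnames(M) <- list(paste0("r", seq_len(nrow(M))),
                        paste0("c", seq_len(ncol(M))))
    M
  }
  writeMatrixTsv(named(model@br), file.path(dir, "br.tsv"))
  writeMatrixTsv(named(model@bd), file.path(dir, "bd.tsv"))
  writeMatrixTsv(named(model@theta), file.path(dir, "theta.tsv"))
  manifest <- list(ranks = as.list(model@ranks),
                   nComponents = model@nComponents,
                   spectra = lapply(emb, function(e) e@singularValues),
                   package = "gruf",
                   version = as.character(utils::packageVersion("gruf")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a serialised model
#'
#' @param dir directory written by \code{\link{writeGrufModel}}.
#' @return a \linkS4class{GrufModel}.
#' @export
readGrufModel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  emb <- lapply(c(ra = "ra", da = "da", fr = "fr", fd = "fd"), function(nm) {
    F <- readMatrixTsv(file.path(dir, paste0(nm, ".tsv")))
    Embedding(rownames(F), unname(F), manifest$spectra[[nm]])
  })
  br <- unname(readMatrixTsv(file.path(dir, "br.tsv")))
  bd <- unname(readMatrixTsv(file.path(dir, "bd.tsv")))
  new("GrufModel", ra = emb$ra, da = emb$da, fr = emb$fr, fd = emb$fd,
      br = br, bd = bd, theta = br %*% t(bd),
      ranks = stats::setNames(as.integer(unlist(manifest$ranks)),
                              c("r", "p", "q")),
      nComponents = as.integer(manifest$nComponents))
}
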
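#' @include AllClasses.R sequence-features.R evaluation.R
NULL

PROTEIN_ALPHABET <- unlist(AA_GROUPS, use.names = FALSE)

# Every artifact draws from its own derived seed so adding a generator stage
# never perturbs the others. Offsets stay small; seeds are kept inside the
# 32-bit integer range.
.subSeed <- function(seed, offset) as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)

#' Generate sequences with planted family structure
#'
#' Sequences are drawn symbol-wise from family-specific composition
#' profiles (sparse Dirichlet draws), so sequences of the same family are
#' compositionally closer — and hence more similar under the
#' 1/(1 + dist) k-mer similarity — than sequences of different families, in
#' expectation.
#'
#' @param count number of sequences (0 gives an empty set).
#' @param lengthRange integer pair (min, max) of sequence lengths; the
#'   default 200-400 nt clears the 35-segment 4-mer minimum of 140.
#' @param alphabet symbol set: the RNA alphabet (default) or the 20
#'   amino-acid codes.
#' @param nFamilies number of composition families.
#' @param seed integer seed; output is deterministic given the seed.
#' @param prefix id prefix.
#' @param minLength lower bound enforced on \code{lengthRange}; default 140
#'   (= 35 * 4), the segmented 4-mer featurisation minimum for RNA. Set
#'   lower for sequences not destined for segmentation.
#' @return a Biostrings \code{RNAStringSet}, \code{AAStringSet} or
#'   \code{BStringSet} (by alphabet), with family stored in the metadata.
#' @export
generateSequences <- function(count, lengthRange = c(200L, 400L),
                              alphabet = RNA_ALPHABET, nFamilies = 2,
                              seed = 1L, prefix = "seq",
                              minLength = if (identical(alphabet, RNA_ALPHABET)) 140L else 3L) {
  if (min(lengthRange) < minLength)
    stop(sprintf("sequence lengths below the featurisation minimum of %d",
                 minLength))
  fams <- rep(seq_len(max(nFamilies, 1)), length.out = count)
  strs <- .withSeed(.subSeed(seed, 11L), {
    profiles <- lapply(seq_len(max(nFamilies, 1)), function(f) {
      w <- stats::rgamma(length(alphabet), shape = 0.5)
      w / sum(w)
    })
    lens <- seq.int(lengthRange[1], lengthRange[2])
    vapply(seq_len(count), function(i) {
      L <- lens[sample.int(length(lens), 1)]
      paste(sample(alphabet, L, replace = TRUE, prob = profiles[[fams[i]]]),
            collapse = "")
    }, character(1))
  })
  names(strs) <- paste0(prefix, seq_len(count), recycle0 = TRUE)
  out <- if (identical(alphabet, RNA_ALPHABET))
    Biostrings::RNAStringSet(strs)
  else if (setequal(alphabet, PROTEIN_ALPHABET))
    Biostrings::AAStringSet(strs)
  else Biostrings::BStringSet(strs)
  S4Vectors::metadata(out) <- list(family = fams)
  out
}

#' Generate a random MeSH-like descriptor forest
#'
#' Builds rooted descriptor trees with dot-separated tree-number codes and
#' occasional extra parent edges (always to the shallower level, so the
#' result stays acyclic), then assigns each disease 1-2 descriptors.
#'
#' @param nDiseases number of diseases to assign.
#' @param depth tree depth below the roots (>= 1).
#' @param branching children per internal node.
#' @param seed integer seed.
#' @param nRoots number of root descriptors.
#' @param multiParentProb probability that a non-root node gains a second
#'   parent from the level above.
#' @return list with \code{hierarchy} (data.frame child/parent),
#'   \code{descriptors} (named list, disease id -> descriptor codes) and
#'   \code{diseaseIds}.
#' @export
generateMeshForest <- function(nDiseases, depth = 3, branching = 2, seed = 1L,
                               nRoots = 2, multiParentProb = 0.1) {
  if (depth < 1) stop("depth must be >= 1")
  .withSeed(.subSeed(seed, 23L), {
    levels <- list(paste0("C", sprintf("%02d", seq_len(nRoots))))
    edges <- data.frame(child = character(), parent = character())
    for (d in seq_len(depth)) {
      prev <- levels[[d]]
      kids <- character()
      for (p in prev) {
        ch <- paste0(p, ".", seq_len(branching))
        kids <- c(kids, ch)
        edges <- rbind(edges, data.frame(child = ch, parent = p))
      }
      # occasional second parent one level up (keeps the graph acyclic)
      if (length(prev) > 1) for (ch in kids) {
        if (stats::runif(1) < multiParentProb) {
          extra <- sample(setdiff(prev, sub("\\.[^.]+$", "", ch)), 1)
          edges <- rbind(edges, data.frame(child = ch, parent = extra))
        }
      }
      levels[[d + 1]] <- kids
    }
    nodes <- unlist(levels)
    diseaseIds <- paste0("disease", seq_len(nDiseases))
    descriptors <- lapply(seq_len(nDiseases), function(i)
      sample(nodes, sample(1:2, 1)))
    names(descriptors) <- diseaseIds
    list(hierarchy = edges, descriptors = descriptors,
         diseaseIds = diseaseIds)
  })
}

#' Generate a planted-structure benchmark dataset
#'
#' Emulates the statistical premise the graph-regression model exploits —
#' similar diseases associate with similar lncRNAs. Latent vectors are drawn
#' for lncRNAs, genes and diseases; bipartite lncRNA-protein and
#' gene-disease interactions arise by thresholding the bilinear scores at
#' the requested density; similarity matrices are 1/(1 + dist) kernels on
#' the latent vectors after adding isotropic Gaussian noise of sd
#' \code{noiseSd} (0 = fully informative side information, large = signal
#' destroyed); the three association variants are built through the
#' association-builder operations, so all of their mutual identities hold by
#' construction. Planted factors are retained for recovery tests.
#'
#' @param m,g,n counts of lncRNAs, genes/proteins, diseases.
#' @param latentDim planted latent dimension (<= min(m, n)).
#' @param noiseSd sd of the noise added to latent vectors before computing
#'   similarities (the planted signal has unit sd per coordinate).
#' @param interactionDensity fraction of bipartite entries set to 1.
#' @param seqLengthRange lncRNA sequence length range.
#' @param seed integer seed; all draws derive sub-seeds from it.
#' @return list with elements \code{rnaSequences}, \code{proteinSequences},
#'   \code{Arp}, \code{Agd} (\linkS4class{BipartiteMatrix}), \code{Sr},
#'   \code{Sd}, \code{Sp} (\linkS4class{SimilarityMatrix}), \code{lda}
#'   (list of binary/discrete/continued \linkS4class{LdaMatrix}) and
#'   \code{truth} (planted latent factors).
#' @export
generatePlantedDataset <- function(m = 60, g = 40, n = 80, latentDim = 5,
                                   noiseSd = 0, interactionDensity = 0.02,
                                   seqLengthRange = c(200L, 400L),
                                   seed = 1L) {
  if (latentDim > min(m, n)) stop("latentDim must be <= min(m, n)")
  if (interactionDensity <= 0 || interactionDensity >= 1)
    stop("interactionDensity must lie in (0, 1)")
  rIds <- paste0("lnc", seq_len(m))
  gIds <- paste0("gene", seq_len(g))
  dIds <- paste0("dis", seq_len(n))

  Hr <- .withSeed(.subSeed(seed, 101L),
                  matrix(stats::rnorm(m * latentDim), m, latentDim))
  Hg <- .withSeed(.subSeed(seed, 102L),
                  matrix(stats::rnorm(g * latentDim), g, latentDim))
  Hd <- .withSeed(.subSeed(seed, 103L),
                  matrix(stats::rnorm(n * latentDim), n, latentDim))
  rownames(Hr) <- rIds; rownames(Hg) <- gIds; rownames(Hd) <- dIds

  threshold <- function(scores, density) {
    if (max(scores) == min(scores))
      stop("interaction density unreachable: constant bilinear scores")
    tau <- stats::quantile(scores, 1 - density, names = FALSE)
    (scores > tau) * 1
  }
  Arp <- BipartiteMatrix(threshold(Hr %*% t(Hg), interactionDensity),
                         rowIds = rIds, colIds = gIds, binary = TRUE)
  Agd <- BipartiteMatrix(threshold(Hg %*% t(Hd), interactionDensity),
                         rowIds = gIds, colIds = dIds, binary = TRUE)

  noisy <- function(H, off) {
    if (noiseSd == 0) return(H)
    H + .withSeed(.subSeed(seed, off),
                  matrix(stats::rnorm(length(H), sd = noiseSd), nrow(H)))
  }
  Sr <- similarityFromFeatures(noisy(Hr, 201L), ids = rIds)
  Sd <- similarityFromFeatures(noisy(Hd, 202L), ids = dIds)
  Sp <- similarityFromFeatures(Hg, ids = gIds)

  lda <- list(binary = buildBinary(Arp, Agd),
              discrete = buildDiscrete(Arp, Agd),
              continued = buildContinued(Arp, Sp, Agd))

  rnaSequences <- generateSequences(m, lengthRange = seqLengthRange,
                                    alphabet = RNA_ALPHABET,
                                    nFamilies = max(2, latentDim),
                                    seed = .subSeed(seed, 301L),
                                    prefix = "lnc")
  proteinSequences <- generateSequences(g, lengthRange = c(50L, 150L),
                                        alphabet = PROTEIN_ALPHABET,
                                        nFamilies = max(2, latentDim),
                                        seed = .subSeed(seed, 302L),
                                        prefix = "gene", minLength = 3L)

  list(rnaSequences = rnaSequences, proteinSequences = proteinSequences,
       Arp = Arp, Agd = Agd, Sr = Sr, Sd = Sd, Sp = Sp, lda = lda,
       truth = list(Hr = Hr, Hg = Hg, Hd = Hd),
       config = list(m = m, g = g, n = n, latentDim = latentDim,
                     noiseSd = noiseSd,
                     interactionDensity = interactionDensity,
                     seqLengthRange = seqLengthRange, seed = seed))
}
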
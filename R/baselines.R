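#' Raw k-mer frequency features of a sequence
#'
#' Sliding-window k-mer counts over the fixed lexicographic ordering of all
#' 4^k possible k-mers (A < C < G < U), divided by the window count so the
#' vector sums to one.
#'
#' @param seq RNA string of length at least k.
#' @param k k-mer length (default 3).
#' @return Named numeric vector of length 4^k summing to 1.
#' @export
kmerFrequencyFeatures <- function(seq, k = 3L) {
  if (nchar(seq) < k)
    inputError("sequence shorter than k = ", k)
  alphabet <- c("A", "C", "G", "U")
  universe <- sort(apply(do.call(expand.grid, rep(list(alphabet), k)), 1,
                         paste, collapse = ""))
  toks <- tokenizeKmers(seq, k)
  counts <- table(factor(toks, levels = universe))
  setNames(as.numeric(counts) / length(toks), universe)
}

#' PCA dimensionality reduction
#'
#' Mean-centred projection onto the leading principal axes. When the feature
#' dimension exceeds the sample count the Gram-matrix route is used, which is
#' algebraically equivalent and much cheaper for wide matrices.
#'
#' @param X Numeric matrix, samples x features.
#' @param dim Target dimension (default 64; must satisfy
#'   \code{dim <= min(nrow(X) - 1, ncol(X))}).
#' @return List with \code{projected} (samples x dim), \code{components}
#'   (dim x features, orthonormal rows), \code{variance} (non-increasing
#'   explained variances) and \code{center}.
#' @export
pcaReduce <- function(X, dim = 64L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (dim > min(n - 1L, p))
    inputError("dim = ", dim, " exceeds min(samples - 1, features) = ",
               min(n - 1L, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  if (p <= n) {
    sv <- svd(Xc, nu = 0, nv = dim)
    comp <- t(sv$v)
    varAll <- sv$d^2 / (n - 1)
  } else {
    G <- tcrossprod(Xc)
    eig <- eigen(G, symmetric = TRUE)
    d <- sqrt(pmax(eig$values[seq_len(dim)], 0))
    keep <- d > 1e-12
    V <- crossprod(Xc, eig$vectors[, seq_len(dim), drop = FALSE])
    V <- sweep(V, 2, ifelse(keep, d, 1), "/")
    comp <- t(V)
    varAll <- pmax(eig$values, 0) / (n - 1)
  }
  list(projected = Xc %*% t(comp), components = comp,
       variance = varAll[seq_len(dim)], center = mu)
}

#' Run a feature-path ablation of the association pipeline
#'
#' Identical cross-validation protocol with only the feature path swapped:
#' "full" is the main pipeline (Skip-Gram + CAE attribute stream fused with
#' PV-DM behaviour streams), "attribute_only" and "behavior_only" drop one
#' stream, "pca" replaces the CAE dimensionality reduction with PCA, and
#' "kmer" replaces the learned embeddings with raw k-mer frequency vectors.
#'
#' @param variant One of "full", "attribute_only", "behavior_only", "pca",
#'   "kmer".
#' @param ds An \linkS4class{AssociationDataset}.
#' @param seed Global run seed.
#' @param config A \code{\link{pipelineConfig}}.
#' @param k Number of folds (default 5).
#' @return A \linkS4class{FoldReport}.
#' @export
runAblation <- function(variant, ds, seed = 1L, config = pipelineConfig(),
                        k = 5L) {
  crossValidate(ds, config = config, k = k, seed = seed, variant = variant)
}
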
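#' PV-DM training configuration
#'
#' @param dim Paragraph/word vector size (default 64).
#' @param k Context half-width (default 1; partner documents are short, and a
#'   narrow window keeps enough predicted positions per document).
#' @param negatives Negative samples per centre word (default 5).
#' @param epochs Training epochs (default 300; documents are a handful of
#'   tokens, so many passes are needed before paragraph vectors separate).
#' @param learningRate Initial learning rate, linearly decayed (default 0.05).
#' @param seed Integer seed.
#' @return A list of class \code{PVDMConfig}.
#' @export
pvdmConfig <- function(dim = 64L, k = 1L, negatives = 5L, epochs = 300L,
                       learningRate = 0.05, seed = 1L) {
  stopifnot(dim >= 1L, k >= 1L)
  structure(list(dim = as.integer(dim), k = as.integer(k),
                 negatives = as.integer(negatives), epochs = as.integer(epochs),
                 learningRate = learningRate, seed = as.integer(seed)),
            class = "PVDMConfig")
}

#' Sentinel token for isolated nodes
#' @export
UNK_TOKEN <- "UNK"

#' Build per-node behaviour documents from the association network
#'
#' Every node (both sides) gets one document whose tokens are its partner ids
#' in first-appearance order of the edge list; isolated nodes get the single
#' sentinel token \code{UNK}. Restricting \code{edges} to a training subset
#' keeps held-out pairs out of the behaviour representation.
#'
#' @param ds An \linkS4class{AssociationDataset}.
#' @param edges Optional two-column data.frame (\code{circ}, \code{mir})
#'   subset of the positives to build from (defaults to all positives).
#' @return Named list of documents; each is a list with \code{nodeId} and
#'   \code{tokens}.
#' @export
buildDocuments <- function(ds, edges = NULL) {
  stopifnot(is(ds, "AssociationDataset"))
  edges <- edges %||% ds@positives
  nodes <- c(ds@circIds, ds@mirIds)
  partners <- setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    cId <- edges$circ[r]
    mId <- edges$mir[r]
    partners[[cId]] <- c(partners[[cId]], mId)
    partners[[mId]] <- c(partners[[mId]], cId)
  }
  docs <- lapply(nodes, function(id) {
    toks <- unique(partners[[id]]) %||% character(0)
    if (!length(toks)) toks <- UNK_TOKEN
    list(nodeId = id, tokens = toks)
  })
  setNames(docs, nodes)
}

#' Exact PV-DM log-likelihood of one document
#'
#' Mean (per token, i.e. divided by document length T) log-probability of each
#' centre word given the average of its 2k context word vectors and the
#' paragraph vector, under the full-vocabulary softmax. Only centres with a
#' complete window on both sides are predicted; documents shorter than 2k+1
#' contribute an empty sum (returned as 0 with a warning).
#'
#' @param doc A document from \code{\link{buildDocuments}}.
#' @param cfg A \code{\link{pvdmConfig}}.
#' @param params List with \code{paragraph} (the document's vector),
#'   \code{wordVectors} and \code{outputVectors}
#'   (\linkS4class{EmbeddingMatrix} objects over the vocabulary).
#' @return Mean log-probability (scalar).
#' @export
pvdmObjective <- function(doc, cfg, params) {
  wv <- params$wordVectors
  ov <- params$outputVectors
  stopifnot(is(wv, "EmbeddingMatrix"), is(ov, "EmbeddingMatrix"))
  idx <- match(doc$tokens, wv@keys)
  if (anyNA(idx))
    inputError("out-of-vocabulary token: ", doc$tokens[which(is.na(idx))[1]])
  T <- length(idx)
  k <- cfg$k
  if (T < 2 * k + 1) {
    warning("document of length ", T, " has no centre with a full +/-", k,
            " context; objective over an empty sum is 0")
    return(0)
  }
  W <- wv@vectors
  O <- ov@vectors
  total <- 0
  for (t in (k + 1):(T - k)) {
    ctxIdx <- idx[setdiff((t - k):(t + k), t)]
    ctx <- (params$paragraph + colSums(W[ctxIdx, , drop = FALSE])) /
      (2 * k + 1)
    s <- drop(O %*% ctx)
    logZ <- max(s) + log(sum(exp(s - max(s))))
    total <- total + s[idx[t]] - logZ
  }
  unname(total / T)
}

#' Train PV-DM paragraph vectors over node documents
#'
#' One \code{dim}-length behaviour vector per node (document). The vocabulary
#' is the node universe plus the \code{UNK} sentinel. Training is
#' negative-sampling SGD, single-threaded, reproducible for a given seed.
#'
#' @param docs Documents from \code{\link{buildDocuments}}.
#' @param cfg A \code{\link{pvdmConfig}}.
#' @return An \linkS4class{EmbeddingMatrix} of paragraph vectors keyed by node
#'   id; word vectors and output vectors are in \code{metadata}.
#' @export
trainPVDM <- function(docs, cfg = pvdmConfig()) {
  if (!length(docs)) inputError("empty document list")
  nodeIds <- vapply(docs, `[[`, "", "nodeId")
  vocab <- c(unique(nodeIds), UNK_TOKEN)
  enc <- lapply(docs, function(d) {
    idx <- match(d$tokens, vocab)
    if (anyNA(idx))
      inputError("document token outside the node universe: ",
                 d$tokens[which(is.na(idx))[1]])
    idx - 1L
  })
  fit <- pvdm_train_cpp(enc, length(vocab), cfg$dim, cfg$k, cfg$negatives,
                        cfg$epochs, cfg$learningRate,
                        cfg$learningRate * 1e-3, cfg$seed)
  embeddingMatrix(nodeIds, fit$paragraph,
                  metadata = list(
                    wordVectors = embeddingMatrix(vocab, fit$word),
                    outputVectors = embeddingMatrix(vocab, fit$output),
                    config = cfg))
}

#' Cosine similarity between two vectors
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in [-1, 1].
#' @export
cosineSimilarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
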
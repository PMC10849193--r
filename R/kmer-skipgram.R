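#' Tokenize an RNA sequence into overlapping k-mers
#'
#' Sliding window of width k, stride 1, yielding \code{len - k + 1} tokens.
#' Sequences shorter than k give an empty token list with a warning.
#'
#' @param seq RNA string over \{A, C, G, U\}.
#' @param k k-mer length (default 3).
#' @return Character vector of k-mer tokens.
#' @examples
#' tokenizeKmers("ACGUA", 3) # "ACG" "CGU" "GUA"
#' @export
tokenizeKmers <- function(seq, k = 3L) {
  stopifnot(k >= 1L)
  seq <- as.character(seq)
  if (grepl("[^ACGU]", seq))
    inputError("non-A/C/G/U character in sequence: '",
               sub(".*?([^ACGU]).*", "\\1", seq), "'")
  n <- nchar(seq)
  if (n < k) {
    warning("sequence of length ", n, " shorter than k = ", k,
            "; no tokens produced")
    return(character(0))
  }
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' k-mer corpus over a set of sequences
#'
#' @slot sentences List of token vectors, one per sequence (named by id).
#' @slot k k-mer length.
#' @slot vocab Ordered unique tokens present in the corpus.
#' @export
setClass("KmerCorpus",
  slots = c(sentences = "list", k = "integer", vocab = "character")
)

setValidity("KmerCorpus", function(object) {
  toks <- unique(unlist(object@sentences, use.names = FALSE))
  if (!setequal(toks %||% character(0), object@vocab))
    "vocab must cover exactly the tokens present"
  else if (length(toks) && any(nchar(toks) != object@k))
    "token length differs from k"
  else TRUE
})

setMethod("show", "KmerCorpus", function(object) {
  cat("KmerCorpus:", length(object@sentences), "sequences, k =", object@k,
      ", vocabulary", length(object@vocab), "\n")
})

#' Build a k-mer corpus from sequences
#'
#' @param seqs Named list/vector of RNA strings.
#' @param k k-mer length (default 3, a 64-token vocabulary).
#' @return A \linkS4class{KmerCorpus}.
#' @export
kmerCorpus <- function(seqs, k = 3L) {
  sentences <- lapply(seqs, tokenizeKmers, k = k)
  vocab <- unique(unlist(sentences, use.names = FALSE)) %||% character(0)
  new("KmerCorpus", sentences = sentences, k = as.integer(k), vocab = vocab)
}

#' Skip-Gram training configuration
#'
#' @param dim Embedding size (default 64).
#' @param window Context half-width omega (default 5).
#' @param negatives Negative samples per positive pair (default 5; only used
#'   by the negative-sampling trainer).
#' @param epochs Training epochs (default 10).
#' @param learningRate Initial learning rate, linearly decayed (default 0.025).
#' @param minCount Minimum token count to keep (default 1).
#' @param seed Integer seed.
#' @param method "negative" (negative-sampling SGD, the fast trainer) or
#'   "softmax" (full-batch exact-softmax gradient ascent for small vocabularies).
#' @return A list of class \code{SkipGramConfig}.
#' @export
skipGramConfig <- function(dim = 64L, window = 5L, negatives = 5L,
                           epochs = 10L, learningRate = 0.025, minCount = 1L,
                           seed = 1L, method = c("negative", "softmax")) {
  stopifnot(dim >= 1L, window >= 1L, negatives >= 0L, epochs >= 0L)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negatives = as.integer(negatives), epochs = as.integer(epochs),
                 learningRate = learningRate, minCount = as.integer(minCount),
                 seed = as.integer(seed), method = match.arg(method)),
            class = "SkipGramConfig")
}

# enumerate (center, context) co-occurrence counts within the window
sgPairCounts <- function(sentences, vocab, window) {
  V <- length(vocab)
  C <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (sen in sentences) {
    idx <- match(sen, vocab)
    if (anyNA(idx)) inputError("out-of-vocabulary token in sentence")
    L <- length(idx)
    for (t in seq_len(L)) {
      lo <- max(1L, t - window)
      hi <- min(L, t + window)
      for (j in lo:hi) {
        if (j == t) next
        C[idx[t], idx[j]] <- C[idx[t], idx[j]] + 1
      }
    }
  }
  C
}

#' Exact Skip-Gram context log-likelihood of one sentence
#'
#' The mean (per token) log-probability of every context token within the
#' window of every centre token, under the full-vocabulary softmax
#' \code{Pr(context | centre) = softmax(embOut %*% u_centre)}.
#'
#' @param sentence Character vector of tokens.
#' @param window Context half-width.
#' @param embIn \linkS4class{EmbeddingMatrix} of input (centre) vectors.
#' @param embOut \linkS4class{EmbeddingMatrix} of output (context) vectors,
#'   with the same keys.
#' @return Mean log-probability (scalar; 0 for a single-token sentence).
#' @export
skipGramObjective <- function(sentence, window, embIn, embOut) {
  stopifnot(is(embIn, "EmbeddingMatrix"), is(embOut, "EmbeddingMatrix"))
  if (!identical(embIn@keys, embOut@keys))
    inputError("input and output embeddings must share keys")
  idx <- match(sentence, embIn@keys)
  if (anyNA(idx))
    inputError("out-of-vocabulary token: ",
               sentence[which(is.na(idx))[1]])
  L <- length(idx)
  if (L <= 1L) return(0)
  U <- embIn@vectors
  V <- embOut@vectors
  total <- 0
  for (t in seq_len(L)) {
    s <- drop(V %*% U[idx[t], ])
    logZ <- max(s) + log(sum(exp(s - max(s))))
    lo <- max(1L, t - window)
    hi <- min(L, t + window)
    for (j in lo:hi) {
      if (j == t) next
      total <- total + s[idx[j]] - logZ
    }
  }
  unname(total / L)
}

# full-batch exact-softmax gradient ascent; tractable for small vocabularies
sgTrainSoftmax <- function(C, dim, epochs, lr, seed, trace = FALSE) {
  V <- nrow(C)
  N <- sum(C)
  withr::with_seed(seed, {
    U <- matrix(runif(V * dim, -0.5, 0.5) / dim, V, dim)
    W <- matrix(runif(V * dim, -0.5, 0.5) / dim, V, dim)
  })
  obj <- numeric(0)
  for (ep in seq_len(epochs)) {
    S <- U %*% t(W)
    mx <- apply(S, 1, max)
    logZ <- mx + log(rowSums(exp(S - mx)))
    P <- exp(S - logZ)
    if (trace) obj <- c(obj, sum(C / N * (S - logZ)))
    G <- C / N - (rowSums(C) / N) * P
    dU <- G %*% W
    dW <- t(G) %*% U
    U <- U + lr * dU
    W <- W + lr * dW
  }
  list(input = U, output = W, trace = obj)
}

#' Train Skip-Gram k-mer embeddings
#'
#' Learns one \code{dim}-length vector per vocabulary token by maximising the
#' context log-likelihood. The default trainer uses negative-sampling SGD
#' (single-threaded, bit-reproducible for a given seed); method "softmax"
#' performs full-batch exact-softmax gradient ascent and can record the exact
#' objective each epoch.
#'
#' @param corpus A \linkS4class{KmerCorpus}.
#' @param cfg A \code{\link{skipGramConfig}}.
#' @param trace Record the exact-softmax objective each epoch (softmax method
#'   only).
#' @return An \linkS4class{EmbeddingMatrix} of input vectors; the output-layer
#'   vectors are in \code{metadata$output}, an objective trace (if requested)
#'   in \code{metadata$trace}.
#' @export
trainSkipGram <- function(corpus, cfg = skipGramConfig(), trace = FALSE) {
  stopifnot(is(corpus, "KmerCorpus"))
  sentences <- corpus@sentences[lengths(corpus@sentences) > 0]
  if (!length(sentences)) inputError("empty corpus")
  counts <- table(factor(unlist(sentences, use.names = FALSE),
                         levels = corpus@vocab))
  vocab <- corpus@vocab[counts >= cfg$minCount]
  if (!length(vocab)) inputError("no token reaches minCount")
  sentences <- lapply(sentences, function(s) s[s %in% vocab])
  sentences <- sentences[lengths(sentences) > 0]

  if (cfg$method == "softmax") {
    C <- sgPairCounts(sentences, vocab, cfg$window)
    fit <- sgTrainSoftmax(C, cfg$dim, cfg$epochs, cfg$learningRate, cfg$seed,
                          trace = trace)
  } else {
    enc <- lapply(sentences, function(s) match(s, vocab) - 1L)
    fit <- sg_train_cpp(enc, length(vocab), cfg$dim, cfg$window,
                        cfg$negatives, cfg$epochs, cfg$learningRate,
                        cfg$learningRate * 1e-3, cfg$seed)
    fit$trace <- numeric(0)
  }
  embeddingMatrix(vocab, fit$input,
                  metadata = list(output = embeddingMatrix(vocab, fit$output),
                                  trace = fit$trace, config = cfg))
}

#' Pool token vectors into one sequence vector
#'
#' The unweighted arithmetic mean of the token embedding vectors.
#'
#' @param tokens Non-empty character vector of tokens.
#' @param emb An \linkS4class{EmbeddingMatrix}.
#' @param id Sequence id used in error messages.
#' @return Numeric vector of the embedding dimension.
#' @export
sequenceVector <- function(tokens, emb, id = "<sequence>") {
  stopifnot(is(emb, "EmbeddingMatrix"))
  if (!length(tokens))
    inputError("no tokens to pool for sequence '", id, "'")
  idx <- match(tokens, emb@keys)
  if (anyNA(idx))
    inputError("out-of-vocabulary token '", tokens[which(is.na(idx))[1]],
               "' in sequence '", id, "'")
  colMeans(emb@vectors[idx, , drop = FALSE])
}

#' Sequence vectors for every sequence of a dataset
#'
#' @param seqs Named list of RNA strings.
#' @param emb Trained \linkS4class{EmbeddingMatrix}.
#' @param k k-mer length used for the embedding.
#' @return Matrix with one row per sequence id.
#' @export
sequenceVectors <- function(seqs, emb, k = 3L) {
  rows <- lapply(names(seqs), function(id) {
    sequenceVector(tokenizeKmers(seqs[[id]], k), emb, id = id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(seqs)
  out
}
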
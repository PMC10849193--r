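# Shared fixtures and independent oracles, built in code at test time.

tinyDataset <- function(withSeqs = TRUE) {
  seqs <- if (withSeqs) {
    list(c1 = "ACGUACGUACGU", c2 = "GGGCACGGGCAC", c3 = "UUUAGGCAUUGA",
         m1 = "ACGUACG", m2 = "GGCACGG")
  } else NULL
  associationDataset(
    circIds = c("c1", "c2", "c3"), mirIds = c("m1", "m2"),
    positives = data.frame(circ = c("c1", "c2", "c1"),
                           mir = c("m1", "m1", "m2")),
    sequences = seqs
  )
}

writeTempFile <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# triple-loop 2-D convolution oracle (cross-correlation form)
convOracle <- function(A, B, mode = c("valid", "full")) {
  mode <- match.arg(mode)
  m1 <- nrow(A); m2 <- ncol(A); n1 <- nrow(B); n2 <- ncol(B)
  if (mode == "full") {
    P <- matrix(0, m1 + 2 * (n1 - 1), m2 + 2 * (n2 - 1))
    P[n1:(n1 + m1 - 1), n2:(n2 + m2 - 1)] <- A
    A <- P
    m1 <- nrow(A); m2 <- ncol(A)
  }
  out <- matrix(0, m1 - n1 + 1, m2 - n2 + 1)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    s <- 0
    for (p in seq_len(n1)) for (q in seq_len(n2))
      s <- s + A[i + p - 1, j + q - 1] * B[p, q]
    out[i, j] <- s
  }
  out
}

# exhaustive concordant/tied pair-counting AUC oracle
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# step-sum average-precision oracle over descending unique scores
aprOracle <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  nPos <- sum(y == 1)
  prevRecall <- 0; ap <- 0
  for (thr in unique(s)) {
    keep <- s >= thr
    prec <- sum(y[keep]) / sum(keep)
    rec <- sum(y[keep]) / nPos
    ap <- ap + (rec - prevRecall) * prec
    prevRecall <- rec
  }
  ap
}

# brute-force enumeration of in-window (centre, context) pairs
windowPairCount <- function(L, window) {
  count <- 0
  for (t in seq_len(L)) for (j in seq_len(L)) {
    if (j == t) next
    if (abs(j - t) <= window) count <- count + 1
  }
  count
}

zeroEmbedding <- function(keys, dim = 4) {
  embeddingMatrix(keys, matrix(0, length(keys), dim))
}

# central finite-difference gradient check; returns max relative error
caeFdCheck <- function(x, model, eps = 1e-5) {
  g <- caeGradients(x, model)
  Efun <- function(m) caeMSE(x, caeDecode(caeEncode(x, m), m))
  maxRel <- 0
  upd <- function(fd, an) {
    denom <- max(abs(fd), abs(an), 1e-8)
    max(maxRel, abs(fd - an) / denom)
  }
  for (k in seq_along(model@W)) {
    for (i in seq_len(nrow(model@W[[k]]))) for (j in seq_len(ncol(model@W[[k]]))) {
      m1 <- model; m1@W[[k]][i, j] <- m1@W[[k]][i, j] + eps
      m2 <- model; m2@W[[k]][i, j] <- m2@W[[k]][i, j] - eps
      maxRel <- upd((Efun(m1) - Efun(m2)) / (2 * eps), g$dW[[k]][i, j])
    }
    m1 <- model; m1@b[k] <- m1@b[k] + eps
    m2 <- model; m2@b[k] <- m2@b[k] - eps
    maxRel <- upd((Efun(m1) - Efun(m2)) / (2 * eps), g$db[k])
  }
  m1 <- model; m1@c <- model@c + eps
  m2 <- model; m2@c <- model@c - eps
  upd((Efun(m1) - Efun(m2)) / (2 * eps), g$dc)
}

randomCAEModel <- function(K, n, activation = "sigmoid", sd = 0.3) {
  caeModel(lapply(seq_len(K), function(k) matrix(rnorm(n * n, sd = sd), n)),
           b = rnorm(K, sd = 0.2), c = rnorm(1, sd = 0.2),
           activation = activation)
}

# two-community planted bipartite graph (within density 0.5, across 0.02)
twoBlockGraph <- function(nc = 12, nm = 12, seed = 5) {
  circ <- sprintf("c%02d", seq_len(nc))
  mir <- sprintf("m%02d", seq_len(nm))
  edges <- withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nc)) for (j in seq_len(nm)) {
      within <- (i <= nc / 2) == (j <= nm / 2)
      if (runif(1) < if (within) 0.5 else 0.02)
        rows[[length(rows) + 1]] <- data.frame(circ = circ[i], mir = mir[j])
    }
    do.call(rbind, rows)
  })
  list(ds = associationDataset(circ, mir, edges),
       block = function(id) as.integer(sub("^[cm]", "", id)) <= nc / 2)
}

# scaled-down planted benchmark configuration for property tests
smallSynthetic <- function(beta, seed, nCirc = 80L, nMir = 50L) {
  syntheticConfig(nCirc = nCirc, nMir = nMir, beta = beta, seed = seed)
}

fastPipeline <- function() {
  pipelineConfig(
    skipgram = skipGramConfig(epochs = 5L),
    cae = caeConfig(epochs = 3L),
    classifier = classifierConfig(epochs = 40L, batchSize = 128L)
  )
}
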
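#' 2-D valid convolution (cross-correlation form)
#'
#' \code{out[i,j] = sum_{p,q} A[i+p-1, j+q-1] * B[p,q]}; an m x m input and an
#' n x n kernel give an (m-n+1) x (m-n+1) output.
#'
#' @param A Input matrix (m x m).
#' @param B Kernel matrix (n x n, n <= m).
#' @return The (m-n+1) x (m-n+1) valid convolution.
#' @export
convValid <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(B) > nrow(A) || ncol(B) > ncol(A))
    inputError("valid convolution needs kernel no larger than input")
  conv_valid_cpp(A, B)
}

#' 2-D full convolution (cross-correlation form)
#'
#' Zero-padded extension of \code{\link{convValid}} so that every overlap
#' offset contributes; an m x m input and an n x n kernel give an
#' (m+n-1) x (m+n-1) output.
#'
#' @param A Input matrix (m x m).
#' @param B Kernel matrix (n x n).
#' @return The (m+n-1) x (m+n-1) full convolution.
#' @export
convFull <- function(A, B) {
  conv_full_cpp(as.matrix(A), as.matrix(B))
}

flipKernel <- function(W) W[rev(seq_len(nrow(W))), rev(seq_len(ncol(W))), drop = FALSE]

caeCube <- function(model) {
  K <- length(model@W)
  n <- nrow(model@W[[1]])
  arr <- array(0, dim = c(n, ncol(model@W[[1]]), K))
  for (k in seq_len(K)) arr[, , k] <- model@W[[k]]
  arr
}

cubeToList <- function(arr) {
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
}

#' CAE training configuration
#'
#' @param K Number of latent feature maps / kernels (default 8).
#' @param kernel Kernel side length n (default 3).
#' @param learningRate SGD learning rate (default 0.01).
#' @param epochs Training epochs (default 100).
#' @param batchSize Signals per SGD update (default 1, plain SGD).
#' @param activation "sigmoid" (default) or "linear" (analytic test hook).
#' @param seed Integer seed (initialisation and shuffling).
#' @return A list of class \code{CAETrainConfig}.
#' @export
caeConfig <- function(K = 8L, kernel = 3L, learningRate = 0.01,
                      epochs = 100L, batchSize = 1L,
                      activation = c("sigmoid", "linear"), seed = 1L) {
  stopifnot(K >= 1L, kernel >= 1L)
  structure(list(K = as.integer(K), kernel = as.integer(kernel),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 activation = match.arg(activation), seed = as.integer(seed)),
            class = "CAETrainConfig")
}

#' Encode a 2-D signal into latent feature maps
#'
#' \code{h^k = sigma(convValid(x, W^k) + b^k)}, one (m-n+1) x (m-n+1) map per
#' kernel.
#'
#' @param x Square numeric matrix.
#' @param model A \linkS4class{CAEModel}.
#' @return List of K latent maps.
#' @export
caeEncode <- function(x, model) {
  x <- as.matrix(x)
  if (nrow(model@W[[1]]) > nrow(x))
    inputError("kernel larger than input signal")
  h <- cae_encode_cpp(x, caeCube(model), model@b,
                      model@activation == "linear")
  cubeToList(h)
}

#' Reconstruct a signal from latent maps
#'
#' \code{y = sigma(sum_k convFull(h^k, flip(W^k)) + c)}; the decoder weights
#' are the doubly flipped encoder kernels (tied), and the output has the input
#' shape m x m since (m-n+1) + n - 1 = m.
#'
#' @param h List of latent maps (all the same shape).
#' @param model A \linkS4class{CAEModel}.
#' @return Reconstructed m x m matrix.
#' @export
caeDecode <- function(h, model) {
  if (length(h) != length(model@W))
    inputError("number of latent maps differs from number of kernels")
  shapes <- vapply(h, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    inputError("inconsistent latent map shapes")
  arr <- array(unlist(h), dim = c(nrow(h[[1]]), ncol(h[[1]]), length(h)))
  cae_decode_cpp(arr, caeCube(model), model@c, model@activation == "linear")
}

#' Mean squared reconstruction error
#'
#' \code{E = 1/(2n) * sum_i (x_i - y_i)^2} with n the number of matrix
#' elements.
#'
#' @param x,y Same-shape numeric matrices.
#' @return Scalar error.
#' @export
caeMSE <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) inputError("shape mismatch in MSE")
  sum((x - y)^2) / (2 * length(x))
}

#' Analytic CAE gradients for one signal
#'
#' Backpropagation through encode/decode/MSE expressed as convolutions:
#' \code{dE/dW^k = convValid(x, dh^k) + convValid(dy, h^k)},
#' \code{dE/db^k = sum(dh^k)}, \code{dE/dc = sum(dy)}, where \code{dy} is the
#' reconstruction delta and \code{dh^k} the latent delta (both including the
#' activation derivative).
#'
#' @param x Square numeric matrix.
#' @param model A \linkS4class{CAEModel}.
#' @param target Reconstruction target (defaults to \code{x}; substituting a
#'   different target is a test hook for residual-linearity checks).
#' @return List with \code{dW} (list), \code{db}, \code{dc}, \code{E},
#'   \code{y} and \code{h}.
#' @export
caeGradients <- function(x, model, target = NULL) {
  res <- cae_grad_cpp(as.matrix(x), caeCube(model), model@b, model@c,
                      model@activation == "linear",
                      if (is.null(target)) NULL else as.matrix(target))
  list(dW = cubeToList(res$dW), db = as.numeric(res$db), dc = res$dc,
       E = res$E, y = res$y, h = cubeToList(res$h))
}

#' Train the convolutional autoencoder by stochastic gradient descent
#'
#' Kernels are initialised from a small uniform distribution, biases at zero;
#' each epoch visits the signals in a reshuffled order and applies plain SGD
#' updates. The per-epoch mean reconstruction error is recorded.
#'
#' @param signals List of square matrices (all the same shape).
#' @param cfg A \code{\link{caeConfig}}.
#' @return A trained \linkS4class{CAEModel}; \code{metadata$trace} holds the
#'   per-epoch mean E.
#' @export
trainCAE <- function(signals, cfg = caeConfig()) {
  if (!length(signals)) inputError("empty signal list")
  m <- nrow(signals[[1]])
  if (cfg$kernel > m) inputError("kernel larger than signals")
  n <- cfg$kernel
  model <- withr::with_seed(cfg$seed, {
    W <- lapply(seq_len(cfg$K), function(k)
      matrix(runif(n * n, -0.5, 0.5) / (n * n), n, n))
    caeModel(W, b = rep(0, cfg$K), c = 0, activation = cfg$activation)
  })
  Wc <- caeCube(model)
  b <- model@b
  cc <- model@c
  linear <- cfg$activation == "linear"
  lr <- cfg$learningRate
  trace <- numeric(cfg$epochs)
  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(signals))
      tot <- 0
      for (i in ord) {
        g <- cae_grad_cpp(signals[[i]], Wc, b, cc, linear)
        tot <- tot + g$E
        Wc <- Wc - lr * g$dW
        b <- b - lr * as.numeric(g$db)
        cc <- cc - lr * g$dc
      }
      trace[ep] <- tot / length(signals)
      if (!is.finite(trace[ep]))
        numericError("CAE training diverged (non-finite loss at epoch ", ep,
                     "); try a smaller learning rate")
    }
  })
  caeModel(cubeToList(Wc), b = b, c = cc, activation = cfg$activation,
           metadata = list(trace = trace, config = cfg))
}

#' Build the 64 x 64 pair signal from two sequence vectors
#'
#' Outer product of the circRNA and miRNA sequence vectors, min-max rescaled
#' to [0, 1] (a constant product maps to all zeros).
#'
#' @param circVec,mirVec Equal-length numeric vectors (64 by default
#'   upstream).
#' @return Square matrix \code{length(circVec) x length(mirVec)} in [0, 1].
#' @export
pairSignal <- function(circVec, mirVec) {
  if (length(circVec) != length(mirVec))
    inputError("pair signal needs equal-length vectors")
  s <- outer(circVec, mirVec)
  rng <- range(s)
  if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else s * 0
}

#' Mean-pool the latent maps of a signal into a K-vector
#'
#' @param x Square numeric matrix.
#' @param model A \linkS4class{CAEModel}.
#' @return Numeric vector of length K (one mean per latent map).
#' @export
poolLatent <- function(x, model) {
  vapply(caeEncode(x, model), mean, numeric(1))
}

#' Attribute embedding of a pair signal
#'
#' Mean-pools each latent map into a K-vector and applies the learned affine
#' projection to the target dimension. The projection is fit jointly with the
#' fusion classifier (see \code{\link{trainClassifier}}); use
#' \code{\link{attributeProjection}} to extract it, or
#' \code{\link{identityProjection}} as a test stub.
#'
#' @param x Square numeric matrix (the pair signal).
#' @param model A trained \linkS4class{CAEModel}.
#' @param proj List with matrix \code{W} (K x dim) and vector \code{b} (dim).
#' @return Numeric vector of length \code{ncol(proj$W)}.
#' @export
attributeEmbedding <- function(x, model, proj) {
  if (is.null(proj) || is.null(proj$W))
    inputError("untrained attribute projection; train the fusion classifier ",
               "first or supply identityProjection()")
  pooled <- poolLatent(x, model)
  if (length(pooled) != nrow(proj$W))
    inputError("projection expects K = ", nrow(proj$W), " latent maps")
  drop(pooled %*% proj$W + proj$b)
}

#' Identity projection stub (K latent maps to K dims)
#'
#' @param K Number of latent maps.
#' @return A projection list usable by \code{\link{attributeEmbedding}}.
#' @export
identityProjection <- function(K) {
  list(W = diag(K), b = rep(0, K))
}

#' Serialize a CAE model to a headered TSV block file
#'
#' Plain-text format: one block per component (kernels, biases, activation)
#' with full double precision, so a write/read round trip is exact.
#'
#' @param model A \linkS4class{CAEModel}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeCAEModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#cae\tv1", paste0("#activation\t", model@activation),
               paste0("#K\t", length(model@W)),
               paste0("#kernel\t", nrow(model@W[[1]]))), con)
  for (k in seq_along(model@W)) {
    writeLines(paste0("#W\t", k), con)
    writeLines(apply(model@W[[k]], 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")), con)
  }
  writeLines(paste0("#b\t", paste(sprintf("%.17g", model@b), collapse = "\t")),
             con)
  writeLines(paste0("#c\t", sprintf("%.17g", model@c)), con)
  invisible(path)
}

#' Read a CAE model written by \code{\link{writeCAEModel}}
#'
#' @param path File path.
#' @return A \linkS4class{CAEModel}.
#' @export
readCAEModel <- function(path) {
  if (!file.exists(path)) inputError("CAE model file not found: ", path)
  lines <- readLines(path)
  getTag <- function(tag) {
    ln <- grep(paste0("^#", tag, "\t"), lines, value = TRUE)[1]
    strsplit(sub(paste0("^#", tag, "\t"), "", ln), "\t")[[1]]
  }
  activation <- getTag("activation")
  K <- as.integer(getTag("K"))
  n <- as.integer(getTag("kernel"))
  W <- vector("list", K)
  for (k in seq_len(K)) {
    at <- which(lines == paste0("#W\t", k))
    block <- lines[(at + 1):(at + n)]
    W[[k]] <- do.call(rbind, lapply(strsplit(block, "\t"), as.numeric))
  }
  caeModel(W, b = as.numeric(getTag("b")), c = as.numeric(getTag("c")),
           activation = activation)
}

#' Serialize an embedding matrix as headered TSV
#'
#' One row per key, full double precision (lossless well beyond 12 significant
#' digits on read-back).
#'
#' @param emb An \linkS4class{EmbeddingMatrix}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeEmbedding <- function(emb, path) {
  df <- data.frame(key = emb@keys, stringsAsFactors = FALSE)
  vals <- apply(emb@vectors, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- paste0("d", seq_len(ncol(emb@vectors)))
  write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an embedding TSV written by \code{\link{writeEmbedding}}
#'
#' @param path TSV path.
#' @return An \linkS4class{EmbeddingMatrix}.
#' @export
readEmbedding <- function(path) {
  if (!file.exists(path)) inputError("embedding file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  embeddingMatrix(df$key, as.matrix(df[, -1, drop = FALSE]))
}
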
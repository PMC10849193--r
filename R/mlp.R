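# Native feed-forward classifier: optional linear projection of the pooled
# CAE stream, then fully connected ReLU layers with inverted dropout, a single
# logistic output unit, binary cross-entropy, and Adam updates. All matrix
# work goes through BLAS; training is deterministic for a given seed.

mlpInitParams <- function(nPooled, projDim, nRest, hidden, seed) {
  withr::with_seed(seed, {
    params <- list()
    inDim <- nRest
    if (nPooled > 0) {
      params$P <- matrix(rnorm(nPooled * projDim, sd = sqrt(2 / nPooled)),
                         nPooled, projDim)
      params$bp <- rep(0, projDim)
      inDim <- inDim + projDim
    }
    sizes <- c(inDim, hidden, 1L)
    params$W <- lapply(seq_len(length(sizes) - 1L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    params$b <- lapply(seq_len(length(sizes) - 1L), function(l)
      rep(0, sizes[l + 1]))
    params
  })
}

mlpForward <- function(params, pooled, rest, dropout = 0, masks = NULL) {
  X <- NULL
  if (!is.null(params$P)) {
    proj <- sweep(pooled %*% params$P, 2, params$bp, "+")
    X <- if (is.null(rest)) proj else cbind(proj, rest)
  } else {
    X <- rest
  }
  L <- length(params$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    H <- pmax(Z, 0)
    if (dropout > 0) H <- H * masks[[l]]
    A[[l + 1]] <- H
  }
  zOut <- drop(A[[L]] %*% params$W[[L]]) + params$b[[L]]
  p <- 1 / (1 + exp(-zOut))
  list(A = A, p = p, X = X)
}

mlpBackward <- function(params, fwd, pooled, rest, y, dropout, masks) {
  nb <- length(y)
  L <- length(params$W)
  A <- fwd$A
  grads <- list(W = vector("list", L), b = vector("list", L))
  delta <- matrix((fwd$p - y) / nb, ncol = 1) # dBCE/dz of logistic output
  grads$W[[L]] <- crossprod(A[[L]], delta)
  grads$b[[L]] <- colSums(delta)
  back <- delta %*% t(params$W[[L]])
  for (l in rev(seq_len(L - 1L))) {
    if (dropout > 0) back <- back * masks[[l]]
    back <- back * (A[[l + 1]] > 0)
    grads$W[[l]] <- crossprod(A[[l]], back)
    grads$b[[l]] <- colSums(back)
    back <- back %*% t(params$W[[l]])
  }
  if (!is.null(params$P)) {
    projDim <- ncol(params$P)
    dProj <- back[, seq_len(projDim), drop = FALSE]
    grads$P <- crossprod(pooled, dProj)
    grads$bp <- colSums(dProj)
  }
  grads
}

adamInit <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^state$t)
      vhat <- v / (1 - beta2^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  keys <- names(params)
  for (key in keys) {
    res <- walk(params[[key]], grads[[key]], state$m[[key]], state$v[[key]])
    params[[key]] <- res$p
    state$m[[key]] <- res$m
    state$v[[key]] <- res$v
  }
  list(params = params, state = state)
}

bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

mlpTrain <- function(pooled, rest, y, cfg) {
  n <- length(y)
  nPooled <- if (is.null(pooled)) 0L else ncol(pooled)
  nRest <- if (is.null(rest)) 0L else ncol(rest)
  params <- mlpInitParams(nPooled, cfg$projDim, nRest, cfg$hidden, cfg$seed)
  state <- adamInit(params)
  L <- length(params$W)
  lossTrace <- numeric(cfg$epochs)
  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      starts <- seq(1L, n, by = cfg$batchSize)
      epLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
        bp <- if (is.null(pooled)) NULL else pooled[idx, , drop = FALSE]
        br <- if (is.null(rest)) NULL else rest[idx, , drop = FALSE]
        masks <- NULL
        if (cfg$dropout > 0) {
          masks <- lapply(seq_len(L - 1L), function(l) {
            cols <- ncol(params$W[[l]])
            matrix(rbinom(length(idx) * cols, 1, 1 - cfg$dropout) /
                     (1 - cfg$dropout), length(idx), cols)
          })
        }
        fwd <- mlpForward(params, bp, br, cfg$dropout, masks)
        grads <- mlpBackward(params, fwd, bp, br, y[idx], cfg$dropout, masks)
        upd <- adamStep(params, grads, state, cfg$learningRate)
        params <- upd$params
        state <- upd$state
        epLoss <- epLoss + bceLoss(fwd$p, y[idx]) * length(idx)
      }
      lossTrace[ep] <- epLoss / n
      if (!is.finite(lossTrace[ep]))
        numericError("classifier training diverged at epoch ", ep)
    }
  })
  list(params = params, trace = lossTrace)
}

mlpPredict <- function(params, pooled, rest) {
  p <- mlpForward(params, pooled, rest, dropout = 0)$p
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
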
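test_that("convolution shape laws hold for all 1 <= n <= m <= 16 with oracle", {
  withr::with_seed(10, {
    for (m in 1:16) for (n in 1:m) {
      A <- matrix(runif(m * m), m)
      B <- matrix(runif(n * n), n)
      v <- convValid(A, B)
      f <- convFull(A, B)
      expect_identical(dim(v), c(m - n + 1L, m - n + 1L))
      expect_identical(dim(f), c(m + n - 1L, m + n - 1L))
      expect_equal(v, convOracle(A, B, "valid"))
      expect_equal(f, convOracle(A, B, "full"))
    }
  })
  expect_error(convValid(matrix(0, 2, 2), matrix(0, 3, 3)), "larger")
})

test_that("convolution special kernels behave as linear-algebra identities", {
  withr::with_seed(11, A <- matrix(rnorm(36), 6))
  expect_equal(convValid(A, matrix(2.5, 1, 1)), 2.5 * A)
  # delta kernel in full convolution shifts a copy of A
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  f <- convFull(A, delta)
  expect_equal(f[2:7, 2:7], A)
  # flip duality: in the cross-correlation convention the central
  # (m-n+1)^2 window of the full form equals the valid form (the doubly
  # flipped kernel of the convolution convention cancels), and applying the
  # flipped kernel in the full form realises true convolution
  withr::with_seed(12, B <- matrix(rnorm(9), 3))
  full <- convFull(A, B)
  expect_equal(full[3:6, 3:6], convValid(A, B))
  flip2 <- B[3:1, 3:1]
  expect_equal(convFull(A, flip2), convOracle(A, flip2, "full"))
})

test_that("encoding follows h = sigma(conv + b) with the valid shape law", {
  model <- caeModel(list(matrix(0, 3, 3), matrix(0, 3, 3)), b = c(0, 0))
  x <- matrix(runif(64), 8)
  h <- caeEncode(x, model)
  expect_length(h, 2)
  expect_identical(dim(h[[1]]), c(6L, 6L))
  expect_true(all(abs(unlist(h) - 0.5) < 1e-12)) # sigma(0) = 0.5

  big <- matrix(runif(64 * 64), 64)
  hBig <- caeEncode(big, caeModel(replicate(4, matrix(0.1, 3, 3),
                                            simplify = FALSE), b = rep(0, 4)))
  expect_identical(dim(hBig[[1]]), c(62L, 62L))

  # raising a map's bias raises every value of that map only
  m1 <- caeModel(list(matrix(0.2, 3, 3), matrix(0.2, 3, 3)), b = c(0, 0))
  m2 <- caeModel(list(matrix(0.2, 3, 3), matrix(0.2, 3, 3)), b = c(1, 0))
  h1 <- caeEncode(x, m1); h2 <- caeEncode(x, m2)
  expect_true(all(h2[[1]] > h1[[1]]))
  expect_equal(h2[[2]], h1[[2]])
})

test_that("decoding restores the input shape through tied flipped kernels", {
  model <- caeModel(list(matrix(0, 3, 3)), b = 0, c = 0)
  h <- list(matrix(0, 6, 6))
  y <- caeDecode(h, model)
  expect_identical(dim(y), c(8L, 8L)) # (m-n+1) + n - 1 = m
  expect_true(all(abs(y - 0.5) < 1e-12))

  # delta kernel with the linear hook: reconstruction is a shifted latent + c
  delta <- matrix(0, 3, 3); delta[1, 3] <- 1 # flip(delta) has 1 at (3, 1)
  lin <- caeModel(list(delta), b = 0, c = 0.25, activation = "linear")
  withr::with_seed(13, hm <- matrix(rnorm(16), 4))
  y2 <- caeDecode(list(hm), lin)
  expect_identical(dim(y2), c(6L, 6L))
  # conv_full(h, flip(delta)) places h shifted by the flipped delta offset
  expect_equal(y2[1:4, 3:6], hm + 0.25)

  expect_error(caeDecode(list(matrix(0, 6, 6), matrix(0, 5, 5)),
                         caeModel(list(matrix(0, 3, 3), matrix(0, 3, 3)),
                                  b = c(0, 0))),
               "inconsistent")
})

test_that("MSE is the half mean squared residual", {
  x <- matrix(runif(25), 5)
  expect_equal(caeMSE(x, x), 0)
  expect_equal(caeMSE(x, x + 2), 2) # residual 2 everywhere: (1/2n) * n * 4
  withr::with_seed(14, y <- matrix(runif(25), 5))
  expect_equal(caeMSE(x, y), sum((x - y)^2) / 50)
  expect_error(caeMSE(x, matrix(0, 4, 4)), "shape")
  expect_gte(caeMSE(x, y), 0)
})

test_that("analytic gradients vanish at a reconstruction fixed point", {
  for (act in c("sigmoid", "linear")) {
    cval <- 0.3
    target <- if (act == "sigmoid") plogis(cval) else cval
    model <- caeModel(list(matrix(0, 3, 3)), b = 0, c = cval,
                      activation = act)
    x <- matrix(target, 8, 8)
    g <- caeGradients(x, model)
    expect_equal(g$E, 0)
    expect_equal(g$dc, 0)
    expect_equal(g$db, 0)
    expect_true(all(abs(g$dW[[1]]) < 1e-14))
  }
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      K <- sample(c(1L, 2L, 4L), 1)
      m <- sample(c(6L, 8L, 10L), 1)
      act <- sample(c("sigmoid", "linear"), 1)
      x <- matrix(runif(m * m), m)
      model <- randomCAEModel(K, 3, activation = act)
    })
    expect_lt(caeFdCheck(x, model), 1e-4)
  }
})

test_that("target substitution scales the reconstruction-bias gradient linearly", {
  # linear hook: dc = sum(y - target)/N, so substituting a target that
  # doubles the residual doubles dc exactly (same forward pass)
  withr::with_seed(15, {
    x <- matrix(runif(36), 6)
    model <- randomCAEModel(2, 3, activation = "linear")
  })
  g <- caeGradients(x, model)
  target2 <- g$y - 2 * (g$y - x)
  g2 <- caeGradients(x, model, target = target2)
  expect_equal(g2$dc, 2 * g$dc, tolerance = 1e-12)
  expect_equal(g2$db, 2 * g$db, tolerance = 1e-10)
})

test_that("SGD training reduces reconstruction error and is reproducible", {
  sig <- replicate(10, matrix(0.7, 16, 16), simplify = FALSE)
  cfg <- caeConfig(K = 4, kernel = 3, epochs = 200, learningRate = 0.05,
                   seed = 1)
  fit <- trainCAE(sig, cfg)
  tr <- fit@metadata$trace
  expect_length(tr, 200)
  expect_lt(tr[length(tr)], 0.1 * tr[1])
  fit2 <- trainCAE(sig, cfg)
  expect_identical(fit@metadata$trace, fit2@metadata$trace)
  expect_error(trainCAE(list(), cfg), "empty")
})

test_that("training with an absurd learning rate reports divergence", {
  withr::with_seed(16, sig <- replicate(5, matrix(rnorm(64, sd = 5), 8),
                                        simplify = FALSE))
  expect_error(
    trainCAE(sig, caeConfig(K = 2, kernel = 3, epochs = 50,
                            learningRate = 1e8, activation = "linear",
                            seed = 2)),
    "smaller learning rate")
})

test_that("pair signals are rescaled outer products", {
  e3 <- replace(rep(0, 8), 3, 1)
  e5 <- replace(rep(0, 8), 5, 1)
  s <- pairSignal(e3, e5)
  expect_equal(s[3, 5], 1)
  expect_equal(sum(s), 1)
  withr::with_seed(17, {
    a <- rnorm(8); b <- rnorm(8)
  })
  raw <- outer(a, b)
  expect_equal(qr(raw)$rank, 1L)
  s2 <- pairSignal(a, b)
  expect_equal(s2, (raw - min(raw)) / (max(raw) - min(raw)))
  expect_true(all(s2 >= 0 & s2 <= 1))
  expect_error(pairSignal(a, b[1:4]), "equal-length")
})

test_that("attribute embeddings pool latent maps through a projection", {
  model <- caeModel(list(matrix(0, 3, 3), matrix(0, 3, 3)), b = c(0, 1))
  x <- matrix(runif(64), 8)
  pooled <- poolLatent(x, model)
  expect_equal(pooled, c(0.5, plogis(1)), tolerance = 1e-12)
  # identity projection returns the pooled means unchanged
  expect_equal(attributeEmbedding(x, model, identityProjection(2)), pooled)
  expect_error(attributeEmbedding(x, model, NULL), "untrained")
  # arbitrary K to 64 projection has length 64
  proj <- list(W = matrix(1, 2, 64), b = rep(0, 64))
  expect_length(attributeEmbedding(x, model, proj), 64)
})

test_that("CAE model serialization round trips exactly", {
  withr::with_seed(18, model <- randomCAEModel(3, 3))
  path <- tempfile(fileext = ".tsv")
  writeCAEModel(model, path)
  back <- readCAEModel(path)
  expect_equal(back@W, model@W)
  expect_equal(back@b, model@b)
  expect_equal(back@c, model@c)
  expect_identical(back@activation, model@activation)
})
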
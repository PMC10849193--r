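test_that("feature fusion is a fixed-order concatenation", {
  z <- rep(0, 64)
  expect_identical(fuseFeatures(z, z, z), rep(0, 192))
  a <- seq_len(64) / 64; b <- rev(a); m <- a * 2
  fused <- fuseFeatures(a, b, m)
  expect_length(fused, 192)
  expect_identical(fused[1:64], a)
  expect_identical(fused[65:128], b)
  expect_error(fuseFeatures(a, b[1:10], m), "matching lengths")
})

test_that("the deep classifier fits a separable toy set and is deterministic", {
  withr::with_seed(20, {
    X <- matrix(rnorm(200 * 5), 200)
    y <- as.integer(X[, 1] + X[, 2] > 0)
  })
  cfg <- classifierConfig(epochs = 100, seed = 1)
  model <- trainClassifier(X, y, cfg)
  acc <- mean((predictScores(model, X) >= 0.5) == y)
  expect_gte(acc, 0.99)
  model2 <- trainClassifier(X, y, cfg)
  expect_identical(model@fit$trace, model2@fit$trace)
  expect_error(trainClassifier(X, rep(1, 200), cfg), "single class")
})

test_that("label permutation destroys held-out discrimination", {
  withr::with_seed(21, {
    X <- matrix(rnorm(400 * 5), 400)
    y <- as.integer(X[, 1] > 0)
    yPerm <- sample(y)
  })
  train <- 1:300; test <- 301:400
  model <- trainClassifier(X[train, ], yPerm[train],
                           classifierConfig(epochs = 50, seed = 2))
  auc <- rocAUC(predictScores(model, X[test, ]), yPerm[test])
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("predictions are strictly inside (0,1) and deterministic at inference", {
  withr::with_seed(22, {
    X <- matrix(rnorm(50 * 4), 50)
    y <- rep(c(0L, 1L), 25)
  })
  model <- trainClassifier(X, y, classifierConfig(epochs = 10, seed = 3))
  p <- predictScores(model, X)
  expect_true(all(p > 0 & p < 1))
  dup <- X[c(1, 1, 2, 2), ]
  pd <- predictScores(model, dup)
  expect_identical(pd[1], pd[2])
  expect_identical(pd[3], pd[4])
})

test_that("scores match a by-hand forward pass on a fixed 2-unit network", {
  params <- list(
    W = list(matrix(c(1, -1, 0.5, 2), 2), matrix(c(0.3, -0.7), 2)),
    b = list(c(0.1, -0.2), 0.05)
  )
  model <- new("FusionModel", backend = "mlp",
               fit = list(params = params), standardize = list(),
               config = list())
  x <- c(0.4, -0.3)
  h <- pmax(c(x %*% params$W[[1]]) + params$b[[1]], 0)
  expected <- 1 / (1 + exp(-(sum(h * params$W[[2]]) + 0.05)))
  got <- predictScores(model, matrix(x, 1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("the attribute projection is trained jointly and extractable", {
  withr::with_seed(23, {
    pooled <- matrix(rnorm(120 * 4), 120)
    rest <- matrix(rnorm(120 * 3), 120)
    y <- as.integer(pooled[, 1] > 0)
  })
  cfg <- classifierConfig(hidden = c(16, 8), epochs = 60, projDim = 6,
                          seed = 4)
  model <- trainClassifier(list(pooled = pooled, rest = rest), y, cfg)
  proj <- attributeProjection(model)
  expect_identical(dim(proj$W), c(4L, 6L))
  # the projection moved away from its random initialisation
  init <- circMiRCAE:::mlpInitParams(4L, 6L, 3L, c(16L, 8L), 4L)
  expect_gt(max(abs(proj$W - init$P)), 1e-4)
  # attributeEmbedding applies it to pooled latent means
  caem <- caeModel(replicate(4, matrix(0, 3, 3), simplify = FALSE),
                   b = rep(0, 4))
  x <- matrix(runif(36), 6)
  expect_equal(attributeEmbedding(x, caem, proj),
               drop(rep(0.5, 4) %*% proj$W + proj$b))
  # a model without a pooled stream has no projection
  plain <- trainClassifier(rest, y, classifierConfig(hidden = c(8),
                                                     epochs = 5, seed = 1))
  expect_error(attributeProjection(plain), "no jointly trained")
})

test_that("candidate ranking is score-descending with lexicographic ties", {
  # h1 = relu(x1), h2 = relu(-x1), out = sigmoid(h1 - h2) = sigmoid(x1)
  params <- list(W = list(matrix(c(1, 0, -1, 0), 2, 2),
                          matrix(c(1, -1), 2, 1)),
                 b = list(c(0, 0), 0))
  model <- new("FusionModel", backend = "mlp",
               fit = list(params = params), standardize = list(),
               config = list())
  pairs <- data.frame(circ = c("c2", "c1", "c1", "c3"),
                      mir = c("m1", "m2", "m1", "m1"))
  X <- cbind(c(2, -2, 0, 0), 0) # scores 0.88, 0.12, 0.5, 0.5
  ranked <- rankCandidates(model, pairs, X)
  expect_identical(ranked$rank, 1:4)
  expect_true(all(diff(ranked$score) <= 0))
  # the two tied mid scores order lexicographically: c1/m1 before c3/m1
  expect_identical(ranked$circ, c("c2", "c1", "c3", "c1"))
  expect_identical(ranked$mir, c("m1", "m1", "m1", "m2"))
  top <- rankCandidates(model, pairs, X, topN = 3)
  expect_equal(nrow(top), 3L)
})

test_that("library classifier backends train and score through one interface", {
  withr::with_seed(24, {
    X <- matrix(rnorm(160 * 4), 160)
    y <- as.integer(X[, 1] + 0.3 * rnorm(160) > 0)
  })
  for (backend in c("logistic", "svm", "rf", "knn", "gbdt")) {
    cfg <- classifierConfig(backend = backend, seed = 5)
    model <- trainClassifier(X, y, cfg)
    p <- predictScores(model, X)
    expect_true(all(p > 0 & p < 1), info = backend)
    expect_gt(rocAUC(p, y), 0.8)
  }
})

test_that("the native checkpoint round trips and reproduces scores", {
  withr::with_seed(25, {
    pooled <- matrix(rnorm(60 * 4), 60)
    rest <- matrix(rnorm(60 * 3), 60)
    y <- rep(c(0L, 1L), 30)
  })
  model <- trainClassifier(list(pooled = pooled, rest = rest), y,
                           classifierConfig(hidden = c(8), epochs = 5,
                                            projDim = 4, seed = 6))
  path <- tempfile(fileext = ".tsv")
  writeFusionModel(model, path)
  back <- readFusionModel(path)
  feats <- list(pooled = pooled[1:5, ], rest = rest[1:5, ])
  expect_equal(predictScores(back, feats), predictScores(model, feats),
               tolerance = 1e-12)
})
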
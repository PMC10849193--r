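#' Fuse attribute and behaviour features for one pair
#'
#' Deterministic concatenation in the fixed order attribute, circRNA
#' behaviour, miRNA behaviour (no rescaling here; streams are standardized
#' upstream, on training folds only).
#'
#' @param attr Attribute vector (64-dim in the default pipeline).
#' @param bc Behaviour vector of the circRNA.
#' @param bm Behaviour vector of the miRNA.
#' @return Concatenated numeric vector of length
#'   \code{length(attr) + length(bc) + length(bm)}.
#' @export
fuseFeatures <- function(attr, bc, bm) {
  if (length(attr) != length(bc) || length(bc) != length(bm))
    inputError("attribute and behaviour vectors must have matching lengths")
  c(attr, bc, bm)
}

#' Fusion classifier configuration
#'
#' @param hidden Hidden layer sizes of the deep classifier (default
#'   \code{c(256, 128, 64)}).
#' @param dropout Dropout rate on hidden activations (default 0.5).
#' @param epochs Training epochs (default 100).
#' @param batchSize Mini-batch size (default 64).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param projDim Output dimension of the jointly trained attribute
#'   projection (default 64).
#' @param backend "mlp" (native deep network with joint attribute projection)
#'   or one of "logistic", "svm", "rf", "knn", "gbdt" (library backends on a
#'   plain feature matrix).
#' @param seed Integer seed.
#' @return A list of class \code{ClassifierConfig}.
#' @export
classifierConfig <- function(hidden = c(256L, 128L, 64L), dropout = 0.5,
                             epochs = 100L, batchSize = 64L,
                             learningRate = 1e-3, projDim = 64L,
                             backend = c("mlp", "logistic", "svm", "rf",
                                         "knn", "gbdt"),
                             seed = 1L) {
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, projDim = as.integer(projDim),
                 backend = match.arg(backend), seed = as.integer(seed)),
            class = "ClassifierConfig")
}

asFeatureParts <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    list(pooled = features$pooled, rest = features$rest)
  } else {
    list(pooled = NULL, rest = as.matrix(features))
  }
}

flattenFeatures <- function(parts) {
  if (is.null(parts$pooled)) parts$rest
  else if (is.null(parts$rest)) parts$pooled
  else cbind(parts$pooled, parts$rest)
}

requireBackend <- function(pkg, backend) {
  if (!requireNamespace(pkg, quietly = TRUE))
    inputError("backend '", backend, "' needs the ", pkg, " package")
}

#' Train the supervised association classifier
#'
#' The default backend is the native deep network: the mean-pooled CAE stream
#' (if supplied as \code{features$pooled}) passes through an affine projection
#' trained jointly with the network (the fine-tuning phase), is concatenated
#' with the remaining streams, and feeds ReLU hidden layers with dropout and a
#' single logistic output unit, minimising binary cross-entropy with Adam
#' mini-batch updates. Library backends operate on the flattened feature
#' matrix.
#'
#' @param features Either a numeric matrix, or a list with elements
#'   \code{pooled} (K-dim CAE pool stream, may be NULL) and \code{rest}
#'   (remaining columns, may be NULL).
#' @param labels 0/1 vector.
#' @param cfg A \code{\link{classifierConfig}}.
#' @return A \linkS4class{FusionModel}.
#' @export
trainClassifier <- function(features, labels, cfg = classifierConfig()) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    inputError("training labels contain a single class")
  parts <- asFeatureParts(features)
  if (cfg$backend == "mlp") {
    fit <- mlpTrain(parts$pooled, parts$rest, labels, cfg)
    return(new("FusionModel", backend = "mlp",
               fit = list(params = fit$params, trace = fit$trace),
               standardize = list(), config = unclass(cfg)))
  }
  X <- flattenFeatures(parts)
  fit <- switch(cfg$backend,
    logistic = {
      colnames(X) <- paste0("X", seq_len(ncol(X)))
      df <- data.frame(y = labels, X, check.names = FALSE)
      list(model = suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial())))
    },
    svm = {
      requireBackend("e1071", "svm")
      withr::with_seed(cfg$seed,
        list(model = e1071::svm(X, factor(labels), probability = TRUE)))
    },
    rf = {
      requireBackend("randomForest", "rf")
      withr::with_seed(cfg$seed,
        list(model = randomForest::randomForest(X, factor(labels))))
    },
    knn = {
      requireBackend("class", "knn")
      list(train = X, labels = labels, k = 5L)
    },
    gbdt = {
      requireBackend("xgboost", "gbdt")
      withr::with_seed(cfg$seed,
        list(model = xgboost::xgboost(
          X, factor(labels, levels = c(0, 1)), nrounds = 100L,
          max_depth = 4L, learning_rate = 0.1, nthread = 1L,
          verbosity = 0L)))
    },
    inputError("unknown backend: ", cfg$backend)
  )
  new("FusionModel", backend = cfg$backend, fit = fit,
      standardize = list(), config = unclass(cfg))
}

#' Predict association scores
#'
#' @param model A trained \linkS4class{FusionModel}.
#' @param features Features in the same shape used for training.
#' @return Scores strictly inside (0, 1); deterministic at inference.
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "FusionModel"))
  if (!length(model@fit)) inputError("untrained model")
  parts <- asFeatureParts(features)
  p <- switch(model@backend,
    mlp = mlpPredict(model@fit$params, parts$pooled, parts$rest),
    logistic = {
      X <- flattenFeatures(parts)
      colnames(X) <- paste0("X", seq_len(ncol(X)))
      as.numeric(predict(model@fit$model,
                         newdata = as.data.frame(X), type = "response"))
    },
    svm = {
      pr <- predict(model@fit$model, flattenFeatures(parts),
                    probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = predict(model@fit$model, flattenFeatures(parts),
                 type = "prob")[, "1"],
    knn = {
      pr <- class::knn(model@fit$train, flattenFeatures(parts),
                       factor(model@fit$labels), k = model@fit$k,
                       prob = TRUE)
      pw <- attr(pr, "prob")
      ifelse(pr == "1", pw, 1 - pw)
    },
    gbdt = predict(model@fit$model, flattenFeatures(parts)),
    inputError("unknown backend: ", model@backend)
  )
  unname(pmin(pmax(as.numeric(p), 1e-12), 1 - 1e-12))
}

#' Extract the jointly trained attribute projection
#'
#' @param model A trained \linkS4class{FusionModel} with the "mlp" backend.
#' @return List with \code{W} (K x projDim) and \code{b}, usable by
#'   \code{\link{attributeEmbedding}}.
#' @export
attributeProjection <- function(model) {
  stopifnot(is(model, "FusionModel"))
  if (model@backend != "mlp" || is.null(model@fit$params$P))
    inputError("model has no jointly trained attribute projection")
  list(W = model@fit$params$P, b = model@fit$params$bp)
}

#' Rank candidate pairs by predicted score
#'
#' @param model A trained \linkS4class{FusionModel}.
#' @param pairs Two-column data.frame (\code{circ}, \code{mir}) of candidate
#'   pairs (training positives excluded by the caller).
#' @param features Features for the candidate pairs, row-parallel.
#' @param topN Optionally keep only the first \code{topN} rows.
#' @return data.frame (circ, mir, score, rank) in descending score order,
#'   ties broken lexicographically by (circ, mir).
#' @export
rankCandidates <- function(model, pairs, features, topN = NULL) {
  scores <- predictScores(model, features)
  ord <- order(-scores, pairs$circ, pairs$mir, method = "radix")
  out <- data.frame(circ = pairs$circ[ord], mir = pairs$mir[ord],
                    score = scores[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  if (!is.null(topN)) out <- head(out, topN)
  rownames(out) <- NULL
  out
}

#' Serialize a native fusion model to a plain-text checkpoint
#'
#' Only the "mlp" backend is serialisable (library backends keep their own
#' native objects in memory).
#'
#' @param model A \linkS4class{FusionModel} with backend "mlp".
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeFusionModel <- function(model, path) {
  if (model@backend != "mlp")
    inputError("only the native mlp backend has a text checkpoint format")
  params <- model@fit$params
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#fusion\tv1", con)
  writeMat <- function(tag, M) {
    M <- as.matrix(M)
    writeLines(paste0("#", tag, "\t", nrow(M), "\t", ncol(M)), con)
    writeLines(apply(M, 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")), con)
  }
  if (!is.null(params$P)) {
    writeMat("P", params$P)
    writeMat("bp", matrix(params$bp, nrow = 1))
  }
  for (l in seq_along(params$W)) {
    writeMat(paste0("W", l), params$W[[l]])
    writeMat(paste0("b", l), matrix(params$b[[l]], nrow = 1))
  }
  invisible(path)
}

#' Read a fusion model checkpoint written by \code{\link{writeFusionModel}}
#'
#' @param path File path.
#' @param config Optional classifier configuration to attach.
#' @return A \linkS4class{FusionModel} with backend "mlp".
#' @export
readFusionModel <- function(path, config = classifierConfig()) {
  if (!file.exists(path)) inputError("fusion model file not found: ", path)
  lines <- readLines(path)
  heads <- grep("^#", lines)
  blocks <- list()
  for (hi in seq_along(heads)) {
    parts <- strsplit(lines[heads[hi]], "\t")[[1]]
    tag <- sub("^#", "", parts[1])
    if (tag == "fusion") next
    nr <- as.integer(parts[2])
    rows <- lines[(heads[hi] + 1):(heads[hi] + nr)]
    blocks[[tag]] <- do.call(rbind, lapply(strsplit(rows, "\t"), as.numeric))
  }
  params <- list()
  if (!is.null(blocks$P)) {
    params$P <- blocks$P
    params$bp <- as.numeric(blocks$bp)
  }
  wTags <- grep("^W[0-9]+$", names(blocks), value = TRUE)
  ord <- order(as.integer(sub("W", "", wTags)))
  params$W <- unname(lapply(wTags[ord], function(t) blocks[[t]]))
  params$b <- unname(lapply(sub("W", "b", wTags[ord]),
                            function(t) as.numeric(blocks[[t]])))
  new("FusionModel", backend = "mlp", fit = list(params = params),
      standardize = list(), config = unclass(config))
}
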
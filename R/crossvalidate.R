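#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the end-to-end association
#' pipeline. Stage seeds are derived deterministically from the global run
#' seed, so one seed reproduces a whole run.
#'
#' @param kmerK k-mer length for tokenization (default 3).
#' @param skipgram \code{\link{skipGramConfig}} for the sequence embeddings.
#' @param pvdm \code{\link{pvdmConfig}} for the behaviour embeddings.
#' @param cae \code{\link{caeConfig}} for the pair-signal autoencoder; the
#'   pipeline default uses 5 epochs over at most \code{caeMaxSignals} signals
#'   (unsupervised pretraining at corpus scale).
#' @param classifier \code{\link{classifierConfig}} for the fusion stage.
#' @param negativeRatio Negative:positive sampling ratio (default 1).
#' @param threshold Decision threshold for confusion metrics (default 0.5).
#' @param caeMaxSignals Cap on the number of pair signals used to fit the CAE
#'   (default 1000; pooled features are still computed for every pair).
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(kmerK = 3L,
                           skipgram = skipGramConfig(),
                           pvdm = pvdmConfig(),
                           cae = caeConfig(epochs = 5L),
                           classifier = classifierConfig(epochs = 60L,
                                                         batchSize = 128L),
                           negativeRatio = 1,
                           threshold = 0.5,
                           caeMaxSignals = 1000L) {
  structure(list(kmerK = as.integer(kmerK), skipgram = skipgram, pvdm = pvdm,
                 cae = cae, classifier = classifier,
                 negativeRatio = negativeRatio, threshold = threshold,
                 caeMaxSignals = as.integer(caeMaxSignals)),
            class = "PipelineConfig")
}

pipelineVariants <- c("full", "attribute_only", "behavior_only", "pca", "kmer")

variantNeedsSequences <- function(variant) {
  variant %in% c("full", "attribute_only", "pca", "kmer")
}

variantNeedsBehavior <- function(variant) {
  variant %in% c("full", "attribute_only", "behavior_only", "pca")
}

# label-free attribute precomputation shared across folds:
# skip-gram sequence vectors, pair signals, and either CAE pooling or PCA
precomputeAttributes <- function(ds, ps, variant, config, seed) {
  out <- list()
  seqs <- rnaSequences(ds)
  if (variant == "kmer") {
    circF <- t(vapply(circIds(ds), function(id)
      kmerFrequencyFeatures(seqs[[id]], config$kmerK),
      numeric(4^config$kmerK)))
    mirF <- t(vapply(mirIds(ds), function(id)
      kmerFrequencyFeatures(seqs[[id]], config$kmerK),
      numeric(4^config$kmerK)))
    out$rest <- cbind(circF[ps@pairs$circ, , drop = FALSE],
                      mirF[ps@pairs$mir, , drop = FALSE])
    return(out)
  }
  sgCfg <- config$skipgram
  sgCfg$seed <- stageSeed(seed, "skipgram")
  corpus <- kmerCorpus(seqs, config$kmerK)
  emb <- trainSkipGram(corpus, sgCfg)
  seqVecs <- sequenceVectors(seqs, emb, config$kmerK)
  signals <- lapply(seq_len(nrow(ps@pairs)), function(i)
    pairSignal(seqVecs[ps@pairs$circ[i], ], seqVecs[ps@pairs$mir[i], ]))
  out$embedding <- emb
  if (variant == "pca") {
    flat <- do.call(rbind, lapply(signals, as.vector))
    red <- pcaReduce(flat, dim = min(64L, nrow(flat) - 1L, ncol(flat)))
    out$rest <- red$projected
  } else {
    caeCfg <- config$cae
    caeCfg$seed <- stageSeed(seed, "cae")
    fitIdx <- seq_len(nrow(ps@pairs))
    if (length(fitIdx) > config$caeMaxSignals)
      fitIdx <- withr::with_seed(caeCfg$seed,
                                 sample(fitIdx, config$caeMaxSignals))
    out$cae <- trainCAE(signals[fitIdx], caeCfg)
    out$pooled <- cae_pool_cpp(signals, caeCube(out$cae), out$cae@b,
                               out$cae@activation == "linear")
  }
  out
}

behaviorMatrix <- function(ds, trainEdges, pvdmCfg) {
  docs <- buildDocuments(ds, trainEdges)
  trainPVDM(docs, pvdmCfg)
}

#' Cross-validate the association pipeline
#'
#' Runs the full stratified k-fold protocol: negatives are sampled once per
#' run, label-free stages (Skip-Gram on sequences, CAE/PCA pretraining on pair
#' signals) are fit once on all sequences/pairs, while the behaviour documents
#' (with held-out positive edges removed) and the classifier are refit per
#' training fold. Held-out pairs are scored and summarised as a
#' \linkS4class{FoldReport}.
#'
#' @param ds An \linkS4class{AssociationDataset}; sequences are required for
#'   every variant except "behavior_only".
#' @param config A \code{\link{pipelineConfig}}.
#' @param k Number of folds (default 5).
#' @param seed Global run seed.
#' @param variant One of "full", "attribute_only", "behavior_only", "pca",
#'   "kmer" (ablation paths; "full" is the main pipeline).
#' @param labeled Optionally a pre-built \linkS4class{LabeledPairSet} to reuse
#'   (e.g. for label-permutation nulls); defaults to sampling negatives from
#'   \code{ds}.
#' @return A \linkS4class{FoldReport}.
#' @export
crossValidate <- function(ds, config = pipelineConfig(), k = 5L, seed = 1L,
                          variant = "full", labeled = NULL) {
  stopifnot(is(ds, "AssociationDataset"))
  if (!variant %in% pipelineVariants)
    inputError("unknown variant '", variant, "'; expected one of ",
               paste(pipelineVariants, collapse = ", "))
  if (variantNeedsSequences(variant) && !length(rnaSequences(ds)))
    inputError("variant '", variant, "' needs sequences attached")
  seed <- as.integer(seed)

  ps <- labeled %||%
    sampleNegatives(ds, config$negativeRatio, stageSeed(seed, "negatives"))
  folds <- kfoldSplit(ps, k, stageSeed(seed, "folds"))
  y <- as.numeric(ps@labels)

  pre <- if (variantNeedsSequences(variant))
    precomputeAttributes(ds, ps, variant, config, seed) else list()

  metricCols <- c("Acc", "Sens", "Spec", "Prec", "MCC", "AUC", "AUPR")
  perFold <- matrix(NA_real_, k, length(metricCols),
                    dimnames = list(NULL, metricCols))
  curves <- vector("list", k)

  for (f in seq_len(k) - 1L) {
    testIdx <- which(folds@fold == f)
    trainIdx <- which(folds@fold != f)

    streamsTrain <- list()
    streamsTest <- list()
    if (!is.null(pre$pooled)) {
      st <- fitStandardizer(pre$pooled[trainIdx, , drop = FALSE])
      streamsTrain$pooled <- applyStandardizer(
        pre$pooled[trainIdx, , drop = FALSE], st)
      streamsTest$pooled <- applyStandardizer(
        pre$pooled[testIdx, , drop = FALSE], st)
    }
    restTrain <- NULL
    restTest <- NULL
    if (!is.null(pre$rest)) {
      st <- fitStandardizer(pre$rest[trainIdx, , drop = FALSE])
      restTrain <- applyStandardizer(pre$rest[trainIdx, , drop = FALSE], st)
      restTest <- applyStandardizer(pre$rest[testIdx, , drop = FALSE], st)
    }
    if (variantNeedsBehavior(variant)) {
      trainPos <- ps@pairs[intersect(trainIdx, which(ps@labels == 1L)), ]
      pvCfg <- config$pvdm
      pvCfg$seed <- stageSeed(seed, paste0("pvdm", f))
      beh <- behaviorMatrix(ds, trainPos, pvCfg)
      B <- embVectors(beh)
      bAll <- cbind(B[ps@pairs$circ, , drop = FALSE],
                    B[ps@pairs$mir, , drop = FALSE])
      st <- fitStandardizer(bAll[trainIdx, , drop = FALSE])
      bTrain <- applyStandardizer(bAll[trainIdx, , drop = FALSE], st)
      bTest <- applyStandardizer(bAll[testIdx, , drop = FALSE], st)
      restTrain <- if (is.null(restTrain)) bTrain else cbind(restTrain, bTrain)
      restTest <- if (is.null(restTest)) bTest else cbind(restTest, bTest)
    }
    streamsTrain$rest <- restTrain
    streamsTest$rest <- restTest

    clsCfg <- config$classifier
    clsCfg$seed <- stageSeed(seed, paste0("classifier", f))
    model <- trainClassifier(streamsTrain, y[trainIdx], clsCfg)
    scores <- predictScores(model, streamsTest)

    cm <- confusionMetrics(
      confusionCounts(scores, y[testIdx], config$threshold))
    perFold[f + 1L, ] <- c(cm, AUC = rocAUC(scores, y[testIdx]),
                           AUPR = prAUC(scores, y[testIdx]))
    curves[[f + 1L]] <- curvePoints(scores, y[testIdx])
  }

  foldsDf <- as.data.frame(perFold)
  new("FoldReport", folds = foldsDf, summary = aggregateFolds(foldsDf),
      k = as.integer(k), seed = seed,
      metadata = list(variant = variant, config = config, curves = curves,
                      foldAssignment = folds, labeled = ps))
}
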
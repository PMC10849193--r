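#' Bipartite circRNA-miRNA association dataset
#'
#' Container for the universe of a bipartite association study: the ordered
#' circRNA and miRNA identifiers, the experimentally supported (positive)
#' pairs, and optionally the RNA sequences (over A/C/G/U) of the nodes.
#'
#' @slot circIds Ordered unique circRNA identifiers.
#' @slot mirIds Ordered unique miRNA identifiers.
#' @slot positives A two-column \code{data.frame} (\code{circ}, \code{mir}) of
#'   known associations; no duplicates.
#' @slot sequences Named list mapping node ids to RNA strings (may be empty).
#' @export
setClass("AssociationDataset",
  slots = c(
    circIds = "character",
    mirIds = "character",
    positives = "data.frame",
    sequences = "list"
  )
)

setValidity("AssociationDataset", function(object) {
  msg <- character()
  if (anyDuplicated(object@circIds)) msg <- c(msg, "duplicated circRNA ids")
  if (anyDuplicated(object@mirIds)) msg <- c(msg, "duplicated miRNA ids")
  if (length(intersect(object@circIds, object@mirIds)) > 0)
    msg <- c(msg, "an id occurs on both sides of the bipartite graph")
  pos <- object@positives
  if (!identical(colnames(pos), c("circ", "mir"))) {
    msg <- c(msg, "positives must have columns 'circ' and 'mir'")
  } else {
    if (!all(pos$circ %in% object@circIds))
      msg <- c(msg, "positive pair references unknown circRNA id")
    if (!all(pos$mir %in% object@mirIds))
      msg <- c(msg, "positive pair references unknown miRNA id")
    if (anyDuplicated(paste(pos$circ, pos$mir, sep = "\r")))
      msg <- c(msg, "duplicated positive pairs")
  }
  if (length(object@sequences)) {
    ids <- names(object@sequences)
    if (is.null(ids) || !all(ids %in% c(object@circIds, object@mirIds)))
      msg <- c(msg, "sequence names must be known node ids")
    bad <- vapply(object@sequences, function(s) grepl("[^ACGU]", s), logical(1))
    if (any(bad))
      msg <- c(msg, paste0("sequence not over {A,C,G,U}: ",
                           paste(head(ids[bad], 3), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AssociationDataset
#'
#' @param circIds,mirIds Node identifier vectors (first-appearance order kept).
#' @param positives Two-column data.frame (\code{circ}, \code{mir}).
#' @param sequences Optional named character vector or list of RNA strings.
#' @return An \linkS4class{AssociationDataset}.
#' @examples
#' ds <- associationDataset(c("c1", "c2"), "m1",
#'   data.frame(circ = "c1", mir = "m1"))
#' circIds(ds)
#' @export
associationDataset <- function(circIds, mirIds, positives,
                               sequences = NULL) {
  positives <- data.frame(
    circ = as.character(positives[[1]]),
    mir = as.character(positives[[2]]),
    stringsAsFactors = FALSE
  )
  seqs <- if (is.null(sequences)) list() else as.list(sequences)
  new("AssociationDataset",
    circIds = as.character(circIds), mirIds = as.character(mirIds),
    positives = positives, sequences = seqs
  )
}

#' @describeIn associationDataset circRNA identifiers
#' @param x An \code{AssociationDataset}.
#' @export
setGeneric("circIds", function(x) standardGeneric("circIds"))

#' @export
setMethod("circIds", "AssociationDataset", function(x) x@circIds)

#' @describeIn associationDataset miRNA identifiers
#' @export
setGeneric("mirIds", function(x) standardGeneric("mirIds"))

#' @export
setMethod("mirIds", "AssociationDataset", function(x) x@mirIds)

#' @describeIn associationDataset the positive pair table
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))

#' @export
setMethod("positivePairs", "AssociationDataset", function(x) x@positives)

#' @describeIn associationDataset named list of RNA sequences
#' @export
setGeneric("rnaSequences", function(x) standardGeneric("rnaSequences"))

#' @export
setMethod("rnaSequences", "AssociationDataset", function(x) x@sequences)

setMethod("show", "AssociationDataset", function(object) {
  cat("AssociationDataset:", length(object@circIds), "circRNAs x",
      length(object@mirIds), "miRNAs,", nrow(object@positives),
      "positive pairs,", length(object@sequences), "sequences\n")
})

#' Labeled circRNA-miRNA pair set
#'
#' Positive pairs (label 1) plus sampled presumed-negative pairs (label 0).
#'
#' @slot pairs Two-column data.frame (\code{circ}, \code{mir}).
#' @slot labels Integer vector in \{0, 1\}, parallel to \code{pairs}.
#' @export
setClass("LabeledPairSet",
  slots = c(pairs = "data.frame", labels = "integer")
)

setValidity("LabeledPairSet", function(object) {
  msg <- character()
  if (nrow(object@pairs) != length(object@labels))
    msg <- c(msg, "pairs and labels lengths differ")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (anyDuplicated(paste(object@pairs$circ, object@pairs$mir, sep = "\r")))
    msg <- c(msg, "duplicated pairs")
  if (length(msg)) msg else TRUE
})

#' @param pairs Two-column data.frame (\code{circ}, \code{mir}).
#' @param labels Integer 0/1 labels.
#' @rdname LabeledPairSet-class
#' @export
labeledPairSet <- function(pairs, labels) {
  new("LabeledPairSet",
    pairs = data.frame(circ = as.character(pairs$circ),
                       mir = as.character(pairs$mir),
                       stringsAsFactors = FALSE),
    labels = as.integer(labels)
  )
}

#' @describeIn LabeledPairSet-class the pair table
#' @param x A \code{LabeledPairSet}.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @export
setMethod("pairTable", "LabeledPairSet", function(x) x@pairs)

#' @describeIn LabeledPairSet-class the 0/1 labels
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @export
setMethod("pairLabels", "LabeledPairSet", function(x) x@labels)

setMethod("show", "LabeledPairSet", function(object) {
  cat("LabeledPairSet:", sum(object@labels == 1L), "positives /",
      sum(object@labels == 0L), "negatives\n")
})

#' Stratified cross-validation fold assignment
#'
#' @slot fold Integer fold index in \code{0..k-1} per pair.
#' @slot k Number of folds.
#' @slot seed Seed used for the shuffle.
#' @export
setClass("FoldAssignment",
  slots = c(fold = "integer", k = "integer", seed = "integer")
)

setValidity("FoldAssignment", function(object) {
  if (any(object@fold < 0L | object@fold >= object@k))
    "fold indices must lie in 0..k-1"
  else TRUE
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment:", length(object@fold), "pairs in", object@k,
      "folds (seed", object@seed, ")\n")
})

#' Embedding matrix (tokens or nodes to real vectors)
#'
#' @slot keys Ordered identifiers (k-mer tokens or node ids).
#' @slot vectors Numeric matrix, one row per key.
#' @slot metadata List of fitting by-products (e.g. output-layer vectors,
#'   objective traces).
#' @export
setClass("EmbeddingMatrix",
  slots = c(keys = "character", vectors = "matrix", metadata = "list")
)

setValidity("EmbeddingMatrix", function(object) {
  msg <- character()
  if (nrow(object@vectors) != length(object@keys))
    msg <- c(msg, "one row per key required")
  if (anyDuplicated(object@keys)) msg <- c(msg, "duplicated keys")
  if (length(object@vectors) && !all(is.finite(object@vectors)))
    msg <- c(msg, "non-finite embedding entries")
  if (length(msg)) msg else TRUE
})

#' @param keys Identifiers.
#' @param vectors Numeric matrix (rows parallel to \code{keys}).
#' @param metadata Optional list.
#' @rdname EmbeddingMatrix-class
#' @export
embeddingMatrix <- function(keys, vectors, metadata = list()) {
  vectors <- as.matrix(vectors)
  rownames(vectors) <- keys
  new("EmbeddingMatrix", keys = as.character(keys), vectors = vectors,
      metadata = metadata)
}

#' @describeIn EmbeddingMatrix-class the keys
#' @param x An \code{EmbeddingMatrix}.
#' @export
setGeneric("embKeys", function(x) standardGeneric("embKeys"))

#' @export
setMethod("embKeys", "EmbeddingMatrix", function(x) x@keys)

#' @describeIn EmbeddingMatrix-class the vectors (rows named by key)
#' @export
setGeneric("embVectors", function(x) standardGeneric("embVectors"))

#' @export
setMethod("embVectors", "EmbeddingMatrix", function(x) x@vectors)

setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix:", length(object@keys), "keys x",
      ncol(object@vectors), "dims\n")
})

#' Tied-weight convolutional autoencoder parameters
#'
#' K shared convolution kernels with one bias per latent map and a single
#' reconstruction bias; the decoder uses the doubly flipped kernels (tied, not
#' free parameters).
#'
#' @slot W List of K square kernel matrices (all the same shape).
#' @slot b Numeric vector of K per-map biases.
#' @slot c Single reconstruction bias.
#' @slot activation "sigmoid" (default) or "linear" (analytic test hook).
#' @slot metadata List (e.g. per-epoch loss trace after training).
#' @export
setClass("CAEModel",
  slots = c(W = "list", b = "numeric", c = "numeric",
            activation = "character", metadata = "list")
)

setValidity("CAEModel", function(object) {
  msg <- character()
  if (!length(object@W)) msg <- c(msg, "at least one kernel required")
  dims <- vapply(object@W, function(w) paste(dim(w), collapse = "x"), "")
  if (length(unique(dims)) > 1) msg <- c(msg, "kernels must share one shape")
  if (length(object@b) != length(object@W))
    msg <- c(msg, "one bias per latent map required")
  if (length(object@c) != 1) msg <- c(msg, "single reconstruction bias required")
  if (!object@activation %in% c("sigmoid", "linear"))
    msg <- c(msg, "activation must be 'sigmoid' or 'linear'")
  if (length(msg)) msg else TRUE
})

#' @param W List of kernel matrices.
#' @param b Per-map biases.
#' @param c Reconstruction bias.
#' @param activation "sigmoid" or "linear".
#' @param metadata Optional list.
#' @rdname CAEModel-class
#' @export
caeModel <- function(W, b, c = 0, activation = "sigmoid", metadata = list()) {
  new("CAEModel", W = W, b = as.numeric(b), c = as.numeric(c),
      activation = activation, metadata = metadata)
}

setMethod("show", "CAEModel", function(object) {
  cat("CAEModel:", length(object@W), "kernels of",
      paste(dim(object@W[[1]]), collapse = "x"),
      "| activation:", object@activation, "\n")
})

#' Supervised fusion classifier
#'
#' @slot backend Classifier backend ("mlp" for the native deep network, or one
#'   of the pluggable library backends).
#' @slot fit Backend-specific fitted parameters.
#' @slot standardize Per-stream z-score parameters fit on training data.
#' @slot config The configuration the model was trained with.
#' @export
setClass("FusionModel",
  slots = c(backend = "character", fit = "list", standardize = "list",
            config = "list")
)

setMethod("show", "FusionModel", function(object) {
  cat("FusionModel: backend", object@backend, "\n")
})

#' Cross-validation fold report
#'
#' Per-fold classification metrics plus mean and sample-SD aggregate rows, in
#' the conventional 5-fold layout: percentages for Acc/Sens/Spec/Prec/MCC and
#' raw AUC/AUPR.
#'
#' @slot folds Per-fold metric data.frame (full precision).
#' @slot summary Two-row data.frame: mean and sample SD across folds.
#' @slot k Number of folds.
#' @slot seed Global seed used for the run.
#' @slot metadata List (variant, configs, curve points, ...).
#' @export
setClass("FoldReport",
  slots = c(folds = "data.frame", summary = "data.frame", k = "integer",
            seed = "integer", metadata = "list")
)

setValidity("FoldReport", function(object) {
  msg <- character()
  pct <- intersect(c("Acc", "Sens", "Spec", "Prec"), colnames(object@folds))
  for (col in pct) {
    v <- object@folds[[col]]
    if (any(v < 0 | v > 100)) msg <- c(msg, paste(col, "outside [0, 100]"))
  }
  if ("MCC" %in% colnames(object@folds) &&
      any(abs(object@folds$MCC) > 100)) msg <- c(msg, "MCC outside [-100, 100]")
  for (col in intersect(c("AUC", "AUPR"), colnames(object@folds))) {
    v <- object@folds[[col]]
    if (any(v < 0 | v > 1)) msg <- c(msg, paste(col, "outside [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FoldReport-class per-fold metrics (full precision)
#' @param x A \code{FoldReport}.
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @export
setMethod("foldMetrics", "FoldReport", function(x) x@folds)

#' @describeIn FoldReport-class mean / sample-SD aggregate rows
#' @export
setGeneric("foldSummary", function(x) standardGeneric("foldSummary"))

#' @export
setMethod("foldSummary", "FoldReport", function(x) x@summary)

setMethod("show", "FoldReport", function(object) {
  cat("FoldReport (", object@k, "-fold CV, seed ", object@seed, ")\n", sep = "")
  print(formatFoldReport(object))
})
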
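#' Read RNA sequences from a FASTA file
#'
#' Identifiers are truncated at the first whitespace, sequences are upper-cased
#' and DNA-style T is normalised to U. Any residue outside \{A, C, G, U\} after
#' normalisation is an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return Named list of RNA strings, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 some circRNA", "acgt"), fa)
#' readRnaFasta(fa)
#' @export
readRnaFasta <- function(path) {
  if (!file.exists(path)) inputError("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) inputError("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonEmpty[1]]), ">"))
    inputError("malformed FASTA: sequence before first header at line ",
               nonEmpty[1], " of ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) inputError("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  offending <- which(vapply(seqs, function(s) grepl("[^ACGU]", s), logical(1)))
  if (length(offending)) {
    ch <- sub(".*?([^ACGU]).*", "\\1", seqs[offending[1]])
    inputError("invalid residue '", ch, "' in record '", ids[offending[1]],
               "' (alphabet is A/C/G/U, with T tolerated)")
  }
  setNames(as.list(seqs), ids)
}

# header row detection: both fields are recognisable column labels, not ids
looksLikeHeader <- function(fields) {
  labels <- c("circ", "circrna", "circrna_id", "circ_id", "mir", "mirna",
              "mirna_id", "mir_id", "source", "target", "id", "name",
              "circrnaid", "mirnaid")
  all(tolower(trimws(fields)) %in% labels)
}

#' Read a circRNA-miRNA association edge list
#'
#' Two-column (circRNA id, miRNA id) tab- or comma-separated file; an optional
#' header row is auto-detected by non-id tokens. Duplicate edges are dropped
#' with a warning; node order is first-appearance order.
#'
#' @param path Path to the edge-list file.
#' @param sequences Optional named list of RNA strings to attach.
#' @return An \linkS4class{AssociationDataset}.
#' @export
readEdgeList <- function(path, sequences = NULL) {
  if (!file.exists(path)) inputError("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) inputError("empty edge list: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 2L)) {
    badLine <- which(nf != 2L)[1]
    inputError("edge list row with ", nf[badLine], " fields (expected 2) ",
               "at line ", badLine, " of ", path)
  }
  circ <- trimws(vapply(rows, `[[`, "", 1L))
  mir <- trimws(vapply(rows, `[[`, "", 2L))
  if (looksLikeHeader(c(circ[1], mir[1]))) {
    circ <- circ[-1]
    mir <- mir[-1]
  }
  if (!length(circ)) inputError("edge list has a header but no rows: ", path)
  key <- paste(circ, mir, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) dropped from ", path)
    circ <- circ[!dup]
    mir <- mir[!dup]
  }
  if (!is.null(sequences)) {
    known <- names(sequences) %in% c(circ, mir)
    if (!all(known)) {
      warning(sum(!known), " sequence(s) for nodes absent from the edge ",
              "list dropped; use the CLI/FASTA route to keep isolated nodes")
      sequences <- sequences[known]
    }
  }
  associationDataset(
    circIds = unique(circ), mirIds = unique(mir),
    positives = data.frame(circ = circ, mir = mir, stringsAsFactors = FALSE),
    sequences = sequences
  )
}

#' Build the binary adjacency (incidence) matrix
#'
#' Rows index miRNAs and columns circRNAs; entry (i, j) is 1 exactly when
#' miRNA i and circRNA j are a known positive pair, 0 otherwise.
#'
#' @param ds An \linkS4class{AssociationDataset}.
#' @return Binary matrix of shape \code{n_mir x n_circ} with dimnames.
#' @export
buildAdjacency <- function(ds) {
  stopifnot(is(ds, "AssociationDataset"))
  validObject(ds)
  dm <- matrix(0L, nrow = length(ds@mirIds), ncol = length(ds@circIds),
               dimnames = list(ds@mirIds, ds@circIds))
  if (nrow(ds@positives)) {
    i <- match(ds@positives$mir, ds@mirIds)
    j <- match(ds@positives$circ, ds@circIds)
    dm[cbind(i, j)] <- 1L
  }
  dm
}

#' Sample presumed-negative pairs
#'
#' Draws \code{round(ratio * n_positives)} pairs uniformly, without
#' replacement, from the unobserved complement of the positive set, and
#' returns positives (label 1) followed by the sampled negatives (label 0).
#'
#' @param ds An \linkS4class{AssociationDataset}.
#' @param ratio Negative:positive ratio (default 1, balanced classes).
#' @param seed Integer seed; the same seed reproduces the same negatives.
#' @return A \linkS4class{LabeledPairSet}.
#' @export
sampleNegatives <- function(ds, ratio = 1, seed = 1L) {
  stopifnot(is(ds, "AssociationDataset"), ratio > 0)
  validObject(ds)
  nc <- length(ds@circIds)
  nm <- length(ds@mirIds)
  npos <- nrow(ds@positives)
  nneg <- round(ratio * npos)
  # linear index over the circ x mir universe
  posIdx <- (match(ds@positives$circ, ds@circIds) - 1L) * nm +
    match(ds@positives$mir, ds@mirIds)
  avail <- nc * nm - npos
  if (avail < nneg)
    inputError("cannot sample ", nneg, " negatives: only ", avail,
               " non-positive pairs available")
  negIdx <- withr::with_seed(seed, {
    pool <- setdiff(seq_len(nc * nm), posIdx)
    sample(pool, nneg)
  })
  negCirc <- ds@circIds[(negIdx - 1L) %/% nm + 1L]
  negMir <- ds@mirIds[(negIdx - 1L) %% nm + 1L]
  labeledPairSet(
    pairs = data.frame(circ = c(ds@positives$circ, negCirc),
                       mir = c(ds@positives$mir, negMir),
                       stringsAsFactors = FALSE),
    labels = c(rep(1L, npos), rep(0L, nneg))
  )
}

#' Stratified k-fold split of a labeled pair set
#'
#' Shuffles within each label class and deals pairs round-robin into k folds,
#' so per-fold class counts differ from the global ratio by at most one pair.
#'
#' @param ps A \linkS4class{LabeledPairSet}.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return A \linkS4class{FoldAssignment}.
#' @export
kfoldSplit <- function(ps, k = 5L, seed = 1L) {
  stopifnot(is(ps, "LabeledPairSet"))
  k <- as.integer(k)
  n <- length(ps@labels)
  if (k < 2L) inputError("k must be at least 2")
  if (k > n) inputError("k = ", k, " exceeds the number of pairs (", n, ")")
  fold <- integer(n)
  withr::with_seed(seed, {
    # deal shuffled members of each class round-robin, continuing the cycle
    # across classes so overall fold sizes also differ by at most one
    start <- 0L
    for (lab in unique(ps@labels)) {
      idx <- sample(which(ps@labels == lab))
      fold[idx] <- as.integer((start + seq_along(idx) - 1L) %% k)
      start <- (start + length(idx)) %% k
    }
  })
  new("FoldAssignment", fold = fold, k = as.integer(k),
      seed = as.integer(seed))
}

#' Export a fold assignment as TSV (pair, label, fold)
#'
#' @param ps The \linkS4class{LabeledPairSet} that was split.
#' @param fa The matching \linkS4class{FoldAssignment}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeFoldAssignment <- function(ps, fa, path) {
  df <- data.frame(circ = ps@pairs$circ, mir = ps@pairs$mir,
                   label = ps@labels, fold = fa@fold)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
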
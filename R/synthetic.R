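#' Synthetic benchmark configuration
#'
#' Defines a planted-signal study: every node is assigned sequence motifs from
#' a shared pool; its RNA sequence is a uniform random background with the
#' motifs embedded at random non-overlapping positions, and each
#' circRNA-miRNA pair is a positive edge with probability
#' \code{logistic(alpha + beta * |shared motifs|)}. The same motif memberships
#' therefore drive both the sequence (attribute) and the network (behaviour)
#' signal.
#'
#' @param nCirc,nMir Node counts (defaults 150 and 80).
#' @param nMotifs Size of the shared motif pool M (default 12).
#' @param motifLength Motif length range in nt (default 6-8).
#' @param motifsPerCirc,motifsPerMir Motifs per node (defaults 2 and 1).
#' @param circLength,mirLength Sequence length ranges (defaults 200-600 and
#'   18-25 nt).
#' @param alpha Baseline edge log-odds (default -2.8; with the default beta
#'   this yields about 1200 positive edges, density about 0.1).
#' @param beta Signal strength, >= 0 (default 2; beta = 0 removes all planted
#'   association signal).
#' @param seed Mandatory integer seed.
#' @return A list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nCirc = 150L, nMir = 80L, nMotifs = 12L,
                            motifLength = c(6L, 8L), motifsPerCirc = 2L,
                            motifsPerMir = 1L, circLength = c(200L, 600L),
                            mirLength = c(18L, 25L), alpha = -2.8, beta = 2,
                            seed = 1L) {
  stopifnot(beta >= 0, nMotifs >= max(motifsPerCirc, motifsPerMir),
            all(motifLength >= 1L), all(circLength >= 1L),
            all(mirLength >= 1L), length(seed) == 1L)
  structure(list(nCirc = as.integer(nCirc), nMir = as.integer(nMir),
                 nMotifs = as.integer(nMotifs),
                 motifLength = as.integer(motifLength),
                 motifsPerCirc = as.integer(motifsPerCirc),
                 motifsPerMir = as.integer(motifsPerMir),
                 circLength = as.integer(circLength),
                 mirLength = as.integer(mirLength),
                 alpha = alpha, beta = beta, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

randomRna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# embed motifs at random non-overlapping positions inside a background string
embedMotifs <- function(background, motifs) {
  if (!length(motifs)) return(background)
  n <- nchar(background)
  if (sum(nchar(motifs)) > n)
    inputError("motifs (total ", sum(nchar(motifs)), " nt) cannot fit in a ",
               n, " nt sequence")
  lens <- nchar(motifs)
  for (attempt in seq_len(200L)) {
    starts <- vapply(lens, function(L) sample.int(n - L + 1L, 1L), integer(1))
    ord <- order(starts)
    s <- starts[ord]
    e <- s + lens[ord] - 1L
    if (length(s) == 1L || all(s[-1] > e[-length(e)])) {
      for (i in seq_along(motifs))
        substr(background, starts[i], starts[i] + lens[i] - 1L) <- motifs[i]
      return(background)
    }
  }
  # dense fallback: place motifs back to back from a random offset
  starts <- cumsum(c(sample.int(n - sum(lens) + 1L, 1L),
                     lens[-length(lens)]))
  for (i in seq_along(motifs))
    substr(background, starts[i], starts[i] + nchar(motifs[i]) - 1L) <-
      motifs[i]
  background
}

#' Generate a synthetic planted-signal dataset
#'
#' @param cfg A \code{\link{syntheticConfig}}.
#' @param dir Optional output directory; when given, writes
#'   \code{circ.fasta}, \code{mir.fasta}, \code{edges.tsv} and the
#'   ground-truth \code{motifs.tsv} (node, comma-separated motif ids).
#' @return List with \code{dataset} (an \linkS4class{AssociationDataset} with
#'   sequences), \code{truth} (node motif memberships), \code{motifs} (the
#'   motif strings) and, when \code{dir} is given, \code{files}.
#' @export
generateSynthetic <- function(cfg = syntheticConfig(), dir = NULL) {
  res <- withr::with_seed(cfg$seed, {
    motifLens <- sample(seq(cfg$motifLength[1], cfg$motifLength[2]),
                        cfg$nMotifs, replace = TRUE)
    motifs <- vapply(motifLens, randomRna, "")
    circIds <- sprintf("circ%03d", seq_len(cfg$nCirc))
    mirIds <- sprintf("mir%03d", seq_len(cfg$nMir))
    circMotifs <- lapply(seq_len(cfg$nCirc), function(i)
      sort(sample(cfg$nMotifs, cfg$motifsPerCirc)))
    mirMotifs <- lapply(seq_len(cfg$nMir), function(i)
      sort(sample(cfg$nMotifs, cfg$motifsPerMir)))
    seqs <- c(
      setNames(lapply(seq_len(cfg$nCirc), function(i) {
        bg <- randomRna(sample(seq(cfg$circLength[1], cfg$circLength[2]), 1L))
        embedMotifs(bg, motifs[circMotifs[[i]]])
      }), circIds),
      setNames(lapply(seq_len(cfg$nMir), function(i) {
        bg <- randomRna(sample(seq(cfg$mirLength[1], cfg$mirLength[2]), 1L))
        embedMotifs(bg, motifs[mirMotifs[[i]]])
      }), mirIds)
    )
    overlap <- outer(seq_len(cfg$nCirc), seq_len(cfg$nMir),
                     Vectorize(function(i, j)
                       length(intersect(circMotifs[[i]], mirMotifs[[j]]))))
    pEdge <- plogis(cfg$alpha + cfg$beta * overlap)
    edge <- matrix(runif(length(pEdge)) < pEdge, nrow(pEdge))
    idx <- which(edge, arr.ind = TRUE)
    # edge-list order: by circRNA then miRNA (deterministic)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    positives <- data.frame(circ = circIds[idx[, 1]], mir = mirIds[idx[, 2]],
                            stringsAsFactors = FALSE)
    list(motifs = motifs, circIds = circIds, mirIds = mirIds,
         circMotifs = circMotifs, mirMotifs = mirMotifs, seqs = seqs,
         positives = positives)
  })
  ds <- associationDataset(res$circIds, res$mirIds, res$positives,
                           sequences = res$seqs)
  truth <- data.frame(
    node = c(res$circIds, res$mirIds),
    motifs = c(vapply(res$circMotifs, paste, "", collapse = ","),
               vapply(res$mirMotifs, paste, "", collapse = ",")),
    stringsAsFactors = FALSE
  )
  out <- list(dataset = ds, truth = truth, motifs = res$motifs)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      circFasta = file.path(dir, "circ.fasta"),
      mirFasta = file.path(dir, "mir.fasta"),
      edges = file.path(dir, "edges.tsv"),
      truth = file.path(dir, "motifs.tsv")
    )
    writeLines(unlist(lapply(res$circIds, function(id)
      c(paste0(">", id), res$seqs[[id]]))), files$circFasta)
    writeLines(unlist(lapply(res$mirIds, function(id)
      c(paste0(">", id), res$seqs[[id]]))), files$mirFasta)
    write.table(res$positives, files$edges, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$files <- files
  }
  out
}

#' Run the planted-signal benchmark
#'
#' Generates a synthetic dataset, runs the full cross-validated pipeline, and
#' compares the mean AUC against an optional floor and ceiling.
#'
#' @param cfg A \code{\link{syntheticConfig}}.
#' @param pipelineCfg A \code{\link{pipelineConfig}}.
#' @param k Number of folds (default 5).
#' @param seed Run seed for the pipeline (the generator uses
#'   \code{cfg$seed}).
#' @param floor,ceiling Optional bounds on the mean AUC.
#' @param variant Pipeline variant (default "full").
#' @return List with the \code{report} (\linkS4class{FoldReport}),
#'   \code{meanAUC}, and \code{pass} (NA when no bounds given).
#' @export
plantedBenchmark <- function(cfg = syntheticConfig(),
                             pipelineCfg = pipelineConfig(), k = 5L,
                             seed = 1L, floor = NULL, ceiling = NULL,
                             variant = "full") {
  sim <- generateSynthetic(cfg)
  report <- crossValidate(sim$dataset, config = pipelineCfg, k = k,
                          seed = seed, variant = variant)
  meanAUC <- foldSummary(report)["Average", "AUC"]
  pass <- NA
  if (!is.null(floor) || !is.null(ceiling)) {
    pass <- TRUE
    if (!is.null(floor) && meanAUC < floor) pass <- FALSE
    if (!is.null(ceiling) && meanAUC > ceiling) pass <- FALSE
  }
  list(report = report, meanAUC = meanAUC, pass = pass)
}
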
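#' @useDynLib circMiRCAE, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats plogis predict prcomp rbinom runif sd setNames
#' @importFrom utils head write.table read.delim
NULL

## Input errors (bad files, bad arguments) carry their own condition class so
## the CLI can map them to exit code 2.
inputError <- function(...) {
  stop(errorCondition(paste0(...), class = c("cmaInputError", "error")))
}

numericError <- function(...) {
  stop(errorCondition(paste0(...), class = c("cmaNumericError", "error")))
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stage seeds are a deterministic hash of the global seed and the stage name,
#' kept below 2^31 so they are valid R integer seeds.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) %% 1048576 * 69621 + h + 1) %% 2147483647)
}

## round half away from zero, with a small guard so that values that are a
## decimal tie up to double representation error (e.g. 84.645) round up
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

logistic <- function(x) 1 / (1 + exp(-x))

logMsg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## column-wise z-score with parameters learned on a training subset
fitStandardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

applyStandardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
}
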
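#' @useDynLib cuedit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fisher.test p.adjust phyper rbinom rnorm runif sd
#'   setNames wilcox.test cor
#' @importFrom utils read.delim write.table head
NULL

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific seed from the master seed so that each generator
# stage is deterministic on its own, independent of call order.
stage_seed <- function(seed, stage) {
  (seed * 131L + stage * 7919L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
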
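#' @keywords internal
#' @useDynLib beatcam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Derive a per-item seed from a root seed
#'
#' All stochastic stages draw their randomness from a single root seed;
#' per-record (or per-trial) substreams are derived with a fixed
#' multiplicative-congruential rule so that record \code{i} is reproducible
#' independently of how many records were generated before it.
#'
#' @param root_seed integer root seed.
#' @param index positive integer identifying the substream.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(root_seed, index) {
  stopifnot(length(root_seed) == 1, length(index) == 1, index >= 0)
  m <- 2147483647 # 2^31 - 1 (Mersenne prime, classic Lehmer modulus)
  a <- 48271
  s <- (as.numeric(root_seed) %% m) * a + as.numeric(index)
  as.integer(s %% m)
}

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards
with_seed <- function(seed, expr) {
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(NULL)
}
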
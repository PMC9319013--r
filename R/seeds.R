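#' Derive a reproducible substream seed from a master seed
#'
#' All randomness in the simulator flows from one master seed through named
#' substreams (e.g. `"coverage/B/2"`, `"expression"`, `"survival"`), so any
#' stage can be regenerated independently of the others. The substream seed
#' is a deterministic 31-bit hash of the master seed and the stream name.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(42, "coverage/A/1")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stream)) {
    # 31-bit multiplicative string hash; constants fit in double precision
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, stream))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
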
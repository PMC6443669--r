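#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed and a stream index to a positive
#' 32-bit integer seed, so every source of randomness in a multi-part run
#' can flow from one user-supplied seed.
#'
#' @param seed Master integer seed.
#' @param stream Stream index (>= 0).
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, stream = 0L) {
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m + 1)
  for (i in seq_len(stream + 1L)) s <- (s * 48271) %% m
  as.integer(s)
}
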
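# Deterministic seed splitting: every generator derives its own RNG seed from
# the master seed and a stage label, so partial re-runs reproduce the full run.

mulmod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

#' Derive a child RNG seed from a master seed and a stage label
#'
#' FNV-1a hash of `"<seed>:<label>"`, reduced to a valid positive 32-bit
#' integer seed. Identical (seed, label) pairs always yield the same child
#' seed; distinct labels decorrelate the stages of a pipeline run.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return integer seed in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), ":", label))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- mulmod32(h, 16777619)
  }
  as.integer(h %% 2147483646 + 1)
}
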
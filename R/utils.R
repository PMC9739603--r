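# Internal helpers: named RNG substreams and stage-tagged logging.

# Deterministic 31-bit substream seed from (seed, label). One substream per
# generator call keeps datasets reproducible when unrelated parameters change.
fw_substream <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

fw_log <- function(stage, ...) {
  message(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, paste0(...)))
}
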
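# internal numerical helpers

logsumexp <- function(v) {
  if (!length(v)) return(-Inf)
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ms <- function(...) stop(sprintf(...), call. = FALSE)

# derive a reproducible child seed (kept below 2^31) from a base seed
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1000003L
}
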
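# Internal helpers shared across modules.

# Fan a global integer seed out to per-component child seeds by fixed offsets.
# Kept below 2^31 so the result is always a valid R integer seed.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "ncmod_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Upper-tail hypergeometric probability P(X >= k) for overlap k between a set
# of size n_draw drawn from a population of size n_pop containing n_success
# marked elements. Single shared implementation behind every enrichment-style
# test in the package.
hyper_upper_p <- function(k, n_success, n_draw, n_pop) {
  if (n_success > n_pop || n_draw > n_pop) {
    stopf("hypergeometric population (%d) smaller than a set (%d, %d)",
          n_pop, n_success, n_draw)
  }
  if (k <= 0) return(1)
  stats::phyper(k - 1, n_success, n_pop - n_success, n_draw, lower.tail = FALSE)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
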
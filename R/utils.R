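# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a base seed and an index
#'
#' All stochastic stages draw their randomness from a single user-supplied
#' seed; per-entity substreams are derived arithmetically so any stage can be
#' regenerated in isolation. The result always fits in a 32-bit integer.
#'
#' @param seed base integer seed.
#' @param index non-negative integer identifying the substream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %%
               2147483647L)
}

# Stop with a classed condition so callers/tests can distinguish validation
# from parse/IO failures.
md_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "microdialysR_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) md_stop(msg, "microdialysR_validation_error")
parse_error <- function(msg) md_stop(msg, "microdialysR_parse_error")

# Median over non-missing values; even counts use the midpoint mean.
median_nonmissing <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
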
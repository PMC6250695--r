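# Internal helpers shared across modules.

# Typed error conditions so callers (and tests) can distinguish malformed
# files (format), invariant violations (validation) and bad configuration.
rs_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "revsig_error", "error")))
}

stop_format <- function(msg, ...) rs_stop(msg, "revsig_format_error", ...)
stop_validation <- function(msg, ...) rs_stop(msg, "revsig_validation_error", ...)
stop_config <- function(msg, ...) rs_stop(msg, "revsig_config_error", ...)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a deterministic per-purpose seed from one global seed so that each
# generator consumes its own RNG substream: adding a generator never
# perturbs the draws of an existing one. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

# Evaluate expr under a named substream of `seed`, restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Full-precision numeric rendering for TSV round-trips.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
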
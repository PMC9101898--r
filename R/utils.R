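# internal helpers

# Run `expr` under a fixed seed without clobbering the caller's RNG stream.
with_local_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed for the k-th independent stream; stays inside 32-bit range.
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003 + 1) * 1009 + 7919 * k) %% 2147483562L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# tolerance for closed (>=) thresholds computed from floating-point means
.THRESH_EPS <- 1e-9
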
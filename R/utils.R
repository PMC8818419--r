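# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All seeded package functions route
# through this so that library calls never perturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Half-up rounding of 100 * num / den to two decimals.  For integer counts
# (the confusion-matrix case) the computation is exact integer arithmetic,
# immune to binary floating-point representation of values like 98.875.
pct_half_up <- function(num, den) {
  if (den == 0) {
    return(NA_real_)
  }
  if (num == round(num) && den == round(den) && den <= .Machine$integer.max) {
    q <- (2 * 10000 * num + den) %/% (2 * den)
    return(q / 100)
  }
  x <- 100 * num / den
  floor(x * 100 + 0.5) / 100
}

# milliseconds <-> samples at a given sampling rate
ms_to_samples <- function(ms, fs) round(ms * fs / 1000)
samples_to_ms <- function(n, fs) n * 1000 / fs

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
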
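# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seeds (kept below .Machine$integer.max).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

verbose_msg <- function(...) {
  if (isTRUE(getOption("ctbalance.verbose", FALSE))) message(...)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

# truncated normal via rejection sampling (no boundary spikes, unlike clipping)
rtrunc_norm <- function(n, mean, sd, lo, hi, max_iter = 1000L) {
  if (n == 0L) return(numeric(0))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  it <- 0L
  while (length(bad) > 0L) {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf(
        "rejection sampling did not converge for N(%g, %g) truncated to [%g, %g]",
        mean, sd, lo, hi), call. = FALSE)
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}
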
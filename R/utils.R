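# Internal helpers: seeded RNG scoping and seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic entry points route
# through this so that library use never perturbs the user's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from (master, salt) with a multiplicative-congruential
# mix. Keeps results in [1, 2^31 - 2] so they are valid R integer seeds;
# distinct salts give effectively independent streams for sampling, weight
# initialisation, per-image texture draws, etc.
deriveSeed <- function(seed, salt) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (k in as.numeric(salt)) {
    s <- (s * 48271 + (k %% m) + 1) %% m
    s <- (s * 69621) %% m
  }
  as.integer(if (s < 1) 1 else s)
}

# Salt labels -> numeric, so deriveSeed can take readable component names.
saltOf <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
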
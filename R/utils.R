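# internal helpers

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

rmsLevel <- function(x) sqrt(mean(x^2))

# taper of length n; periodic variants (COLA-friendly at hop = n / 2^k)
makeWindow <- function(n, windowFn) {
  i <- seq_len(n) - 1L
  switch(windowFn,
    hann = 0.5 - 0.5 * cos(2 * pi * i / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * i / n),
    rect = rep(1, n),
    stop("unknown windowFn: ", windowFn)
  )
}
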
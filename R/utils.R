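# Internal helpers shared across modules.

# Set the RNG to a known state and return a restorer function, so package
# functions are deterministic under their `seed` argument without clobbering
# the caller's random stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Derive a stream-specific child seed from a base seed; keeps independent
# draws for independent cohort components while staying inside 32-bit range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + stream) %% 2147483647
}

# Truncated-below normal draws by resampling.
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
    guard <- guard + 1L
  }
  x[x < lower] <- lower
  x
}

# Lognormal multiplier with mean 1 and the requested coefficient of
# variation (cv = 0 returns exactly 1).
rlnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
}
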
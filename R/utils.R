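# internal helpers shared across modules

# Deterministic substream seed derivation: fold a root seed and a sequence of
# stream identifiers through a Weyl/LCG-style mix, staying inside the
# positive 32-bit range R's set.seed() accepts. The scheme is documented so
# per-subject / per-stream reproducibility survives reordering of calls.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed %% 2147483647)
  for (k in ids) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# AR(1) series with unit stationary variance, zero mean
ar1_series <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1)))
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < min)
    stop("'", name, "' must be an integer >= ", min)
  invisible(as.integer(x))
}

# two-tailed display rounding used in reports (3 decimals)
display_threshold <- function(x) round(x, 3)
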
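# internal helpers: seed derivation and scoped RNG state

# Derive a 31-bit child seed from (seed, key). Lehmer-style mixing keeps all
# intermediates below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(seed, key) {
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  h <- 0
  for (k in utf8ToInt(as.character(key))) h <- (h * 131 + k) %% m
  s <- (s * 48271) %% m
  as.integer((s + h) %% m + 1)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# circular standard deviation of day-of-year values, in days
circular_sd_days <- function(doy, period = 365) {
  ang <- 2 * pi * doy / period
  R <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) * period / (2 * pi)
}

# separable Gaussian-kernel smoother: returns a standardised (mean 0, sd 1)
# smooth random field of dimension nr x nc
gaussian_field <- function(nr, nc, range_cells = 3) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  smoother <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / range_cells)^2)
    k / rowSums(k)
  }
  f <- smoother(nr) %*% z %*% t(smoother(nc))
  (f - mean(f)) / stats::sd(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
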
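# Barcode-less signal generators. These teach the classifier what a
# barcode-free window looks like: flat signal, white Gaussian noise and
# smooth 1-D gradient (Perlin) noise.

#' Flat signal
#'
#' @param n Number of samples.
#' @param level Constant value.
#' @return Numeric vector of `n` identical values.
#' @export
gen_flat <- function(n, level = 0) {
  if (n < 1) stopf("n must be >= 1")
  rep(level, n)
}

#' Gaussian noise signal
#'
#' @param n Number of samples.
#' @param seed Optional seed.
#' @param sd Noise sd.
#' @return Numeric vector of i.i.d. normal samples.
#' @export
gen_gaussian <- function(n, seed = NULL, sd = 1) {
  if (n < 1) stopf("n must be >= 1")
  with_seed(seed, stats::rnorm(n, sd = sd))
}

#' One-dimensional gradient (Perlin) noise
#'
#' Coherent noise: random gradients are placed on a regular lattice and
#' values between lattice points are obtained by smoothstep-interpolating
#' the two neighbouring gradient ramps. The result is a smooth signal
#' bounded in `[-1, 1]` that is exactly 0 at every lattice point, with a
#' much higher lag-1 autocorrelation than white Gaussian noise.
#'
#' @param n Number of samples.
#' @param seed Optional seed.
#' @param scale Samples per lattice cell (default 64).
#' @return Numeric vector of length `n`.
#' @export
gen_perlin <- function(n, seed = NULL, scale = 64) {
  if (n < 1) stopf("n must be >= 1")
  with_seed(seed, {
    n_cells <- ceiling((n - 1) / scale) + 1L
    grad <- stats::runif(n_cells + 1L, -1, 1)
    x <- (seq_len(n) - 1) / scale
    i <- floor(x)
    t <- x - i
    fade <- t^3 * (t * (t * 6 - 15) + 10)   # smoothstep (quintic)
    g0 <- grad[i + 1L]
    g1 <- grad[i + 2L]
    (1 - fade) * (g0 * t) + fade * (g1 * (t - 1))
  })
}
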
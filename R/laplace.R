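#' Zero-centred Laplace samples
#'
#' Draws i.i.d. samples from the Laplace (double-exponential) distribution
#' with location 0 and scale `scale`, the noise primitive of the release
#' mechanism. The standard deviation is `scale * sqrt(2)`.
#'
#' @param scale Positive scale parameter (for a release this is T/epsilon).
#' @param n Number of samples.
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @examples
#' sd(sample_laplace(1, 1e4, seed = 1)) # close to sqrt(2)
#' @export
sample_laplace <- function(scale, n, seed = NULL) {
  check_number(scale, "scale", lower = 0, strict = TRUE)
  check_number(n, "n", lower = 0)
  with_seed_opt(seed, {
    u <- runif(n, min = -0.5, max = 0.5)
    -scale * sign(u) * log1p(-2 * abs(u))
  })
}

# P(Laplace(0, scale) < x); continuous, so strict/non-strict agree.
laplace_cdf <- function(x, scale) {
  ifelse(x < 0, 0.5 * exp(x / scale), 1 - 0.5 * exp(-x / scale))
}
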
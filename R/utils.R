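#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from one integer seed; each stage
#' (cohort synthesis, permutations, spins, ...) draws from its own named
#' substream so that enabling or disabling one stage never shifts another
#' stage's random numbers. The derived seed is a deterministic 31-bit hash
#' of the master seed and the stream name.
#'
#' @param seed master integer seed.
#' @param stream character stream name, e.g. `"cohort"`, `"perm"`, `"spin"`.
#' @return an integer in `[0, 2^31 - 1]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "perm")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# run code under a local RNG state seeded from `seed`, restoring the caller's
# RNG afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# band-limited (low..high Hz) unit-variance Gaussian signals by spectral
# synthesis: complex Gaussian Fourier coefficients inside the passband only.
# Returns an n x k matrix sampled at `dt` seconds.
band_limited_noise <- function(n, k, dt = 1, low = 0.02, high = 0.1) {
  freqs <- (0:(n - 1)) / (n * dt)
  half <- freqs > 0 & freqs <= 1 / (2 * dt)
  inband <- half & freqs >= low & freqs <= high
  if (!any(inband)) stop("no Fourier bins inside the passband; series too short")
  coef <- matrix(0 + 0i, n, k)
  nb <- sum(inband)
  coef[inband, ] <- complex(real = rnorm(nb * k), imaginary = rnorm(nb * k))
  # hermitian symmetry -> real inverse transform
  conj_idx <- (n + 2) - which(inband)
  coef[conj_idx, ] <- Conj(coef[inband, , drop = FALSE])
  x <- Re(mvfft(coef, inverse = TRUE)) / n
  scale(x, center = TRUE, scale = apply(x, 2, sd))[, , drop = FALSE]
}

# symmetric matrix from an upper-triangle vector (diagonal zero)
unflatten_edges <- function(v, n, regions = NULL) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(regions)) dimnames(m) <- list(regions, regions)
  m
}

flatten_edges <- function(m) m[upper.tri(m)]

# edge (i, j) index pairs matching flatten_edges() ordering (column-major
# upper triangle)
edge_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
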
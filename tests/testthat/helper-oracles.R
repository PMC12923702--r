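# Independent brute-force oracles used across tests.

# LZ76 exhaustive-history phrase count straight from the definition: a new
# phrase ends at the first position where the running substring cannot be
# copied from anywhere in the preceding text (overlap allowed).
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  count <- 0L
  pos <- 1L
  while (pos <= n) {
    len <- 1L
    while (pos + len - 1L <= n) {
      sub <- substr(s, pos, pos + len - 1L)
      hist <- substr(s, 1L, pos + len - 2L)
      if (!grepl(sub, hist, fixed = TRUE)) break
      len <- len + 1L
    }
    count <- count + 1L
    pos <- pos + len
  }
  count
}

# power-iteration eigenvector oracle (independent of eigen())
power_iteration_ec <- function(m, tol = 1e-12, max_iter = 10000) {
  v <- rep(1 / sqrt(nrow(m)), nrow(m))
  for (i in seq_len(max_iter)) {
    v_new <- m %*% v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (sqrt(sum((v_new - v)^2)) < tol) break
    v <- v_new
  }
  as.vector(v_new)
}

# Moran's I with inverse-distance weights (spatial autocorrelation check)
morans_i <- function(values, xyz) {
  d <- as.matrix(dist(xyz))
  w <- 1 / d
  diag(w) <- 0
  z <- values - mean(values)
  n <- length(values)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}

# small default-free cohort for quick tests
tiny_cohort <- function(seed = 5, n_a = 3, n_b = 3, n_regions = 50,
                        n_volumes = c(mid = 150), ...) {
  generate_cohort(cohort_spec(n_group_a = n_a, n_group_b = n_b,
                              n_regions = n_regions, n_volumes = n_volumes,
                              seed = seed, ...))
}

# smooth map on a geometry (for spin-test scenarios)
smooth_map <- function(geometry, seed, autocorr_length = 1) {
  generate_receptor_map(geometry, autocorr_length = autocorr_length,
                        seed = seed)$value
}
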
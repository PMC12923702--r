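make_matrices <- function(n_subj, n_regions, seed, shift = NULL) {
  set.seed(seed)
  lapply(seq_len(n_subj), function(s) {
    m <- matrix(0, n_regions, n_regions,
                dimnames = list(sprintf("r%02d", 1:n_regions),
                                sprintf("r%02d", 1:n_regions)))
    v <- rnorm(sum(upper.tri(m)))
    if (!is.null(shift)) v[shift$edges] <- v[shift$edges] + shift$delta
    m[upper.tri(m)] <- v
    m + t(m)
  })
}

test_that("identical groups yield zero t and no significant edges", {
  ms <- make_matrices(5, 10, seed = 1)
  cmp <- edge_permutation_test(ms, ms, n_perm = 200, seed = 2)
  expect_equal(max(abs(cmp$t_stat)), 0)
  expect_false(any(cmp$significant))
  expect_identical(nrow(direction_proportions(cmp)), 0L)
  expect_equal(degree_from_significance(cmp)$degree, rep(0L, 10))
})

test_that("max-T p-values are monotone in |t| and bounded below", {
  a <- make_matrices(8, 12, seed = 3)
  b <- make_matrices(8, 12, seed = 4)
  cmp <- edge_permutation_test(a, b, n_perm = 300, seed = 5)
  up <- upper.tri(cmp$t_stat)
  o <- order(abs(cmp$t_stat[up]))
  p_sorted <- cmp$p_fwe[up][o]
  expect_true(all(diff(p_sorted) <= 1e-12))
  expect_true(all(cmp$p_fwe[up] >= 1 / 301))
  expect_true(isSymmetric(cmp$significant))
  # fixed seed reproduces the mask exactly
  cmp2 <- edge_permutation_test(a, b, n_perm = 300, seed = 5)
  expect_identical(cmp$p_fwe, cmp2$p_fwe)
})

test_that("group swap flips t signs and direction proportions", {
  shift <- list(edges = 1:8, delta = 3)
  a <- make_matrices(10, 8, seed = 6)
  b <- make_matrices(10, 8, seed = 7, shift = shift)
  cab <- edge_permutation_test(a, b, n_perm = 500, seed = 8)
  cba <- edge_permutation_test(b, a, n_perm = 500, seed = 8)
  expect_equal(cab$t_stat, -cba$t_stat)
  dab <- direction_proportions(cab)
  dba <- direction_proportions(cba)
  expect_gt(dab$n_significant, 0)
  expect_equal(dab$pct_stronger_a, dba$pct_stronger_b)
  expect_equal(dab$pct_stronger_a + dab$pct_stronger_b, 100)
})

test_that("degree counts incident significant edges", {
  a <- make_matrices(10, 6, seed = 9)
  b <- make_matrices(10, 6, seed = 10, shift = list(edges = 1, delta = 5))
  cmp <- edge_permutation_test(a, b, n_perm = 500, seed = 11)
  deg <- degree_from_significance(cmp)
  idx <- which(upper.tri(cmp$significant), arr.ind = TRUE)
  # edge 1 in flattening order is (1, 2)
  expect_gte(deg$degree[1], 1)
  expect_equal(sum(deg$degree),
               2 * sum(cmp$significant[upper.tri(cmp$significant)]))
})

test_that("eigenvector centrality agrees with a power-iteration oracle", {
  # uniform matrix -> uniform centrality
  m <- matrix(1, 5, 5) - diag(5)
  expect_equal(unname(eigenvector_centrality(m)), rep(1 / sqrt(5), 5))
  # two cliques, heavier one dominates
  m2 <- matrix(0, 6, 6)
  m2[1:3, 1:3] <- 3; m2[4:6, 4:6] <- 1
  diag(m2) <- 0
  ec <- eigenvector_centrality(m2)
  expect_gt(sum(ec[1:3]^2), 0.99)
  set.seed(12)
  for (k in 1:50) {
    r <- matrix(runif(400), 20, 20)
    r <- r + t(r); diag(r) <- 0
    expect_equal(unname(eigenvector_centrality(r)), power_iteration_ec(r),
                 tolerance = 1e-8)
  }
  expect_error(eigenvector_centrality(matrix(0, 4, 4)), "all-zero")
})

test_that("EC group difference is A minus B and antisymmetric", {
  set.seed(13)
  eca <- matrix(runif(40), 8, 5, dimnames = list(NULL, paste0("r", 1:5)))
  ecb <- matrix(runif(40), 8, 5, dimnames = list(NULL, paste0("r", 1:5)))
  d <- ec_group_difference(eca, ecb)
  expect_equal(d$ec_difference, colMeans(eca) - colMeans(ecb),
               ignore_attr = TRUE)
  expect_equal(ec_group_difference(eca, eca)$ec_difference, rep(0, 5))
  expect_equal(ec_group_difference(ecb, eca)$ec_difference, -d$ec_difference)
})

test_that("Cohen's d matches the hand-computed pooled formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(14)
  big_a <- rnorm(20000, mean = 1); big_b <- rnorm(20000, mean = 0)
  expect_equal(cohens_d(big_a, big_b), 1, tolerance = 0.05)
  a <- c(2, 4, 6, 8); b <- c(1, 2, 3, 4)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("Welch variant agrees with pooled t under equal variances", {
  a <- make_matrices(12, 6, seed = 15)
  b <- make_matrices(12, 6, seed = 16)
  cp <- edge_permutation_test(a, b, n_perm = 200, seed = 17)
  cw <- edge_permutation_test(a, b, n_perm = 200, seed = 17, welch = TRUE)
  expect_equal(cp$t_stat, cw$t_stat, tolerance = 0.2)
  expect_equal(sign(cp$t_stat), sign(cw$t_stat))
})

test_that("network pair summary assigns overlapping regions to all networks", {
  part <- tibble::tibble(
    region = c("r01", "r02", "r03", "r04", "r01"),
    network = c("n1", "n1", "n2", "n2", "n2"))
  a <- make_matrices(10, 4, seed = 18)
  b <- make_matrices(10, 4, seed = 19, shift = list(edges = 1, delta = 6))
  cmp <- edge_permutation_test(a, b, n_perm = 300, seed = 20)
  np <- network_pair_summary(cmp, part)
  # edge (r01, r02): r01 is in n1 and n2 -> contributes to n1-n1 and n1-n2
  expect_true(all(c("n1", "n2") %in% c(np$network_a, np$network_b)))
  expect_equal(sum(np$n_stronger_a + np$n_stronger_b) >= 2, TRUE)
})
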
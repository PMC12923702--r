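test_that("receptor normalization is affine-invariant with range [0, 1]", {
  expect_equal(normalize_receptor(c(1, 2, 3)), c(0, 0.5, 1))
  set.seed(40)
  x <- runif(30)
  nx <- normalize_receptor(x)
  expect_equal(range(nx), c(0, 1))
  expect_equal(normalize_receptor(3 * x + 7), nx, tolerance = 1e-12)
  expect_error(normalize_receptor(rep(2, 10)), "constant")
})

test_that("PLS recovers a noise-free planted map in one component", {
  set.seed(41)
  X <- cbind(MOR = runif(50), D2DR = runif(50))
  Y <- X %*% c(1, -2)
  fit <- pls_fit(X, cbind(a = Y, b = -0.5 * Y), n_components = 2)
  expect_gte(fit$cov_share[1], 0.99)
  expect_gte(fit$y_var_share[1], 0.99)
})

test_that("PLS scalars are invariant to joint region reordering", {
  set.seed(42)
  X <- cbind(MOR = runif(40), D2DR = runif(40))
  Y <- scale(X %*% matrix(rnorm(8), 2, 4) + matrix(rnorm(160, sd = 0.5), 40))
  f1 <- pls_fit(X, Y)
  perm <- sample(40)
  f2 <- pls_fit(X[perm, ], Y[perm, ])
  expect_equal(f1$cov_share, f2$cov_share, tolerance = 1e-10)
  expect_equal(f1$y_var_share, f2$y_var_share, tolerance = 1e-10)
  expect_equal(f1$vip, f2$vip, tolerance = 1e-8)
})

test_that("component-1 weights match the SVD-of-cross-covariance oracle", {
  set.seed(43)
  for (k in 1:20) {
    X <- matrix(runif(60), 30, 2, dimnames = list(NULL, c("MOR", "D2DR")))
    Y <- matrix(rnorm(120), 30, 4)
    fit <- pls_fit(X, Y)
    sv <- svd(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)))
    expect_gte(abs(sum(sv$u[, 1] * fit$weights[, 1])), 0.999)
  }
})

test_that("PLS agrees with mixOmics on a larger instance", {
  skip_if_not_installed("mixOmics")
  set.seed(44)
  X <- matrix(rnorm(300), 60, 5)
  Y <- matrix(rnorm(240), 60, 4)
  fit <- pls_fit(X, Y, n_components = 2)
  mo <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression", scale = FALSE)
  for (a in 1:2) {
    w_mo <- mo$loadings$X[, a]
    w_mo <- w_mo / sqrt(sum(w_mo^2))
    expect_gte(abs(sum(w_mo * fit$weights[, a])), 0.999)
  }
})

test_that("VIP satisfies its algebraic identity and a hand computation", {
  set.seed(45)
  X <- cbind(MOR = runif(30), D2DR = runif(30))
  Y <- scale(X %*% matrix(rnorm(8), 2, 4) + matrix(rnorm(120, sd = 0.4), 30))
  fit <- pls_fit(X, Y)
  expect_equal(sum(fit$vip^2), 2, tolerance = 1e-6)
  # direct evaluation of the formula from the stored weights / SS
  W <- fit$weights; ss <- fit$y_var_share
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  by_hand <- sqrt(2 * (wn %*% ss) / sum(ss))
  expect_equal(unname(fit$vip), as.vector(by_hand))
  # an uninformative predictor's VIP falls toward 0, the other toward sqrt(2)
  Y1 <- cbind(y = X[, 1] + rnorm(30, sd = 1e-6))
  f1 <- pls_fit(X, Y1, n_components = 1)
  expect_gt(f1$vip["MOR"], 1.3)
  expect_lt(f1$vip["D2DR"], 0.5)
})

test_that("spin maps are hemisphere/class-preserving bijections", {
  geom <- parcel_geometry(default_network_partition(114))
  spin <- build_spin_null(geom, n_perm = 100, seed = 46)
  ids <- seq_len(nrow(geom))
  for (p in c(1, 50, 100)) {
    expect_setequal(spin$perms[p, ], ids)
    expect_equal(geom$is_cortical[spin$perms[p, ]], geom$is_cortical)
    ctx <- geom$is_cortical
    expect_equal(geom$hemisphere[spin$perms[p, ]][ctx], geom$hemisphere[ctx])
  }
  # identity rotation yields the identity assignment
  ctx_xyz <- as.matrix(geom[geom$is_cortical & geom$hemisphere == "L",
                            c("x", "y", "z")])
  expect_equal(mifcdyn:::greedy_nearest(ctx_xyz, ctx_xyz),
               seq_len(nrow(ctx_xyz)))
  # determinism
  spin2 <- build_spin_null(geom, n_perm = 100, seed = 46)
  expect_identical(spin$perms, spin2$perms)
})

test_that("spin maps preserve spatial correlation better than shuffles", {
  geom <- parcel_geometry(default_network_partition(114))
  spin <- build_spin_null(geom, n_perm = 50, seed = 47)
  x <- smooth_map(geom, seed = 1)
  y <- smooth_map(geom, seed = 2)
  spin_r <- mean(abs(apply(spin$perms, 1,
                           function(p) cor(x, y[p], method = "spearman"))))
  set.seed(48)
  shuf_r <- mean(abs(sapply(1:50, function(i)
    cor(x, sample(y), method = "spearman"))))
  expect_gt(spin_r, shuf_r)
})

test_that("spin p-value matches a brute-force count", {
  nulls <- c(0.9, -0.8, 0.1, -0.2, 0.5, 0.55, -0.05, 0.3, -0.6, 0.05)
  nulls <- rep(nulls, 10)  # >= 100 values
  emp <- 0.52
  expect_equal(spin_pvalue(emp, nulls),
               (1 + sum(abs(nulls) >= 0.52)) / 101)
  expect_equal(spin_pvalue(0, nulls), 1)
  expect_equal(spin_pvalue(99, rep(0.1, 10000)), 1 / 10001)
})

test_that("spearman correlation matches a rank-then-pearson oracle", {
  geom <- parcel_geometry(default_network_partition(64))
  spin <- build_spin_null(geom, n_perm = 120, seed = 49)
  x <- smooth_map(geom, seed = 3)
  expect_equal(spearman_spin(x, exp(x), spin)$rho, 1)
  expect_equal(spearman_spin(x, -x^3, spin)$rho, -1)
  set.seed(50)
  for (k in 1:50) {
    a <- sample(20, 64, replace = TRUE)   # ties present
    b <- sample(20, 64, replace = TRUE)
    expect_equal(cor(a, b, method = "spearman"),
                 cor(rank(a), rank(b)), tolerance = 1e-12)
  }
  sp <- spearman_spin(x, smooth_map(geom, seed = 4), spin)
  expect_true(sp$p_spin >= 1 / 121 && sp$p_spin <= 1)
  expect_error(spearman_spin(x, rep(1, 64), spin), "constant")
})

test_that("network mean scores average overlapping regions into each network", {
  part <- tibble::tibble(region = c("a", "b", "c", "d", "e", "f", "a"),
                         network = c("n1", "n1", "n2", "n2", "n3", "n3", "n2"))
  sc <- c(a = 1, b = 3, c = 5, d = 7, e = 2, f = 4)
  nm <- network_mean_scores(sc, part)
  expect_equal(nm$mean_score[nm$network == "n1"], 2)
  expect_equal(nm$mean_score[nm$network == "n2"], (5 + 7 + 1) / 3)
  expect_equal(nm$mean_score[nm$network == "n3"], 3)
  # constant scores give every network that constant
  nc <- network_mean_scores(setNames(rep(7, 6), names(sc)), part)
  expect_true(all(nc$mean_score == 7))
})
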
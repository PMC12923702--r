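#' Normalize a receptor-availability map
#'
#' Z-scores the per-region values across regions, then min-max rescales to
#' `[0, 1]` — the normalization applied to molecular predictor maps before
#' the PLS. Invariant under positive affine transforms of the input.
#'
#' @param raw numeric per-region values (>= 2 distinct values).
#' @return numeric vector in `[0, 1]` with min 0 and max 1.
#' @export
#' @examples
#' normalize_receptor(c(1, 2, 3))  # 0, 0.5, 1
normalize_receptor <- function(raw) {
  if (!all(is.finite(raw))) stop("non-finite receptor values", call. = FALSE)
  if (length(unique(raw)) < 2)
    stop("constant receptor map cannot be normalized", call. = FALSE)
  z <- (raw - mean(raw)) / sd(raw)
  (z - min(z)) / (max(z) - min(z))
}

#' Assemble the PLS input matrices
#'
#' Aligns receptor maps (molecular predictors, normalized to `[0, 1]`) and
#' functional response maps on a common region set. Response columns are
#' standardized (mean 0, SD 1) since the four responses live on
#' incommensurate scales.
#'
#' @param receptors tibble with `region`, `receptor`, `value` (long form).
#' @param responses data frame with a `region` column plus one numeric
#'   column per functional response.
#' @return list of class `pls_input` with matrices `X` (regions x
#'   predictors, in `[0,1]`), `Y` (regions x responses, standardized) and
#'   `regions`.
#' @export
pls_input <- function(receptors, responses) {
  wide <- tidyr::pivot_wider(receptors[, c("region", "receptor", "value")],
                             names_from = "receptor", values_from = "value")
  common <- intersect(wide$region, responses$region)
  if (length(common) < 10) stop("fewer than 10 aligned regions", call. = FALSE)
  mismatch <- c(setdiff(wide$region, responses$region),
                setdiff(responses$region, wide$region))
  if (length(mismatch) > 0)
    warning("dropping unaligned regions: ", paste(mismatch, collapse = ", "))
  X <- as.matrix(wide[match(common, wide$region), -1, drop = FALSE])
  X <- apply(X, 2, normalize_receptor)
  Yd <- responses[match(common, responses$region), , drop = FALSE]
  Y <- as.matrix(Yd[, setdiff(names(Yd), "region"), drop = FALSE])
  sds <- apply(Y, 2, sd)
  if (any(sds == 0)) {
    warning("constant response column(s) left at zero after centering: ",
            paste(colnames(Y)[sds == 0], collapse = ", "))
    sds[sds == 0] <- 1
  }
  Y <- scale(Y, center = TRUE, scale = sds)
  if (anyNA(X) || anyNA(Y)) stop("missing values after alignment", call. = FALSE)
  structure(list(X = X, Y = Y, regions = common), class = "pls_input")
}

#' Partial least squares (PLS2) of functional responses on molecular maps
#'
#' Deflation-based NIPALS PLS2 regression of the response block `Y` on the
#' predictor block `X` (both column-centred internally; pass standardized
#' inputs via [pls_input()]). Per component it reports the predictor
#' weights, region-level predictor ("latent variable") scores, response
#' weights and scores, the share of total X-Y cross-covariance carried by
#' the component (squared singular-value share of the cross-covariance
#' matrix), and the share of Y variance explained by the component's
#' rank-one regression.
#'
#' @param input a `pls_input`, or a predictor matrix (then `Y` required).
#' @param Y response matrix when `input` is a bare matrix.
#' @param n_components number of latent variables (<= number of
#'   predictors).
#' @return object of class `pls_fit`: list with `weights` (p x A),
#'   `x_scores` (regions x A), `y_weights`, `y_scores`, `x_loadings`,
#'   `cov_share`, `y_var_share` (proportions), `vip`, `regions`,
#'   `predictors`, `responses`.
#' @export
pls_fit <- function(input, Y = NULL, n_components = 2) {
  if (inherits(input, "pls_input")) {
    X <- input$X; Y <- input$Y; regions <- input$regions
  } else {
    X <- as.matrix(input); regions <- rownames(X) %||% seq_len(nrow(X))
  }
  if (is.null(Y)) stop("`Y` is required", call. = FALSE)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  if (nrow(X) < 10) stop("need >= 10 regions", call. = FALSE)
  n_components <- min(n_components, ncol(X))
  X0 <- scale(X, center = TRUE, scale = FALSE)
  Y0 <- scale(Y, center = TRUE, scale = FALSE)
  if (qr(X0)$rank < ncol(X0))
    stop("rank-deficient predictor block after centering", call. = FALSE)

  sv <- svd(crossprod(X0, Y0))
  cov_share <- (sv$d^2 / sum(sv$d^2))[seq_len(n_components)]

  p <- ncol(X0); q <- ncol(Y0)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  C <- matrix(0, q, n_components)
  Tm <- matrix(0, nrow(X0), n_components); U <- matrix(0, nrow(X0), n_components)
  ss_y_tot <- sum(Y0^2)
  y_var_share <- numeric(n_components)
  Xa <- X0; Ya <- Y0
  for (a in seq_len(n_components)) {
    u <- Ya[, which.max(apply(Ya, 2, stats::var))]
    for (it in 1:500) {
      w <- crossprod(Xa, u); w <- w / sqrt(sum(w^2))
      tt <- Xa %*% w
      cc <- crossprod(Ya, tt) / sum(tt^2)
      u_new <- Ya %*% cc / sum(cc^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * sqrt(sum(u^2))) { u <- u_new; break }
      u <- u_new
    }
    pp <- crossprod(Xa, tt) / sum(tt^2)
    y_var_share[a] <- sum(tt^2) * sum(cc^2) / ss_y_tot
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc
    Tm[, a] <- tt; U[, a] <- u
    Xa <- Xa - tcrossprod(tt, pp)
    Ya <- Ya - tcrossprod(tt, cc)
  }
  dimnames(W) <- list(colnames(X), paste0("LV", seq_len(n_components)))
  fit <- structure(list(
    weights = W, x_scores = Tm, y_weights = C, y_scores = U, x_loadings = P,
    cov_share = cov_share, y_var_share = y_var_share,
    regions = regions, predictors = colnames(X),
    responses = colnames(Y) %||% paste0("y", seq_len(q)),
    n_components = n_components), class = "pls_fit")
  fit$vip <- vip(fit)
  fit
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d regions, %d predictors, %d responses, %d component(s)\n",
              length(x$regions), length(x$predictors), length(x$responses),
              x$n_components))
  cat("  covariance share:", paste(sprintf("%.1f%%", 100 * x$cov_share),
                                   collapse = ", "), "\n")
  cat("  VIP:", paste(sprintf("%s=%.2f", names(x$vip), x$vip),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a[ SS_a (w_ja / ||w_a||)^2 ] / sum_a SS_a )`,
#' where `p` is the number of predictors and `SS_a` the Y variance
#' explained by component `a`. Satisfies `sum_j VIP_j^2 = p`; VIP > 1 marks
#' a predictor as important to the model.
#'
#' @param fit a `pls_fit`.
#' @return named per-predictor VIP scores.
#' @export
vip <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  W <- fit$weights
  ss <- fit$y_var_share
  p <- nrow(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  out <- sqrt(p * as.vector(wn %*% ss) / sum(ss))
  names(out) <- rownames(W)
  out
}

#' Build a spatial spin-permutation null
#'
#' Generates `n_perm` region-index bijections that preserve spatial
#' autocorrelation: per permutation a random 3D rotation is applied to one
#' hemisphere's cortical centroids and its mirror image to the other, and
#' each cortical parcel is mapped to the nearest rotated parcel within its
#' hemisphere (greedy assignment in order of increasing distance, so
#' conflicts resolve by distance rank). Subcortical regions, which live off
#' the sphere, are uniformly permuted among themselves. The identity
#' rotation yields the identity map.
#'
#' @param geometry geometry tibble (`region`, `x`, `y`, `z`, `hemisphere`,
#'   `is_cortical`); cortical centroids must be unit vectors.
#' @param n_perm number of permutation maps.
#' @param seed integer seed.
#' @return object of class `spin_null`: list with `perms` (n_perm x
#'   regions matrix of region indices), `regions`, `seed`.
#' @export
build_spin_null <- function(geometry, n_perm = 10000, seed = 1) {
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  if (anyDuplicated(round(xyz, 10)))
    stop("duplicate centroids in geometry", call. = FALSE)
  ctx <- which(geometry$is_cortical)
  nrm <- sqrt(rowSums(xyz[ctx, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("cortical centroids must lie on the unit sphere", call. = FALSE)
  sub <- which(!geometry$is_cortical)
  hemi_idx <- split(ctx, geometry$hemisphere[ctx])
  mirror <- diag(c(-1, 1, 1))
  n_reg <- nrow(geometry)
  perms <- matrix(0L, n_perm, n_reg)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      rot <- random_rotation()
      map <- integer(n_reg)
      for (h in names(hemi_idx)) {
        idx <- hemi_idx[[h]]
        R_h <- if (h == names(hemi_idx)[1]) rot else mirror %*% rot %*% mirror
        rotated <- xyz[idx, , drop = FALSE] %*% t(R_h)
        map[idx] <- idx[greedy_nearest(xyz[idx, , drop = FALSE], rotated)]
      }
      if (length(sub) > 0) map[sub] <- sub[sample.int(length(sub))]
      perms[p, ] <- map
    }
  })
  structure(list(perms = perms, regions = geometry$region, seed = seed,
                 n_perm = n_perm), class = "spin_null")
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))   # unique, Haar-distributed
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# assignment[i] = index (into rows of `rotated`) assigned to original
# parcel i; greedy over pairs in increasing distance order
greedy_nearest <- function(original, rotated) {
  n <- nrow(original)
  d2 <- outer(rowSums(original^2), rowSums(rotated^2), "+") -
    2 * tcrossprod(original, rotated)
  ord <- order(d2)
  assigned_orig <- logical(n); assigned_rot <- logical(n)
  out <- integer(n); left <- n
  for (k in ord) {
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (!assigned_orig[i] && !assigned_rot[j]) {
      out[i] <- j
      assigned_orig[i] <- TRUE; assigned_rot[j] <- TRUE
      left <- left - 1
      if (left == 0) break
    }
  }
  out
}

#' Two-tailed permutation p-value against a null distribution
#'
#' `p = (1 + #{null : |null| >= |empirical|}) / (n_null + 1)`.
#'
#' @param empirical_stat observed statistic.
#' @param null_stats numeric vector of >= 100 null statistics.
#' @return p-value in `(0, 1]`.
#' @export
spin_pvalue <- function(empirical_stat, null_stats) {
  if (length(null_stats) < 100) stop("need >= 100 null values", call. = FALSE)
  (1 + sum(abs(null_stats) >= abs(empirical_stat))) / (length(null_stats) + 1)
}

#' Spearman correlation with parametric and spin p-values
#'
#' Rank correlation between a per-region predictor score and a per-region
#' functional response, with the usual parametric p-value and a spin
#' p-value from recomputing rho under each spatial permutation map applied
#' to the response.
#'
#' @param predictor_score,response aligned per-region numeric vectors.
#' @param spin a `spin_null` built on the same region ordering.
#' @return tibble with `rho`, `p`, `p_spin`.
#' @export
spearman_spin <- function(predictor_score, response, spin) {
  stopifnot(inherits(spin, "spin_null"))
  if (length(predictor_score) != length(response) ||
      length(response) != ncol(spin$perms))
    stop("predictor, response and spin maps must align", call. = FALSE)
  if (sd(predictor_score) == 0 || sd(response) == 0)
    stop("constant vector", call. = FALSE)
  rho <- cor(predictor_score, response, method = "spearman")
  p <- suppressWarnings(
    cor.test(predictor_score, response, method = "spearman")$p.value)
  rx <- scale(rank(predictor_score))[, 1]
  ry <- rank(response)
  # ranks are permutation-equivariant: rank(y[perm]) == rank(y)[perm]
  null_rho <- as.vector(
    (matrix(scale(ry)[spin$perms], nrow(spin$perms)) %*% rx) /
      (length(rx) - 1))
  tibble(rho = rho, p = p, p_spin = spin_pvalue(rho, null_rho))
}

#' Spin test for PLS covariance shares
#'
#' Refits the PLS under each spatial permutation map applied to the rows of
#' the response block and compares each component's empirical covariance
#' share against its spin-null distribution.
#'
#' @param input a `pls_input`.
#' @param spin a `spin_null` on the same region ordering.
#' @param n_components components to test.
#' @return tibble with `component`, `cov_share`, `y_var_share`, `spin_p`.
#' @export
pls_spin_test <- function(input, spin, n_components = 2) {
  stopifnot(inherits(input, "pls_input"), inherits(spin, "spin_null"))
  fit <- pls_fit(input, n_components = n_components)
  X0 <- scale(input$X, center = TRUE, scale = FALSE)
  shares <- function(Yp) {
    d2 <- svd(crossprod(X0, scale(Yp, center = TRUE, scale = FALSE)))$d^2
    (d2 / sum(d2))[seq_len(n_components)]
  }
  null_shares <- apply(spin$perms, 1,
                       function(pm) shares(input$Y[pm, , drop = FALSE]))
  null_shares <- matrix(null_shares, nrow = n_components)
  spin_p <- vapply(seq_len(n_components), function(a)
    spin_pvalue(fit$cov_share[a], null_shares[a, ]), numeric(1))
  tibble(component = seq_len(n_components),
         cov_share = fit$cov_share,
         y_var_share = fit$y_var_share,
         spin_p = spin_p)
}

#' Network-averaged latent-variable scores
#'
#' Mean of per-region scores within each functional network; regions with
#' overlapping membership contribute to each of their networks.
#'
#' @param scores named per-region numeric vector (names = region ids), or
#'   unnamed vector aligned with `partition`'s distinct regions.
#' @param partition region-network membership tibble.
#' @return tibble with `network`, `mean_score`, `n_regions`.
#' @export
network_mean_scores <- function(scores, partition) {
  regs <- unique(partition$region)
  if (is.null(names(scores))) {
    if (length(scores) != length(regs))
      stop("unnamed scores must align with the partition's regions", call. = FALSE)
    names(scores) <- regs
  }
  missing_reg <- setdiff(partition$region, names(scores))
  if (length(missing_reg) > 0)
    stop("regions without scores: ", paste(missing_reg, collapse = ", "),
         call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(tibble(network = partition$network,
                           score = scores[partition$region]), .data$network),
    mean_score = mean(.data$score), n_regions = dplyr::n(), .groups = "drop")
  if (any(out$n_regions == 0)) stop("empty network", call. = FALSE)
  out
}
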
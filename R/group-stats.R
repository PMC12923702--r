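#' Edge-wise two-group permutation test with max-T familywise correction
#'
#' For every edge, a pooled-variance two-sample t statistic (group A minus
#' group B) compares the two groups' connectivity matrices. The familywise
#' null is built by shuffling group labels `n_perm` times and recording the
#' maximum |t| over all edges per shuffle; each edge's corrected p-value is
#' `p_fwe = (1 + #permutations with max|t| >= |t_obs|) / (n_perm + 1)`
#' (two-tailed, never exactly zero). An edge is significant when
#' `p_fwe < alpha`.
#'
#' @param matrices_a,matrices_b lists of symmetric region x region matrices
#'   (miFC or contrast), one per subject, identical dimensions.
#' @param n_perm number of label permutations (>= 100).
#' @param alpha familywise significance level.
#' @param seed integer seed for the permutation draws.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return object of class `edge_comparison`: list with symmetric matrices
#'   `t_stat`, `p_fwe`, `significant`, plus `max_t_null`, `regions`,
#'   `n_perm`, `alpha`, `seed`, `n_a`, `n_b`.
#' @seealso [direction_proportions()], [degree_from_significance()],
#'   [tidy.edge_comparison()]
#' @export
edge_permutation_test <- function(matrices_a, matrices_b, n_perm = 10000,
                                  alpha = 0.05, seed = 1, welch = FALSE) {
  if (length(matrices_a) < 2 || length(matrices_b) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  dims <- unique(c(lapply(matrices_a, dim), lapply(matrices_b, dim)))
  if (length(dims) != 1) stop("matrices differ in shape", call. = FALSE)
  R <- dims[[1]][1]
  regions <- rownames(matrices_a[[1]]) %||% sprintf("r%03d", seq_len(R))
  data <- rbind(
    do.call(rbind, lapply(matrices_a, flatten_edges)),
    do.call(rbind, lapply(matrices_b, flatten_edges)))
  n_a <- length(matrices_a); n_b <- length(matrices_b)
  n <- n_a + n_b
  perms <- with_seed(seed, t(replicate(n_perm, sample.int(n, n_a))))
  if (welch) {
    res <- maxt_perm_welch(data, seq_len(n_a), perms)
  } else {
    res <- maxt_perm_cpp(data, seq_len(n_a) - 1L, perms - 1L)
  }
  t_obs <- res$t_obs
  p_fwe <- vapply(abs(t_obs),
                  function(tt) (1 + sum(res$max_t >= tt)) / (n_perm + 1),
                  numeric(1))
  structure(list(
    t_stat = unflatten_edges(t_obs, R, regions),
    p_fwe = unflatten_edges(p_fwe, R, regions) + diag(1, R),
    significant = unflatten_edges(p_fwe < alpha, R, regions) > 0,
    max_t_null = res$max_t, regions = regions, n_perm = n_perm,
    alpha = alpha, seed = seed, n_a = n_a, n_b = n_b, welch = welch),
    class = "edge_comparison")
}

# R fallback implementing the Welch variant of the max-T scheme
maxt_perm_welch <- function(data, ga, perms) {
  welch_t <- function(idx_a) {
    a <- data[idx_a, , drop = FALSE]
    b <- data[-idx_a, , drop = FALSE]
    va <- apply(a, 2, stats::var) / nrow(a)
    vb <- apply(b, 2, stats::var) / nrow(b)
    (colMeans(a) - colMeans(b)) / sqrt(va + vb)
  }
  t_obs <- welch_t(ga)
  max_t <- apply(perms, 1, function(p) max(abs(welch_t(p))))
  list(t_obs = t_obs, max_t = max_t)
}

#' @export
print.edge_comparison <- function(x, ...) {
  n_sig <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf(
    "<edge_comparison> %d regions, %d vs %d subjects, %d perms: %d significant edges (alpha=%g)\n",
    length(x$regions), x$n_a, x$n_b, x$n_perm, n_sig, x$alpha))
  invisible(x)
}

#' Direction proportions among significant edges
#'
#' Among the significant edges, the percentage with a positive t statistic
#' (stronger in group A) and with a negative one (stronger in group B).
#' With no significant edges the result is an empty tibble, not an error.
#'
#' @param cmp an `edge_comparison`.
#' @return tibble with `n_significant`, `pct_stronger_a`, `pct_stronger_b`
#'   (percentages summing to 100), or a zero-row tibble.
#' @export
direction_proportions <- function(cmp) {
  stopifnot(inherits(cmp, "edge_comparison"))
  up <- upper.tri(cmp$significant)
  sig_t <- cmp$t_stat[up][cmp$significant[up]]
  if (length(sig_t) == 0)
    return(tibble(n_significant = integer(0), pct_stronger_a = numeric(0),
                  pct_stronger_b = numeric(0)))
  tibble(n_significant = length(sig_t),
         pct_stronger_a = 100 * mean(sig_t > 0),
         pct_stronger_b = 100 * mean(sig_t < 0))
}

#' Per-region degree of significant group differences
#'
#' Degree counts, per region, the edges whose connectivity differs
#' significantly between groups (regardless of direction): the row sums of
#' the symmetric significance mask.
#'
#' @param cmp an `edge_comparison`.
#' @return tibble with `region`, `degree`.
#' @export
degree_from_significance <- function(cmp) {
  stopifnot(inherits(cmp, "edge_comparison"))
  tibble(region = cmp$regions, degree = as.integer(rowSums(cmp$significant)))
}

#' Eigenvector centrality of a connectivity matrix
#'
#' Leading eigenvector of a symmetric nonnegative connectivity matrix
#' (Perron-Frobenius), unit Euclidean norm, oriented nonnegative. Captures
#' how much a region participates in whole-brain communication.
#'
#' @param m symmetric nonnegative region x region matrix with zero diagonal.
#' @return named per-region numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(m) {
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("matrix must be symmetric", call. = FALSE)
  if (any(m < 0)) stop("matrix must be nonnegative", call. = FALSE)
  if (all(m == 0)) stop("all-zero matrix has no centrality", call. = FALSE)
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)                      # clip fp negatives; Perron vector >= 0
  v <- v / sqrt(sum(v^2))
  names(v) <- rownames(m)
  v
}

#' Group difference in mean eigenvector centrality
#'
#' Per region, the mean eigenvector centrality over group A's subjects minus
#' the mean over group B's (with the healthy-control group as A this is the
#' HC - MD orientation; the orientation is recorded in the result).
#'
#' @param ec_a,ec_b subjects x regions matrices (or lists of per-subject
#'   vectors) of eigenvector centralities.
#' @return tibble with `region`, `ec_mean_a`, `ec_mean_b`, `ec_difference`.
#' @export
ec_group_difference <- function(ec_a, ec_b) {
  as_mat <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  a <- as_mat(ec_a); b <- as_mat(ec_b)
  if (ncol(a) != ncol(b)) stop("region counts differ", call. = FALSE)
  out <- tibble(region = colnames(a) %||% sprintf("r%03d", seq_len(ncol(a))),
                ec_mean_a = unname(colMeans(a)),
                ec_mean_b = unname(colMeans(b)))
  out$ec_difference <- out$ec_mean_a - out$ec_mean_b
  attr(out, "orientation") <- "A - B"
  out
}

#' Cohen's d (pooled)
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' usual n-1-weighted pooled standard deviation.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return numeric scalar.
#' @export
cohens_d <- function(sample_a, sample_b) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 values", call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(sample_a) +
              (n2 - 1) * stats::var(sample_b)) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean(sample_a) - mean(sample_b)) / sp
}

#' Aggregate significant edges by network pair
#'
#' Counts significant edges between (and within) functional networks, split
#' by direction — the summary behind circle-plot figures. Regions with
#' overlapping membership contribute to each of their networks.
#'
#' @param cmp an `edge_comparison`.
#' @param partition region-network membership tibble.
#' @return tibble with `network_a`, `network_b`, `n_stronger_a`,
#'   `n_stronger_b`.
#' @export
network_pair_summary <- function(cmp, partition) {
  stopifnot(inherits(cmp, "edge_comparison"))
  idx <- edge_index(length(cmp$regions))
  up <- cmp$significant[upper.tri(cmp$significant)]
  tvals <- cmp$t_stat[upper.tri(cmp$t_stat)]
  keep <- which(up)
  if (length(keep) == 0)
    return(tibble(network_a = character(0), network_b = character(0),
                  n_stronger_a = integer(0), n_stronger_b = integer(0)))
  nets_of <- split(partition$network, partition$region)
  rows <- purrr::map_dfr(keep, function(k) {
    ra <- cmp$regions[idx[k, 1]]; rb <- cmp$regions[idx[k, 2]]
    combos <- expand.grid(na = nets_of[[ra]], nb = nets_of[[rb]],
                          stringsAsFactors = FALSE)
    pair <- t(apply(combos, 1, sort))
    tibble(network_a = pair[, 1], network_b = pair[, 2],
           stronger_a = tvals[k] > 0)
  })
  dplyr::summarise(dplyr::group_by(rows, .data$network_a, .data$network_b),
                   n_stronger_a = sum(.data$stronger_a),
                   n_stronger_b = sum(!.data$stronger_a), .groups = "drop")
}
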
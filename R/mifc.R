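#' Z-score regional timeseries
#'
#' Centres each region's timeseries to mean 0 and scales to unit sample
#' standard deviation (denominator n - 1).
#'
#' @param ts a `regional_timeseries` or a volumes x regions matrix.
#' @return the same type of object, z-scored per region.
#' @export
zscore_timeseries <- function(ts) {
  x <- timeseries_matrix(ts)
  if (nrow(x) < 2) stop("need at least 2 volumes", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z <- scale(x, center = TRUE, scale = sds)
  attributes(z)[c("scaled:center", "scaled:scale")] <- NULL
  replace_timeseries_matrix(ts, z)
}

timeseries_matrix <- function(ts) {
  if (inherits(ts, "regional_timeseries")) ts$data
  else if (is.matrix(ts)) ts
  else stop("expected a matrix or regional_timeseries", call. = FALSE)
}

replace_timeseries_matrix <- function(ts, x) {
  if (inherits(ts, "regional_timeseries")) { ts$data <- x; ts } else x
}

# equiprobable (quantile) binning: average-tie ranks cut into n_bins
# rank-quantile bins; deterministic, invariant under strictly monotone maps
quantile_bin_codes <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  code <- ceiling(n_bins * r / n)
  as.integer(pmin(pmax(code, 1L), n_bins)) - 1L   # 0-based for the backend
}

#' Plug-in mutual information between two sample vectors
#'
#' Histogram (plug-in) estimate of mutual information in bits,
#' `I = sum p(i,j) log2[p(i,j) / (p(i) p(j))]`, on an equiprobable
#' (quantile) binning of each marginal into `n_bins` bins. Symmetric in its
#' arguments and nonnegative. Quantile binning makes the estimate invariant
#' under strictly monotone transforms of either input. The plug-in estimator
#' has an upward bias of roughly `(n_bins - 1)^2 / (2 T ln 2)` bits for
#' independent inputs of length `T`.
#'
#' @param x,y numeric vectors of equal length (>= 8), no missing values.
#' @param n_bins number of quantile bins (>= 2), default 8.
#' @return mutual information in bits.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(5000)
#' mutual_information(x, x)           # = log2(8): the binned marginal entropy
#' mutual_information(x, rnorm(5000)) # near 0
mutual_information <- function(x, y, n_bins = 8) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 8) stop("need at least 8 samples", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs contain missing or non-finite values", call. = FALSE)
  codes <- cbind(quantile_bin_codes(x, n_bins), quantile_bin_codes(y, n_bins))
  mi_allpairs_cpp(codes, as.integer(n_bins))[1, 2]
}

#' Pairwise mutual-information functional connectivity matrix
#'
#' Computes the symmetric region x region miFC matrix (bits) over a whole
#' acquisition or over a restricted volume set (a task condition's volumes).
#' The (restricted) segment is z-scored per region before estimation, then
#' each pair's mutual information is estimated with the plug-in quantile-bin
#' estimator. Diagonal is fixed at 0 by convention.
#'
#' @param ts a `regional_timeseries` or volumes x regions matrix.
#' @param volume_indices optional 1-based volume indices restricting the
#'   estimate to a condition's volumes; `NULL` uses all volumes.
#' @param n_bins quantile bins per marginal.
#' @param min_volumes estimator floor: minimum volumes required
#'   (default `8 * n_bins`).
#' @return region x region matrix with attributes `n_volumes_used`,
#'   `n_bins`.
#' @seealso [mutual_information()], [contrast_mifc()], [select_volumes()]
#' @export
mifc_matrix <- function(ts, volume_indices = NULL, n_bins = 8,
                        min_volumes = 8 * n_bins) {
  x <- timeseries_matrix(ts)
  if (!is.null(volume_indices)) {
    if (any(volume_indices < 1 | volume_indices > nrow(x)))
      stop("volume indices out of range", call. = FALSE)
    x <- x[volume_indices, , drop = FALSE]
  }
  if (nrow(x) < min_volumes)
    stop(sprintf("%d volumes available but the estimator floor is %d",
                 nrow(x), min_volumes), call. = FALSE)
  x <- zscore_timeseries(x)
  codes <- apply(x, 2, quantile_bin_codes, n_bins = n_bins)
  m <- mi_allpairs_cpp(codes, as.integer(n_bins))
  dimnames(m) <- list(colnames(x), colnames(x))
  attr(m, "n_volumes_used") <- nrow(x)
  attr(m, "n_bins") <- n_bins
  m
}

#' Condition-versus-neutral miFC contrast matrix
#'
#' Entrywise difference of two condition-restricted miFC matrices from the
#' same subject's timeseries, e.g. drug cues minus neutral cues or reward
#' minus neutral anticipation. May be negative.
#'
#' @inheritParams mifc_matrix
#' @param indices_a,indices_b volume-index sets for the two conditions.
#' @return region x region symmetric contrast matrix (bits).
#' @export
contrast_mifc <- function(ts, indices_a, indices_b, n_bins = 8,
                          min_volumes = 8 * n_bins) {
  a <- mifc_matrix(ts, indices_a, n_bins, min_volumes)
  b <- mifc_matrix(ts, indices_b, n_bins, min_volumes)
  out <- a - b
  attr(out, "n_volumes_used") <- c(attr(a, "n_volumes_used"),
                                   attr(b, "n_volumes_used"))
  attr(out, "n_bins") <- n_bins
  out
}

#' Write / read an miFC matrix as TSV with a JSON sidecar
#'
#' Matrices are serialized with a region-ID header row and column; estimator
#' parameters go to `<path>.json`.
#'
#' @param m matrix from [mifc_matrix()] or [contrast_mifc()].
#' @param path TSV path.
#' @return `path`, invisibly (`write_mifc`); the matrix (`read_mifc`).
#' @export
write_mifc <- function(m, path) {
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n_volumes_used = attr(m, "n_volumes_used"),
               n_bins = attr(m, "n_bins"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mifc
#' @export
read_mifc <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(m, "n_volumes_used") <- meta$n_volumes_used
    attr(m, "n_bins") <- meta$n_bins
  }
  m
}
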
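#' Tidy an edge comparison into a per-edge tibble
#'
#' @param x an `edge_comparison`.
#' @param significant_only keep only significant edges.
#' @param ... unused.
#' @return tibble with `region_a`, `region_b`, `t_stat`, `p_fwe`,
#'   `significant`.
#' @export
tidy.edge_comparison <- function(x, significant_only = FALSE, ...) {
  idx <- edge_index(length(x$regions))
  up <- upper.tri(x$t_stat)
  out <- tibble(region_a = x$regions[idx[, 1]],
                region_b = x$regions[idx[, 2]],
                t_stat = x$t_stat[up], p_fwe = x$p_fwe[up],
                significant = x$significant[up])
  if (significant_only) out <- out[out$significant, ]
  out
}

#' One-row summary of an edge comparison
#'
#' @param x an `edge_comparison`.
#' @param ... unused.
#' @return tibble with edge counts, direction split and test settings.
#' @export
glance.edge_comparison <- function(x, ...) {
  up <- upper.tri(x$significant)
  sig_t <- x$t_stat[up][x$significant[up]]
  tibble(n_edges = sum(up), n_significant = length(sig_t),
         pct_stronger_a = if (length(sig_t)) 100 * mean(sig_t > 0) else NA_real_,
         pct_stronger_b = if (length(sig_t)) 100 * mean(sig_t < 0) else NA_real_,
         n_perm = x$n_perm, alpha = x$alpha, n_a = x$n_a, n_b = x$n_b)
}

#' Tidy a PLS fit into a per-component tibble
#'
#' @param x a `pls_fit`.
#' @param ... unused.
#' @return tibble with `component`, `cov_share`, `y_var_share` and one
#'   weight column per predictor.
#' @export
tidy.pls_fit <- function(x, ...) {
  out <- tibble(component = seq_len(x$n_components),
                cov_share = x$cov_share, y_var_share = x$y_var_share)
  dplyr::bind_cols(out, as_tibble(t(x$weights),
                                  .name_repair = ~paste0("w_", .x)))
}

#' One-row summary of a PLS fit
#'
#' @param x a `pls_fit`.
#' @param ... unused.
#' @return tibble with dimensions, leading covariance share and top VIP.
#' @export
glance.pls_fit <- function(x, ...) {
  tibble(n_regions = length(x$regions), n_predictors = length(x$predictors),
         n_responses = length(x$responses), n_components = x$n_components,
         cov_share_1 = x$cov_share[1],
         top_vip_predictor = names(which.max(x$vip)),
         top_vip = max(x$vip))
}

#' Tidy a state timeseries into a per-volume tibble
#'
#' @param x a `state_timeseries`.
#' @param ... unused.
#' @return tibble with `volume`, `time`, `state`, `coherence` (the winning
#'   template's mean coherence), `tie`.
#' @export
tidy.state_timeseries <- function(x, ...) {
  v <- seq_along(x$labels)
  tibble(volume = v,
         time = (v - 1) * (if (is.na(x$tr)) 1 else x$tr),
         state = x$labels,
         coherence = x$coherence[cbind(v, as.integer(x$labels))],
         tie = v %in% x$ties)
}

#' Plot the significant-edge t-statistic matrix
#'
#' Heatmap of per-edge t statistics, masking non-significant edges.
#'
#' @param object an `edge_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.edge_comparison <- function(object, ...) {
  df <- tidy(object)
  df$t_masked <- ifelse(df$significant, df$t_stat, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_a, y = .data$region_b,
                                   fill = .data$t_masked)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  na.value = "grey95",
                                  name = "t (A - B)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d significant edges (max-T, alpha = %g)",
                                  sum(df$significant), object$alpha)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot PLS component shares and VIP scores
#'
#' @param object a `pls_fit`.
#' @param ... unused.
#' @return a ggplot (percent covariance per component, VIP per predictor).
#' @export
autoplot.pls_fit <- function(object, ...) {
  comp <- tibble(panel = "% covariance",
                 x = paste0("LV", seq_len(object$n_components)),
                 y = 100 * object$cov_share)
  vips <- tibble(panel = "VIP", x = names(object$vip), y = object$vip)
  df <- dplyr::bind_rows(comp, vips)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::geom_hline(data = tibble(panel = "VIP", yint = 1),
                        ggplot2::aes(yintercept = .data$yint),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a state sequence
#'
#' @param object a `state_timeseries`.
#' @param ... unused.
#' @return a ggplot of the network label over time.
#' @export
autoplot.state_timeseries <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$state)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of an miFC or contrast matrix
#'
#' @param m region x region matrix from [mifc_matrix()] or
#'   [contrast_mifc()].
#' @return a ggplot.
#' @export
plot_mifc <- function(m) {
  df <- as_tibble(as.data.frame.table(m, responseName = "mi"))
  names(df)[1:2] <- c("region_a", "region_b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_a, y = .data$region_b,
                                   fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "bits") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
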
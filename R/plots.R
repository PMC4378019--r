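#' Tidiers for duetseq result objects
#'
#' Broom-style [generics::tidy()] and [generics::glance()] methods:
#' `tidy.expression_set()` returns long per-sample expression,
#' `tidy.moderated_fit()` the per-gene cell means, `glance.moderated_fit()`
#' the fit dimensions and empirical-Bayes hyperparameters, and
#' `tidy.fpca_result()` the variance-explained table.
#'
#' @param x A duetseq result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.duetseq
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Volcano plot of a DEG table
#'
#' @param deg_table Tibble from [call_degs()].
#' @param fc_threshold,q_threshold Thresholds drawn as guides.
#' @return A ggplot.
#' @export
plot_volcano <- function(deg_table, fc_threshold = 1, q_threshold = 0.01) {
  ggplot2::ggplot(deg_table,
                  ggplot2::aes(x = .data$log2FC, y = -log10(.data$q),
                               colour = .data$is_DEG)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 fold-change (mutant - WT)",
                  y = "-log10 q-value", colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Cluster sizes from a classified allocation
#'
#' @param labels Tibble from [classify_clusters()].
#' @return A ggplot.
#' @export
plot_allocation_clusters <- function(labels) {
  counts <- dplyr::count(labels, .data$cluster)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$cluster, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_allocation_clusters
#' @param object An `allocation_fit`.
#' @param ... Passed on.
#' @export
autoplot.allocation_fit <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("beta_F", "beta_S", "beta_FS"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::mutate(term = factor(.data$term,
                                levels = c("beta_F", "beta_S", "beta_FS")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey90") +
    ggplot2::labs(x = NULL, y = "allocation coefficient (log2)") +
    ggplot2::theme_minimal()
}

#' Scree plot of a functional PCA
#'
#' @param object An `fpca_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fpca_result <- function(object, ...) {
  d <- tidy.fpca_result(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = .data$var_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "black") +
    ggplot2::labs(x = "component", y = "variance explained") +
    ggplot2::theme_minimal()
}

#' Heatmap of summit-centred profiles
#'
#' Rows ordered (and masked) per [heatmap_order()].
#'
#' @param mat Regions x bins matrix (reads per million).
#' @param ordering Optional result of [heatmap_order()].
#' @return A ggplot.
#' @export
plot_profile_heatmap <- function(mat, ordering = NULL) {
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  keep <- if (is.null(ordering)) ids else ordering$order
  sub <- mat[keep, , drop = FALSE]
  colnames(sub) <- sprintf("bin%03d", seq_len(ncol(sub)))
  d <- tibble::as_tibble(sub, rownames = "region") |>
    tidyr::pivot_longer(-"region", names_to = "bin", values_to = "value") |>
    dplyr::mutate(bin = as.integer(factor(.data$bin,
                                          levels = unique(.data$bin))),
                  region = factor(.data$region, levels = rev(keep)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$region,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "profile bin", y = NULL, fill = "RPM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Bar plot of permutation enrichment Z-scores
#'
#' @param enrichment Row-bound tibbles from [permutation_enrichment()] or
#'   [cooccurrence()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  id_col <- if ("motif_id" %in% names(enrichment)) "motif_id" else "motifs"
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data[[id_col]], y = .data$z,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 3, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "permutation Z-score") +
    ggplot2::theme_minimal()
}

#' Histogram of nearest motif-to-motif distances
#'
#' @param hist Tibble from [distance_histogram()].
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_start + 25,
                                     y = .data$n)) +
    ggplot2::geom_col(width = 45, fill = "steelblue") +
    ggplot2::labs(x = "nearest distance (bp)", y = "motif pairs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
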
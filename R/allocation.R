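#' Decompose expression into single-factor and complex contributions
#'
#' Signal-allocation analysis over the 2x2 genetic design. With presence
#' indicators `f` (functional FLC) and `s` (functional SVP) and the model
#' `y = b0 + bF*f + bS*s + bFS*f*s` (baseline = double mutant), the terms
#' are closed-form contrasts of the genotype cell means:
#' `bF = mean(svp) - mean(flc_svp)`, `bS = mean(flc) - mean(flc_svp)`,
#' `bFS = mean(WT) - mean(flc) - mean(svp) + mean(flc_svp)`.
#' A negative presence coefficient means the factor (or complex) represses
#' the gene. Standard errors and p-values use the moderated variance of the
#' underlying fit.
#'
#' @param fit A `moderated_fit` from [fit_linear_model()] covering all four
#'   genotypes (`WT`, `flc`, `svp`, `flc_svp`).
#' @param tissue,condition Design cell selectors.
#' @return An `allocation_fit` tibble: gene_id, beta_F, se_F, p_F, beta_S,
#'   se_S, p_S, beta_FS, se_FS, p_FS.
#' @export
fit_allocation <- function(fit, tissue = "leaf", condition = "SD") {
  stopifnot(inherits(fit, "moderated_fit"))
  need <- c("WT", "flc", "svp", "flc_svp")
  missing <- setdiff(need, unique(fit$cells$genotype))
  if (length(missing)) {
    stop("missing genotype(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(fit$s2_post)) fit <- ebayes_moderate(fit)
  cl <- vapply(need, function(g) cell_label(fit, g, tissue, condition),
               character(1))
  contrasts <- list(
    F = setNames(c(1, -1), cl[c("svp", "flc_svp")]),
    S = setNames(c(1, -1), cl[c("flc", "flc_svp")]),
    FS = setNames(c(1, -1, -1, 1), cl[c("WT", "flc", "svp", "flc_svp")])
  )
  out <- purrr::imap(contrasts, function(ct, nm) {
    st <- contrast_stats(fit, ct)
    setNames(st[, c("estimate", "se", "p")],
             paste0(c("beta_", "se_", "p_"), nm))
  })
  res <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(fit$all_coefficients)), out$F, out$S,
    out$FS)
  attr(res, "tissue") <- tissue
  attr(res, "condition") <- condition
  class(res) <- c("allocation_fit", class(res))
  res
}

#' Filter genes for the allocation analysis
#'
#' Keeps genes up-regulated (DEG, direction up) in at least one mutant
#' versus WT, and excludes genes whose expression change is larger in a
#' single mutant than in the double mutant (beyond one pooled standard
#' error of the difference), because such patterns cannot be explained by
#' repression through the two factors and their complex alone.
#'
#' @param deg_flc,deg_svp,deg_double DEG tables from [call_degs()] for the
#'   `flc`, `svp` and `flc_svp` contrasts against WT (same tissue and
#'   condition).
#' @param fit The `moderated_fit` the DEG tables came from (for the pooled
#'   SE of the single-minus-double difference).
#' @param margin_multiplier Multiplier on the pooled SE margin.
#' @param margin Optional fixed margin (log2 units) replacing the SE-based
#'   one; `fit` may then be omitted.
#' @return Tibble: gene_id, keep (logical), reason (`kept`,
#'   `excluded_not_up`, `excluded_single_exceeds_double`).
#' @export
filter_genes <- function(deg_flc, deg_svp, deg_double, fit = NULL,
                         margin_multiplier = 1, margin = NULL) {
  tissue <- deg_double$tissue[1]
  condition <- deg_double$condition[1]
  if (is.null(margin)) {
    stopifnot(inherits(fit, "moderated_fit"))
    if (is.null(fit$s2_post)) fit <- ebayes_moderate(fit)
    cl <- vapply(c("flc", "svp", "flc_svp"),
                 function(g) cell_label(fit, g, tissue, condition),
                 character(1))
    se_fd <- contrast_stats(fit,
                            setNames(c(1, -1), cl[c("flc", "flc_svp")]))$se
    se_sd <- contrast_stats(fit,
                            setNames(c(1, -1), cl[c("svp", "flc_svp")]))$se
  } else {
    se_fd <- se_sd <- margin / max(margin_multiplier, 1e-12)
  }

  up <- function(d) d$is_DEG & d$direction == "up"
  stopifnot(identical(deg_flc$gene_id, deg_double$gene_id),
            identical(deg_svp$gene_id, deg_double$gene_id))
  any_up <- up(deg_flc) | up(deg_svp) | up(deg_double)
  exceeds <- (deg_flc$log2FC > deg_double$log2FC + margin_multiplier * se_fd) |
    (deg_svp$log2FC > deg_double$log2FC + margin_multiplier * se_sd)
  tibble::tibble(
    gene_id = deg_double$gene_id,
    keep = any_up & !exceeds,
    reason = dplyr::case_when(
      !any_up ~ "excluded_not_up",
      exceeds ~ "excluded_single_exceeds_double",
      TRUE ~ "kept"
    )
  )
}

#' Classify genes into regulatory clusters
#'
#' Applies coefficient significance (moderated p, BH-adjusted within each
#' coefficient across genes, threshold `alpha`) with precedence D, B, C, A:
#' `D_complex` (interaction significant and negative), `B_compensatory`
#' (interaction significant positive with both single terms significant
#' negative), `C_additive` (both single terms significant negative, no
#' interaction), `A_FLC_only` / `A_SVP_only` (only one single term,
#' negative), else `unclassified`. Genes excluded by [filter_genes()] carry
#' their exclusion reason as label.
#'
#' @param alloc An `allocation_fit` from [fit_allocation()].
#' @param filter Optional filter tibble from [filter_genes()].
#' @param alpha Significance level on BH-adjusted coefficient p-values.
#' @return Tibble: gene_id, cluster, plus the adjusted p-values
#'   (`padj_F`, `padj_S`, `padj_FS`).
#' @export
classify_clusters <- function(alloc, filter = NULL, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  res <- alloc |>
    dplyr::mutate(
      padj_F = p.adjust(.data$p_F, "BH"),
      padj_S = p.adjust(.data$p_S, "BH"),
      padj_FS = p.adjust(.data$p_FS, "BH"),
      sig_F = .data$padj_F < alpha,
      sig_S = .data$padj_S < alpha,
      sig_FS = .data$padj_FS < alpha,
      cluster = dplyr::case_when(
        sig_FS & beta_FS < 0 ~ "D_complex",
        sig_FS & beta_FS > 0 & sig_F & beta_F < 0 & sig_S & beta_S < 0 ~
          "B_compensatory",
        sig_F & beta_F < 0 & sig_S & beta_S < 0 & !sig_FS ~ "C_additive",
        sig_F & beta_F < 0 & !sig_S & !sig_FS ~ "A_FLC_only",
        sig_S & beta_S < 0 & !sig_F & !sig_FS ~ "A_SVP_only",
        TRUE ~ "unclassified"
      )
    )
  if (!is.null(filter)) {
    res <- res |>
      dplyr::left_join(dplyr::select(filter, "gene_id", "keep", "reason"),
                       by = "gene_id") |>
      dplyr::mutate(cluster = dplyr::if_else(.data$keep, .data$cluster,
                                             .data$reason)) |>
      dplyr::select(-"keep", -"reason")
    }
  dplyr::select(res, "gene_id", "cluster", "beta_F", "beta_S", "beta_FS",
                "padj_F", "padj_S", "padj_FS")
}

#' Compare recovered clusters with planted regulatory modes
#'
#' @param truth Truth tibble with `gene_id` and `mode` (from
#'   [simulate_expression()]).
#' @param labels Tibble with `gene_id` and `cluster` from
#'   [classify_clusters()].
#' @return An `allocation_recovery` list: `confusion` (mode x cluster
#'   counts), `per_mode` (precision/recall per planted mode over all planted
#'   genes), `accuracy` (fraction of analysed, i.e. non-excluded, genes whose
#'   cluster matches the planted mode) and `n_analysed`.
#' @export
allocation_recovery <- function(truth, labels) {
  if (!all(labels$gene_id %in% truth$gene_id)) {
    stop("gene ids in labels not covered by truth", call. = FALSE)
  }
  expected <- c(FLC_only = "A_FLC_only", SVP_only = "A_SVP_only",
                additive = "C_additive", compensatory = "B_compensatory",
                complex = "D_complex", null = "none")
  j <- dplyr::inner_join(truth[, c("gene_id", "mode")],
                         labels[, c("gene_id", "cluster")], by = "gene_id") |>
    dplyr::mutate(expected = expected[.data$mode],
                  analysed = !.data$cluster %in%
                    c("excluded_not_up", "excluded_single_exceeds_double"))
  confusion <- j |> dplyr::count(.data$mode, .data$cluster) |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "n",
                       values_fill = 0L)
  analysed <- dplyr::filter(j, .data$analysed)
  accuracy <- if (nrow(analysed)) {
    mean(analysed$cluster == analysed$expected |
           (analysed$expected == "none" &
              analysed$cluster == "unclassified"))
  } else {
    NA_real_
  }
  per_mode <- j |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(
      n = dplyr::n(),
      recall = mean(.data$cluster == .data$expected |
                      (.data$expected == "none" & !.data$analysed) |
                      (.data$expected == "none" &
                         .data$cluster == "unclassified")),
      .groups = "drop")
  precision <- j |>
    dplyr::filter(.data$cluster %in% expected) |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(precision = mean(.data$cluster == .data$expected),
                     .groups = "drop")
  structure(list(confusion = confusion, per_mode = per_mode,
                 precision = precision, accuracy = accuracy,
                 n_analysed = nrow(analysed)),
            class = "allocation_recovery")
}

#' @export
print.allocation_recovery <- function(x, ...) {
  cat("<allocation_recovery> accuracy", round(x$accuracy, 3), "over",
      x$n_analysed, "analysed genes\n")
  print(x$confusion)
  invisible(x)
}
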
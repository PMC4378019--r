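#' Two-set overlap counts
#'
#' @param set_a,set_b Character vectors of gene (or region) ids.
#' @param labels Length-2 labels for the two sets.
#' @return Tibble (`venn_counts`): label_a, label_b, only_a, shared,
#'   only_b.
#' @export
venn_counts <- function(set_a, set_b, labels = c("A", "B")) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  tibble::tibble(label_a = labels[1], label_b = labels[2],
                 only_a = length(a) - shared, shared = shared,
                 only_b = length(b) - shared)
}

#' Shared percentages of each set
#'
#' @param counts A `venn_counts` tibble.
#' @return Tibble: pct_of_a, pct_of_b (rounded integer percentages of each
#'   set that is shared).
#' @export
shared_fraction <- function(counts) {
  size_a <- counts$only_a + counts$shared
  size_b <- counts$only_b + counts$shared
  if (size_a == 0 || size_b == 0) stop("empty set", call. = FALSE)
  tibble::tibble(pct_of_a = round(100 * counts$shared / size_a),
                 pct_of_b = round(100 * counts$shared / size_b))
}

#' Complex-dependency gene sets
#'
#' Derives, from the dependency-classified target-gene sets of the two
#' TFs: `complex_enriched` = union of the two `2TF` gene sets (genes bound
#' only when both factors are present, for either TF); `complex_exclusive`
#' = intersection of the two `2TF` sets; `independent` = genes in both
#' `1TF` sets (bound by each factor alone).
#'
#' @param svp_2tf,flc_2tf,svp_1tf,flc_1tf Character vectors of gene ids.
#' @return List of three character vectors with a `provenance` tibble
#'   attribute (gene, set, source).
#' @export
dependency_sets <- function(svp_2tf, flc_2tf, svp_1tf = character(),
                            flc_1tf = character()) {
  enriched <- union(svp_2tf, flc_2tf)
  exclusive <- intersect(svp_2tf, flc_2tf)
  independent <- intersect(svp_1tf, flc_1tf)
  prov <- dplyr::bind_rows(
    tibble::tibble(gene = enriched, set = "complex_enriched",
                   source = dplyr::case_when(
                     enriched %in% svp_2tf & enriched %in% flc_2tf ~ "both",
                     enriched %in% svp_2tf ~ "SVP_2TF",
                     TRUE ~ "FLC_2TF")),
    tibble::tibble(gene = exclusive, set = "complex_exclusive",
                   source = "both"),
    tibble::tibble(gene = independent, set = "independent", source = "both")
  )
  structure(list(complex_enriched = enriched,
                 complex_exclusive = exclusive,
                 independent = independent),
            provenance = prov)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with optional Yates continuity correction (default
#' on), df = 1. Without correction the statistic equals the squared
#' two-proportion z-statistic.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param correct Apply the Yates continuity correction.
#' @return Tibble: statistic, df, p, correct.
#' @export
chisq_2x2 <- function(table, correct = TRUE) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  if (all(table == table[1, 1])) {
    # uniform table: expected == observed, chi-square exactly 0
    return(tibble::tibble(statistic = 0, df = 1L, p = 1, correct = correct))
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic), df = 1L,
                 p = unname(ct$p.value), correct = correct)
}

#' Proportion of DEGs that are direct targets
#'
#' For every contrast x tissue x direction stratum of a DEG table, the
#' percentage of differentially expressed genes present in a TF's
#' target-gene list.
#'
#' @param deg_table A DEG table (or row-bound tables) from [call_degs()].
#' @param targets Named list of character vectors of target gene ids, one
#'   per TF.
#' @return Tibble: tf, contrast, tissue, direction, n_degs, n_targets,
#'   pct (rounded integer).
#' @export
direct_target_report <- function(deg_table, targets) {
  stopifnot(is.list(targets), !is.null(names(targets)))
  degs <- dplyr::filter(deg_table, .data$is_DEG)
  purrr::imap_dfr(targets, function(tg, tf) {
    degs |>
      dplyr::group_by(.data$contrast, .data$tissue, .data$direction) |>
      dplyr::summarise(
        n_degs = dplyr::n(),
        n_targets = sum(.data$gene_id %in% tg),
        pct = round(100 * sum(.data$gene_id %in% tg) / dplyr::n()),
        .groups = "drop") |>
      dplyr::mutate(tf = tf) |>
      dplyr::select("tf", dplyr::everything())
  })
}
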
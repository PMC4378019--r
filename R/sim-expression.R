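#' Simulate a factorial mutant expression experiment
#'
#' Generates log2 expression for a 4-genotype (WT, flc, svp, flc_svp) x
#' 2-tissue (leaf, apex) x replicate design under the 2x2 presence-indicator
#' model used by the allocation analysis: with `f` and `s` indicating a
#' functional FLC / SVP allele, the cell mean of a gene is
#' `b0 + bF*f + bS*s + bFS*f*s`. Planted regulatory modes set the
#' coefficients (with `e = effect_size`):
#' FLC_only `(-e, 0, 0)`, SVP_only `(0, -e, 0)`, additive `(-e, -e, 0)`,
#' compensatory `(-e, -e, +e)`, complex `(0, 0, -e)`, null `(0, 0, 0)`.
#' A negative presence coefficient therefore means the factor represses the
#' gene. Gaussian observation noise (`noise_sd`) and a per-replicate offset
#' shared across genes, genotypes and tissues (`replicate_effect_sd`) are
#' added; planted effects are identical in both tissues.
#'
#' @param config A [sim_config()].
#' @return An `expression_set` list: `values` (genes x samples matrix of
#'   log2 expression), `sample_meta` (tibble: sample_id, genotype, tissue,
#'   condition, replicate) and `truth` (tibble: gene_id, mode, beta_F,
#'   beta_S, beta_FS, baseline).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  modes <- config$expr_modes
  n_genes <- sum(modes)
  genotypes <- c("WT", "flc", "svp", "flc_svp")
  f_ind <- c(WT = 1, flc = 0, svp = 1, flc_svp = 0)   # functional FLC present
  s_ind <- c(WT = 1, flc = 1, svp = 0, flc_svp = 0)   # functional SVP present
  e <- config$effect_size
  mode_coef <- tibble::tribble(
    ~mode, ~beta_F, ~beta_S, ~beta_FS,
    "FLC_only", -e, 0, 0,
    "SVP_only", 0, -e, 0,
    "additive", -e, -e, 0,
    "compensatory", -e, -e, e,
    "complex", 0, 0, -e,
    "null", 0, 0, 0
  )

  with_stream(config$seed, "expression", {
    gene_modes <- sample(rep(names(modes), times = modes))
    truth <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      mode = gene_modes,
      baseline = rnorm(n_genes, mean = 8, sd = 1.5)
    ) |>
      dplyr::left_join(mode_coef, by = "mode")

    meta <- tidyr::expand_grid(
      genotype = genotypes, tissue = c("leaf", "apex"),
      replicate = seq_len(config$n_replicates)
    ) |>
      dplyr::mutate(condition = "SD",
                    sample_id = sprintf("%s_%s_r%d", .data$genotype,
                                        .data$tissue, .data$replicate)) |>
      dplyr::select("sample_id", "genotype", "tissue", "condition",
                    "replicate")

    # one offset per biological replicate, shared across genotypes, tissues
    # and genes: the R_r term of the fitted model
    rep_offsets <- rnorm(config$n_replicates,
                         sd = config$replicate_effect_sd)

    cell_mean <- function(g) {
      truth$baseline + truth$beta_F * f_ind[[g]] + truth$beta_S * s_ind[[g]] +
        truth$beta_FS * f_ind[[g]] * s_ind[[g]]
    }
    values <- vapply(seq_len(nrow(meta)), function(j) {
      m <- meta[j, ]
      cell_mean(m$genotype) + rep_offsets[m$replicate] +
        rnorm(n_genes, sd = config$noise_sd)
    }, numeric(n_genes))
    dimnames(values) <- list(truth$gene_id, meta$sample_id)

    structure(list(values = values, sample_meta = meta,
                   truth = dplyr::select(truth, "gene_id", "mode", "beta_F",
                                         "beta_S", "beta_FS", "baseline")),
              class = "expression_set")
  })
}

#' Assemble an expression set from a matrix and sample metadata
#'
#' @param values Numeric genes x samples matrix of log2 expression with
#'   dimnames.
#' @param sample_meta Tibble with `sample_id`, `genotype`, `tissue`,
#'   `condition`, `replicate`; `sample_id` must match `colnames(values)`.
#' @return An `expression_set`.
#' @export
expression_set <- function(values, sample_meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            identical(colnames(values), sample_meta$sample_id),
            !anyNA(sample_meta$genotype))
  structure(list(values = values, sample_meta = tibble::as_tibble(sample_meta),
                 truth = NULL),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set>", nrow(x$values), "genes x", ncol(x$values),
      "samples (", paste(unique(x$sample_meta$genotype), collapse = ", "),
      ")\n")
  invisible(x)
}

#' @rdname tidy.duetseq
#' @export
tidy.expression_set <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "log2_expr") |>
    dplyr::left_join(x$sample_meta, by = "sample_id")
}
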
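#' Simulation configuration for the synthetic study design
#'
#' Bundles every knob of the synthetic-data generator: a small genome with
#' annotated genes and planted cis-elements, replicate ChIP coverage tracks
#' containing binding regions of known genotype dependency, and a factorial
#' expression experiment over the four genotypes (WT, single mutants, double
#' mutant) with planted regulatory modes.
#'
#' The defaults emulate the study design this package models: a 4-genotype x
#' 2-tissue x 3-replicate expression layout with log2 effect size 2, and
#' triplicate ChIP samples per genotype at Arabidopsis-like GC content.
#'
#' @param seed Integer seed; every generated artefact derives its own RNG
#'   stream from `(seed, role)` so stages can be regenerated independently.
#' @param genome_length Total genome length in bp across chromosomes.
#' @param gc_content Fraction of G+C bases in `(0, 1)`.
#' @param n_chroms Number of chromosomes (genome length split evenly).
#' @param n_genes Number of non-overlapping gene models to place.
#' @param gene_length_range Length-2 bp vector, min/max gene length.
#' @param n_replicates ChIP replicates per genotype.
#' @param library_size Reads per ChIP sample; expected coverage is rescaled so
#'   each track sums to this.
#' @param background_rate Expected reads per bp of Poisson background before
#'   library rescaling.
#' @param peak_counts Named integer vector with elements `UB`, `one_TF`, `two_TF`:
#'   number of planted binding regions that are ubiquitous, mutant-only
#'   (one factor present) and WT-only (both factors present).
#' @param peak_enrichment Summit fold-enrichment of planted peaks over
#'   background.
#' @param peak_width_range Length-2 bp vector of planted peak widths.
#' @param shape_shift Fraction of UB regions whose width doubles in the
#'   mutant genotype (planted shape difference).
#' @param expr_modes Named integer vector of gene counts per planted
#'   regulatory mode: `FLC_only`, `SVP_only`, `additive`, `compensatory`,
#'   `complex`, `null`.
#' @param effect_size Planted log2 effect magnitude `e`.
#' @param noise_sd Per-observation Gaussian noise sd (log2 units).
#' @param replicate_effect_sd Sd of the shared per-replicate offset
#'   (log2 units), mirroring a biological-replicate block effect.
#'
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 50000, n_genes = 10)
#' cfg$gc_content
sim_config <- function(seed = 1L,
                       genome_length = 500000L,
                       gc_content = 0.36,
                       n_chroms = 2L,
                       n_genes = 600L,
                       gene_length_range = c(300L, 500L),
                       n_replicates = 3L,
                       library_size = 1e6,
                       background_rate = 2,
                       peak_counts = c(UB = 40L, one_TF = 30L, two_TF = 30L),
                       peak_enrichment = 20,
                       peak_width_range = c(100L, 200L),
                       shape_shift = 0.5,
                       expr_modes = c(FLC_only = 100L, SVP_only = 100L,
                                      additive = 100L, compensatory = 100L,
                                      complex = 100L, null = 100L),
                       effect_size = 2,
                       noise_sd = 0.2,
                       replicate_effect_sd = 0.1) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    n_chroms = as.integer(n_chroms),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_replicates = as.integer(n_replicates),
    library_size = library_size,
    background_rate = background_rate,
    peak_counts = peak_counts,
    peak_enrichment = peak_enrichment,
    peak_width_range = as.integer(peak_width_range),
    shape_shift = shape_shift,
    expr_modes = vapply(expr_modes, as.integer, integer(1)),
    effect_size = effect_size,
    noise_sd = noise_sd,
    replicate_effect_sd = replicate_effect_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$genome_length > 0, cfg$n_chroms >= 1,
    cfg$gc_content > 0, cfg$gc_content < 1,
    cfg$n_genes >= 0, cfg$n_replicates >= 1,
    all(cfg$peak_counts >= 0), all(cfg$expr_modes >= 0),
    cfg$shape_shift >= 0, cfg$shape_shift <= 1,
    cfg$noise_sd >= 0, cfg$replicate_effect_sd >= 0,
    length(cfg$gene_length_range) == 2,
    diff(cfg$gene_length_range) >= 0,
    length(cfg$peak_width_range) == 2,
    all(c("UB", "one_TF", "two_TF") %in% names(cfg$peak_counts)),
    all(c("FLC_only", "SVP_only", "additive", "compensatory",
          "complex", "null") %in% names(cfg$expr_modes))
  )
  # the genome must comfortably hold all requested content
  content <- sum(cfg$peak_counts) * 2 * max(cfg$peak_width_range) +
    cfg$n_genes * max(cfg$gene_length_range)
  if (cfg$genome_length < content) {
    stop("genome_length ", cfg$genome_length,
         " too small for requested genes and peaks (need >= ", content, ")",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$genome_length, "bp x",
      x$n_chroms, "chrom |", x$n_genes, "genes |",
      sum(x$peak_counts), "regions/TF |", sum(x$expr_modes), "expr genes\n")
  invisible(x)
}
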
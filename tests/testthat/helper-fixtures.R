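# Small shared configurations; every fixture is generated in code.

small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = 60000L, n_chroms = 1L,
               n_genes = 20L,
               peak_counts = c(UB = 4L, one_TF = 3L, two_TF = 3L),
               library_size = 2e5,
               expr_modes = c(FLC_only = 10L, SVP_only = 10L, additive = 10L,
                              compensatory = 10L, complex = 10L, null = 10L))
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# an expression_set with exactly prescribed genotype cell means, no noise
exact_expression <- function(means, n_reps = 3, tissue = "leaf") {
  genotypes <- names(means[[1]])
  meta <- tidyr::expand_grid(genotype = genotypes,
                             tissue = tissue,
                             replicate = seq_len(n_reps)) |>
    dplyr::mutate(condition = "SD",
                  sample_id = sprintf("%s_%s_r%d", genotype, tissue,
                                      replicate)) |>
    dplyr::select(sample_id, genotype, tissue, condition, replicate)
  values <- t(vapply(means, function(m) m[meta$genotype], numeric(nrow(meta))))
  rownames(values) <- names(means)
  colnames(values) <- meta$sample_id
  expression_set(values, meta)
}

# a coverage track with constant background and optional rectangular blocks
flat_track <- function(n_bins = 5000, lambda = NULL, counts = NULL,
                       bin = 10L, blocks = list()) {
  counts <- counts %||% if (is.null(lambda)) rep(1L, n_bins) else
    rpois(n_bins, lambda)
  for (b in blocks) {
    idx <- (b$start %/% bin + 1):(b$end %/% bin)
    counts[idx] <- b$value
  }
  coverage_track(tibble::tibble(chrom = "chr1",
                                start = seq(0L, by = bin,
                                            length.out = length(counts)),
                                end = seq(bin, by = bin,
                                          length.out = length(counts)),
                                count = counts),
                 bin_size = bin)
}

make_peaks <- function(starts, ends, chrom = "chr1", scores = NULL) {
  duetseq:::as_peak_set(tibble::tibble(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    summit = as.integer((starts + ends) %/% 2),
    score = scores %||% rep(10, length(starts))))
}
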
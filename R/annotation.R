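#' Assign peaks to genes by the promoter/downstream window rule
#'
#' A peak is assigned to every gene whose extended span it overlaps: the
#' window reaches `upstream` bp (default 3 kb) beyond the transcription
#' start site and `downstream` bp (default 1 kb) beyond the transcription
#' end site, measured in transcription direction (strand-aware). Genes with
#' at least one assigned peak form the target-gene set.
#'
#' @param peaks A `peak_set` (or tibble with chrom/start/end/summit).
#' @param genes Gene-model tibble from [simulate_genome()] (0-based
#'   half-open `start`/`end`, `strand`, `tss`, `tes`).
#' @param upstream,downstream Window extensions in bp.
#' @param mode `"overlap"` (any bp of the peak inside the window, default)
#'   or `"summit"` (summit containment).
#' @param nearest_only If `TRUE`, keep only the gene with the smallest
#'   absolute summit-to-TSS distance per peak.
#' @return Tibble: peak_id, gene_id, relation (`upstream_promoter`,
#'   `genic`, `downstream`), distance (summit to TSS, signed in
#'   transcription direction).
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream = 3000L,
                                  downstream = 1000L,
                                  mode = c("overlap", "summit"),
                                  nearest_only = FALSE) {
  mode <- match.arg(mode)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in gene models", call. = FALSE)
  }
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(peak_id = character(), gene_id = character(),
                          relation = character(), distance = integer()))
  }
  g <- genes |>
    dplyr::mutate(
      win_start = dplyr::if_else(.data$strand == "+",
                                 .data$start - upstream,
                                 .data$start - downstream),
      win_end = dplyr::if_else(.data$strand == "+",
                               .data$end + downstream,
                               .data$end + upstream)
    )
  hits <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(peaks), "peak_id", "chrom", "start",
                  "end", "summit"),
    dplyr::select(g, "gene_id", "chrom", gene_start = "start",
                  gene_end = "end", "strand", "tss", "tes", "win_start",
                  "win_end"),
    by = "chrom", relationship = "many-to-many")
  hits <- if (mode == "overlap") {
    dplyr::filter(hits, .data$start < .data$win_end,
                  .data$end > .data$win_start)
  } else {
    dplyr::filter(hits, .data$summit >= .data$win_start,
                  .data$summit < .data$win_end)
  }
  out <- hits |>
    dplyr::mutate(
      distance = dplyr::if_else(.data$strand == "+",
                                .data$summit - .data$tss,
                                .data$tss - .data$summit),
      dist_tes = dplyr::if_else(.data$strand == "+",
                                .data$summit - .data$tes,
                                .data$tes - .data$summit),
      relation = dplyr::case_when(
        distance < 0 ~ "upstream_promoter",
        dist_tes > 0 ~ "downstream",
        TRUE ~ "genic"
      )
    ) |>
    dplyr::select("peak_id", "gene_id", "relation", "distance")
  if (nearest_only) {
    out <- out |>
      dplyr::group_by(.data$peak_id) |>
      dplyr::slice_min(abs(.data$distance), n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  dplyr::arrange(out, .data$peak_id, .data$gene_id)
}

#' Target genes of a peak set
#'
#' @inheritParams assign_peaks_to_genes
#' @return Character vector of gene ids with at least one assigned peak.
#' @export
target_genes <- function(peaks, genes, upstream = 3000L, downstream = 1000L) {
  unique(assign_peaks_to_genes(peaks, genes, upstream, downstream)$gene_id)
}

#' Classify the genomic location of peak summits
#'
#' Classifies each summit with precedence
#' `proximal_promoter > 5'UTR > 3'UTR > exon > intron >
#' immediate_downstream > intergenic`, where the proximal promoter spans
#' `promoter_bp` upstream of a TSS and the immediate downstream region
#' `downstream_bp` beyond a TES (both strand-aware). No enhancer class is
#' emitted: the synthetic genome has no enhancer annotation.
#'
#' @param peaks A `peak_set`.
#' @param genes Gene models with `exons`, `utr5_*`, `utr3_*` columns.
#' @param promoter_bp,downstream_bp Window sizes in bp.
#' @return Tibble: peak_id, feature_class.
#' @export
classify_peak_location <- function(peaks, genes, promoter_bp = 3000L,
                                   downstream_bp = 1000L) {
  classes <- c("proximal_promoter", "5'UTR", "3'UTR", "exon", "intron",
               "immediate_downstream", "intergenic")
  cls <- purrr::map_chr(seq_len(nrow(peaks)), function(i) {
    s <- peaks$summit[i]
    chrom <- peaks$chrom[i]
    g <- genes[genes$chrom == chrom, ]
    if (nrow(g) == 0) return("intergenic")
    found <- "intergenic"
    rank <- function(x) match(x, classes)
    consider <- function(cur, cand) if (rank(cand) < rank(cur)) cand else cur
    for (j in seq_len(nrow(g))) {
      gj <- g[j, ]
      in_prom <- if (gj$strand == "+") {
        s >= gj$tss - promoter_bp && s < gj$tss
      } else {
        s > gj$tss && s <= gj$tss + promoter_bp
      }
      if (in_prom) found <- consider(found, "proximal_promoter")
      if (s >= gj$utr5_start && s < gj$utr5_end) found <- consider(found, "5'UTR")
      if (s >= gj$utr3_start && s < gj$utr3_end) found <- consider(found, "3'UTR")
      if (s >= gj$start && s < gj$end) {
        ex <- gj$exons[[1]]
        in_exon <- any(s >= ex$start & s < ex$end)
        found <- consider(found, if (in_exon) "exon" else "intron")
      }
      in_down <- if (gj$strand == "+") {
        s > gj$tes && s <= gj$tes + downstream_bp
      } else {
        s < gj$tes && s >= gj$tes - downstream_bp
      }
      if (in_down) found <- consider(found, "immediate_downstream")
    }
    found
  })
  tibble::tibble(peak_id = peaks$peak_id, feature_class = cls)
}

#' Distribution of summit locations over feature classes
#'
#' @param location Tibble from [classify_peak_location()].
#' @return Tibble: feature_class, n, fraction (sums to 1).
#' @export
peak_location_summary <- function(location) {
  location |>
    dplyr::count(.data$feature_class, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}
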
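#' Write the synthetic genome to FASTA
#'
#' @param truth A `genome_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(truth, path) {
  seqs <- Biostrings::DNAStringSet(as_genome_strings(truth))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Write gene models to GFF3
#'
#' Emits gene, exon and UTR features (1-based inclusive coordinates).
#'
#' @param genes Gene tibble from [simulate_genome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  feats <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    dplyr::bind_rows(
      tibble::tibble(type = "gene", start = g$start, end = g$end),
      tibble::tibble(type = "exon", start = ex$start, end = ex$end),
      tibble::tibble(type = "five_prime_UTR", start = g$utr5_start,
                     end = g$utr5_end),
      tibble::tibble(type = "three_prime_UTR", start = g$utr3_start,
                     end = g$utr3_end)
    ) |>
      dplyr::mutate(chrom = g$chrom, strand = g$strand, ID = g$gene_id)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand, type = feats$type, ID = feats$ID)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reconstructs the internal 0-based half-open gene tibble (gene span,
#' strand, TSS/TES, exons, UTRs) from gene/exon/UTR features keyed by the
#' `ID` attribute.
#'
#' @param path GFF3 file.
#' @return Gene tibble as produced by [simulate_genome()].
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$ID))
  genes <- df |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::mutate(
      tss = dplyr::if_else(.data$strand == "+", .data$start, .data$end - 1L),
      tes = dplyr::if_else(.data$strand == "+", .data$end - 1L, .data$start))
  exons <- df |> dplyr::filter(.data$type == "exon")
  utr5 <- df |> dplyr::filter(.data$type == "five_prime_UTR")
  utr3 <- df |> dplyr::filter(.data$type == "three_prime_UTR")
  genes$exons <- purrr::map(genes$gene_id, function(id) {
    e <- exons[exons$gene_id == id, c("start", "end")]
    tibble::as_tibble(e)
  })
  pick <- function(d, id, col) {
    v <- d[d$gene_id == id, ][[col]]
    if (length(v)) v[1] else NA_integer_
  }
  genes$utr5_start <- vapply(genes$gene_id, pick, integer(1), d = utr5,
                             col = "start")
  genes$utr5_end <- vapply(genes$gene_id, pick, integer(1), d = utr5,
                           col = "end")
  genes$utr3_start <- vapply(genes$gene_id, pick, integer(1), d = utr3,
                             col = "start")
  genes$utr3_end <- vapply(genes$gene_id, pick, integer(1), d = utr3,
                           col = "end")
  dplyr::select(genes, "gene_id", "chrom", "start", "end", "strand",
                "tss", "tes", "exons", "utr5_start", "utr5_end",
                "utr3_start", "utr3_end")
}

#' Write a coverage track to bedGraph
#' @param track A `coverage_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$count)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file.
#' @param bin_size Nominal bin size (inferred from the data if omitted).
#' @return A `coverage_track`.
#' @export
read_coverage_bedgraph <- function(path, bin_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bins <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    count = gr$score)
  coverage_track(bins, bin_size = bin_size %||%
                   as.integer(median(bins$end - bins$start)))
}

#' Write peaks as narrowPeak-style BED6+
#'
#' Columns: chrom, start, end, name, score, strand (`.`), summit offset
#' from start.
#'
#' @param peaks A `peak_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  readr::write_tsv(
    tibble::tibble(chrom = peaks$chrom, start = peaks$start,
                   end = peaks$end, name = peaks$peak_id,
                   score = round(peaks$score, 3), strand = ".",
                   summit_offset = peaks$summit - peaks$start),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a narrowPeak-style BED6+ peak file
#' @param path BED file from [write_peaks_bed()].
#' @return A `peak_set`.
#' @export
read_peaks_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                            "score", "strand",
                                            "summit_offset"),
                        show_col_types = FALSE)
  as_peak_set(tibble::tibble(chrom = df$chrom, start = df$start,
                             end = df$end,
                             summit = df$start + df$summit_offset,
                             score = df$score))
}

#' Write planted motif sites as BED6
#' @param motif_sites Tibble from [simulate_genome()] truth.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motifs_bed <- function(motif_sites, path) {
  readr::write_tsv(
    tibble::tibble(chrom = motif_sites$chrom, start = motif_sites$start,
                   end = motif_sites$end, name = motif_sites$motif_id,
                   score = 0, strand = motif_sites$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Write an expression set as TSV
#'
#' One row per gene; sample columns are named `genotype_tissue_rN` and the
#' condition is constant per file.
#'
#' @param expr An `expression_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(tibble::as_tibble(expr$values, rownames = "gene_id"),
                   path)
  invisible(path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#' @param path TSV file.
#' @param condition Condition label for all samples.
#' @return An `expression_set` (without truth).
#' @export
read_expression_tsv <- function(path, condition = "SD") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  values <- as.matrix(df[, -1])
  rownames(values) <- df$gene_id
  parts <- stringr::str_match(colnames(values), "^(.*)_(leaf|apex)_r(\\d+)$")
  if (anyNA(parts[, 1])) {
    stop("sample columns must be named genotype_tissue_rN", call. = FALSE)
  }
  meta <- tibble::tibble(sample_id = colnames(values),
                         genotype = parts[, 2], tissue = parts[, 3],
                         condition = condition,
                         replicate = as.integer(parts[, 4]))
  expression_set(values, meta)
}

#' Write PWMs in MEME minimal text format
#' @param pwms Named list of `pwm` objects (or a single `pwm`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$motif_id)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (p in pwms) {
    lines <- c(lines, paste("MOTIF", p$motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       p$width),
               apply(p$probs, 2, function(col) {
                 paste(sprintf("%.6f", col), collapse = " ")
               }),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read PWMs from MEME minimal text format
#' @param path MEME text file.
#' @param eps Pseudocount recorded on the rebuilt `pwm` objects.
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, eps = 0.01) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF ", lines)
  out <- list()
  for (m in motif_at) {
    id <- sub("^MOTIF\\s+", "", lines[m])
    id <- strsplit(id, "\\s+")[[1]][1]
    hdr <- grep("^letter-probability matrix", lines[(m + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[m + hdr]))
    rows <- lines[(m + hdr + 1):(m + hdr + w)]
    probs <- t(vapply(strsplit(trimws(rows), "\\s+"),
                      function(x) as.numeric(x), numeric(4)))
    obj <- structure(list(motif_id = id, width = w, probs = t(probs),
                          eps = eps,
                          background = c(A = 0.25, C = 0.25, G = 0.25,
                                         T = 0.25)),
                     class = "pwm")
    rownames(obj$probs) <- c("A", "C", "G", "T")
    out[[id]] <- obj
  }
  out
}

#' Write a complete synthetic data set to a directory
#'
#' Emits FASTA (genome), GFF3 (genes), BED6 (planted motifs), bedGraph
#' coverage per TF x genotype x replicate, and the expression TSV.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param tfs TFs to simulate coverage for.
#' @return Invisible list with the `genome_truth` and `expression_set`.
#' @export
write_simulation <- function(config, dir, tfs = c("SVP", "FLC")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_genome(config)
  write_genome_fasta(truth, file.path(dir, "genome.fa"))
  write_genes_gff3(truth$genes, file.path(dir, "genes.gff3"))
  write_motifs_bed(truth$motif_sites, file.path(dir, "motifs.bed"))
  for (tf in tfs) {
    for (gt in c("WT", "mutant")) {
      for (r in seq_len(config$n_replicates)) {
        track <- simulate_chip_coverage(truth, gt, r, tf = tf)
        write_coverage_bedgraph(
          track, file.path(dir, sprintf("%s_%s_r%d.bedGraph", tf, gt, r)))
      }
    }
  }
  expr <- simulate_expression(config)
  write_expression_tsv(expr, file.path(dir, "expression.tsv"))
  invisible(list(truth = truth, expression = expr))
}
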
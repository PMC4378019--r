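#' Generate a synthetic genome with gene models, binding regions and motifs
#'
#' Builds a random genome at the requested GC content, places non-overlapping
#' compact gene models and, for each of the two transcription factors, a set
#' of binding regions of known dependency category: `UB` (bound in both
#' genotypes), `1TF` (bound only in the mutant of the partner, i.e. when one
#' factor acts alone) and `2TF` (bound only in WT, when both factors are
#' present). Each region carries a planted CArG-box at its summit; `UB` and
#' `2TF` regions additionally carry a G-box 150 bp downstream of the
#' CArG-box, and SVP `UB`/`2TF` regions a CE-box 100 bp upstream, so motif
#' enrichment, co-occurrence and distance statistics have known truth. The
#' CArG spacer is T-biased in `1TF` regions and A-biased elsewhere.
#'
#' All coordinates are internal 0-based half-open; exporters convert.
#'
#' @param config A [sim_config()].
#' @return A `genome_truth` list with elements `sequence` (named character
#'   vector, one element per chromosome), `genes`, `regions`, `motif_sites`
#'   (tibbles) and `config`.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  chrom_len <- rep(config$genome_length %/% config$n_chroms, config$n_chroms)
  chrom_len[config$n_chroms] <- chrom_len[config$n_chroms] +
    config$genome_length %% config$n_chroms
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))

  truth <- with_stream(config$seed, "genome", {
    sequence <- vapply(chrom_len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - config$gc_content) / 2, config$gc_content / 2,
                            config$gc_content / 2, (1 - config$gc_content) / 2)),
            collapse = "")
    }, character(1))
    names(sequence) <- chroms

    # layout items: genes + binding regions for both TFs, shuffled, packed
    # sequentially with random gaps
    items <- layout_items(config)
    placed <- place_items(items, chroms, chrom_len)

    genes <- placed |>
      dplyr::filter(.data$type == "gene") |>
      dplyr::mutate(
        gene_id = sprintf("g%04d", dplyr::row_number()),
        strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
        tss = dplyr::if_else(.data$strand == "+", .data$start, .data$end - 1L),
        tes = dplyr::if_else(.data$strand == "+", .data$end - 1L, .data$start)
      ) |>
      dplyr::select("gene_id", "chrom", "start", "end", "strand",
                    "tss", "tes") |>
      add_gene_structure()

    regions <- placed |>
      dplyr::filter(.data$type == "region") |>
      dplyr::mutate(
        region_id = sprintf("%s_%s_%03d", tolower(.data$tf), .data$category,
                            dplyr::row_number()),
        summit = .data$start + (.data$end - .data$start) %/% 2L,
        width = .data$width,
        start = .data$summit - .data$width %/% 2L,
        end = .data$start + .data$width
      ) |>
      dplyr::group_by(.data$tf) |>
      dplyr::mutate(shape_shifted = .data$category == "UB" &
                      dplyr::row_number() %in%
                        which(.data$category == "UB")[seq_len(
                          round(config$shape_shift *
                                  sum(.data$category == "UB")))]) |>
      dplyr::ungroup() |>
      dplyr::select("region_id", "tf", "category", "chrom", "start", "end",
                    "summit", "width", "shape_shifted")

    motifs <- plant_motifs(regions, config)
    for (i in seq_len(nrow(motifs$sites))) {
      s <- motifs$sites[i, ]
      seq_i <- motifs$seqs[i]
      if (s$strand == "-") seq_i <- revcomp(seq_i)
      substr(sequence[[s$chrom]], s$start + 1L, s$end) <- seq_i
    }

    list(sequence = sequence, genes = genes, regions = regions,
         motif_sites = motifs$sites, config = config)
  })
  structure(truth, class = "genome_truth")
}

# reserve lengths: genes get their length, regions width + 400 bp flanks so
# doubled-width peaks and planted flanking motifs never collide
layout_items <- function(config) {
  g <- if (config$n_genes > 0) {
    tibble::tibble(
      type = "gene",
      width = sample_lengths(config$n_genes, config$gene_length_range),
      reserve = width, tf = NA_character_, category = NA_character_
    )
  } else {
    tibble::tibble(type = character(), width = integer(), reserve = integer(),
                   tf = character(), category = character())
  }
  r <- purrr::map_dfr(c("SVP", "FLC"), function(tf) {
    cats <- rep(c("UB", "1TF", "2TF"),
                times = config$peak_counts[c("UB", "one_TF", "two_TF")])
    if (length(cats) == 0) return(NULL)
    tibble::tibble(
      type = "region",
      width = sample_lengths(length(cats), config$peak_width_range),
      reserve = width + 400L, tf = tf, category = cats
    )
  })
  items <- dplyr::bind_rows(g, r)
  if (nrow(items)) items[sample.int(nrow(items)), ] else items
}

sample_lengths <- function(n, range) {
  as.integer(sample(seq(range[1], range[2]), n, replace = TRUE))
}

place_items <- function(items, chroms, chrom_len) {
  if (nrow(items) == 0) {
    return(tibble::tibble(type = character(), chrom = character(),
                          start = integer(), end = integer(),
                          width = integer(), tf = character(),
                          category = character()))
  }
  # split items across chromosomes proportionally to length
  assignment <- rep(seq_along(chroms),
                    times = diff(round(c(0, cumsum(chrom_len / sum(chrom_len)))
                                       * nrow(items))))
  purrr::map_dfr(seq_along(chroms), function(ci) {
    it <- items[assignment == ci, ]
    if (nrow(it) == 0) return(NULL)
    slack <- chrom_len[ci] - sum(it$reserve)
    if (slack < 0) {
      stop("chromosome ", chroms[ci], " too small for requested content",
           call. = FALSE)
    }
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, nrow(it) + 1)))
    start <- cumsum(gaps[seq_len(nrow(it))] +
                      dplyr::lag(it$reserve, default = 0L)) |> as.integer()
    # centre each item inside its reserve
    off <- as.integer((it$reserve - it$width) %/% 2L)
    tibble::tibble(type = it$type, chrom = chroms[ci],
                   start = start + off, end = start + off + it$width,
                   width = it$width, tf = it$tf, category = it$category)
  })
}

# two exons (intron in the middle third) plus terminal 50 bp UTRs
add_gene_structure <- function(genes) {
  if (nrow(genes) == 0) {
    genes$exons <- list()
    genes$utr5_start <- genes$utr5_end <- integer(0)
    genes$utr3_start <- genes$utr3_end <- integer(0)
    return(genes)
  }
  genes$exons <- purrr::pmap(genes[, c("start", "end")], function(start, end) {
    L <- end - start
    e1_end <- start + as.integer(0.4 * L)
    e2_start <- start + as.integer(0.6 * L)
    tibble::tibble(start = c(start, e2_start), end = c(e1_end, end))
  })
  u <- pmin(50L, (genes$end - genes$start) %/% 4L)
  plus <- genes$strand == "+"
  genes$utr5_start <- ifelse(plus, genes$start, genes$end - u)
  genes$utr5_end <- ifelse(plus, genes$start + u, genes$end)
  genes$utr3_start <- ifelse(plus, genes$end - u, genes$start)
  genes$utr3_end <- ifelse(plus, genes$end, genes$start + u)
  genes
}

# motif placement relative to the planted CArG-box at the summit
plant_motifs <- function(regions, config) {
  if (nrow(regions) == 0) {
    return(list(sites = tibble::tibble(chrom = character(), start = integer(),
                                       end = integer(), strand = character(),
                                       motif_id = character(),
                                       region_id = character()),
                seqs = character()))
  }
  sites <- list()
  seqs <- character()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    at_bias <- if (r$category == "1TF") c(A = 0.3, T = 0.7) else c(A = 0.7, T = 0.3)
    spacer <- paste(sample(names(at_bias), 6, replace = TRUE, prob = at_bias),
                    collapse = "")
    carg_start <- r$summit - 5L
    sites[[length(sites) + 1]] <- tibble::tibble(
      chrom = r$chrom, start = carg_start, end = carg_start + 10L,
      strand = sample(c("+", "-"), 1), motif_id = "CArG_6",
      region_id = r$region_id)
    seqs <- c(seqs, paste0("CC", spacer, "GG"))
    if (r$category %in% c("UB", "2TF")) {
      sites[[length(sites) + 1]] <- tibble::tibble(
        chrom = r$chrom, start = carg_start + 150L, end = carg_start + 156L,
        strand = "+", motif_id = "G_box", region_id = r$region_id)
      seqs <- c(seqs, "CACGTG")
      if (r$tf == "SVP") {
        sites[[length(sites) + 1]] <- tibble::tibble(
          chrom = r$chrom, start = carg_start - 100L, end = carg_start - 85L,
          strand = sample(c("+", "-"), 1), motif_id = "CE_box",
          region_id = r$region_id)
        seqs <- c(seqs, random_ce_box())
      }
    }
  }
  list(sites = dplyr::bind_rows(sites), seqs = seqs)
}

# 15 positions: [CA]CGG[GT][AT]A[TG][AT]GCCGGT
ce_box_alternatives <- function() {
  list(c("C", "A"), "C", "G", "G", c("G", "T"), c("A", "T"), "A",
       c("T", "G"), c("A", "T"), "G", "C", "C", "G", "G", "T")
}

random_ce_box <- function() {
  paste(vapply(ce_box_alternatives(), function(a) sample(a, 1), character(1)),
        collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL),
                                function(s) paste(rev(s), collapse = ""),
                                character(1)))
}

#' @export
print.genome_truth <- function(x, ...) {
  cat("<genome_truth>", length(x$sequence), "chromosome(s),",
      sum(nchar(x$sequence)), "bp;", nrow(x$genes), "genes;",
      nrow(x$regions), "binding regions;", nrow(x$motif_sites),
      "planted motif sites\n")
  invisible(x)
}
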
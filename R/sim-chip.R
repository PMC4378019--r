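#' Simulate a replicate ChIP coverage track
#'
#' Produces binned read counts (default 10 bp bins tiling every chromosome)
#' as Poisson background plus Gaussian-kernel enrichment around the planted
#' summits of the regions active in the requested genotype: `UB` regions are
#' enriched in both genotypes, `2TF` regions only in `WT` (both factors
#' present) and `1TF` regions only in `mutant` (partner factor absent).
#' Shape-shifted `UB` regions double their width in the mutant. Expected
#' intensity is rescaled so each track sums to `library_size` reads in
#' expectation; the kernel sd is width/4, truncated at 2 sd.
#'
#' @param truth A `genome_truth` from [simulate_genome()].
#' @param genotype `"WT"` or `"mutant"` (the partner-factor mutant).
#' @param replicate Replicate index (its own RNG stream).
#' @param tf Which factor's ChIP experiment, `"SVP"` or `"FLC"`.
#' @param bin_size Bin width in bp.
#' @return A `coverage_track` tibble with columns `chrom`, `start`, `end`,
#'   `count` and attributes `bin_size` and `library_size` (realised total).
#' @export
simulate_chip_coverage <- function(truth, genotype, replicate = 1L,
                                   tf = "SVP", bin_size = 10L) {
  stopifnot(inherits(truth, "genome_truth"))
  if (!genotype %in% c("WT", "mutant")) {
    stop("unknown genotype label: ", genotype, call. = FALSE)
  }
  cfg <- truth$config
  lambda <- expected_coverage(truth, genotype, tf, bin_size)
  lambda$mu <- lambda$mu * cfg$library_size / sum(lambda$mu)
  counts <- with_stream(cfg$seed,
                        paste("chip", tf, genotype, replicate, sep = "_"),
                        rpois(nrow(lambda), lambda$mu))
  coverage_track(
    tibble::tibble(chrom = lambda$chrom, start = lambda$start,
                   end = lambda$end, count = counts),
    bin_size = bin_size
  )
}

# expected (unscaled) per-bin intensity for one sample
expected_coverage <- function(truth, genotype, tf, bin_size = 10L) {
  cfg <- truth$config
  bins <- purrr::imap_dfr(truth$sequence, function(s, chrom) {
    L <- nchar(s)
    start <- seq(0L, L - 1L, by = bin_size)
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + as.integer(bin_size), L))
  })
  mu <- cfg$background_rate * (bins$end - bins$start)
  reg <- active_regions(truth$regions, genotype, tf)
  if (nrow(reg)) {
    for (i in seq_len(nrow(reg))) {
      r <- reg[i, ]
      w <- if (isTRUE(r$shape_shifted) && genotype == "mutant") {
        2L * r$width
      } else {
        r$width
      }
      sdev <- w / 4
      idx <- which(bins$chrom == r$chrom &
                     bins$start + bin_size / 2 >= r$summit - 2 * sdev &
                     bins$start + bin_size / 2 <= r$summit + 2 * sdev)
      centre <- bins$start[idx] + (bins$end[idx] - bins$start[idx]) / 2
      mu[idx] <- mu[idx] + cfg$peak_enrichment * cfg$background_rate *
        (bins$end[idx] - bins$start[idx]) *
        exp(-(centre - r$summit)^2 / (2 * sdev^2))
    }
  }
  bins$mu <- mu
  bins
}

active_regions <- function(regions, genotype, tf) {
  regions |>
    dplyr::filter(.data$tf == .env$tf,
                  .data$category == "UB" |
                    (.data$category == "2TF" & .env$genotype == "WT") |
                    (.data$category == "1TF" & .env$genotype == "mutant"))
}

#' Construct a coverage track
#'
#' @param bins Tibble with `chrom`, `start`, `end`, `count`; bins must tile
#'   each chromosome contiguously.
#' @param bin_size Nominal bin width in bp.
#' @return A `coverage_track` tibble; `library_size` attribute is the total
#'   read count.
#' @export
coverage_track <- function(bins, bin_size = 10L) {
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(bins)),
            all(bins$count >= 0), all(bins$start < bins$end))
  out <- tibble::as_tibble(bins)
  attr(out, "bin_size") <- as.integer(bin_size)
  attr(out, "library_size") <- sum(out$count)
  class(out) <- c("coverage_track", class(out))
  out
}

bin_size_of <- function(track) {
  attr(track, "bin_size") %||% as.integer(median(track$end - track$start))
}

library_size_of <- function(track) {
  attr(track, "library_size") %||% sum(track$count)
}
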
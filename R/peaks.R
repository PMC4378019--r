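#' Call enriched regions from a coverage track
#'
#' A local-Poisson peak caller: each bin is tested against a local rate
#' `lambda = max(genome mean, mean over 1 kb, 5 kb and 10 kb windows)`
#' computed from the control track or, absent a control, from the sample
#' itself excluding the tested bin. Bins with an upper-tail Poisson p-value
#' below `p_threshold` are merged when separated by at most `merge_gap` bp;
#' merged regions shorter than `min_width` bp are dropped. The summit is
#' the leftmost maximum of a lightly smoothed (3-bin moving average)
#' coverage inside the peak, and the score is `-log10` of the smallest bin
#' p-value.
#'
#' @param sample A `coverage_track`.
#' @param control Optional `coverage_track` with matching bins.
#' @param p_threshold Poisson upper-tail p-value cutoff.
#' @param merge_gap Maximum gap (bp) between significant bins to merge.
#' @param min_width Minimum peak width (bp).
#' @return A `peak_set` tibble: peak_id, chrom, start, end, summit, score,
#'   support.
#' @export
call_peaks <- function(sample, control = NULL, p_threshold = 1e-3,
                       merge_gap = 150L, min_width = 100L) {
  stopifnot(inherits(sample, "coverage_track"))
  if (nrow(sample) == 0) stop("empty coverage track", call. = FALSE)
  bin <- bin_size_of(sample)
  if (!is.null(control)) {
    if (!setequal(unique(sample$chrom), unique(control$chrom))) {
      stop("sample and control cover different chromosomes", call. = FALSE)
    }
    if (bin_size_of(control) != bin) {
      stop("bin sizes differ between sample and control", call. = FALSE)
    }
  }
  ref <- control %||% sample
  genome_mean <- mean(ref$count)

  peaks <- purrr::map_dfr(split(seq_len(nrow(sample)), sample$chrom),
                          function(idx) {
    x <- sample$count[idx]
    r <- ref$count[match_bins(sample[idx, ], ref)]
    lam <- local_lambda(r, bin, genome_mean,
                        exclude_centre = is.null(control))
    pval <- ppois(x - 1, lam, lower.tail = FALSE)
    sig <- which(pval < p_threshold)
    if (length(sig) == 0) return(NULL)
    gap_bins <- as.integer(ceiling(merge_gap / bin))
    grp <- cumsum(c(1L, diff(sig) > gap_bins + 1L))
    starts <- sample$start[idx]
    smoothed <- roll_mean(x, 1L)
    purrr::map_dfr(split(sig, grp), function(bins_in_peak) {
      b0 <- min(bins_in_peak)
      b1 <- max(bins_in_peak)
      p_start <- starts[b0]
      p_end <- sample$end[idx][b1]
      if (p_end - p_start < min_width) return(NULL)
      inside <- b0:b1
      summit_bin <- inside[which.max(smoothed[inside])]
      tibble::tibble(
        chrom = sample$chrom[idx][1],
        start = p_start, end = p_end,
        summit = as.integer(starts[summit_bin] + bin %/% 2L),
        score = max(-log10(pmax(pval[bins_in_peak], 1e-320))))
    })
  })
  as_peak_set(peaks)
}

match_bins <- function(bins, ref) {
  match(paste(bins$chrom, bins$start), paste(ref$chrom, ref$start))
}

# max over genome mean and centred window means of 1, 5, 10 kb; optionally
# excluding the centre bin from each window
local_lambda <- function(r, bin, genome_mean, exclude_centre = FALSE) {
  lam <- rep(genome_mean, length(r))
  for (w in c(1000L, 5000L, 10000L)) {
    k <- max(1L, as.integer(round(w / bin / 2)))
    sums <- roll_sum(r, k)
    ns <- roll_n(length(r), k)
    m <- if (exclude_centre) (sums - r) / pmax(ns - 1, 1) else sums / ns
    lam <- pmax(lam, m)
  }
  lam
}

# centred rolling sum / count with partial windows at the edges
roll_sum <- function(x, k) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - k, 0L)
  hi <- pmin(seq_len(n) + k, n)
  cs[hi + 1] - cs[lo + 1]
}

roll_n <- function(n, k) {
  pmin(seq_len(n) + k, n) - pmax(seq_len(n) - k, 0L)
}

roll_mean <- function(x, k) {
  roll_sum(x, k) / roll_n(length(x), k)
}

as_peak_set <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    peaks <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), summit = integer(),
                            score = numeric())
  }
  peaks <- peaks |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(peak_id = sprintf("peak_%04d", dplyr::row_number()),
                  support = if ("support" %in% names(peaks)) .data$support
                            else 1L) |>
    dplyr::select("peak_id", "chrom", "start", "end", "summit", "score",
                  "support")
  stopifnot(all(peaks$start < peaks$end),
            all(peaks$start <= peaks$summit & peaks$summit < peaks$end))
  class(peaks) <- c("peak_set", class(tibble::tibble()))
  peaks
}

#' Consensus peaks supported by multiple replicates
#'
#' Replaces a full irreproducible-discovery-rate analysis with an
#' overlap-based filter: peaks from different replicates are linked when
#' their reciprocal overlap (shared length relative to each peak) reaches
#' `min_reciprocal_overlap`; a consensus region is emitted when peaks from
#' at least `min_reps` distinct replicates mutually overlap. The consensus
#' interval is the union of the supporting peaks and the summit is taken
#' from the highest-score supporting peak.
#'
#' @param replicate_sets List of `peak_set` tibbles (>= 2).
#' @param min_reps Minimum number of supporting replicates.
#' @param min_reciprocal_overlap Minimum reciprocal overlap fraction.
#' @return A consensus `peak_set` with `support` = replicate count.
#' @export
reproducible_peaks <- function(replicate_sets, min_reps = 2L,
                               min_reciprocal_overlap = 0.5) {
  stopifnot(length(replicate_sets) >= 2)
  if (min_reps > length(replicate_sets)) {
    stop("min_reps exceeds the number of replicate sets", call. = FALSE)
  }
  pool <- purrr::imap_dfr(replicate_sets, function(ps, i) {
    dplyr::mutate(tibble::as_tibble(ps), replicate = i)
  })
  if (nrow(pool) == 0) return(as_peak_set(NULL))
  pool <- dplyr::arrange(pool, .data$chrom, .data$start)
  # cluster by any overlap, then search for the best mutually-overlapping
  # replicate-distinct subset within each cluster
  cluster <- integer(nrow(pool))
  cur <- 0L
  cur_end <- -Inf
  cur_chrom <- ""
  for (i in seq_len(nrow(pool))) {
    if (pool$chrom[i] != cur_chrom || pool$start[i] >= cur_end) {
      cur <- cur + 1L
      cur_chrom <- pool$chrom[i]
      cur_end <- pool$end[i]
    } else {
      cur_end <- max(cur_end, pool$end[i])
    }
    cluster[i] <- cur
  }
  consensus <- purrr::map_dfr(split(seq_len(nrow(pool)), cluster),
                              function(idx) {
    sub <- pool[idx, ]
    best <- best_clique(sub, min_reciprocal_overlap)
    if (length(best) < min_reps) return(NULL)
    supp <- sub[best, ]
    top <- supp[which.max(supp$score), ]
    tibble::tibble(chrom = supp$chrom[1],
                   start = min(supp$start), end = max(supp$end),
                   summit = top$summit, score = top$score,
                   support = length(unique(supp$replicate)))
  })
  as_peak_set(consensus)
}

reciprocal_overlap_ok <- function(s1, e1, s2, e2, frac) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ov >= frac * (e1 - s1) & ov >= frac * (e2 - s2)
}

# largest replicate-distinct pairwise-overlapping subset (exhaustive for
# small clusters, greedy by score otherwise)
best_clique <- function(sub, frac) {
  n <- nrow(sub)
  if (n == 1) return(1L)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    reciprocal_overlap_ok(sub$start[i], sub$end[i], sub$start[j], sub$end[j],
                          frac) & sub$replicate[i] != sub$replicate[j]
  })
  diag(adj) <- TRUE
  score_of <- function(members) {
    c(length(unique(sub$replicate[members])), sum(sub$score[members]))
  }
  if (n <= 10) {
    best <- integer(0)
    best_key <- c(0, -Inf)
    for (mask in seq_len(2^n - 1)) {
      members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (anyDuplicated(sub$replicate[members])) next
      if (length(members) > 1 &&
          !all(adj[members, members])) next
      key <- score_of(members)
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best <- members
        best_key <- key
      }
    }
    best
  } else {
    ord <- order(-sub$score)
    members <- integer(0)
    for (i in ord) {
      if (sub$replicate[i] %in% sub$replicate[members]) next
      if (all(adj[i, members])) members <- c(members, i)
    }
    sort(members)
  }
}
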
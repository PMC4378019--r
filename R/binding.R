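#' Classify binding regions by genotype dependency
#'
#' Compares the consensus peak sets of one TF in WT (partner present) and in
#' the partner mutant: regions overlapping by at least one bp in both sets
#' are `UB` (ubiquitous), WT-only regions are `2TF` (require both factors)
#' and mutant-only regions are `1TF`. Many-to-one overlaps collapse to a
#' single UB region anchored on the WT peak and its summit.
#'
#' @param peaks_wt,peaks_mutant Consensus `peak_set` tibbles for the same TF
#'   in the two genotypes.
#' @return A `region_category` tibble: region_id, chrom, start, end, summit,
#'   category, source_peak (WT or mutant peak id).
#' @export
classify_dependency <- function(peaks_wt, peaks_mutant) {
  wt <- tibble::as_tibble(peaks_wt)
  mu <- tibble::as_tibble(peaks_mutant)
  ov_wt <- overlaps_any(wt, mu)
  ov_mu <- overlaps_any(mu, wt)
  out <- dplyr::bind_rows(
    wt |> dplyr::mutate(category = dplyr::if_else(ov_wt, "UB", "2TF"),
                        source_peak = .data$peak_id),
    mu[!ov_mu, ] |> dplyr::mutate(category = "1TF",
                                  source_peak = .data$peak_id)
  ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(region_id = sprintf("region_%04d", dplyr::row_number())) |>
    dplyr::select("region_id", "chrom", "start", "end", "summit",
                  "category", "source_peak")
  class(out) <- c("region_category", class(tibble::tibble()))
  out
}

# does each interval in a overlap any interval in b (>= 1 bp)?
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

#' Library-normalized region scores in two conditions
#'
#' Scores each region as reads-per-million inside the region interval in
#' each condition's coverage, and records the sign of the A-minus-B
#' difference.
#'
#' @param regions Tibble with region_id/chrom/start/end.
#' @param coverage_a,coverage_b `coverage_track`s for conditions A and B.
#' @return Tibble: region_id, score_a, score_b, diff_sign (-1, 0, 1).
#' @export
normalized_scores <- function(regions, coverage_a, coverage_b) {
  la <- library_size_of(coverage_a)
  lb <- library_size_of(coverage_b)
  if (la <= 0 || lb <= 0) stop("zero library size", call. = FALSE)
  score <- function(track, lib) {
    vapply(seq_len(nrow(regions)), function(i) {
      idx <- track$chrom == regions$chrom[i] &
        track$start < regions$end[i] & track$end > regions$start[i]
      sum(track$count[idx]) * 1e6 / lib
    }, numeric(1))
  }
  sa <- score(coverage_a, la)
  sb <- score(coverage_b, lb)
  tibble::tibble(region_id = regions$region_id, score_a = sa, score_b = sb,
                 diff_sign = sign(sa - sb))
}

#' Summarise how many regions score higher in condition A
#'
#' @param scores Tibble from [normalized_scores()].
#' @return Tibble: n, n_higher, pct_higher (rounded integer percentage).
#' @export
score_direction_summary <- function(scores) {
  tibble::tibble(
    n = nrow(scores),
    n_higher = sum(scores$diff_sign > 0),
    pct_higher = round(100 * sum(scores$diff_sign > 0) / nrow(scores))
  )
}

#' Extract summit-centred coverage profiles
#'
#' Bins reads-per-million coverage into fixed-width bins spanning
#' `[summit - halfwidth, summit + halfwidth)` for every region and sample.
#' Windows are snapped to the coverage bin grid; bins outside the
#' chromosome are zero-filled and the region flagged as clipped.
#'
#' @param regions Tibble with region_id, chrom, summit.
#' @param coverage_list Named list of `coverage_track`s (one per sample).
#' @param halfwidth Half-window in bp (750 matches the usual +/-750 bp
#'   summit window).
#' @param bin Profile bin width in bp (multiple of the coverage bin size).
#' @return A `profile_matrix`: list with `values` (rows = region x sample,
#'   columns = bins, reads per million), `info` tibble (region_id,
#'   sample_id, clipped), `halfwidth`, `bin`.
#' @export
extract_profiles <- function(regions, coverage_list, halfwidth = 750L,
                             bin = 30L) {
  stopifnot(length(coverage_list) >= 1)
  if (is.null(names(coverage_list))) {
    names(coverage_list) <- sprintf("sample_%d", seq_along(coverage_list))
  }
  n_bins <- as.integer(2 * halfwidth / bin)
  rows <- list()
  info <- list()
  for (s in names(coverage_list)) {
    track <- coverage_list[[s]]
    cbin <- bin_size_of(track)
    stopifnot(bin %% cbin == 0)
    k <- bin %/% cbin
    lib <- library_size_of(track)
    per_chrom <- split(tibble::as_tibble(track), track$chrom)
    # cumulative counts per chromosome for O(1) window sums (tracks are
    # regular tilings starting at 0)
    cums <- lapply(per_chrom, function(tr) c(0, cumsum(tr$count)))
    for (i in seq_len(nrow(regions))) {
      chrom <- regions$chrom[i]
      tr <- per_chrom[[chrom]]
      if (is.null(tr)) stop("region on unknown chromosome: ", chrom,
                            call. = FALSE)
      chrom_len <- max(tr$end)
      n_track <- nrow(tr)
      s0 <- round((regions$summit[i] - halfwidth) / cbin) * cbin
      if (s0 >= chrom_len || s0 + 2 * halfwidth <= 0) {
        stop("region ", regions$region_id[i], " lies outside chromosome",
             call. = FALSE)
      }
      i0 <- s0 %/% cbin + seq(0L, by = k, length.out = n_bins)  # 0-based
      i1 <- i0 + k
      lo <- pmin(pmax(i0, 0L), n_track)
      hi <- pmin(pmax(i1, 0L), n_track)
      vals <- (cums[[chrom]][hi + 1] - cums[[chrom]][lo + 1]) * 1e6 / lib
      clipped <- s0 < 0 || s0 + 2 * halfwidth > chrom_len
      rows[[length(rows) + 1]] <- vals
      info[[length(info) + 1]] <- tibble::tibble(
        region_id = regions$region_id[i], sample_id = s, clipped = clipped)
    }
  }
  values <- do.call(rbind, rows)
  info <- dplyr::bind_rows(info)
  rownames(values) <- paste(info$region_id, info$sample_id, sep = "|")
  structure(list(values = values, info = info, halfwidth = halfwidth,
                 bin = bin),
            class = "profile_matrix")
}

#' Functional PCA of coverage profiles
#'
#' Centers the profile rows by the mean profile and decomposes the row
#' covariance by singular value decomposition; component loadings are
#' orthonormal curves over the window, scores are row projections, and
#' variance-explained fractions are non-increasing.
#'
#' @param profiles A `profile_matrix` or plain numeric matrix (rows =
#'   observations, columns = bins).
#' @param var_cutoff Retain the smallest number of components whose
#'   cumulative variance fraction reaches this value.
#' @return An `fpca_result`: mean_profile, loadings, scores,
#'   var_explained, k_retained, info.
#' @export
fpca <- function(profiles, var_cutoff = 0.85) {
  mat <- if (inherits(profiles, "profile_matrix")) profiles$values else profiles
  info <- if (inherits(profiles, "profile_matrix")) profiles$info else NULL
  if (nrow(mat) < 2) stop("need at least 2 profile rows", call. = FALSE)
  mu <- colMeans(mat)
  centred <- sweep(mat, 2, mu)
  sv <- svd(centred)
  tot <- sum(sv$d^2)
  if (tot < 1e-12) {
    return(structure(list(mean_profile = mu,
                          loadings = sv$v[, 0, drop = FALSE],
                          scores = matrix(0, nrow(mat), 0,
                                          dimnames = list(rownames(mat),
                                                          NULL)),
                          var_explained = numeric(0), k_retained = 0L,
                          info = info),
                     class = "fpca_result"))
  }
  var_explained <- sv$d^2 / tot
  keep <- var_explained > 1e-12
  scores <- (sv$u %*% diag(sv$d, length(sv$d)))[, keep, drop = FALSE]
  rownames(scores) <- rownames(mat)
  k <- which(cumsum(var_explained[keep]) >= var_cutoff)[1]
  structure(list(mean_profile = mu,
                 loadings = sv$v[, keep, drop = FALSE],
                 scores = scores,
                 var_explained = var_explained[keep],
                 k_retained = as.integer(k),
                 info = info),
            class = "fpca_result")
}

#' @rdname tidy.duetseq
#' @export
tidy.fpca_result <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_explained),
                 var_explained = x$var_explained,
                 cumulative = cumsum(x$var_explained))
}

#' Two-sample Hotelling T-squared test
#'
#' `T2 = (n1*n2/(n1+n2)) * d' S_pooled^-1 d` for the mean difference `d` of
#' multivariate scores, with the F transform
#' `F = ((n1+n2-p-1)/(p*(n1+n2-2))) * T2` on `(p, n1+n2-p-1)` degrees of
#' freedom. A singular pooled covariance falls back to the Moore-Penrose
#' pseudo-inverse and is flagged.
#'
#' @param x1,x2 Numeric matrices (rows = observations, columns = score
#'   dimensions) or vectors for the univariate case.
#' @return Tibble: T2, statistic (F), df1, df2, p, singular.
#' @export
hotelling_t2 <- function(x1, x2) {
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  stopifnot(ncol(x1) == ncol(x2))
  n1 <- nrow(x1)
  n2 <- nrow(x2)
  p <- ncol(x1)
  if (n1 + n2 - p - 1 < 1) {
    stop("too few observations for dimension ", p, call. = FALSE)
  }
  d <- colMeans(x1) - colMeans(x2)
  s_pooled <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) /
    (n1 + n2 - 2)
  singular <- FALSE
  inv <- tryCatch(solve(s_pooled), error = function(e) {
    singular <<- TRUE
    MASS::ginv(s_pooled)
  })
  if (!singular && rcond_safe(s_pooled) < 1e-12) {
    singular <- TRUE
    inv <- MASS::ginv(s_pooled)
  }
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% inv %*% d)
  if (!is.finite(t2) || t2 < 0) t2 <- 0
  fstat <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * t2
  pval <- pf(fstat, p, n1 + n2 - p - 1, lower.tail = FALSE)
  tibble::tibble(T2 = t2, statistic = fstat, df1 = p, df2 = n1 + n2 - p - 1,
                 p = pval, singular = singular)
}

rcond_safe <- function(m) {
  if (any(!is.finite(m))) return(0)
  tryCatch(rcond(m), error = function(e) 0)
}

#' Shape-based differential binding over all regions
#'
#' Extracts summit-centred profiles for two groups of replicate samples,
#' fits a single functional PCA over the stacked rows of all regions and
#' samples, retains the smallest number of components reaching
#' `var_cutoff` cumulative variance (capped at `n1+n2-3` so the F transform
#' keeps positive denominator df), and tests each region by Hotelling's
#' T-squared on the replicate-level scores, with BH adjustment across
#' regions; regions are significant at adjusted p <= `alpha`.
#'
#' @param regions Tibble with region_id, chrom, summit.
#' @param coverage_group1,coverage_group2 Named lists of `coverage_track`s
#'   (replicates of condition 1 and 2).
#' @param halfwidth,bin Profile window parameters (see
#'   [extract_profiles()]).
#' @param var_cutoff Cumulative-variance rule for retained components.
#' @param alpha Significance threshold on BH-adjusted p-values.
#' @return A `diffbind_result` tibble: region_id, T2, p, padj, significant,
#'   singular, k (components used).
#' @export
diff_binding <- function(regions, coverage_group1, coverage_group2,
                         halfwidth = 750L, bin = 30L, var_cutoff = 0.85,
                         alpha = 0.05) {
  n1 <- length(coverage_group1)
  n2 <- length(coverage_group2)
  stopifnot(n1 >= 2, n2 >= 2)
  if (is.null(names(coverage_group1))) {
    names(coverage_group1) <- sprintf("g1_r%d", seq_len(n1))
  }
  if (is.null(names(coverage_group2))) {
    names(coverage_group2) <- sprintf("g2_r%d", seq_len(n2))
  }
  prof <- extract_profiles(regions, c(coverage_group1, coverage_group2),
                           halfwidth = halfwidth, bin = bin)
  fp <- fpca(prof, var_cutoff = var_cutoff)
  k <- min(fp$k_retained, n1 + n2 - 3L, ncol(fp$scores))
  if (is.na(k) || k < 1) {
    stop("no informative shape components (profiles have no variance)",
         call. = FALSE)
  }
  res <- purrr::map_dfr(unique(regions$region_id), function(rid) {
    rows1 <- fp$info$region_id == rid &
      fp$info$sample_id %in% names(coverage_group1)
    rows2 <- fp$info$region_id == rid &
      fp$info$sample_id %in% names(coverage_group2)
    ht <- hotelling_t2(fp$scores[rows1, seq_len(k), drop = FALSE],
                       fp$scores[rows2, seq_len(k), drop = FALSE])
    dplyr::mutate(ht, region_id = rid, k = k)
  })
  res |>
    dplyr::mutate(padj = p.adjust(.data$p, "BH"),
                  significant = .data$padj <= alpha) |>
    dplyr::select("region_id", "T2", "p", "padj", "significant",
                  "singular", "k")
}

#' Heatmap row ordering by maximum median bin
#'
#' Computes, per region, medians over non-overlapping column windows and
#' orders regions by the maximum window median, descending (stable on
#' ties). Regions containing any value above `intensity_cutoff` are masked
#' out of the ordering.
#'
#' @param mat Numeric matrix, rows = regions (rownames used as ids),
#'   columns = profile bins.
#' @param n_bins_for_median Number of columns per median window.
#' @param intensity_cutoff Mask regions containing any value above this.
#' @return List: `order` (kept region ids, sorted), `mask` (excluded ids),
#'   `max_median` (named vector).
#' @export
heatmap_order <- function(mat, n_bins_for_median = 5L,
                          intensity_cutoff = 20) {
  stopifnot(is.matrix(mat))
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  windows <- split(seq_len(ncol(mat)),
                   ceiling(seq_len(ncol(mat)) / n_bins_for_median))
  max_med <- apply(mat, 1, function(row) {
    max(vapply(windows, function(w) median(row[w]), numeric(1)))
  })
  names(max_med) <- ids
  masked <- apply(mat, 1, function(row) any(row > intensity_cutoff))
  keep <- which(!masked)
  ord <- keep[order(-max_med[keep])]   # order() is stable for ties
  list(order = ids[ord], mask = ids[masked], max_median = max_med)
}
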
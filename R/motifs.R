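#' Build the CArG, G-box and CE-box position weight matrices
#'
#' Constructs consensus-with-pseudocount PWMs: `CArG_5`, `CArG_6`, `CArG_7`
#' are `CC` + an A/T spacer of 5-7 positions + `GG` (spacer positions give
#' probability `0.5 - eps` to each of A and T); `G_box` is the palindromic
#' consensus `CACGTG`; `CE_box` encodes
#' `[CA]CGG[GT][AT]A[TG][AT]GCCGGT` (15 positions) with bracketed
#' alternatives uniform. Fixed consensus positions carry `1 - 3*eps` with
#' pseudocount `eps` elsewhere.
#'
#' @param eps Pseudocount probability per non-consensus base.
#' @return Named list of `pwm` objects.
#' @export
build_motifs <- function(eps = 0.01) {
  carg <- function(n) {
    c(list("C", "C"), rep(list(c("A", "T")), n), list("G", "G"))
  }
  list(
    CArG_5 = pwm("CArG_5", carg(5), eps),
    CArG_6 = pwm("CArG_6", carg(6), eps),
    CArG_7 = pwm("CArG_7", carg(7), eps),
    G_box = pwm("G_box", as.list(strsplit("CACGTG", "")[[1]]), eps),
    CE_box = pwm("CE_box", ce_box_alternatives(), eps)
  )
}

#' Construct a position weight matrix
#'
#' @param motif_id Motif name.
#' @param positions List of character vectors: the allowed base(s) at each
#'   position; allowed bases share `1 - (4 - n_allowed)*eps` uniformly,
#'   the rest get `eps`.
#' @param eps Pseudocount probability.
#' @param background Background base frequencies (A, C, G, T); may be
#'   overridden at scan time.
#' @return A `pwm` object: probs (4 x width), motif_id, width, eps,
#'   background.
#' @export
pwm <- function(motif_id, positions, eps = 0.01,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  bases <- c("A", "C", "G", "T")
  probs <- vapply(positions, function(allowed) {
    stopifnot(all(allowed %in% bases))
    p <- setNames(rep(eps, 4), bases)
    p[allowed] <- (1 - (4 - length(allowed)) * eps) / length(allowed)
    p
  }, numeric(4))
  stopifnot(abs(colSums(probs) - 1) < 1e-12)
  structure(list(motif_id = motif_id, width = length(positions),
                 probs = probs, eps = eps,
                 background = background / sum(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$motif_id, "width", x$width, "\n")
  print(round(x$probs, 3))
  invisible(x)
}

# log-odds in integer ticks of `delta` log2 units; all scoring and the DP
# score distribution share this discretization, so match p-values are exact
# for the discretized matrix
pwm_ticks <- function(pwm, background = NULL, delta = 0.01) {
  bg <- background %||% pwm$background
  bg <- bg / sum(bg)
  lo <- log2(sweep(pwm$probs, 1, bg, "/"))
  round(lo / delta)
}

# exact distribution of the tick score under the 0-order background:
# returns support (ticks) and upper-tail probabilities
pwm_score_distribution <- function(ticks, background) {
  bg <- background / sum(background)
  cur <- 1
  cur_min <- 0
  for (k in seq_len(ncol(ticks))) {
    col <- ticks[, k]
    sh_min <- min(col)
    span <- (length(cur) - 1) + (max(col) - sh_min)
    nxt <- numeric(span + 1)
    for (b in 1:4) {
      sh <- col[b] - sh_min
      idx <- (1 + sh):(sh + length(cur))
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_min <- cur_min + sh_min
  }
  support <- cur_min + seq_along(cur) - 1
  list(support = support, prob = cur, upper_tail = rev(cumsum(rev(cur))))
}

# upper-tail p-value for observed tick scores
pwm_pvalue <- function(scores_ticks, dist) {
  idx <- pmin(pmax(scores_ticks - dist$support[1] + 1, 1),
              length(dist$support))
  p <- dist$upper_tail[idx]
  p[scores_ticks > dist$support[length(dist$support)]] <- 0
  p[scores_ticks < dist$support[1]] <- 1
  p
}

encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), NULL)[[1]], c("A", "C", "G", "T"))
  v
}

revcomp_pwm_ticks <- function(ticks) {
  ticks[4:1, rev(seq_len(ncol(ticks))), drop = FALSE]
}

# score all windows of one encoded sequence with a tick matrix; windows
# containing N (NA codes) score NA
score_windows <- function(code, ticks) {
  w <- ncol(ticks)
  n <- length(code) - w + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (k in seq_len(w)) {
    sc <- sc + ticks[code[k:(k + n - 1)], k]
  }
  sc
}

#' Scan sequences for PWM matches with exact p-values
#'
#' Scores every window on both strands with the discretized log-odds matrix
#' (0.01 log2-unit granularity) and assigns each score an exact upper-tail
#' p-value under the 0-order background via dynamic programming over the
#' discrete score distribution. Windows containing `N` are skipped. The
#' background is estimated from the scanned sequences unless supplied.
#'
#' @param seqs Named character vector of sequences (e.g. one per region or
#'   chromosome), alphabet `ACGTN`.
#' @param pwm A `pwm`.
#' @param p_threshold Keep matches with p-value strictly below this.
#' @param background Optional base frequencies; default: estimated from
#'   `seqs` (N excluded).
#' @param both_strands Scan the reverse strand too.
#' @param delta Log-odds discretization in log2 units.
#' @return Tibble (`motif_match`): seq_id, start (0-based), end, strand,
#'   score (log2 odds), p.
#' @export
scan_pwm <- function(seqs, pwm, p_threshold = 0.001, background = NULL,
                     both_strands = TRUE, delta = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%d", seq_along(seqs))
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) stop("invalid alphabet in sequence(s): ",
                     paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  codes <- lapply(seqs, encode_seq)
  if (is.null(background)) {
    tab <- table(factor(unlist(codes), levels = 1:4))
    background <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  }
  background <- background / sum(background)
  ticks <- pwm_ticks(pwm, background, delta)
  dist <- pwm_score_distribution(ticks, background)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- purrr::map_dfr(names(seqs), function(id) {
    code <- codes[[id]]
    purrr::map_dfr(strands, function(strand) {
      tk <- if (strand == "+") ticks else revcomp_pwm_ticks(ticks)
      sc <- score_windows(code, tk)
      if (length(sc) == 0) return(NULL)
      pv <- pwm_pvalue(sc, dist)
      hit <- which(!is.na(sc) & pv < p_threshold)
      if (length(hit) == 0) return(NULL)
      tibble::tibble(seq_id = id, start = hit - 1L,
                     end = hit - 1L + pwm$width, strand = strand,
                     score = sc[hit] * delta, p = pv[hit])
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          score = numeric(), p = numeric())
  }
  dplyr::mutate(out, motif_id = pwm$motif_id) |>
    dplyr::arrange(.data$seq_id, .data$start, .data$strand)
}

as_genome_strings <- function(genome) {
  if (inherits(genome, "genome_truth")) return(genome$sequence)
  if (methods::is(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

#' Scan genomic regions for PWM matches
#'
#' Extracts each region's sequence from the genome and scans it with
#' [scan_pwm()] under the genome-wide background; match coordinates are
#' reported on the genome.
#'
#' @param regions Tibble with region_id, chrom, start, end (0-based
#'   half-open).
#' @param genome A `genome_truth`, named character vector or
#'   `DNAStringSet`.
#' @inheritParams scan_pwm
#' @return Tibble: region_id, chrom, start, end, strand, score, p,
#'   motif_id.
#' @export
scan_regions <- function(regions, genome, pwm, p_threshold = 0.001,
                         background = NULL, delta = 0.01) {
  gseq <- as_genome_strings(genome)
  if (is.null(background)) background <- genome_background(gseq)
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    substr(gseq[[regions$chrom[i]]], regions$start[i] + 1L, regions$end[i])
  }, character(1))
  names(seqs) <- regions$region_id
  hits <- scan_pwm(seqs, pwm, p_threshold, background, delta = delta)
  if (nrow(hits) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), score = numeric(),
                          p = numeric(), motif_id = character()))
  }
  hits |>
    dplyr::rename(region_id = "seq_id") |>
    dplyr::left_join(dplyr::select(regions, "region_id", "chrom",
                                   region_start = "start"),
                     by = "region_id") |>
    dplyr::mutate(start = .data$start + .data$region_start,
                  end = .data$end + .data$region_start) |>
    dplyr::select("region_id", "chrom", "start", "end", "strand", "score",
                  "p", "motif_id")
}

genome_background <- function(gseq) {
  counts <- rowSums(vapply(gseq, function(s) {
    tabulate(encode_seq(s), nbins = 4)
  }, numeric(4)))
  # Laplace pseudocount keeps log-odds finite for absent bases
  (counts + 1) / (sum(counts) + 4)
}

#' Permutation Z-score enrichment of a motif in a region set
#'
#' Scans the whole genome once for significant matches, counts regions
#' containing at least one match, and compares with `n_sets` random region
#' sets of exactly matched lengths placed uniformly on the genome. When the
#' null sd is zero the Z-score is 0 if the observation equals the null mean
#' and is reported infinite (significant iff observed exceeds the mean)
#' otherwise.
#'
#' @param regions Tibble with region_id, chrom, start, end.
#' @param pwm A `pwm` (or list of one).
#' @param genome Genome as in [scan_regions()].
#' @param n_sets Number of permutation sets.
#' @param seed Integer seed for region placement.
#' @param p_threshold Match significance threshold.
#' @param background Optional base frequencies (default: genome-wide).
#' @return An `enrichment_result` tibble: motif_id, n_regions, observed,
#'   null_mean, null_sd, z, significant (Z > 3).
#' @export
permutation_enrichment <- function(regions, pwm, genome, n_sets = 1000L,
                                   seed = 1L, p_threshold = 0.001,
                                   background = NULL) {
  gseq <- as_genome_strings(genome)
  starts <- genome_match_starts(gseq, pwm, p_threshold, background)
  obs <- count_hit_regions(regions, starts, pwm$width)
  null_counts <- null_hit_counts(regions, starts, pwm$width, gseq, n_sets,
                                 seed)
  null_mean <- mean(null_counts)
  null_sd <- sd(null_counts)
  if (is.na(null_sd) || null_sd == 0) {
    z <- if (obs == null_mean) 0 else Inf * sign(obs - null_mean)
    signif <- is.infinite(z) && obs > null_mean
  } else {
    z <- (obs - null_mean) / null_sd
    signif <- z > 3
  }
  tibble::tibble(motif_id = pwm$motif_id, n_regions = nrow(regions),
                 observed = obs, null_mean = null_mean, null_sd = null_sd,
                 z = z, significant = signif)
}

# genome-wide significant match starts, per chromosome, sorted
genome_match_starts <- function(gseq, pwm, p_threshold, background = NULL) {
  bg <- background %||% genome_background(gseq)
  hits <- scan_pwm(gseq, pwm, p_threshold, background = bg)
  hits <- hits[order(hits$seq_id, hits$start), ]
  split(hits$start, factor(hits$seq_id, levels = names(gseq)))[names(gseq)]
}

# regions containing >= 1 match window entirely inside them
count_hit_regions <- function(regions, starts, width) {
  sum(vapply(seq_len(nrow(regions)), function(i) {
    st <- starts[[regions$chrom[i]]]
    if (is.null(st) || length(st) == 0) return(FALSE)
    lo <- regions$start[i]
    hi <- regions$end[i] - width
    if (hi < lo) return(FALSE)
    any(st >= lo & st <= hi)
  }, logical(1)))
}

null_hit_counts <- function(regions, starts, width, gseq, n_sets, seed) {
  chrom_len <- nchar(gseq)
  lens <- regions$end - regions$start
  with_stream(seed, "motif_permutation", {
    vapply(seq_len(n_sets), function(i) {
      rnd <- random_regions(lens, chrom_len)
      count_hit_regions(rnd, starts, width)
    }, numeric(1))
  })
}

random_regions <- function(lens, chrom_len) {
  chroms <- names(chrom_len)
  out_chrom <- character(length(lens))
  out_start <- integer(length(lens))
  for (i in seq_along(lens)) {
    slots <- pmax(chrom_len - lens[i] + 1, 0)
    if (sum(slots) == 0) stop("region longer than any chromosome",
                              call. = FALSE)
    ci <- sample.int(length(chroms), 1, prob = slots)
    out_chrom[i] <- chroms[ci]
    out_start[i] <- sample.int(slots[ci], 1) - 1L
  }
  tibble::tibble(region_id = sprintf("rnd_%d", seq_along(lens)),
                 chrom = out_chrom, start = out_start,
                 end = out_start + lens)
}

#' Permutation test of motif co-occurrence within regions
#'
#' Counts regions containing at least one significant match of each of two
#' motifs and compares with length-matched random region sets, as in
#' [permutation_enrichment()].
#'
#' @param regions Tibble with region_id, chrom, start, end.
#' @param pwm_a,pwm_b `pwm` objects.
#' @inheritParams permutation_enrichment
#' @return Tibble: motifs, n_regions, observed, null_mean, null_sd, z,
#'   significant.
#' @export
cooccurrence <- function(regions, pwm_a, pwm_b, genome, n_sets = 1000L,
                         seed = 1L, p_threshold = 0.001,
                         background = NULL) {
  gseq <- as_genome_strings(genome)
  st_a <- genome_match_starts(gseq, pwm_a, p_threshold, background)
  st_b <- genome_match_starts(gseq, pwm_b, p_threshold, background)
  hit_both <- function(reg) {
    hits_a <- region_has_match(reg, st_a, pwm_a$width)
    hits_b <- region_has_match(reg, st_b, pwm_b$width)
    sum(hits_a & hits_b)
  }
  obs <- hit_both(regions)
  chrom_len <- nchar(gseq)
  lens <- regions$end - regions$start
  null_counts <- with_stream(seed, "motif_cooccurrence", {
    vapply(seq_len(n_sets), function(i) {
      hit_both(random_regions(lens, chrom_len))
    }, numeric(1))
  })
  null_mean <- mean(null_counts)
  null_sd <- sd(null_counts)
  if (is.na(null_sd) || null_sd == 0) {
    z <- if (obs == null_mean) 0 else Inf * sign(obs - null_mean)
    signif <- is.infinite(z) && obs > null_mean
  } else {
    z <- (obs - null_mean) / null_sd
    signif <- z > 3
  }
  tibble::tibble(motifs = paste(pwm_a$motif_id, pwm_b$motif_id, sep = "+"),
                 n_regions = nrow(regions), observed = obs,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 significant = signif)
}

region_has_match <- function(regions, starts, width) {
  vapply(seq_len(nrow(regions)), function(i) {
    st <- starts[[regions$chrom[i]]]
    if (is.null(st) || length(st) == 0) return(FALSE)
    hi <- regions$end[i] - width
    hi >= regions$start[i] && any(st >= regions$start[i] & st <= hi)
  }, logical(1))
}

#' Nearest distances between matches of two motifs within regions
#'
#' For every A match, the absolute start-to-start distance to the nearest B
#' match in the same region; regions lacking B matches contribute nothing.
#'
#' @param matches_a,matches_b Match tibbles from [scan_regions()] (need
#'   region_id and start).
#' @return Tibble: region_id, distance.
#' @export
nearest_distances <- function(matches_a, matches_b) {
  b_by_region <- split(matches_b$start, matches_b$region_id)
  out <- purrr::map_dfr(seq_len(nrow(matches_a)), function(i) {
    b <- b_by_region[[matches_a$region_id[i]]]
    if (is.null(b) || length(b) == 0) return(NULL)
    tibble::tibble(region_id = matches_a$region_id[i],
                   distance = min(abs(matches_a$start[i] - b)))
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(region_id = character(), distance = integer())
  }
  out
}

#' Histogram of nearest distances
#'
#' @param distances Tibble from [nearest_distances()].
#' @param binwidth Bin width in bp.
#' @param max_distance Upper edge of the last bin.
#' @return Tibble: bin_start, bin_end, n.
#' @export
distance_histogram <- function(distances, binwidth = 50L,
                               max_distance = 1000L) {
  edges <- seq(0L, max_distance, by = binwidth)
  bin <- cut(distances$distance, breaks = edges, right = FALSE,
             include.lowest = FALSE)
  tibble::tibble(bin_start = head(edges, -1), bin_end = edges[-1],
                 n = as.integer(table(bin)))
}

#' Spacer base composition of CArG matches
#'
#' Extracts, strand-resolved (motif orientation), the spacer positions of
#' each CArG match (positions between the `CC` and `GG` flanks) and
#' tabulates base frequencies per spacer position. Each row sums to the
#' number of matches.
#'
#' @param matches Match tibble from [scan_regions()] for a CArG PWM (needs
#'   chrom/start/end/strand).
#' @param genome Genome as in [scan_regions()].
#' @return Tibble: position (1-based within spacer), A, C, G, T.
#' @export
stretch_composition <- function(matches, genome) {
  gseq <- as_genome_strings(genome)
  if (nrow(matches) == 0) {
    return(tibble::tibble(position = integer(), A = integer(),
                          C = integer(), G = integer(), T = integer()))
  }
  width <- unique(matches$end - matches$start)
  stopifnot(length(width) == 1)
  spacer_len <- width - 4L
  seqs <- vapply(seq_len(nrow(matches)), function(i) {
    s <- substr(gseq[[matches$chrom[i]]], matches$start[i] + 1L,
                matches$end[i])
    if (matches$strand[i] == "-") s <- revcomp(s)
    substr(s, 3L, 2L + spacer_len)
  }, character(1))
  mat <- do.call(rbind, strsplit(seqs, NULL))
  purrr::map_dfr(seq_len(spacer_len), function(pos) {
    tab <- table(factor(mat[, pos], levels = c("A", "C", "G", "T")))
    tibble::tibble(position = pos, A = as.integer(tab["A"]),
                   C = as.integer(tab["C"]), G = as.integer(tab["G"]),
                   T = as.integer(tab["T"]))
  })
}
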
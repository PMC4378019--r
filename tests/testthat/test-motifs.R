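test_that("built PWMs have the published widths and proper columns", {
  mots <- build_motifs()
  expect_equal(mots$CArG_5$width, 9)     # CC + 5 + GG
  expect_equal(mots$CArG_6$width, 10)    # CC + 6 + GG
  expect_equal(mots$CArG_7$width, 11)
  expect_equal(mots$G_box$width, 6)
  # [CA]CGG[GT][AT]A[TG][AT]GCCGGT spells 15 positions
  expect_equal(mots$CE_box$width, 15)
  for (m in mots) {
    expect_true(all(abs(colSums(m$probs) - 1) < 1e-12))
    expect_gte(m$width, 4)
  }
  # spacer positions weight A/T evenly, flanks are near-consensus
  expect_equal(unname(mots$CArG_6$probs["A", 3]), 0.49)
  expect_equal(unname(mots$CArG_6$probs["T", 3]), 0.49)
  expect_equal(unname(mots$CArG_6$probs["C", 1]), 0.97)
})

test_that("DP score p-values equal exhaustive enumeration up to width 8", {
  bgs <- list(rep(0.25, 4), c(0.32, 0.18, 0.18, 0.32))
  pwms <- list(
    pwm("w4", list("A", c("A", "T"), "C", c("G", "T")), eps = 0.02),
    pwm("w6", as.list(strsplit("CACGTG", "")[[1]])),
    pwm("w8", c(list("C", "C"), rep(list(c("A", "T")), 4), list("G", "G")))
  )
  for (bg in bgs) {
    for (p in pwms) {
      ticks <- duetseq:::pwm_ticks(p, bg)
      dist <- duetseq:::pwm_score_distribution(ticks, bg)
      codes <- as.matrix(expand.grid(rep(list(1:4), p$width)))
      sc <- codes
      scores <- vapply(seq_len(nrow(codes)), function(i) {
        sum(ticks[cbind(codes[i, ], seq_len(p$width))])
      }, numeric(1))
      probs <- apply(codes, 1, function(cd) prod(bg[cd]))
      for (s in unique(scores)) {
        expect_equal(duetseq:::pwm_pvalue(s, dist), sum(probs[scores >= s]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("consensus sequences are significant matches on both strands", {
  mots <- build_motifs()
  seqs <- c(r1 = "TTTTTTCCAAATAAGGTTTTTT")
  hits <- scan_pwm(seqs, mots$CArG_6, background = rep(0.25, 4))
  expect_gte(nrow(hits), 1)
  expect_true(all(hits$start == 6))
  expect_true(all(hits$p < 0.001))
  # reverse-complemented input mirrors positions and flips strands
  rc <- c(r1 = duetseq:::revcomp(seqs[[1]]))
  hits_rc <- scan_pwm(rc, mots$CArG_6, background = rep(0.25, 4))
  L <- nchar(seqs[[1]])
  expect_setequal(unname(hits_rc$start), unname(L - hits$end))
  expect_setequal(paste(hits_rc$start, hits_rc$strand),
                  paste(L - hits$end,
                        unname(c("+" = "-", "-" = "+")[hits$strand])))
  # invalid alphabet errors; N windows are skipped silently
  expect_error(scan_pwm(c(x = "ACGU"), mots$G_box), "alphabet")
  expect_equal(nrow(scan_pwm(c(x = "CACNTGCACNTG"), mots$G_box,
                             background = rep(0.25, 4))), 0)
  # motif wider than the sequence -> empty result, no error
  expect_equal(nrow(scan_pwm(c(x = "ACG"), mots$G_box,
                             background = rep(0.25, 4))), 0)
})

test_that("lowering the match threshold never increases match counts", {
  tr <- simulate_genome(small_config(seed = 51))
  m <- build_motifs()$CArG_6
  thresholds <- c(0.01, 0.003, 0.001, 3e-4, 1e-4)
  counts <- vapply(thresholds, function(th) {
    nrow(scan_pwm(tr$sequence, m, p_threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region scans map coordinates to the genome and respect order", {
  tr <- simulate_genome(small_config(seed = 52))
  reg <- tr$regions |>
    dplyr::mutate(start = .data$summit - 250L, end = .data$summit + 250L)
  hits <- scan_regions(reg, tr, build_motifs()$CArG_6)
  expect_gt(nrow(hits), 0)
  # every planted CArG position is recovered
  planted <- tr$motif_sites[tr$motif_sites$motif_id == "CArG_6", ]
  expect_true(all(planted$start %in% hits$start))
  # shuffling the region order leaves the match set unchanged
  hits2 <- scan_regions(reg[sample.int(nrow(reg)), ], tr,
                        build_motifs()$CArG_6)
  expect_setequal(paste(hits$chrom, hits$start, hits$strand),
                  paste(hits2$chrom, hits2$start, hits2$strand))
})

test_that("permutation Z flags planted motifs and spares motif-free nulls", {
  # AT-rich genome holds essentially no G-box-like windows; G-boxes are
  # then planted into 20 regions
  set.seed(61)
  raw <- paste(sample(c("A", "C", "G", "T"), 120000, replace = TRUE,
                      prob = c(0.45, 0.05, 0.05, 0.45)),
               collapse = "")
  starts <- seq(2000, 110000, by = 5400)[1:20]
  for (s in starts) substr(raw, s + 100, s + 105) <- "CACGTG"
  genome <- c(chr1 = raw)
  regions <- tibble::tibble(region_id = sprintf("p%02d", 1:20),
                            chrom = "chr1", start = starts,
                            end = starts + 500L)
  gbox <- build_motifs()$G_box
  en <- permutation_enrichment(regions, gbox, genome, n_sets = 300,
                               seed = 9, background = rep(0.25, 4))
  expect_equal(en$observed, 20)
  expect_lt(en$null_mean, 2)
  expect_true(en$significant)
  expect_gt(en$z, 3)
  # length-matched random regions in the scrubbed genome are null
  null_regions <- tibble::tibble(region_id = sprintf("n%02d", 1:20),
                                 chrom = "chr1",
                                 start = starts + 1000L,
                                 end = starts + 1500L)
  en0 <- permutation_enrichment(null_regions, gbox, genome, n_sets = 300,
                                seed = 10, background = rep(0.25, 4))
  expect_lt(abs(en0$z), 3)
  expect_false(en0$significant)
})

test_that("a motif absent from the genome gives a zero-defined Z", {
  genome <- c(chr1 = paste(rep("AT", 5000), collapse = ""))
  regions <- tibble::tibble(region_id = "r1", chrom = "chr1",
                            start = 100L, end = 600L)
  en <- permutation_enrichment(regions, build_motifs()$G_box, genome,
                               n_sets = 50, seed = 3)
  expect_equal(en$observed, 0)
  expect_equal(en$null_mean, 0)
  expect_equal(en$z, 0)
  expect_false(en$significant)
  expect_error(
    permutation_enrichment(tibble::tibble(region_id = "r", chrom = "chr1",
                                          start = 0L, end = 20000L),
                           build_motifs()$G_box, genome, n_sets = 2,
                           seed = 1),
    "longer than any chromosome")
})

test_that("permutation Z is stable across seeds", {
  set.seed(62)
  raw <- paste(sample(c("A", "C", "G", "T"), 120000, replace = TRUE,
                      prob = c(0.45, 0.05, 0.05, 0.45)),
               collapse = "")
  starts <- seq(2000, 110000, by = 5400)[1:20]
  for (s in starts) substr(raw, s + 100, s + 105) <- "CACGTG"
  genome <- c(chr1 = raw)
  regions <- tibble::tibble(region_id = sprintf("p%02d", 1:20),
                            chrom = "chr1", start = starts,
                            end = starts + 500L)
  gbox <- build_motifs()$G_box
  z1 <- permutation_enrichment(regions, gbox, genome, n_sets = 1000,
                               seed = 1, background = rep(0.25, 4))$z
  z2 <- permutation_enrichment(regions, gbox, genome, n_sets = 1000,
                               seed = 2, background = rep(0.25, 4))$z
  expect_lt(abs(z1 - z2), 0.5)
  expect_gt(min(z1, z2), 3)
})

test_that("co-occurrence counts regions holding both motifs", {
  tr <- simulate_genome(small_config(seed = 54))
  mots <- build_motifs()
  reg <- tr$regions |>
    dplyr::filter(.data$tf == "SVP") |>
    dplyr::mutate(start = .data$summit - 250L, end = .data$summit + 250L)
  co <- cooccurrence(reg, mots$CArG_6, mots$G_box, tr, n_sets = 200,
                     seed = 4)
  # planted G-boxes accompany CArG only in UB and 2TF regions
  expect_gte(co$observed, sum(reg$category %in% c("UB", "2TF")))
  expect_true(co$significant)
  # regions lacking one motif contribute nothing
  only_a <- tibble::tibble(region_id = "x", chrom = reg$chrom[1],
                           start = reg$start[1], end = reg$start[1] + 20L)
  co0 <- cooccurrence(only_a, mots$CArG_6, mots$G_box, tr, n_sets = 10,
                      seed = 5)
  expect_equal(co0$observed, 0)
})

test_that("nearest distances concentrate at the planted 150 bp offset", {
  tr <- simulate_genome(small_config(seed = 55))
  mots <- build_motifs()
  reg <- tr$regions |>
    dplyr::filter(.data$tf == "SVP", .data$category %in% c("UB", "2TF")) |>
    dplyr::mutate(start = .data$summit - 250L, end = .data$summit + 250L)
  a <- scan_regions(reg, tr, mots$CArG_6)
  b <- scan_regions(reg, tr, mots$G_box)
  d <- nearest_distances(a, b)
  h <- distance_histogram(d)
  bin_150 <- which(h$bin_start == 150)
  expect_equal(unname(which.max(h$n)), bin_150)
  # direct example: single pair at distance 150
  d1 <- nearest_distances(
    tibble::tibble(region_id = "r", start = 100L),
    tibble::tibble(region_id = "r", start = 250L))
  expect_equal(d1$distance, 150)
  # no partner motif in the region -> no distance recorded
  d2 <- nearest_distances(tibble::tibble(region_id = "r", start = 100L),
                          tibble::tibble(region_id = "other", start = 1L))
  expect_equal(nrow(d2), 0)
})

test_that("spacer composition is strand-resolved and recovers planted bias", {
  # all matches on the consensus CCAAAAAAGG -> 100% A at each position
  genome <- c(chr1 = paste0(strrep("T", 50), "CCAAAAAAGG", strrep("T", 50),
                            duetseq:::revcomp("CCAAAAAAGG"), strrep("T", 50)))
  reg <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(0L, 100L), end = c(100L, 170L))
  hits <- scan_regions(reg, genome, build_motifs()$CArG_6,
                       background = rep(0.25, 4))
  # one forward match plus its reverse-complement occurrence: the
  # strand-resolved spacers are identical all-A rows
  hits <- dplyr::bind_rows(
    dplyr::filter(hits, .data$region_id == "r1", .data$strand == "+"),
    dplyr::filter(hits, .data$region_id == "r2", .data$strand == "-"))
  hits <- dplyr::distinct(hits, .data$region_id, .data$strand,
                          .keep_all = TRUE)
  comp <- stretch_composition(hits, genome)
  expect_equal(comp$A, rep(nrow(hits), 6))
  expect_equal(comp$T, rep(0L, 6))
  expect_equal(nrow(hits), 2)

  # planted 70% T bias in 1TF spacers is recovered within 5%
  cfg <- small_config(seed = 56, peak_counts = c(UB = 0L, one_TF = 60L,
                                                 two_TF = 0L),
                      genome_length = 150000L, n_genes = 0L)
  tr <- simulate_genome(cfg)
  sites <- tr$motif_sites[tr$motif_sites$motif_id == "CArG_6", ]
  sites$region_id <- sites$motif_id
  comp2 <- stretch_composition(sites, tr)
  frac_t <- comp2$T / rowSums(comp2[, c("A", "C", "G", "T")])
  expect_lt(max(abs(frac_t - 0.7)), 0.12)
  expect_equal(unique(rowSums(comp2[, c("A", "C", "G", "T")])), nrow(sites))
})
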
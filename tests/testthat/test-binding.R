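test_that("dependency classification performs exact set arithmetic", {
  # identical sets -> all UB
  p <- make_peaks(c(1000, 5000), c(1400, 5400))
  rc <- classify_dependency(p, p)
  expect_true(all(rc$category == "UB"))
  # disjoint sets -> 2TF and 1TF only
  q <- make_peaks(c(9000, 12000), c(9400, 12400))
  rc2 <- classify_dependency(p, q)
  expect_setequal(rc2$category, c("2TF", "1TF"))
  expect_equal(sum(rc2$category == "2TF"), 2)
  expect_equal(sum(rc2$category == "1TF"), 2)
  # set-arithmetic oracle at larger scale: 523- and 264-style counts
  set.seed(44)
  wt_starts <- seq(0, by = 2000, length.out = 523)
  mut_starts <- c(wt_starts[1:200], seq(1.2e6, by = 2000, length.out = 64))
  wt <- make_peaks(wt_starts, wt_starts + 400)
  mut <- make_peaks(mut_starts, mut_starts + 400)
  rc3 <- classify_dependency(wt, mut)
  counts <- table(rc3$category)
  expect_equal(unname(counts["UB"]), 200)
  expect_equal(unname(counts["2TF"]), 323)
  expect_equal(unname(counts["1TF"]), 64)
  # conservation: |UB| + |2TF| = |WT|, |UB| + |1TF| = |mutant| (1:1 overlap)
  expect_equal(sum(counts[c("UB", "2TF")]), nrow(wt))
  expect_equal(sum(counts[c("UB", "1TF")]), nrow(mut))
})

test_that("normalized scores scale by library size and summarise direction", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chr1",
                            start = c(1000L, 3000L), end = c(1400L, 3400L))
  base <- flat_track(counts = rep(0L, 500),
                     blocks = list(list(start = 1000, end = 1400, value = 25L),
                                   list(start = 3000, end = 3400, value = 25L)))
  # equal libraries, equal counts -> zero differences
  ns <- normalized_scores(regions, base, base)
  expect_equal(ns$diff_sign, c(0, 0))
  expect_equal(score_direction_summary(ns)$pct_higher, 0)
  # same counts but twice the library in B -> halved score, A higher
  bigger <- base
  bigger$count <- bigger$count * 2L
  attr(bigger, "library_size") <- sum(bigger$count)
  ns2 <- normalized_scores(regions, base, bigger)
  expect_equal(ns2$score_a, ns2$score_b, tolerance = 1e-12)
  # explicit 100-vs-50 case from region read counts 100 at libs 1e6 and 2e6
  track_a <- flat_track(counts = c(rep(0L, 100), rep(10L, 10),
                                   rep(0L, 390)))
  attr(track_a, "library_size") <- 1e6
  track_b <- track_a
  attr(track_b, "library_size") <- 2e6
  reg <- tibble::tibble(region_id = "r", chrom = "chr1", start = 1000L,
                        end = 1100L)
  ns3 <- normalized_scores(reg, track_a, track_b)
  expect_equal(ns3$score_a, 100)
  expect_equal(ns3$score_b, 50)
  expect_equal(ns3$diff_sign, 1)
  expect_error(normalized_scores(reg, track_a,
                                 structure(track_b, library_size = 0)),
               "zero library")
})

test_that("the 144-region worked example reproduces 120 regions at 83%", {
  scores <- tibble::tibble(region_id = sprintf("r%03d", 1:144),
                           score_a = c(rep(2, 120), rep(1, 24)),
                           score_b = c(rep(1, 120), rep(2, 24)),
                           diff_sign = c(rep(1, 120), rep(-1, 24)))
  summ <- score_direction_summary(scores)
  expect_equal(summ$n_higher, 120)
  expect_equal(summ$pct_higher, 83)
})

test_that("fraction_higher is invariant under equal library rescaling", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chr1",
                            start = c(1000L, 3000L), end = c(1400L, 3400L))
  set.seed(5)
  a <- flat_track(lambda = 5, n_bins = 500)
  b <- flat_track(lambda = 5, n_bins = 500)
  s1 <- score_direction_summary(normalized_scores(regions, a, b))
  a2 <- a; a2$count <- a2$count * 3L
  attr(a2, "library_size") <- sum(a2$count)
  b2 <- b; b2$count <- b2$count * 3L
  attr(b2, "library_size") <- sum(b2$count)
  s2 <- score_direction_summary(normalized_scores(regions, a2, b2))
  expect_equal(s1$pct_higher, s2$pct_higher)
})

test_that("profile extraction aligns, scales and zero-fills correctly", {
  regions <- tibble::tibble(region_id = "r1", chrom = "chr1",
                            summit = 5000L)
  flat <- flat_track(counts = rep(3L, 1000))
  prof <- extract_profiles(regions, list(s1 = flat), halfwidth = 750L,
                           bin = 30L)
  # flat coverage: every 30 bp bin holds 3 bins of 3 reads, RPM-scaled
  expect_equal(ncol(prof$values), 50)
  expect_equal(unname(prof$values[1, ]),
               rep(9 * 1e6 / sum(flat$count), 50))
  expect_false(prof$info$clipped[1])
  # summit near the chromosome start: left bins zero-filled, flagged
  edge <- tibble::tibble(region_id = "r2", chrom = "chr1", summit = 100L)
  prof2 <- extract_profiles(edge, list(s1 = flat), halfwidth = 750L)
  expect_true(prof2$info$clipped[1])
  expect_equal(unname(prof2$values[1, 1:10]), rep(0, 10))
  # entirely outside the chromosome -> error
  out <- tibble::tibble(region_id = "r3", chrom = "chr1", summit = 20000L)
  expect_error(extract_profiles(out, list(s1 = flat)), "outside")
})

test_that("symmetric planted peaks give symmetric mean profiles", {
  cfg <- small_config(seed = 41, peak_counts = c(UB = 6L, one_TF = 0L,
                                                 two_TF = 0L),
                      n_genes = 0L, genome_length = 60000L,
                      library_size = 6e5, peak_enrichment = 30)
  tr <- simulate_genome(cfg)
  reg <- dplyr::filter(tr$regions, .data$tf == "SVP")
  prof <- extract_profiles(reg, list(s1 = simulate_chip_coverage(tr, "WT", 1)))
  m <- colMeans(prof$values)
  m <- m - min(m)
  asym <- sum(abs(m - rev(m))) / sum(m)
  expect_lt(asym, 0.2)
})

test_that("fPCA recovers structure and reconstructs the data", {
  # all rows identical -> no variance, no components
  flat <- matrix(5, nrow = 4, ncol = 20)
  fp <- fpca(flat)
  expect_equal(fp$k_retained, 0L)
  expect_equal(ncol(fp$scores), 0)
  expect_error(fpca(flat[1, , drop = FALSE]), "at least 2")

  # two noiseless shape families separate on component 1
  x <- seq(-2, 2, length.out = 40)
  narrow <- dnorm(x, sd = 0.5)
  wide <- dnorm(x, sd = 1.2)
  mat <- rbind(narrow, narrow, narrow, wide, wide, wide)
  fp2 <- fpca(mat)
  expect_equal(fp2$var_explained[1], 1, tolerance = 1e-10)
  s1 <- fp2$scores[, 1]
  expect_equal(length(unique(round(s1, 8))), 2)
  expect_true(max(abs(range(s1[1:3]) - s1[1])) < 1e-8)

  # SVD identity: full reconstruction of the centred matrix
  set.seed(8)
  rnd <- matrix(rnorm(30 * 25), 30, 25)
  fp3 <- fpca(rnd)
  recon <- fp3$scores %*% t(fp3$loadings)
  centred <- sweep(rnd, 2, fp3$mean_profile)
  expect_lt(max(abs(recon - centred)), 1e-8)
  # loadings orthonormal, variance fractions non-increasing and <= 1
  expect_equal(t(fp3$loadings) %*% fp3$loadings,
               diag(ncol(fp3$loadings)), tolerance = 1e-8)
  expect_true(all(diff(fp3$var_explained) <= 1e-12))
  expect_lte(sum(fp3$var_explained), 1 + 1e-12)
})

test_that("Hotelling T2 matches the univariate t and degenerate cases", {
  ht <- hotelling_t2(c(0, 1, 2), c(3, 4, 5))
  expect_equal(ht$T2, 13.5)
  tt <- t.test(c(0, 1, 2), c(3, 4, 5), var.equal = TRUE)
  expect_equal(ht$T2, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht$p, tt$p.value, tolerance = 1e-10)

  same <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  ht2 <- hotelling_t2(same, same)
  expect_equal(ht2$T2, 0)
  expect_equal(ht2$p, 1)

  # singular pooled covariance falls back to the pseudo-inverse
  x1 <- cbind(c(1, 2, 3), c(2, 4, 6))
  x2 <- cbind(c(4, 5, 6), c(8, 10, 12))
  ht3 <- hotelling_t2(x1, x2)
  expect_true(ht3$singular)
  expect_gte(ht3$T2, 0)
  expect_error(hotelling_t2(cbind(1, 1), cbind(2, 2)), "too few")
})

test_that("Hotelling type-I error is nominal on null score sets", {
  set.seed(55)
  n_regions <- 2000
  pvals <- vapply(seq_len(n_regions), function(i) {
    s <- matrix(rnorm(12), 6, 2)
    hotelling_t2(s[1:3, ], s[4:6, ])$p
  }, numeric(1))
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.01)
})

test_that("differential binding flags planted shape shifts after BH", {
  cfg <- small_config(seed = 42, peak_counts = c(UB = 24L, one_TF = 0L,
                                                 two_TF = 0L),
                      n_genes = 0L, genome_length = 200000L,
                      library_size = 1e6, shape_shift = 0.5)
  tr <- simulate_genome(cfg)
  covW <- setNames(lapply(1:3, function(r) {
    simulate_chip_coverage(tr, "WT", r)
  }), paste0("wt", 1:3))
  covM <- setNames(lapply(1:3, function(r) {
    simulate_chip_coverage(tr, "mutant", r)
  }), paste0("mu", 1:3))
  reg <- dplyr::filter(tr$regions, .data$tf == "SVP", .data$category == "UB")
  db <- diff_binding(reg, covW, covM)
  res <- dplyr::left_join(db, reg[, c("region_id", "shape_shifted")],
                          by = "region_id")
  # width-ratio-2 shape shifts: >= 80% detected at adjusted p <= 0.05
  expect_gte(mean(res$significant[res$shape_shifted]), 0.8)
  expect_true(all(db$k <= 3))
})

test_that("heatmap ordering sorts by max median bin and masks outliers", {
  mat <- rbind(r1 = c(rep(5, 5), rep(0, 5)),
               r2 = c(rep(3, 5), rep(1, 5)),
               r3 = c(rep(9, 5), rep(2, 5)))
  ord <- heatmap_order(mat, n_bins_for_median = 5)
  expect_equal(ord$order, c("r3", "r1", "r2"))
  expect_equal(unname(ord$max_median[c("r1", "r2", "r3")]), c(5, 3, 9))
  # a single value over the cutoff masks the region
  mat2 <- mat
  mat2["r3", 10] <- 21
  ord2 <- heatmap_order(mat2, n_bins_for_median = 5)
  expect_equal(ord2$mask, "r3")
  expect_equal(ord2$order, c("r1", "r2"))
  # ties preserve input order (stable sort)
  mat3 <- rbind(a = rep(4, 10), b = rep(4, 10), c = rep(4, 10))
  expect_equal(heatmap_order(mat3, 5)$order, c("a", "b", "c"))
})
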
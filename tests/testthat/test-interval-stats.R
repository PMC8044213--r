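test_that("Jaccard matches per-base counting and its invariants hold", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  expect_equal(interval_jaccard(a, b), 50 / 150)
  expect_equal(interval_jaccard(a, a), 1)
  disjoint <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  expect_equal(interval_jaccard(a, disjoint), 0)
  expect_error(interval_jaccard(a[0, ], b[0, ]), "empty")

  set.seed(71)
  for (r in 1:8) {
    x <- rand_intervals(15)
    y <- rand_intervals(12)
    j <- interval_jaccard(x, y)
    expect_equal(j, bf_jaccard(x, y), tolerance = 1e-12)
    expect_equal(j, interval_jaccard(y, x))  # symmetry
    expect_true(j >= 0 && j <= 1)
  }
})

test_that("reciprocal overlap applies the strict both-sides rule", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 40L, end = 140L)
  expect_equal(nrow(reciprocal_overlap(a, b)$pairs), 1L)  # overlap 60 > 50
  b2 <- data.frame(chrom = "chr1", start = 90L, end = 300L)
  expect_equal(nrow(reciprocal_overlap(a, b2)$pairs), 0L)  # overlap 10
  expect_error(reciprocal_overlap(a, b, min_frac = 0), "min_frac")
  expect_error(reciprocal_overlap(a, b, min_frac = 1.2), "min_frac")

  # brute-force equivalence on random sets, both modes
  set.seed(72)
  for (r in 1:5) {
    x <- rand_intervals(60)
    y <- rand_intervals(60)
    for (es in c(FALSE, TRUE)) {
      got <- reciprocal_overlap(x, y, either_side = es)$pairs
      want <- bf_reciprocal(x, y, either_side = es)
      got_keys <- if (nrow(got)) paste(got$idx_a, got$idx_b) else character(0)
      want_keys <- if (is.null(want)) character(0)
                   else paste(want[, 1], want[, 2])
      expect_setequal(got_keys, want_keys)
    }
  }
})

test_that("nearest TSS distances follow the strand-signed convention", {
  tss <- data.frame(chrom = "chr1", pos = c(1000L, 5000L),
                    strand = c("+", "-"),
                    gene_id = c("gplus", "gminus"))
  iv <- data.frame(chrom = "chr1",
                   start = c(950L, 1450L, 5200L),
                   end = c(1050L, 1550L, 5300L))
  nt <- nearest_tss(iv, tss)
  expect_equal(nt$distance, c(0, 500, -250))  # midpoint at TSS; +500 3' of
  expect_equal(nt$gene_id, c("gplus", "gplus", "gminus"))
  expect_error(nearest_tss(iv, tss[0, ]), "empty")

  set.seed(73)
  for (r in 1:5) {
    x <- rand_intervals(40)
    t <- data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                    pos = sample.int(5000, 30),
                    strand = sample(c("+", "-"), 30, replace = TRUE),
                    gene_id = paste0("g", 1:30))
    expect_equal(nearest_tss(x, t)$distance, bf_nearest(x, t))
  }
})

test_that("feature annotation follows the documented precedence", {
  gm <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                   tss = 10000L, tts = 20000L,
                   exon_starts = "10000,15000", exon_ends = "11000,16000")
  # 100 bp upstream of the TSS with a 1 kb window -> promoter
  ann <- annotate_features(data.frame(chrom = "chr1", start = 9850L,
                                      end = 9950L), gm)
  expect_equal(ann$feature, "promoter")
  # gene desert -> intergenic
  ann2 <- annotate_features(data.frame(chrom = "chr1", start = 500000L,
                                       end = 500100L), gm)
  expect_equal(ann2$feature, "intergenic")
  # overlapping both promoter and intron -> promoter wins
  ann3 <- annotate_features(data.frame(chrom = "chr1", start = 9500L,
                                       end = 14000L), gm)
  expect_equal(ann3$feature, "promoter")
  # inside the second exon / in the intron
  ann4 <- annotate_features(data.frame(chrom = "chr1", start = 15100L,
                                       end = 15200L), gm)
  expect_equal(ann4$feature, "exon")
  ann5 <- annotate_features(data.frame(chrom = "chr1", start = 12000L,
                                       end = 12100L), gm)
  expect_equal(ann5$feature, "intron")
  expect_error(annotate_features(data.frame(chrom = "chr1", start = 1L,
                                            end = 2L),
                                 data.frame(gene_id = "g1",
                                            chrom = "chr1", strand = "+",
                                            tss = 1000L, tts = 2000L,
                                            exon_starts = "10,20",
                                            exon_ends = "15")),
               "malformed exon")
})

test_that("gene-set overlap p-values match hypergeometric enumeration", {
  bg <- paste0("g", 1:100)
  res <- gene_set_overlap_test(bg, bg, bg)
  expect_equal(res$p_value, 1)

  # table (5,5,5,85)
  set_a <- bg[1:10]
  set_b <- bg[c(1:5, 11:15)]
  res2 <- gene_set_overlap_test(set_a, set_b, bg)
  expect_equal(res2$p_value, bf_fisher_p(5, 5, 5, 85), tolerance = 1e-9)
  # symmetric in the two sets
  res3 <- gene_set_overlap_test(set_b, set_a, bg)
  expect_equal(res2$p_value, res3$p_value)

  # disjoint small sets in a large background: no enrichment signal
  res4 <- gene_set_overlap_test(bg[1:3], bg[4:6], bg)
  expect_gt(res4$p_value, 0.5)
  expect_error(gene_set_overlap_test(c("zz"), bg[1:3], bg), "subsets")

  set.seed(74)
  for (r in 1:20) {
    n11 <- sample(0:6, 1); n12 <- sample(0:8, 1)
    n21 <- sample(0:8, 1); n22 <- sample(5:60, 1)
    a <- as.character(seq_len(n11 + n12))
    b <- as.character(c(seq_len(n11), n11 + n12 + seq_len(n21)))
    bg2 <- as.character(seq_len(n11 + n12 + n21 + n22))
    expect_equal(gene_set_overlap_test(a, b, bg2)$p_value,
                 bf_fisher_p(n11, n12, n21, n22), tolerance = 1e-9)
  }
})

test_that("binned meta-profiles have the right geometry and means", {
  set.seed(75)
  pos <- seq(0, 30000, by = 25)
  tot <- rpois(length(pos), 50)
  tr <- make_track(pos, rbinom(length(pos), tot, 0.6), tot)
  iv <- data.frame(chrom = "chr1", start = c(8000L, 20000L),
                   end = c(12000L, 24000L))

  sm <- bin_signal(tr, iv, mode = "center", flank_bp = 2000, bin_bp = 100)
  expect_equal(ncol(sm$matrix), 40L)  # 2 * 2000 / 100
  expect_true(all(abs(sm$col_means - 0.6) < 0.1))

  # uniform exact track: every column mean equals the level
  tru <- make_track(pos, rep(3, length(pos)), rep(4, length(pos)))
  smu <- bin_signal(tru, iv, mode = "center")
  expect_true(all(abs(smu$col_means - 0.75) < 1e-12))
  # mass conservation over the tiled window
  expect_equal(sum(smu$col_means) * 100, 2 * 2000 * 0.75)

  sms <- bin_signal(tru, iv, mode = "scaled", flank_bp = 1000,
                    bin_bp = 100, body_bins = 10)
  expect_equal(ncol(sms$matrix), 10 + 2 * 10)
  expect_true(all(abs(sms$col_means - 0.75) < 1e-12))

  expect_error(bin_signal(tr, iv, bin_bp = 0), "positive")
  expect_error(bin_signal(tr, iv, flank_bp = 1050, bin_bp = 100), "divide")
})

test_that("meta-profiles over planted DMEs mirror the truth table", {
  cfg <- sim_config(seed = 77, n_chroms = 1, chrom_length = 4e5,
                    n_foundational = 4, n_canyons = 1, n_dme = 10,
                    coverage_mean = 15, non_cpg_sites = 200,
                    pattern_weights = list(B1a = c(P1 = 1),
                                           B2 = c(P2 = 1)))
  g <- generate_genome(1, cfg$chrom_length, 100, seed = cfg$seed)
  arch <- plant_architecture(g, cfg)
  dme <- arch$intervals[arch$intervals$layer == "dme", ]
  pro <- simulate_wgbs(arch, "proB", "B1a", cfg)
  mat <- simulate_wgbs(arch, "WT", "B1a", cfg)
  body <- function(track) {
    sm <- bin_signal(track, dme, mode = "scaled", flank_bp = 1000,
                     bin_bp = 100, body_bins = 10)
    mean(sm$col_means[11:20])
  }
  # P1 = (0.8, 0.2, 0.2): demethylated body in mature B1a but not proB
  expect_gt(body(pro), 0.7)
  expect_lt(body(mat), 0.3)
})

test_that("rank correlation agrees with a hand-rolled tie-aware oracle", {
  expect_equal(correlate_over_intervals(1:10, 10:1), -1)
  expect_equal(correlate_over_intervals(1:10, 1:10), 1)
  expect_true(is.na(correlate_over_intervals(rep(1, 5), 1:5)))
  expect_error(correlate_over_intervals(1:2, 1:2), "3 complete")

  set.seed(76)
  for (r in 1:10) {
    x <- sample(1:8, 50, replace = TRUE)  # heavy ties
    y <- x * -0.5 + rnorm(50)
    expect_equal(correlate_over_intervals(x, y), bf_spearman(x, y),
                 tolerance = 1e-12)
  }
})
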
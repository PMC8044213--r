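test_that("beta difference score has exact symmetry properties", {
  expect_equal(beta_diff_score(3, 6, 3, 6), 0.5)
  # complement property for continuous posteriors
  set.seed(41)
  for (r in 1:20) {
    ta <- sample(1:15, 1); tb <- sample(1:15, 1)
    ma <- sample(0:ta, 1); mb <- sample(0:tb, 1)
    s1 <- beta_diff_score(ma, ta, mb, tb)
    s2 <- beta_diff_score(mb, tb, ma, ta)
    expect_equal(s1 + s2, 1, tolerance = 1e-12)
  }
  expect_error(beta_diff_score(0, 0, 1, 2), "coverage")
})

test_that("exact finite-sum score equals numerical quadrature", {
  # spot grid here; the exhaustive <=20 sweep runs in the acceptance suite
  s <- beta_diff_score(5, 5, 0, 5)
  expect_equal(s, quad_diff_score(5, 5, 0, 5), tolerance = 1e-8)
  set.seed(42)
  for (r in 1:50) {
    ta <- sample(1:20, 1); tb <- sample(1:20, 1)
    ma <- sample(0:ta, 1); mb <- sample(0:tb, 1)
    expect_equal(beta_diff_score(ma, ta, mb, tb),
                 quad_diff_score(ma, ta, mb, tb), tolerance = 1e-8)
  }
})

test_that("per-track scoring joins on position and skips zero coverage", {
  a <- make_track(pos = c(10, 20, 30), meth = c(1, 0, 5),
                  total = c(5, 0, 5))
  b <- make_track(pos = c(10, 20, 40), meth = c(4, 2, 1),
                  total = c(5, 4, 2))
  sc <- diff_score_track(a, b)
  expect_equal(sc$pos, 10)
  expect_equal(sc$score, beta_diff_score(1, 5, 4, 5))
  expect_gt(attr(sc, "n_skipped"), 0)
})

test_that("DMR filters apply the 10-CpG / 5-significant rule exactly", {
  # constructed toy: one A-HMR with no overlapping B-HMR
  mk_scores <- function(n_cpgs, n_sig) {
    pos <- seq(100, by = 50, length.out = n_cpgs)
    # significant hypo-in-A: score <= 0.05; others 0.5
    score <- rep(0.5, n_cpgs)
    if (n_sig > 0) score[seq_len(n_sig)] <- 0.01
    data.frame(chrom = "chr1", pos = pos,
               meth_a = 0L, total_a = 5L, meth_b = 5L, total_b = 5L,
               score = score)
  }
  hmr_a <- data.frame(chrom = "chr1", start = 50L, end = 1000L)
  hmr_b <- data.frame(chrom = character(), start = integer(),
                      end = integer())

  d <- call_dmrs(hmr_a, hmr_b, mk_scores(12, 7))
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hypo_in_a")
  expect_equal(d$n_cpgs, 12L)
  expect_equal(d$n_sig, 7L)

  expect_equal(nrow(call_dmrs(hmr_a, hmr_b, mk_scores(8, 8))), 0L)
  expect_equal(nrow(call_dmrs(hmr_a, hmr_b, mk_scores(12, 4))), 0L)

  # identical HMR sets leave no candidate fragments
  expect_equal(nrow(call_dmrs(hmr_a, hmr_a, mk_scores(12, 7))), 0L)
})

test_that("DMR calling is symmetric under swapping the two samples", {
  set.seed(43)
  pos <- cumsum(sample(60:140, 400, replace = TRUE))
  lev_a <- rep(0.85, 400); lev_a[100:129] <- 0.05
  lev_b <- rep(0.85, 400); lev_b[300:329] <- 0.05
  tot_a <- rpois(400, 10); tot_b <- rpois(400, 10)
  tr_a <- make_track(pos, rbinom(400, tot_a, lev_a), tot_a)
  tr_b <- make_track(pos, rbinom(400, tot_b, lev_b), tot_b)
  hmr_a <- call_hmrs(tr_a, meth_hmm(tr_a, max_iter = 30))
  hmr_b <- call_hmrs(tr_b, meth_hmm(tr_b, max_iter = 30))
  d_ab <- call_dmrs(hmr_a, hmr_b, diff_score_track(tr_a, tr_b))
  d_ba <- call_dmrs(hmr_b, hmr_a, diff_score_track(tr_b, tr_a))
  expect_equal(d_ab[, c("chrom", "start", "end")],
               d_ba[order(match(d_ba$direction,
                                c("hypo_in_b", "hypo_in_a"))),
                    c("chrom", "start", "end")],
               ignore_attr = TRUE)
  swap <- c(hypo_in_a = "hypo_in_b", hypo_in_b = "hypo_in_a")
  expect_setequal(paste(d_ab$start, d_ab$direction),
                  paste(d_ba$start, unname(swap[d_ba$direction])))
})

test_that("region methylation is the coverage-weighted mean with NA gaps", {
  tr <- make_track(pos = c(100, 200, 900), meth = c(3, 1, 4),
                   total = c(4, 4, 4))
  iv <- data.frame(chrom = "chr1", start = c(50L, 400L),
                   end = c(300L, 600L))
  rs <- region_meth_stat(tr, iv)
  expect_equal(rs$mean_meth, c(0.5, NA_real_))
  expect_equal(rs$n_cpgs, c(2L, 0L))

  # brute-force per-read tally on a simulated 50-CpG interval
  set.seed(44)
  tot <- rpois(50, 8) + 1L
  meth <- rbinom(50, tot, 0.3)
  tr2 <- make_track(pos = seq(1000, by = 20, length.out = 50),
                    meth = meth, total = tot)
  rs2 <- region_meth_stat(tr2, data.frame(chrom = "chr1", start = 990L,
                                          end = 2000L))
  reads <- unlist(mapply(function(m, t) c(rep(1, m), rep(0, t - m)),
                         meth, tot))
  expect_equal(rs2$mean_meth, mean(reads))
})

test_that("three identical tracks yield zero DDMRs", {
  set.seed(45)
  pos <- cumsum(sample(60:140, 300, replace = TRUE))
  tot <- rpois(300, 10)
  lev <- rep(0.85, 300); lev[100:119] <- 0.05
  tr <- make_track(pos, rbinom(300, tot, lev), tot)
  fit <- meth_hmm(tr, max_iter = 30)
  hmrs <- call_hmrs(tr, fit)
  dd <- construct_ddmrs(list(proB = tr, WT = tr, KO = tr),
                        hmrs = list(proB = hmrs, WT = hmrs, KO = hmrs))
  expect_equal(nrow(dd), 0L)
  expect_error(construct_ddmrs(list(proB = tr, WT = tr)), "KO")
})

test_that("a planted DNMT3A-dependent interval is recovered as a DDMR", {
  set.seed(46)
  n <- 600
  pos <- cumsum(sample(60:140, n, replace = TRUE))
  dme <- 280:309  # 30 CpGs
  mk <- function(level_in_dme) {
    lev <- rep(0.85, n); lev[dme] <- level_in_dme
    tot <- rpois(n, 20)
    make_track(pos, rbinom(n, tot, lev), tot)
  }
  tracks <- list(proB = mk(0.8), WT = mk(0.8), KO = mk(0.2))
  hmrs <- lapply(tracks, function(tr)
    call_hmrs(tr, meth_hmm(tr, max_iter = 30)))
  dd <- construct_ddmrs(tracks, hmrs = hmrs)
  expect_equal(nrow(dd), 1L)
  v <- unlist(dd[1, c("mean_proB", "mean_WT", "mean_KO")])
  expect_true(all(abs(v - c(0.8, 0.8, 0.2)) < 0.1))
  # merged interval set is sorted and non-overlapping by construction
  expect_true(all(dd$end > dd$start))
})
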
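test_that("posterior decoding matches exhaustive path enumeration", {
  set.seed(31)
  params <- hmm_params(trans = matrix(c(0.9, 0.1, 0.2, 0.8), 2,
                                      byrow = TRUE),
                       init_p = c(0.4, 0.6),
                       alpha = c(1, 7), beta = c(8, 2))
  for (n in c(2, 5, 9, 12)) {
    total <- rpois(n, 8) + 1L
    meth <- rbinom(n, total, sample(c(0.1, 0.8), n, replace = TRUE))
    tr <- make_track(pos = cumsum(sample(50:150, n)), meth = meth,
                     total = total)
    fit <- meth_hmm(tr, init = params, tol = Inf)  # decode at init params
    post <- predict(fit, tr)
    oracle <- enum_posterior(meth, total, params$trans, params$init_p,
                             params$alpha, params$beta)
    expect_lt(max(abs(post$posterior_hypo - oracle)), 1e-9)
  }
})

test_that("EM log-likelihood is monotone and tol=Inf returns the init", {
  set.seed(32)
  n <- 400
  level <- rep(c(0.85, 0.05, 0.85), c(150, 80, 170))
  total <- rpois(n, 6)
  tr <- make_track(pos = cumsum(sample(40:160, n, replace = TRUE)),
                   meth = rbinom(n, total, level), total = total)
  fit <- meth_hmm(tr, max_iter = 40)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))

  fit0 <- meth_hmm(tr, tol = Inf)
  expect_equal(fit0$params$alpha, hmm_params()$alpha)
  expect_equal(fit0$params$trans, hmm_params()$trans)
  expect_length(fit0$loglik_trace, 1L)

  expect_error(meth_hmm(make_track(pos = c(1, 50), meth = c(0, 0),
                                   total = c(0, 0))),
               "covered CpGs")
})

test_that("EM recovers two-state emission means from simulated data", {
  set.seed(33)
  n <- 3000
  # simulate from a known two-state chain with means 0.05 / 0.85
  st <- integer(n); st[1] <- 2L
  for (t in 2:n)
    st[t] <- if (runif(1) < 0.98) st[t - 1] else 3L - st[t - 1]
  total <- rpois(n, 10)
  meth <- rbinom(n, total, c(0.05, 0.85)[st])
  tr <- make_track(pos = cumsum(sample(50:150, n, replace = TRUE)),
                   meth = meth, total = total)
  fit <- meth_hmm(tr, max_iter = 60)
  m <- coef(fit)
  expect_lt(abs(m[["hypo_mean"]] - 0.05), 0.05)
  expect_lt(abs(m[["hyper_mean"]] - 0.85), 0.05)
  expect_s3_class(logLik(fit), "logLik")
})

test_that("a planted hypomethylated block is recovered with tight bounds", {
  set.seed(34)
  pos <- cumsum(sample(80:120, 200, replace = TRUE))
  level <- rep(0.85, 200)
  level[90:109] <- 0.05  # 20 CpGs ~ 2 kb
  total <- rpois(200, 10)
  tr <- make_track(pos = pos, meth = rbinom(200, total, level),
                   total = total)
  fit <- meth_hmm(tr, max_iter = 40)
  hmrs <- call_hmrs(tr, fit)
  expect_equal(nrow(hmrs), 1L)
  covered <- predict(fit, tr)
  idx_start <- match(hmrs$start[1], covered$pos)
  idx_end <- match(hmrs$end[1] - 2L, covered$pos)
  true_start <- which(covered$pos == pos[90])
  true_end <- which(covered$pos == pos[109])
  expect_lte(abs(idx_start - true_start), 2)
  expect_lte(abs(idx_end - true_end), 2)
})

test_that("a uniformly hypermethylated track yields no HMRs", {
  set.seed(35)
  total <- rpois(500, 10)
  tr <- make_track(pos = cumsum(sample(80:120, 500, replace = TRUE)),
                   meth = rbinom(500, total, 0.85), total = total)
  fit <- meth_hmm(tr, max_iter = 40)
  expect_equal(nrow(call_hmrs(tr, fit)), 0L)
})

test_that("model methods (predict, simulate, residuals) are coherent", {
  set.seed(36)
  level <- rep(c(0.85, 0.05, 0.85), c(100, 40, 100))
  total <- rpois(240, 10)
  tr <- make_track(pos = cumsum(sample(80:120, 240, replace = TRUE)),
                   meth = rbinom(240, total, level), total = total)
  fit <- meth_hmm(tr, max_iter = 40)
  post <- predict(fit)
  expect_true(all(post$posterior_hypo >= 0 & post$posterior_hypo <= 1))
  sim <- simulate(fit, seed = 1, coverage_mean = 10)
  expect_s3_class(sim, "methylome_track")
  expect_equal(nrow(sim), fit$n_sites)
  r <- residuals(fit)
  expect_length(r, fit$n_sites)
  expect_lt(abs(mean(r)), 0.1)
  expect_output(print(summary(fit)), "occupancy")
})

test_that("canyon classification is an exact length threshold", {
  hmrs <- data.frame(chrom = "chr1",
                     start = c(0L, 10000L, 20000L),
                     end = c(3400L, 13500L, 23600L),
                     n_cpgs = c(30L, 40L, 50L),
                     mean_meth = 0.05)
  hmrs$length <- hmrs$end - hmrs$start
  cy <- call_canyons(hmrs)
  expect_equal(cy$length, c(3500L, 3600L))
  expect_equal(nrow(call_canyons(hmrs[0, ])), 0L)
  expect_equal(nrow(call_canyons(hmrs, min_length = 0)), 3L)
  expect_error(call_canyons(hmrs, min_length = -1), "non-negative")
  # pure filter: invariant to input order
  shuffled <- hmrs[c(3, 1, 2), ]
  expect_setequal(call_canyons(shuffled)$start, cy$start)
})

test_that("HMR length statistics and K-S match brute force", {
  hmrs <- data.frame(chrom = "chr1", start = c(0, 1000, 5000),
                     end = c(100, 1200, 5300))
  st <- hmr_length_stats(hmrs, genome_size = 1e4)
  expect_equal(st$median_length, 200)
  expect_equal(st$n, 3L)
  expect_equal(st$genome_fraction, 600 / 1e4)
  expect_error(hmr_length_stats(hmrs[0, ]), "empty")

  expect_equal(hmr_ks_stat(c(100, 200, 300), c(100, 200, 300))$statistic, 0)

  # K-S equals the ECDF sup-difference on random sets
  set.seed(37)
  for (r in 1:5) {
    a <- sample(50:5000, sample(10:100, 1), replace = TRUE)
    b <- sample(50:5000, sample(10:100, 1), replace = TRUE)
    grid <- sort(unique(c(a, b)))
    sup <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
    expect_equal(hmr_ks_stat(a, b)$statistic, sup, tolerance = 1e-12)
  }
})
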
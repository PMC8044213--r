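# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Gauss-Legendre nodes/weights on [0, 1] via Golub-Welsch (eigen of the
# Jacobi matrix). Exact for polynomial integrands of degree <= 2n - 1.
gauss_legendre01 <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- 2 * ev$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

# quadrature oracle for P(p_a > p_b) under Beta(m+1, t-m+1) posteriors:
# integrand dbeta(x, a1, b1) * pbeta(x, a2, b2) is a polynomial of degree
# <= a1 + b1 + a2 + b2, so 64 nodes are exact for totals <= 20
quad_diff_score <- local({
  gl <- gauss_legendre01(64)
  function(ma, ta, mb, tb) {
    a1 <- ma + 1; b1 <- ta - ma + 1
    a2 <- mb + 1; b2 <- tb - mb + 1
    sum(gl$w * dbeta(gl$x, a1, b1) * pbeta(gl$x, a2, b2))
  }
})

# exhaustive posterior state marginals of a 2-state HMM by path enumeration
enum_posterior <- function(meth, total, trans, init_p, alpha, beta) {
  n <- length(meth)
  emis <- function(s, i)
    choose(total[i], meth[i]) *
      beta(meth[i] + alpha[s], total[i] - meth[i] + beta[s]) /
      beta(alpha[s], beta[s])
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  joint <- apply(paths, 1, function(st) {
    p <- init_p[st[1]] * emis(st[1], 1)
    for (t in seq_len(n - 1))
      p <- p * trans[st[t], st[t + 1]] * emis(st[t + 1], t + 1)
    p
  })
  sapply(seq_len(n), function(t)
    sum(joint[paths[, t] == 1]) / sum(joint))
}

# per-base-pair Jaccard on small coordinate spaces
bf_jaccard <- function(a, b, max_coord = 10000) {
  cover <- function(iv) {
    hit <- character(0)
    for (j in seq_len(nrow(iv)))
      hit <- c(hit, paste(iv$chrom[j], seq(iv$start[j], iv$end[j] - 1)))
    unique(hit)
  }
  ca <- cover(a); cb <- cover(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# all-pairs reciprocal overlap
bf_reciprocal <- function(a, b, min_frac = 0.5, either_side = FALSE) {
  pairs <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov <= 0) next
    la <- a$end[i] - a$start[i]; lb <- b$end[j] - b$start[j]
    keep <- if (either_side) ov > min_frac * la || ov > min_frac * lb
            else ov > min_frac * la && ov > min_frac * lb
    if (keep) pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

# exhaustive nearest-TSS search
bf_nearest <- function(intervals, tss) {
  sapply(seq_len(nrow(intervals)), function(j) {
    mid <- floor((intervals$start[j] + intervals$end[j]) / 2)
    t <- tss[tss$chrom == intervals$chrom[j], , drop = FALSE]
    d <- abs(mid - t$pos)
    k <- which.min(d)
    if (t$strand[k] == "-") t$pos[k] - mid else mid - t$pos[k]
  })
}

# two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins
bf_fisher_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; c1 <- n11 + n21; n <- n11 + n12 + n21 + n22
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  obs <- dhyper(n11, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Spearman correlation with hand-rolled average ranks
bf_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random small interval sets for oracle comparisons
rand_intervals <- function(n, chroms = c("chr1", "chr2"),
                           max_coord = 5000) {
  start <- sample.int(max_coord - 100, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample(10:300, n, replace = TRUE))
}

# small track construction helper
make_track <- function(pos, meth, total, chrom = "chr1", strand = "+",
                       context = "CpG", sample_id = "test") {
  methylome_track(
    data.frame(chrom = chrom, pos = pos, strand = strand,
               context = context, meth = meth, total = total),
    sample_id = sample_id)
}
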
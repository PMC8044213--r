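#' Exact Beta-posterior differential methylation score
#'
#' With independent uniform-prior posteriors `p_A ~ Beta(meth_a + 1,
#' unmeth_a + 1)` and `p_B ~ Beta(meth_b + 1, unmeth_b + 1)`, returns
#' `P(p_A > p_B)` by the exact finite-sum identity for integer shape
#' parameters (all terms positive, evaluated on the log scale):
#' \deqn{P(X > Y) = \sum_{i=0}^{a_1-1}
#'   \frac{B(a_2+i,\; b_1+b_2)}{(b_1+i)\,B(1+i,\;b_1)\,B(a_2,b_2)}}
#'
#' @param meth_a,total_a,meth_b,total_b integer count vectors (recycled).
#' @return Numeric vector of probabilities `P(p_A > p_B)`.
#' @export
beta_diff_score <- function(meth_a, total_a, meth_b, total_b) {
  n <- max(length(meth_a), length(total_a), length(meth_b), length(total_b))
  meth_a <- rep_len(meth_a, n); total_a <- rep_len(total_a, n)
  meth_b <- rep_len(meth_b, n); total_b <- rep_len(total_b, n)
  if (any(total_a <= 0) || any(total_b <= 0))
    stop("both sites must have positive coverage")
  a1 <- meth_a + 1; b1 <- total_a - meth_a + 1
  a2 <- meth_b + 1; b2 <- total_b - meth_b + 1
  vapply(seq_len(n), function(k) {
    i <- 0:(a1[k] - 1)
    sum(exp(lbeta(a2[k] + i, b1[k] + b2[k]) - log(b1[k] + i) -
              lbeta(1 + i, b1[k]) - lbeta(a2[k], b2[k])))
  }, numeric(1))
}

#' Per-CpG differential methylation scores between two tracks
#'
#' Joins the covered CpGs of both tracks on `(chrom, pos)` and computes
#' [beta_diff_score()] at each shared site. Sites with zero coverage in
#' either track are skipped; their count is recorded in the `n_skipped`
#' attribute.
#'
#' @param track_a,track_b [methylome_track()] objects (CpG context).
#' @return Data frame `chrom, pos, meth_a, total_a, meth_b, total_b, score`
#'   where `score = P(p_A > p_B)`.
#' @export
diff_score_track <- function(track_a, track_b) {
  a <- as.data.frame(track_a)
  a <- a[a$context == "CpG", c("chrom", "pos", "meth", "total")]
  b <- as.data.frame(track_b)
  b <- b[b$context == "CpG", c("chrom", "pos", "meth", "total")]
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  covered <- m$total_a > 0 & m$total_b > 0
  n_skipped <- sum(!covered) +
    (nrow(a) - nrow(m)) + (nrow(b) - nrow(m))
  m <- m[covered, , drop = FALSE]
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  m$score <- beta_diff_score(m$meth_a, m$total_a, m$meth_b, m$total_b)
  rownames(m) <- NULL
  attr(m, "n_skipped") <- n_skipped
  m
}

# per-chromosome IRanges view of a BED-style interval frame
split_iranges <- function(iv) {
  lapply(split(iv, iv$chrom), function(d)
    IRanges(start = d$start + 1L, end = d$end))
}

iranges_to_bed <- function(ir_by_chrom) {
  out <- lapply(names(ir_by_chrom), function(ch) {
    ir <- ir_by_chrom[[ch]]
    if (!length(ir)) return(NULL)
    data.frame(chrom = ch, start = BiocGenerics::start(ir) - 1L,
               end = BiocGenerics::end(ir))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  out[order(out$chrom, out$start), , drop = FALSE]
}

# interval-set difference a \ b (both BED-style), per chromosome
interval_setdiff <- function(a, b) {
  ia <- split_iranges(a)
  ib <- split_iranges(b)
  out <- lapply(names(ia), function(ch) {
    d <- if (ch %in% names(ib))
      BiocGenerics::setdiff(ia[[ch]], ib[[ch]]) else
        IRanges::reduce(ia[[ch]])
    if (!length(d)) return(NULL)
    data.frame(chrom = ch, start = BiocGenerics::start(d) - 1L,
               end = BiocGenerics::end(d))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions from HMR sets and CpG scores
#'
#' Candidate fragments are the parts of one sample's HMRs not covered by the
#' other's (an HMR present in A but not B makes a hypo-in-A candidate, and
#' vice versa). A fragment becomes a DMR when it spans at least `min_cpgs`
#' scored CpGs of which at least `min_sig` are significant in the concordant
#' direction: for hypo-in-A fragments `P(p_A < p_B) >= sig_level`
#' (i.e. `score <= 1 - sig_level`), for hypo-in-B `score >= sig_level`.
#'
#' @param hmrs_a,hmrs_b HMR data frames from [call_hmrs()].
#' @param scores output of [diff_score_track()] for the same two tracks
#'   (A first).
#' @param min_cpgs minimum scored CpGs per retained DMR.
#' @param min_sig minimum concordantly significant CpGs.
#' @param sig_level one-sided significance level for a CpG.
#' @return Data frame `chrom, start, end, direction, n_cpgs, n_sig,
#'   mean_a, mean_b`.
#' @export
call_dmrs <- function(hmrs_a, hmrs_b, scores, min_cpgs = 10L,
                      min_sig = 5L, sig_level = 0.95) {
  frag_a <- interval_setdiff(hmrs_a, hmrs_b)
  frag_b <- interval_setdiff(hmrs_b, hmrs_a)
  score_frags <- function(frags, direction) {
    if (!nrow(frags)) return(NULL)
    rows <- lapply(seq_len(nrow(frags)), function(j) {
      s <- scores[scores$chrom == frags$chrom[j] &
                    scores$pos >= frags$start[j] &
                    scores$pos < frags$end[j], , drop = FALSE]
      sig <- if (direction == "hypo_in_a")
        s$score <= 1 - sig_level else s$score >= sig_level
      data.frame(chrom = frags$chrom[j], start = frags$start[j],
                 end = frags$end[j], direction = direction,
                 n_cpgs = nrow(s), n_sig = sum(sig),
                 mean_a = sum(s$meth_a) / sum(s$total_a),
                 mean_b = sum(s$meth_b) / sum(s$total_b))
    })
    do.call(rbind, rows)
  }
  out <- rbind(score_frags(frag_a, "hypo_in_a"),
               score_frags(frag_b, "hypo_in_b"))
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_cpgs = integer(), n_sig = integer(),
                      mean_a = numeric(), mean_b = numeric()))
  out <- out[out$n_cpgs >= min_cpgs & out$n_sig >= min_sig, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage-weighted mean methylation over intervals
#'
#' For each half-open interval, `sum(meth) / sum(total)` over the CpGs it
#' contains. Intervals with no covered CpG get `NA` (missing, not zero).
#'
#' @param track a [methylome_track()].
#' @param intervals BED-style data frame (`chrom, start, end`).
#' @return Data frame `chrom, start, end, mean_meth, n_cpgs`.
#' @export
region_meth_stat <- function(track, intervals) {
  x <- as.data.frame(track)
  x <- x[x$context == "CpG" & x$total > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(intervals)), function(j) {
    s <- x[x$chrom == intervals$chrom[j] &
             x$pos >= intervals$start[j] &
             x$pos < intervals$end[j], , drop = FALSE]
    data.frame(chrom = intervals$chrom[j], start = intervals$start[j],
               end = intervals$end[j],
               mean_meth = if (nrow(s)) sum(s$meth) / sum(s$total)
                           else NA_real_,
               n_cpgs = nrow(s))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_meth = numeric(),
                      n_cpgs = integer())
  rownames(out) <- NULL
  out
}

#' Construct DNMT3A-dependent DMRs from three conditions of one lineage
#'
#' Computes pairwise DMRs for (proB, WT), (proB, KO) and (WT, KO), merges
#' the union of all retained DMR intervals (0 bp slack), keeps merged
#' intervals supported by at least `min_support` distinct pairwise
#' comparisons, and annotates each with its per-condition mean methylation
#' vector `(proB, WT, KO)` via [region_meth_stat()].
#'
#' @param tracks named list of [methylome_track()]s: `proB`, `WT`, `KO`.
#' @param hmrs named list of HMR sets for the same conditions (if missing,
#'   HMMs are fitted and HMRs called per condition).
#' @param min_cpgs,min_sig,sig_level DMR filters, see [call_dmrs()].
#' @param min_support minimum number of pairwise comparisons that must
#'   contribute a DMR overlapping the merged interval.
#' @param ... passed to [meth_hmm()] when `hmrs` is `NULL`.
#' @return Data frame `chrom, start, end, mean_proB, mean_WT, mean_KO,
#'   n_cpgs, support`, sorted and non-overlapping.
#' @export
construct_ddmrs <- function(tracks, hmrs = NULL, min_cpgs = 10L,
                            min_sig = 5L, sig_level = 0.95,
                            min_support = 1L, ...) {
  need <- c("proB", "WT", "KO")
  if (!all(need %in% names(tracks)))
    stop("tracks must be a named list with proB, WT and KO")
  if (is.null(hmrs)) {
    hmrs <- lapply(tracks[need], function(tr)
      call_hmrs(tr, meth_hmm(tr, ...)))
  }
  if (!all(need %in% names(hmrs)))
    stop("hmrs must be a named list with proB, WT and KO")
  pairs <- list(c("proB", "WT"), c("proB", "KO"), c("WT", "KO"))
  dmr_sets <- lapply(pairs, function(pr) {
    sc <- diff_score_track(tracks[[pr[1]]], tracks[[pr[2]]])
    call_dmrs(hmrs[[pr[1]]], hmrs[[pr[2]]], sc,
              min_cpgs = min_cpgs, min_sig = min_sig,
              sig_level = sig_level)
  })
  names(dmr_sets) <- vapply(pairs, paste, collapse = "_", character(1))
  all_dmrs <- do.call(rbind, lapply(names(dmr_sets), function(nm) {
    d <- dmr_sets[[nm]]
    if (!nrow(d)) return(NULL)
    d$comparison <- nm
    d[, c("chrom", "start", "end", "comparison")]
  }))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_proB = numeric(),
                      mean_WT = numeric(), mean_KO = numeric(),
                      n_cpgs = integer(), support = integer())
  if (is.null(all_dmrs) || !nrow(all_dmrs)) return(empty)

  merged <- merge_intervals(all_dmrs)
  # support: number of distinct pairwise comparisons overlapping each merged
  # interval
  support <- integer(nrow(merged))
  for (j in seq_len(nrow(merged))) {
    ov <- all_dmrs$chrom == merged$chrom[j] &
      all_dmrs$start < merged$end[j] & all_dmrs$end > merged$start[j]
    support[j] <- length(unique(all_dmrs$comparison[ov]))
  }
  merged$support <- support
  merged <- merged[merged$support >= min_support, , drop = FALSE]
  if (!nrow(merged)) return(empty)

  v <- lapply(need, function(cond)
    region_meth_stat(tracks[[cond]], merged)$mean_meth)
  merged$mean_proB <- v[[1]]
  merged$mean_WT <- v[[2]]
  merged$mean_KO <- v[[3]]
  merged$n_cpgs <- region_meth_stat(tracks$WT, merged)$n_cpgs
  rownames(merged) <- NULL
  merged[, c("chrom", "start", "end", "mean_proB", "mean_WT", "mean_KO",
             "n_cpgs", "support")]
}
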
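#' Merge (union-reduce) an interval set
#'
#' Collapses overlapping or book-ended intervals per chromosome into a
#' sorted, non-overlapping set (0-based half-open throughout).
#'
#' @param intervals BED-style data frame (`chrom, start, end`).
#' @return Merged data frame `chrom, start, end`.
#' @export
merge_intervals <- function(intervals) {
  if (!nrow(intervals))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  ir <- split_iranges(intervals)
  out <- iranges_to_bed(lapply(ir, IRanges::reduce))
  rownames(out) <- NULL
  out
}

#' Jaccard statistic between two interval sets
#'
#' Base-pair intersection over base-pair union after internally merging each
#' set; ranges from 0 (no overlap) to 1 (identical coverage).
#'
#' @param set_a,set_b BED-style data frames.
#' @return A single number in `[0, 1]`.
#' @export
interval_jaccard <- function(set_a, set_b) {
  if (!nrow(set_a) && !nrow(set_b))
    stop("both interval sets are empty")
  a <- merge_intervals(set_a)
  b <- merge_intervals(set_b)
  bp <- function(x) sum(as.numeric(x$end - x$start))
  un <- bp(merge_intervals(rbind(a[, 1:3], b[, 1:3])))
  inter <- bp(a) + bp(b) - un
  inter / un
}

#' Reciprocally overlapping interval pairs
#'
#' A pair is reported when the overlap length is strictly greater than
#' `min_frac` of the length of *each* interval ("over 50% overlap",
#' required of both sides); `either_side = TRUE` relaxes to either interval.
#'
#' @param set_a,set_b BED-style data frames.
#' @param min_frac required overlap fraction in `(0, 1]`.
#' @param either_side require the fraction of only one interval.
#' @return List with `pairs` (indices into each set plus overlap bp),
#'   `n_a_overlapped` and `n_b_overlapped`.
#' @export
reciprocal_overlap <- function(set_a, set_b, min_frac = 0.5,
                               either_side = FALSE) {
  if (min_frac <= 0 || min_frac > 1)
    stop("min_frac must lie in (0, 1]")
  empty <- list(pairs = data.frame(idx_a = integer(), idx_b = integer(),
                                   overlap_bp = integer()),
                n_a_overlapped = 0L, n_b_overlapped = 0L)
  if (!nrow(set_a) || !nrow(set_b)) return(empty)
  pairs <- NULL
  for (ch in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    ai <- which(set_a$chrom == ch)
    bi <- which(set_b$chrom == ch)
    ira <- IRanges(set_a$start[ai] + 1L, set_a$end[ai])
    irb <- IRanges(set_b$start[bi] + 1L, set_b$end[bi])
    fo <- findOverlaps(ira, irb)
    if (!length(fo)) next
    ov <- width(pintersect(ira[queryHits(fo)], irb[subjectHits(fo)]))
    la <- width(ira[queryHits(fo)])
    lb <- width(irb[subjectHits(fo)])
    keep <- if (either_side)
      ov > min_frac * la | ov > min_frac * lb
    else
      ov > min_frac * la & ov > min_frac * lb
    if (!any(keep)) next
    pairs <- rbind(pairs, data.frame(idx_a = ai[queryHits(fo)[keep]],
                                     idx_b = bi[subjectHits(fo)[keep]],
                                     overlap_bp = ov[keep]))
  }
  if (is.null(pairs)) return(empty)
  list(pairs = pairs,
       n_a_overlapped = length(unique(pairs$idx_a)),
       n_b_overlapped = length(unique(pairs$idx_b)))
}

#' Signed distance from interval midpoints to the nearest TSS
#'
#' The distance runs from the closest TSS to the interval midpoint, signed
#' by the TSS strand: positive downstream (3') of the TSS, negative
#' upstream, 0 when the midpoint coincides with the TSS.
#'
#' @param intervals BED-style data frame.
#' @param tss data frame `chrom, pos, strand, gene_id`.
#' @return Data frame `gene_id, distance`, one row per interval (`NA` where
#'   the chromosome has no TSS).
#' @export
nearest_tss <- function(intervals, tss) {
  if (!nrow(tss)) stop("empty TSS set")
  mid <- floor((intervals$start + intervals$end) / 2)
  out <- data.frame(gene_id = rep(NA_character_, nrow(intervals)),
                    distance = rep(NA_real_, nrow(intervals)))
  for (j in seq_len(nrow(intervals))) {
    t <- tss[tss$chrom == intervals$chrom[j], , drop = FALSE]
    if (!nrow(t)) next
    d <- abs(mid[j] - t$pos)
    k <- which.min(d)
    signed <- if (t$strand[k] == "-") t$pos[k] - mid[j] else mid[j] - t$pos[k]
    out$gene_id[j] <- t$gene_id[k]
    out$distance[j] <- signed
  }
  out
}

#' Read a minimal transcript table gene model
#'
#' Tab-separated with header: `gene_id, chrom, strand, tss, tts` plus
#' optional comma-separated `exon_starts`, `exon_ends` and optional
#' `utr5_start, utr5_end, utr3_start, utr3_end` spans. Without exon columns
#' the whole gene body counts as exon.
#'
#' @param path file path.
#' @return Gene model data frame.
#' @export
read_gene_model <- function(path) {
  gm <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tts")
  if (!all(need %in% names(gm)))
    stop("malformed gene model: needs columns ",
         paste(need, collapse = ", "))
  gm
}

# expand a gene model into per-feature interval tables
gene_model_features <- function(gm, promoter_window, tts_window) {
  body_start <- pmin(gm$tss, gm$tts)
  body_end <- pmax(gm$tss, gm$tts) + 1L
  feat <- list(
    promoter = data.frame(chrom = gm$chrom,
                          start = pmax(0L, gm$tss - promoter_window),
                          end = gm$tss + promoter_window + 1L),
    TTS = data.frame(chrom = gm$chrom,
                     start = pmax(0L, gm$tts - tts_window),
                     end = gm$tts + tts_window + 1L))
  grab_span <- function(s, e) {
    ok <- !is.na(s) & !is.na(e) & e > s
    data.frame(chrom = gm$chrom[ok], start = s[ok], end = e[ok])
  }
  feat$utr5 <- if (all(c("utr5_start", "utr5_end") %in% names(gm)))
    grab_span(gm$utr5_start, gm$utr5_end) else
      data.frame(chrom = character(), start = integer(), end = integer())
  feat$utr3 <- if (all(c("utr3_start", "utr3_end") %in% names(gm)))
    grab_span(gm$utr3_start, gm$utr3_end) else
      data.frame(chrom = character(), start = integer(), end = integer())
  if (all(c("exon_starts", "exon_ends") %in% names(gm))) {
    ex <- lapply(seq_len(nrow(gm)), function(i) {
      s <- suppressWarnings(as.integer(strsplit(
        as.character(gm$exon_starts[i]), ",")[[1]]))
      e <- suppressWarnings(as.integer(strsplit(
        as.character(gm$exon_ends[i]), ",")[[1]]))
      if (length(s) != length(e) || anyNA(s) || anyNA(e))
        stop("malformed exon list for gene ", gm$gene_id[i])
      data.frame(chrom = gm$chrom[i], start = s, end = e, body_i = i)
    })
    ex <- do.call(rbind, ex)
    feat$exon <- ex[, c("chrom", "start", "end")]
    bodies <- data.frame(chrom = gm$chrom, start = body_start,
                         end = body_end)
    feat$intron <- interval_setdiff(bodies, feat$exon)
  } else {
    feat$exon <- data.frame(chrom = gm$chrom, start = body_start,
                            end = body_end)
    feat$intron <- data.frame(chrom = character(), start = integer(),
                              end = integer())
  }
  feat
}

#' Annotate intervals with genomic features
#'
#' Labels each interval with exactly one feature by overlap under the
#' precedence promoter > TTS > 5'UTR > 3'UTR > exon > intron > intergenic,
#' where promoter = TSS +/- `promoter_window` and TTS = termination site
#' +/- `tts_window`. Nearest gene and signed TSS distance come from
#' [nearest_tss()].
#'
#' @param intervals BED-style data frame.
#' @param gene_model data frame as read by [read_gene_model()].
#' @param promoter_window,tts_window half-widths in bp.
#' @return Data frame `feature, nearest_gene, tss_distance`, one row per
#'   interval.
#' @export
annotate_features <- function(intervals, gene_model,
                              promoter_window = 1000, tts_window = 100) {
  feat <- gene_model_features(gene_model, promoter_window, tts_window)
  precedence <- c("promoter", "TTS", "utr5", "utr3", "exon", "intron")
  pretty <- c(promoter = "promoter", TTS = "TTS", utr5 = "5'UTR",
              utr3 = "3'UTR", exon = "exon", intron = "intron")
  overlaps_any <- function(iv_row, set) {
    any(set$chrom == iv_row$chrom & set$start < iv_row$end &
          set$end > iv_row$start)
  }
  feature <- character(nrow(intervals))
  for (j in seq_len(nrow(intervals))) {
    row <- intervals[j, , drop = FALSE]
    hit <- "intergenic"
    for (f in precedence) {
      if (nrow(feat[[f]]) && overlaps_any(row, feat[[f]])) {
        hit <- pretty[[f]]
        break
      }
    }
    feature[j] <- hit
  }
  tssd <- nearest_tss(intervals,
                      data.frame(chrom = gene_model$chrom,
                                 pos = gene_model$tss,
                                 strand = gene_model$strand,
                                 gene_id = gene_model$gene_id))
  data.frame(feature = feature, nearest_gene = tssd$gene_id,
             tss_distance = tssd$distance)
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' Two-sided Fisher's exact test on the 2x2 membership table induced by the
#' two sets over a common background (e.g. all expressed genes).
#'
#' @param set_a,set_b character vectors of gene ids, subsets of
#'   `background`.
#' @param background character vector of background gene ids.
#' @return List with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
gene_set_overlap_test <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  background <- unique(background)
  if (!all(set_a %in% background) || !all(set_b %in% background))
    stop("both gene sets must be subsets of the background")
  n11 <- length(intersect(set_a, set_b))
  n12 <- length(setdiff(set_a, set_b))
  n21 <- length(setdiff(set_b, set_a))
  n22 <- length(background) - n11 - n12 - n21
  tab <- matrix(c(n11, n12, n21, n22), 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Binned signal matrix over intervals (meta-profiles)
#'
#' `mode = "center"` tiles `2 * flank_bp / bin_bp` bins of `bin_bp` around
#' each interval midpoint; `mode = "scaled"` length-normalises each interval
#' body to `body_bins` bins flanked by fixed-width flank bins. Each cell is
#' the coverage-weighted mean methylation of the CpGs falling in the bin;
#' empty bins are `NA` and are excluded (not zero-filled) from the column
#' means, so low-coverage bins do not drag profiles toward zero.
#'
#' @param track a [methylome_track()].
#' @param intervals BED-style data frame.
#' @param mode `"center"` or `"scaled"`.
#' @param flank_bp,bin_bp flank extent and bin width (`bin_bp` must divide
#'   `flank_bp`).
#' @param body_bins number of body bins in scaled mode.
#' @return List of class `signal_matrix`: `matrix` (intervals x bins),
#'   `col_means`, and the binning metadata.
#' @export
bin_signal <- function(track, intervals, mode = c("center", "scaled"),
                       flank_bp = 2000, bin_bp = 100, body_bins = 20L) {
  mode <- match.arg(mode)
  if (bin_bp <= 0) stop("bin_bp must be positive")
  if (flank_bp %% bin_bp != 0) stop("bin_bp must divide flank_bp")
  x <- as.data.frame(track)
  x <- x[x$context == "CpG" & x$total > 0, , drop = FALSE]
  nf <- flank_bp %/% bin_bp
  ncol_out <- if (mode == "center") 2L * nf else 2L * nf + body_bins
  mat <- matrix(NA_real_, nrow(intervals), ncol_out)
  bin_mean <- function(s, lo, hi) {
    sel <- s$pos >= lo & s$pos < hi
    if (!any(sel)) return(NA_real_)
    sum(s$meth[sel]) / sum(s$total[sel])
  }
  for (j in seq_len(nrow(intervals))) {
    s <- x[x$chrom == intervals$chrom[j], , drop = FALSE]
    if (!nrow(s)) next
    if (mode == "center") {
      mid <- floor((intervals$start[j] + intervals$end[j]) / 2)
      edges <- mid - flank_bp + bin_bp * (0:(2L * nf))
      for (k in seq_len(ncol_out))
        mat[j, k] <- bin_mean(s, edges[k], edges[k + 1])
    } else {
      left <- intervals$start[j] - flank_bp + bin_bp * (0:nf)
      body <- seq(intervals$start[j], intervals$end[j],
                  length.out = body_bins + 1L)
      right <- intervals$end[j] + bin_bp * (0:nf)
      edges <- c(left[-length(left)], NA, right[-length(right)], NA)
      for (k in seq_len(nf))
        mat[j, k] <- bin_mean(s, left[k], left[k + 1])
      for (k in seq_len(body_bins))
        mat[j, nf + k] <- bin_mean(s, body[k], body[k + 1])
      for (k in seq_len(nf))
        mat[j, nf + body_bins + k] <- bin_mean(s, right[k], right[k + 1])
    }
  }
  structure(list(matrix = mat,
                 col_means = colMeans(mat, na.rm = TRUE),
                 mode = mode, flank_bp = flank_bp, bin_bp = bin_bp,
                 body_bins = if (mode == "scaled") body_bins else 0L),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal matrix: %d intervals x %d bins (%s mode)\n",
              nrow(x$matrix), ncol(x$matrix), x$mode))
  invisible(x)
}

#' Rank correlation of paired per-interval values
#'
#' Spearman rank correlation (average ranks for ties) of two per-interval
#' signals, e.g. methylation vs chromatin accessibility; Pearson available
#' behind the `method` flag. Pairs with missing values are dropped;
#' constant input on either side yields `NA` (undefined correlation).
#'
#' @param values_x,values_y numeric vectors of equal length (>= 3 complete
#'   pairs).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation coefficient, or `NA` when undefined.
#' @export
correlate_over_intervals <- function(values_x, values_y,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(values_x, values_y)
  x <- values_x[ok]; y <- values_y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}
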
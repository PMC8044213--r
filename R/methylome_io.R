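#' Construct a methylome track
#'
#' A methylome track is a data frame of per-cytosine read counts with columns
#' `chrom`, `pos` (0-based position of the C on the plus strand), `strand`
#' (`"+"`/`"-"`), `context` (`"CpG"`, `"CHG"` or `"CHH"`), `meth` (reads
#' reporting a protected, i.e. unconverted, cytosine) and `total` (total
#' reads). Rows are kept sorted by `(chrom, pos)`.
#'
#' @param df data frame with the six columns above.
#' @param sample_id optional sample label stored as an attribute.
#' @return A `methylome_track` (a sorted data frame).
#' @export
methylome_track <- function(df, sample_id = NA_character_) {
  need <- c("chrom", "pos", "strand", "context", "meth", "total")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing track columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$context <- as.character(df$context)
  if (any(df$total < 0) || any(df$meth < 0))
    stop("negative read counts")
  if (any(df$meth > df$total))
    stop("meth count exceeds total count")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("methylome_track", "data.frame"),
            sample_id = sample_id)
}

#' @export
print.methylome_track <- function(x, ...) {
  cat(sprintf("methylome track '%s': %d sites on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  cov <- x$total > 0
  if (any(cov))
    cat(sprintf("  mean coverage %.2f, overall level %.4f\n",
                mean(x$total), sum(x$meth) / sum(x$total)))
  print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Per-site methylation level
#'
#' `meth / total`, `NA` where a site has no coverage.
#'
#' @param track a [methylome_track()].
#' @return Numeric vector in `[0, 1]` (or `NA`).
#' @export
meth_level <- function(track) {
  ifelse(track$total > 0, track$meth / track$total, NA_real_)
}

#' Read a methcounts-style per-cytosine count table
#'
#' Expects whitespace-delimited columns `chrom pos strand context level
#' coverage`. Positions are taken as 0-based. The methylated read count is
#' reconstructed as `round(level * coverage)` (round-half-to-even, since the
#' source format stores a ratio rather than counts).
#'
#' @param path file path.
#' @param context_filter context to retain (default `"CpG"`); `NULL` keeps
#'   all contexts.
#' @param sample_id sample label; defaults to the file name.
#' @return A [methylome_track()].
#' @export
read_methcounts <- function(path, context_filter = "CpG",
                            sample_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        meth = integer(), total = integer())
    return(methylome_track(empty, sample_id = sample_id))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("malformed methcounts line ", which(nf != 6L)[1L],
         ": expected 6 fields, got ", nf[nf != 6L][1L])
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  level <- suppressWarnings(as.numeric(m[, 5L]))
  coverage <- suppressWarnings(as.numeric(m[, 6L]))
  bad <- which(is.na(pos) | is.na(level) | is.na(coverage))
  if (length(bad))
    stop("malformed methcounts line ", bad[1L], ": non-numeric field")
  if (any(level < 0 | level > 1))
    stop("methylation level outside [0,1] at line ",
         which(level < 0 | level > 1)[1L])
  if (any(coverage < 0))
    stop("negative coverage at line ", which(coverage < 0)[1L])
  df <- data.frame(chrom = m[, 1L], pos = pos, strand = m[, 3L],
                   context = m[, 4L],
                   meth = as.integer(round(level * coverage)),
                   total = as.integer(round(coverage)))
  if (!is.null(context_filter))
    df <- df[df$context %in% context_filter, , drop = FALSE]
  methylome_track(df, sample_id = sample_id)
}

#' Write a methylome track in methcounts format
#'
#' @param track a [methylome_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_methcounts <- function(track, path) {
  level <- ifelse(track$total > 0, track$meth / track$total, 0)
  out <- sprintf("%s\t%d\t%s\t%s\t%.10g\t%d",
                 track$chrom, track$pos, track$strand, track$context,
                 level, track$total)
  writeLines(out, path)
  invisible(path)
}

#' Merge symmetric CpG dyads
#'
#' A minus-strand CpG at position `p` reports the same dyad as the
#' plus-strand site at `p - 1`; their counts are summed into one plus-strand
#' record at the plus-strand C position. Unpaired sites are kept as-is, so
#' the operation is idempotent and conserves total read counts. Non-CpG
#' contexts pass through unchanged.
#'
#' @param track a [methylome_track()].
#' @return A merged [methylome_track()].
#' @export
merge_symmetric_cpgs <- function(track) {
  cpg <- track$context == "CpG"
  rest <- as.data.frame(track)[!cpg, , drop = FALSE]
  x <- as.data.frame(track)[cpg, , drop = FALSE]
  plus <- x[x$strand == "+", , drop = FALSE]
  minus <- x[x$strand == "-", , drop = FALSE]
  key_plus <- paste(plus$chrom, plus$pos)
  key_minus <- paste(minus$chrom, minus$pos - 1L)
  idx <- match(key_minus, key_plus)
  paired <- !is.na(idx)
  if (any(paired)) {
    tgt <- idx[paired]
    plus$meth[tgt] <- plus$meth[tgt] + minus$meth[paired]
    plus$total[tgt] <- plus$total[tgt] + minus$total[paired]
  }
  out <- rbind(plus, minus[!paired, , drop = FALSE], rest)
  methylome_track(out, sample_id = attr(track, "sample_id"))
}

#' Estimate the bisulfite conversion rate from non-CpG cytosines
#'
#' Non-CpG cytosines (CHH/CHG) are assumed unmethylated, so every converted
#' read at these sites reflects a successful conversion. The rate is the
#' fraction of non-CpG reads read as T:
#' `(total reads - protected reads) / total reads`.
#'
#' @param track a [methylome_track()] containing CHH/CHG sites.
#' @return A `conversion_stats` list with `conversion_rate` and
#'   `n_sites_used`.
#' @export
estimate_conversion_rate <- function(track) {
  noncpg <- track$context %in% c("CHH", "CHG")
  tot <- sum(track$total[noncpg])
  if (tot == 0)
    stop("no covered non-CpG cytosines; cannot estimate conversion rate")
  prot <- sum(track$meth[noncpg])
  structure(list(conversion_rate = (tot - prot) / tot,
                 n_sites_used = sum(noncpg & track$total > 0)),
            class = "conversion_stats")
}

#' @export
print.conversion_stats <- function(x, ...) {
  cat(sprintf("bisulfite conversion rate: %.4f (%d non-CpG sites)\n",
              x$conversion_rate, x$n_sites_used))
  invisible(x)
}

#' Coverage-weighted modified fraction per cytosine context
#'
#' @param track a [methylome_track()].
#' @return Named numeric vector of `sum(meth)/sum(total)` per context.
#' @export
global_methylation_summary <- function(track) {
  if (!nrow(track)) stop("empty track")
  meth <- tapply(track$meth, track$context, sum)
  tot <- tapply(track$total, track$context, sum)
  out <- as.numeric(meth) / as.numeric(tot)
  names(out) <- names(meth)
  out
}

#' Read a BED interval file
#'
#' BED3+ dialect, 0-based half-open. The first six columns are named
#' `chrom, start, end, name, score, strand`; any further columns keep their
#' `V*` names.
#'
#' @param path file path.
#' @return Data frame of intervals sorted by `(chrom, start)`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "",
                   colClasses = NA)
  std <- c("chrom", "start", "end", "name", "score", "strand")
  n <- min(ncol(df), 6L)
  names(df)[seq_len(n)] <- std[seq_len(n)]
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$start >= df$end))
    stop("invalid interval with start >= end at record ",
         which(df$start >= df$end)[1L])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' Writes every column of `intervals` tab-separated with no header, so
#' BED6+ extra columns (e.g. CpG counts, mean methylation) survive a
#' round-trip through [read_bed()].
#'
#' @param intervals data frame with at least `chrom`, `start`, `end`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$start >= intervals$end))
    stop("invalid interval with start >= end")
  write.table(intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a methylation level track as bedGraph
#'
#' One record per covered site: `chrom  pos  pos+1  level`.
#'
#' @param track a [methylome_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  cov <- track$total > 0
  x <- track[cov, , drop = FALSE]
  out <- sprintf("%s\t%d\t%d\t%.6g", x$chrom, x$pos, x$pos + 1L,
                 x$meth / x$total)
  writeLines(out, path)
  invisible(path)
}
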
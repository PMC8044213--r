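#' Estimate TAB-Seq efficiencies from spike-in controls
#'
#' Spike-in templates of known composition calibrate the assay: the
#' glucosylation protection efficiency `g_protect` is the protected (read
#' as C) fraction of the pure-5hmC control, the bisulfite conversion rate
#' `c_conv` is the converted fraction of the unmethylated control, and the
#' TET oxidation efficiency `f_ox` solves the pure-5mC control's protected
#' fraction `p = (1 - f_ox) + f_ox * (1 - c_conv)`.
#'
#' @param spike_hmc,spike_mc,spike_unmeth [methylome_track()]s of the
#'   pure-5hmC, pure-5mC and fully unmethylated controls.
#' @param min_coverage minimum aggregate read count per control.
#' @return A `tabseq_eff` list with `f_ox`, `g_protect`, `c_conv` and the
#'   aggregate coverages used.
#' @export
estimate_efficiencies <- function(spike_hmc, spike_mc, spike_unmeth,
                                  min_coverage = 100) {
  frac <- function(tr, what) {
    tot <- sum(tr$total)
    if (tot < min_coverage)
      stop("insufficient aggregate coverage (", tot, ") on the ", what,
           " control")
    c(sum(tr$meth) / tot, tot)
  }
  ph <- frac(spike_hmc, "pure-5hmC")
  pm <- frac(spike_mc, "pure-5mC")
  pu <- frac(spike_unmeth, "unmethylated")
  c_conv <- 1 - pu[1]
  g_protect <- ph[1]
  if (c_conv <= 0)
    stop("conversion rate estimated as 0; cannot solve for f_ox")
  f_ox <- (1 - pm[1]) / c_conv
  clamp <- function(x, nm) {
    if (x < 0 || x > 1) {
      warning(nm, " solved outside [0,1] (", signif(x, 4), "); clamped")
      x <- min(1, max(0, x))
    }
    x
  }
  structure(list(f_ox = clamp(f_ox, "f_ox"),
                 g_protect = clamp(g_protect, "g_protect"),
                 c_conv = clamp(c_conv, "c_conv"),
                 coverage = c(hmc = ph[2], mc = pm[2], unmeth = pu[2])),
            class = "tabseq_eff")
}

#' @export
print.tabseq_eff <- function(x, ...) {
  cat(sprintf(paste0("TAB-Seq efficiencies: TET oxidation %.3f, ",
                     "5hmC protection %.3f, conversion %.3f\n"),
              x$f_ox, x$g_protect, x$c_conv))
  invisible(x)
}

#' Euclidean projection onto the probability simplex
#'
#' @param v numeric vector, or matrix with one point per row.
#' @return Projected vector/matrix: non-negative entries summing to 1.
#' @export
project_simplex <- function(v) {
  proj1 <- function(x) {
    u <- sort(x, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(x - theta, 0)
  }
  if (is.null(dim(v))) proj1(v) else t(apply(v, 1, proj1))
}

#' Deconvolve (unmethylated, 5mC, 5hmC) fractions from paired assays
#'
#' WGBS protects both 5mC and 5hmC while TAB-Seq protects only
#' (glucosylated) 5hmC, so the two protected fractions identify the
#' cytosine-state simplex. With `u = 1 - m - h` the forward model is
#' `p_wgbs = (m + h) + u (1 - c)` and
#' `p_tab = h g + m (1 - f) + (u + m f)(1 - c)`, solved linearly:
#' `m + h = (p_wgbs - (1 - c)) / c` and
#' `h = (p_tab - (1 - c) - (m + h) c (1 - f)) / (g - 1 + c - c (1 - f))`.
#' Solutions outside the simplex are Euclidean-projected onto it unless
#' `project = FALSE` (raw solutions reported).
#'
#' @param meth_wgbs,total_wgbs,meth_tab,total_tab count vectors for the
#'   paired WGBS and TAB-Seq observations (recycled to a common length).
#' @param eff a [estimate_efficiencies()] result (or a compatible list with
#'   `f_ox`, `g_protect`, `c_conv`).
#' @param project project onto the simplex (default `TRUE`).
#' @return Data frame `u, m, h` (and `u_raw, m_raw, h_raw` when
#'   `project = TRUE`).
#' @export
estimate_5hmc <- function(meth_wgbs, total_wgbs, meth_tab, total_tab, eff,
                          project = TRUE) {
  f <- eff$f_ox; g <- eff$g_protect; cc <- eff$c_conv
  denom <- g - 1 + cc - cc * (1 - f)
  if (abs(denom) < 1e-6)
    stop("degenerate system: g_protect is indistinguishable from the 5mC ",
         "protection channel (g = 1 - f*c under the model); the 5hmC ",
         "fraction is not identifiable")
  n <- max(length(meth_wgbs), length(meth_tab))
  meth_wgbs <- rep_len(meth_wgbs, n); total_wgbs <- rep_len(total_wgbs, n)
  meth_tab <- rep_len(meth_tab, n); total_tab <- rep_len(total_tab, n)
  if (any(total_wgbs <= 0) || any(total_tab <= 0))
    stop("both assays must cover each site")
  p_w <- meth_wgbs / total_wgbs
  p_t <- meth_tab / total_tab
  s <- (p_w - (1 - cc)) / cc           # m + h
  h <- (p_t - (1 - cc) - s * cc * (1 - f)) / denom
  m <- s - h
  u <- 1 - s
  raw <- cbind(u = u, m = m, h = h)
  if (!project)
    return(as.data.frame(raw))
  proj <- project_simplex(raw)
  out <- as.data.frame(proj)
  names(out) <- c("u", "m", "h")
  out$u_raw <- raw[, "u"]; out$m_raw <- raw[, "m"]; out$h_raw <- raw[, "h"]
  out
}

#' Per-CpG or per-region cytosine-state estimates from paired tracks
#'
#' Joins a WGBS and a TAB-Seq track on `(chrom, pos)` and deconvolves each
#' shared covered CpG; with `regions` supplied, counts are aggregated over
#' each interval before solving (per-CpG estimates at ~5x are noisy, so the
#' region mode is how region-level 5hmC statements are operationalised).
#'
#' @param wgbs_track,tab_track paired [methylome_track()]s.
#' @param eff a [estimate_efficiencies()] result.
#' @param regions optional BED-style data frame for region-level estimates.
#' @param project see [estimate_5hmc()].
#' @return Data frame of positions (or intervals) with `u, m, h` and the
#'   coverage in both assays.
#' @export
estimate_5hmc_track <- function(wgbs_track, tab_track, eff, regions = NULL,
                                project = TRUE) {
  a <- as.data.frame(wgbs_track)
  a <- a[a$context == "CpG", c("chrom", "pos", "meth", "total")]
  b <- as.data.frame(tab_track)
  b <- b[b$context == "CpG", c("chrom", "pos", "meth", "total")]
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_wgbs", "_tab"))
  m <- m[m$total_wgbs > 0 & m$total_tab > 0, , drop = FALSE]
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  if (is.null(regions)) {
    est <- estimate_5hmc(m$meth_wgbs, m$total_wgbs, m$meth_tab, m$total_tab,
                         eff, project = project)
    return(cbind(m[, c("chrom", "pos", "total_wgbs", "total_tab")], est))
  }
  rows <- lapply(seq_len(nrow(regions)), function(j) {
    s <- m[m$chrom == regions$chrom[j] & m$pos >= regions$start[j] &
             m$pos < regions$end[j], , drop = FALSE]
    data.frame(chrom = regions$chrom[j], start = regions$start[j],
               end = regions$end[j],
               meth_wgbs = sum(s$meth_wgbs), total_wgbs = sum(s$total_wgbs),
               meth_tab = sum(s$meth_tab), total_tab = sum(s$total_tab))
  })
  r <- do.call(rbind, rows)
  ok <- r$total_wgbs > 0 & r$total_tab > 0
  est <- as.data.frame(matrix(NA_real_, nrow(r), 3,
                              dimnames = list(NULL, c("u", "m", "h"))))
  if (any(ok)) {
    e <- estimate_5hmc(r$meth_wgbs[ok], r$total_wgbs[ok], r$meth_tab[ok],
                       r$total_tab[ok], eff, project = project)
    est[ok, c("u", "m", "h")] <- e[, c("u", "m", "h")]
  }
  cbind(r[, c("chrom", "start", "end", "total_wgbs", "total_tab")], est)
}

#' Average 5hmC by signed distance from HMR boundaries
#'
#' Anchors every HMR start and end, computes each CpG's signed distance to
#' the edge (positive = inside the HMR, negative = outside; strand-agnostic)
#' and averages `h` in bins of `bin_bp` across `+/- flank_bp`. The bin count
#' is `2 * flank_bp / bin_bp`.
#'
#' @param hmrs HMR data frame (`chrom, start, end`).
#' @param hmc data frame with `chrom, pos, h` (e.g. from
#'   [estimate_5hmc_track()]).
#' @param flank_bp,bin_bp profile extent and bin width in bp.
#' @return Data frame `dist_lo, dist_hi, mid, mean_h, n` (one row per bin).
#' @export
hmc_boundary_profile <- function(hmrs, hmc, flank_bp = 2000, bin_bp = 100) {
  if (bin_bp <= 0) stop("bin_bp must be positive")
  breaks <- seq(-flank_bp, flank_bp, by = bin_bp)
  acc_h <- numeric(length(breaks) - 1)
  acc_n <- numeric(length(breaks) - 1)
  for (j in seq_len(nrow(hmrs))) {
    s <- hmc[hmc$chrom == hmrs$chrom[j], , drop = FALSE]
    if (!nrow(s)) next
    for (d in list(s$pos - hmrs$start[j],     # start edge: inside = +
                   hmrs$end[j] - s$pos)) {    # end edge: inside = +
      keep <- d >= -flank_bp & d < flank_bp
      if (!any(keep)) next
      bin <- findInterval(d[keep], breaks, rightmost.closed = FALSE)
      acc_h <- acc_h + tapply_sum(s$h[keep], bin, length(acc_h))
      acc_n <- acc_n + tabulate(bin, nbins = length(acc_n))
    }
  }
  data.frame(dist_lo = breaks[-length(breaks)], dist_hi = breaks[-1],
             mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             mean_h = ifelse(acc_n > 0, acc_h / acc_n, NA_real_),
             n = acc_n)
}

# sum of x by integer bin index into a fixed number of bins
tapply_sum <- function(x, bin, nbins) {
  out <- numeric(nbins)
  agg <- tapply(x, bin, sum)
  out[as.integer(names(agg))] <- agg
  out
}
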
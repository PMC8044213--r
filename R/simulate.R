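#' Simulation configuration for synthetic methylome studies
#'
#' Bundles every knob of the synthetic generator. Defaults reproduce the
#' study conditions the pipeline is validated under: ~5x read coverage per
#' CpG, 98.5% bisulfite conversion, a hypermethylated background (0.85)
#' carrying a shared foundational layer of hypomethylated regions (0.05) and
#' a dynamic layer of DNMT3A-maintained enhancer intervals whose methylation
#' follows condition-specific pattern vectors over (proB, WT mature,
#' KO mature) in two B-cell lineages, and TAB-Seq tracks at ~90% TET
#' oxidation and ~98% conversion efficiency with pure-5hmC / pure-5mC /
#' unmethylated spike-in controls.
#'
#' @param seed integer master seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @param coverage_mean mean reads per CpG (Poisson).
#' @param conversion_rate WGBS bisulfite conversion rate.
#' @param background_level CpG methylation of the hypermethylated background.
#' @param hmr_level CpG methylation inside foundational HMRs.
#' @param n_chroms,chrom_length,cpg_spacing_mean genome geometry; inter-CpG
#'   gaps are geometric with the given mean.
#' @param n_foundational,n_canyons,n_dme number of planted foundational
#'   HMRs (of which `n_canyons` exceed the canyon cutoff) and dynamic
#'   (DME) intervals.
#' @param hmr_cpg_range,dme_cpg_range CpG counts per planted interval
#'   (inclusive ranges).
#' @param canyon_min_length minimum planted canyon length in bp.
#' @param non_cpg_sites number of fully unmethylated CHH/CHG sites added per
#'   simulated track to exercise conversion-rate estimation.
#' @param tab_f_ox,tab_g_protect,tab_conversion TAB-Seq TET oxidation
#'   efficiency of 5mC, glucosylation protection efficiency of 5hmC, and
#'   bisulfite conversion rate.
#' @param spike_sites,spike_coverage size and mean coverage of each spike-in
#'   control track.
#' @param hmc_base,hmc_edge_bump,hmc_edge_sd 5hmC truth model: baseline 5hmC
#'   level, amplitude of the Gaussian enrichment at foundational HMR
#'   boundaries, and its width (bp).
#' @param pattern_weights named list (one element per lineage) of pattern-id
#'   weights used to allocate DME intervals to pattern vectors.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       coverage_mean = 5,
                       conversion_rate = 0.985,
                       background_level = 0.85,
                       hmr_level = 0.05,
                       n_chroms = 2L,
                       chrom_length = 1.2e6,
                       cpg_spacing_mean = 100,
                       n_foundational = 20L,
                       n_canyons = 4L,
                       n_dme = 120L,
                       hmr_cpg_range = c(15L, 35L),
                       dme_cpg_range = c(18L, 30L),
                       canyon_min_length = 3500,
                       non_cpg_sites = 3000L,
                       tab_f_ox = 0.90,
                       tab_g_protect = 0.97,
                       tab_conversion = 0.98,
                       spike_sites = 2000L,
                       spike_coverage = 5,
                       hmc_base = 0.03,
                       hmc_edge_bump = 0.10,
                       hmc_edge_sd = 500,
                       pattern_weights = default_pattern_weights()) {
  rates <- c(conversion_rate, background_level, hmr_level, tab_f_ox,
             tab_g_protect, tab_conversion, hmc_base, hmc_edge_bump)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0,1]")
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' Default pattern-vector weights per lineage
#'
#' Allocation weights over the default 12-vector catalog used when planting
#' DME intervals. Six patterns carry all the weight (mirroring the dominance
#' of a few methylation trajectories in real B-cell methylomes), and in the
#' B1a lineage loss-of-modification shapes (P1, P2, P7) hold 75% of it.
#'
#' @return Named list with numeric weight vectors for `B1a` and `B2`.
#' @export
default_pattern_weights <- function() {
  list(
    B1a = c(P1 = 0.35, P2 = 0.15, P4 = 0.10, P6 = 0.08, P7 = 0.25,
            P10 = 0.07),
    B2 = c(P1 = 0.10, P2 = 0.25, P4 = 0.22, P6 = 0.15, P7 = 0.18,
           P10 = 0.10)
  )
}

#' Generate CpG positions for a synthetic genome
#'
#' Inter-CpG gaps are geometric with mean `cpg_spacing_mean`, giving
#' approximately `chrom_length / cpg_spacing_mean` CpGs per chromosome.
#'
#' @param n_chroms number of chromosomes (`chr1`, `chr2`, ...).
#' @param chrom_length chromosome length in bp.
#' @param cpg_spacing_mean mean inter-CpG spacing in bp (> 1).
#' @param seed integer seed.
#' @return Named list of strictly increasing integer position vectors, with
#'   attribute `chrom_length`.
#' @export
generate_genome <- function(n_chroms = 2L, chrom_length = 1.2e6,
                            cpg_spacing_mean = 100, seed = 1L) {
  if (chrom_length <= 0) stop("chrom_length must be positive")
  if (cpg_spacing_mean <= 1) stop("cpg_spacing_mean must exceed 1")
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_chroms)) {
    n_draw <- ceiling(chrom_length / cpg_spacing_mean * 1.5) + 50L
    gaps <- rgeom(n_draw, 1 / cpg_spacing_mean) + 1L
    pos <- cumsum(gaps)
    out[[paste0("chr", i)]] <- as.integer(pos[pos < chrom_length - 2L])
  }
  attr(out, "chrom_length") <- chrom_length
  out
}

# largest-remainder allocation of n items to weights
allocate_counts <- function(weights, n) {
  w <- weights / sum(weights)
  raw <- w * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1L
  }
  stats::setNames(as.integer(k), names(weights))
}

#' Plant a foundational + dynamic methylome architecture
#'
#' Places non-overlapping intervals along the CpG map: foundational HMRs
#' shared by every condition and lineage (a subset long enough to be
#' canyons) and DME intervals whose methylation follows a pattern vector per
#' lineage. Pattern ids are allocated to DMEs by largest-remainder rounding
#' of the configured weights, then shuffled over interval positions, so the
#' realised pattern composition matches the weights up to rounding.
#'
#' @param genome output of [generate_genome()].
#' @param config a [sim_config()].
#' @param catalog pattern catalog (default [default_pattern_catalog()]).
#' @return A `meth_architecture` list: `genome`, `intervals` (the truth
#'   table of planted intervals), `tss`, `genes`, `catalog` and the level
#'   parameters.
#' @export
plant_architecture <- function(genome, config = sim_config(),
                               catalog = default_pattern_catalog()) {
  set.seed(config$seed + 1L)
  n_f <- config$n_foundational
  n_c <- config$n_canyons
  n_d <- config$n_dme
  if (n_c > n_f) stop("n_canyons cannot exceed n_foundational")
  plan <- c(rep("canyon", n_c), rep("foundational", n_f - n_c),
            rep("dme", n_d))
  plan <- sample(plan)

  rows <- vector("list", length(plan))
  chroms <- names(genome)
  ci <- 1L
  i <- 5L  # CpG index pointer within current chromosome
  for (k in seq_along(plan)) {
    type <- plan[k]
    placed <- FALSE
    while (!placed) {
      if (ci > length(chroms))
        stop("genome too small to place requested intervals")
      pos <- genome[[chroms[ci]]]
      gap <- sample(12:28, 1L)
      i_start <- i + gap
      ncpg <- switch(type,
        canyon = max(config$hmr_cpg_range),
        foundational = sample(config$hmr_cpg_range[1]:config$hmr_cpg_range[2], 1L),
        dme = sample(config$dme_cpg_range[1]:config$dme_cpg_range[2], 1L))
      i_end <- i_start + ncpg - 1L
      if (type == "canyon") {
        # extend until the interval exceeds the canyon cutoff
        while (i_end <= length(pos) &&
               pos[i_end] + 2L - pos[i_start] <= config$canyon_min_length)
          i_end <- i_end + 1L
      }
      if (i_end > length(pos) - 5L) {
        ci <- ci + 1L
        i <- 5L
        next
      }
      rows[[k]] <- data.frame(
        chrom = chroms[ci], start = pos[i_start], end = pos[i_end] + 2L,
        layer = if (type == "dme") "dme" else "foundational",
        canyon = type == "canyon", n_cpgs = i_end - i_start + 1L)
      i <- i_end
      placed <- TRUE
    }
  }
  intervals <- do.call(rbind, rows)
  if (is.null(intervals))
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), layer = character(),
                            canyon = logical(), n_cpgs = integer())
  intervals$id <- sprintf("iv%03d", seq_len(nrow(intervals)))

  # pattern allocation per lineage (deterministic composition, shuffled order)
  is_dme <- intervals$layer == "dme"
  for (lin in names(config$pattern_weights)) {
    counts <- allocate_counts(config$pattern_weights[[lin]], sum(is_dme))
    ids <- sample(rep(names(counts), counts))
    col <- paste0("pattern_", lin)
    intervals[[col]] <- rep(NA_character_, nrow(intervals))
    intervals[[col]][is_dme] <- ids
  }

  # one gene TSS near each DME, plus background genes
  dme <- intervals[is_dme, , drop = FALSE]
  tss_dme <- data.frame(
    chrom = dme$chrom,
    pos = dme$end + sample(500:4000, nrow(dme), replace = TRUE),
    strand = sample(c("+", "-"), nrow(dme), replace = TRUE),
    gene_id = sprintf("gene_%s", dme$id))
  n_bg <- 40L
  bg_chrom <- sample(chroms, n_bg, replace = TRUE)
  tss_bg <- data.frame(
    chrom = bg_chrom,
    pos = vapply(bg_chrom, function(ch)
      as.integer(sample(genome[[ch]], 1L)), integer(1)),
    strand = sample(c("+", "-"), n_bg, replace = TRUE),
    gene_id = sprintf("bg_gene_%03d", seq_len(n_bg)))
  tss <- rbind(tss_dme, tss_bg)
  tss <- tss[order(tss$chrom, tss$pos), , drop = FALSE]
  rownames(tss) <- NULL
  genes <- data.frame(dme_id = dme$id, gene_id = sprintf("gene_%s", dme$id))

  structure(list(genome = genome, intervals = intervals, tss = tss,
                 genes = genes, catalog = catalog,
                 background_level = config$background_level,
                 hmr_level = config$hmr_level,
                 canyon_min_length = config$canyon_min_length),
            class = "meth_architecture")
}

#' @export
print.meth_architecture <- function(x, ...) {
  iv <- x$intervals
  cat(sprintf(paste0("methylome architecture: %d CpGs on %d chromosome(s)\n",
                     "  %d foundational HMRs (%d canyons), %d DME intervals\n"),
              sum(lengths(x$genome)), length(x$genome),
              sum(iv$layer == "foundational"), sum(iv$canyon),
              sum(iv$layer == "dme")))
  invisible(x)
}

condition_index <- function(condition) {
  idx <- match(condition, c("proB", "WT", "KO"))
  if (is.na(idx)) stop("unknown condition '", condition,
                       "'; expected proB, WT or KO")
  idx
}

#' True per-CpG modification levels for one condition and lineage
#'
#' @param arch a [plant_architecture()] result.
#' @param condition one of `"proB"`, `"WT"`, `"KO"`.
#' @param lineage lineage label matching the architecture's pattern columns.
#' @return Data frame `chrom, pos, level`.
#' @export
truth_levels <- function(arch, condition, lineage) {
  cidx <- condition_index(condition)
  pcol <- paste0("pattern_", lineage)
  if (!pcol %in% names(arch$intervals))
    stop("unknown lineage '", lineage, "'")
  cat_levels <- as.matrix(arch$catalog[, c("proB", "WT", "KO")])
  rownames(cat_levels) <- arch$catalog$id
  out <- lapply(names(arch$genome), function(ch) {
    pos <- arch$genome[[ch]]
    lev <- rep(arch$background_level, length(pos))
    iv <- arch$intervals[arch$intervals$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(iv))) {
      sel <- pos >= iv$start[j] & pos < iv$end[j]
      lev[sel] <- if (iv$layer[j] == "foundational") arch$hmr_level
                  else cat_levels[iv[[pcol]][j], cidx]
    }
    data.frame(chrom = ch, pos = pos, level = lev)
  })
  do.call(rbind, out)
}

#' True per-CpG cytosine states (u, m, h) for TAB-Seq simulation
#'
#' The modified level from [truth_levels()] is split into 5mC and 5hmC: the
#' 5hmC component is a baseline plus a Gaussian bump centred on foundational
#' HMR boundaries (TET activity concentrates at HMR edges), capped by the
#' modified level; `u + m + h = 1` at every CpG.
#'
#' @inheritParams truth_levels
#' @param config a [sim_config()] (supplies the 5hmC parameters).
#' @return Data frame `chrom, pos, u, m, h`.
#' @export
truth_cytosine_states <- function(arch, condition, lineage, config) {
  tl <- truth_levels(arch, condition, lineage)
  found <- arch$intervals[arch$intervals$layer == "foundational", ,
                          drop = FALSE]
  h <- numeric(nrow(tl))
  for (ch in unique(tl$chrom)) {
    sel <- tl$chrom == ch
    edges <- c(found$start[found$chrom == ch], found$end[found$chrom == ch])
    if (length(edges)) {
      d <- vapply(tl$pos[sel], function(p) min(abs(p - edges)), numeric(1))
      h[sel] <- config$hmc_base +
        config$hmc_edge_bump * exp(-d^2 / (2 * config$hmc_edge_sd^2))
    } else {
      h[sel] <- config$hmc_base
    }
  }
  h <- pmin(h, tl$level)
  data.frame(chrom = tl$chrom, pos = tl$pos,
             u = 1 - tl$level, m = tl$level - h, h = h)
}

track_seed <- function(config, condition, lineage, offset = 0L) {
  lin_idx <- match(lineage, c("B1a", "B2"))
  if (is.na(lin_idx)) lin_idx <- 3L
  config$seed + 1000L * lin_idx + 100L * condition_index(condition) + offset
}

sample_counts <- function(n, coverage_mean, p_protect) {
  total <- rpois(n, coverage_mean)
  meth <- rbinom(n, total, p_protect)
  list(meth = meth, total = total)
}

noncpg_sites <- function(genome, n, conversion_rate) {
  if (n <= 0)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      meth = integer(), total = integer()))
  chroms <- names(genome)
  ch <- sample(chroms, n, replace = TRUE)
  pos <- floor(runif(n, 0, attr(genome, "chrom_length") - 1))
  cnt <- sample_counts(n, 5, 1 - conversion_rate)
  data.frame(chrom = ch, pos = as.integer(pos),
             strand = "+", context = sample(c("CHH", "CHG"), n, replace = TRUE),
             meth = cnt$meth, total = cnt$total)
}

#' Simulate a WGBS track for one condition and lineage
#'
#' Per CpG, `total ~ Poisson(coverage_mean)` and the protected (read-as-C)
#' count is binomial with success probability
#' `level + (1 - level) * (1 - conversion_rate)`: modified cytosines are
#' always protected, unmethylated ones escape conversion at rate
#' `1 - conversion_rate`. Fully unmethylated non-CpG sites are added to
#' support conversion-rate estimation.
#'
#' @inheritParams truth_levels
#' @param config a [sim_config()].
#' @return A [methylome_track()].
#' @export
simulate_wgbs <- function(arch, condition, lineage, config = sim_config()) {
  set.seed(track_seed(config, condition, lineage))
  tl <- truth_levels(arch, condition, lineage)
  p <- tl$level + (1 - tl$level) * (1 - config$conversion_rate)
  cnt <- sample_counts(nrow(tl), config$coverage_mean, p)
  cpg <- data.frame(chrom = tl$chrom, pos = tl$pos, strand = "+",
                    context = "CpG", meth = cnt$meth, total = cnt$total)
  non <- noncpg_sites(arch$genome, config$non_cpg_sites,
                      config$conversion_rate)
  methylome_track(rbind(cpg, non),
                  sample_id = paste(lineage, condition, sep = "_"))
}

#' Simulate a TAB-Seq track plus spike-in controls
#'
#' Under TAB-Seq only 5hmC stays protected: glucosylated 5hmC (rate
#' `g_protect`) reads as C, 5mC is TET-oxidised (rate `f_ox`) and then
#' converts like unmethylated C, and unprotected cytosines escape conversion
#' at rate `1 - conversion`. The per-read protection probability is
#' `h*g + m*(1-f) + (u + m*f)*(1-c)`. Spike-in controls are generated from
#' pure-5hmC, pure-5mC and fully unmethylated templates under the same
#' efficiencies.
#'
#' @inheritParams truth_cytosine_states
#' @return List with elements `track` (the TAB-Seq [methylome_track()]),
#'   `spikes` (list `hmc`, `mc`, `unmeth` of spike-in tracks) and `truth`
#'   (the per-CpG `(u, m, h)` table).
#' @export
simulate_tabseq <- function(arch, condition, lineage, config = sim_config()) {
  f <- config$tab_f_ox; g <- config$tab_g_protect; cc <- config$tab_conversion
  if (any(c(f, g, cc) < 0 | c(f, g, cc) > 1))
    stop("TAB-Seq efficiencies must lie in [0,1]")
  set.seed(track_seed(config, condition, lineage, offset = 7L))
  truth <- truth_cytosine_states(arch, condition, lineage, config)
  p <- truth$h * g + truth$m * (1 - f) + (truth$u + truth$m * f) * (1 - cc)
  cnt <- sample_counts(nrow(truth), config$coverage_mean, p)
  track <- methylome_track(
    data.frame(chrom = truth$chrom, pos = truth$pos, strand = "+",
               context = "CpG", meth = cnt$meth, total = cnt$total),
    sample_id = paste(lineage, condition, "tab", sep = "_"))
  spike <- function(name, p_protect) {
    n <- config$spike_sites
    cnt <- sample_counts(n, config$spike_coverage, p_protect)
    methylome_track(
      data.frame(chrom = paste0("spike_", name), pos = seq_len(n) * 10L,
                 strand = "+", context = "CpG",
                 meth = cnt$meth, total = cnt$total),
      sample_id = paste0("spike_", name))
  }
  spikes <- list(hmc = spike("5hmC", g),
                 mc = spike("5mC", (1 - f) + f * (1 - cc)),
                 unmeth = spike("unmeth", 1 - cc))
  list(track = track, spikes = spikes, truth = truth)
}

#' Simulate a complete two-lineage, three-condition methylome study
#'
#' Generates the genome, plants the architecture, simulates a WGBS track for
#' every (lineage, condition) combination and a TAB-Seq track (with
#' spike-ins) for each wild-type mature sample. All randomness derives from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `config`, `arch`, `wgbs` (nested list
#'   `[[lineage]][[condition]]`) and `tabseq` (`[[lineage]]`).
#' @export
simulate_methylome_study <- function(config = sim_config()) {
  genome <- generate_genome(config$n_chroms, config$chrom_length,
                            config$cpg_spacing_mean, seed = config$seed)
  arch <- plant_architecture(genome, config)
  lineages <- names(config$pattern_weights)
  wgbs <- lapply(lineages, function(lin)
    sapply(c("proB", "WT", "KO"), function(cond)
      simulate_wgbs(arch, cond, lin, config), simplify = FALSE))
  names(wgbs) <- lineages
  tabseq <- lapply(lineages, function(lin)
    simulate_tabseq(arch, "WT", lin, config))
  names(tabseq) <- lineages
  list(config = config, arch = arch, wgbs = wgbs, tabseq = tabseq)
}

#' Write a simulated study to disk as a re-loadable fixture
#'
#' Emits methcounts-style tracks per condition, the planted truth intervals
#' and TSS annotations as BED, the DME-to-gene table, and the truth table;
#' everything reloads through [read_methcounts()] / [read_bed()].
#'
#' @param study a [simulate_methylome_study()] result.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
emit_fixture <- function(study, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory ", out_dir)
  files <- character(0)
  for (lin in names(study$wgbs)) {
    for (cond in names(study$wgbs[[lin]])) {
      f <- file.path(out_dir, sprintf("%s_%s.meth", lin, cond))
      write_methcounts(study$wgbs[[lin]][[cond]], f)
      files <- c(files, f)
    }
  }
  iv <- study$arch$intervals
  f <- file.path(out_dir, "truth_intervals.bed")
  write_bed(iv[, c("chrom", "start", "end", "id", "n_cpgs", "layer",
                   "canyon", grep("^pattern_", names(iv), value = TRUE))], f)
  files <- c(files, f)
  tss <- study$arch$tss
  f <- file.path(out_dir, "tss.bed")
  write_bed(data.frame(chrom = tss$chrom, start = tss$pos,
                       end = tss$pos + 1L, name = tss$gene_id,
                       score = 0L, strand = tss$strand), f)
  files <- c(files, f)
  f <- file.path(out_dir, "dme_genes.tsv")
  write.table(study$arch$genes, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
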
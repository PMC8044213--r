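---
title: "Methylome segmentation and DNMT3A-dependent differential methylation with methdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome segmentation and DNMT3A-dependent differential methylation with methdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

## The biological setting

Mature B lymphocytes come in two flavours with very different methylomes:
innate-like, self-renewing B1a cells and conventional follicular B2 cells.
Developmental comparisons of whole-genome bisulfite sequencing (WGBS) data
across proB precursors, wild-type mature B cells and *Dnmt3a*-deficient
mature B cells suggest a two-layer architecture: a *foundational* methylome
of hypomethylated regions (HMRs) on a hypermethylated background, shared
between lineages, overlaid by a *dynamic* layer of enhancer-like intervals
whose methylation requires ongoing DNMT3A activity and whose trajectory
across (proB, wild-type mature, knockout mature) differs by lineage.

`methdyn` implements the computational chain needed to make and test such
statements on per-CpG count data: HMR/canyon segmentation, per-CpG
differential scoring, DMR and three-condition DDMR construction,
pattern-vector classification, interval statistics, meta-profiles and joint
5mC/5hmC estimation from paired WGBS/TAB-Seq — together with a synthetic
methylome generator so that every stage can be validated against planted
ground truth without any external download.

## Segmentation: a two-state beta-binomial HMM

`meth_hmm()` fits a two-state hidden Markov model over the covered CpGs of
a track. Covered sites are chained in genomic order; chains break at
chromosome boundaries and at inter-CpG gaps longer than `gap_limit`
(default 1000 bp) so that decoding never bridges CpG deserts — without the
split, two distant hypomethylated CpGs can fuse into a spurious mega-HMR.

Emissions are beta-binomial: at ~5x coverage, per-CpG counts are
overdispersed relative to a binomial with a shared state mean, and a
binomial emission tends to over-segment. The binomial family remains
available via `hmm_params(emission = "binomial")` for well-covered data.
Defaults initialise the hypomethylated state at mean 0.1
(`alpha = 1, beta = 9`), the hypermethylated state at mean 0.8
(`alpha = 8, beta = 2`), self-transitions at 0.99, and the initial
distribution uniform. Restarts (`n_restarts`) jitter these
multiplicatively under the supplied seed.

Fitting is Baum–Welch EM with scaled forward–backward. The transition and
initial-distribution updates are closed-form; the beta-binomial shape
update is a short Nelder–Mead ascent of the weighted likelihood accepted
only when it improves it, i.e. a generalized EM step, so the log-likelihood
trace is non-decreasing on every input (this is asserted in the tests).
Convergence is declared when the improvement drops to `tol` (default 1e-3
log-likelihood units); `tol = Inf` short-circuits to a single E-step, which
is also how the decoding-only path is exercised. Zero-coverage CpGs carry
no information under either state and are skipped, not imputed.

`call_hmrs()` posterior-decodes (`P(hypo) > 0.5`) and converts maximal
hypo runs into intervals from the first CpG's position to the last CpG's
position + 2 — the `+2` covers the CpG dyad, a documented convention since
the underlying data are dyad-merged plus-strand positions. `call_canyons()`
is a pure threshold filter at `length >= 3500` bp ("3.5 kb or longer");
the boundary case 3500 is therefore a canyon. A minimum CpG count per HMR
is exposed (`min_cpgs`, default 1) rather than guessed, since the original
segmentation convention is not documented.

## Differential methylation

`beta_diff_score()` scores each CpG shared by two tracks with
$P(p_A > p_B)$ under independent uniform-prior posteriors
$p \sim \mathrm{Beta}(\text{meth}+1, \text{unmeth}+1)$, evaluated by the
exact finite-sum identity for integer shapes (all terms positive, summed on
the log scale). The suite checks it against 64-node Gauss–Legendre
quadrature — exact here because the integrand is polynomial — over every
count pair with totals up to 20. This concrete posterior is a documented
reimplementation choice, not a claim of bit-compatibility with any
particular published scorer.

`call_dmrs()` forms candidate fragments as the parts of one sample's HMRs
not covered by the other's, then applies the count filters: a retained DMR
spans at least 10 scored CpGs of which at least 5 are significantly
differential in the concordant direction. Significance is one-sided at
`sig_level = 0.95`: a hypo-in-A fragment needs $P(p_A < p_B) \ge 0.95$
(equivalently `score <= 0.05`), mirrored for hypo-in-B. The per-CpG cutoff
is configuration because only the count filters, not the tail level, are
fixed conventions. Swapping the two samples swaps directions but yields
identical intervals (tested).

`construct_ddmrs()` runs the three pairwise comparisons (proB vs WT, proB
vs KO, WT vs KO) of one lineage, union-merges all retained DMR intervals
with 0 bp slack (no merge radius is documented anywhere, so the least
presumptive choice is used), and annotates each merged interval with its
per-condition mean methylation vector via coverage-weighted
`region_meth_stat()`. How many pairwise comparisons must support a merged
interval is genuinely open; the default `min_support = 1` (union) is the
most inclusive reading and is exposed as a parameter. Intervals with no
covered CpG report `NA`, never 0 — an unobserved region is not an
unmethylated one.

## Pattern classification

Each DDMR's (proB, WT, KO) vector is assigned to one of 12 template
vectors over low/intermediate/high = 0.2/0.5/0.8 by maximum Pearson
correlation, with no vector assigned twice. Two numerical facts shape the
implementation. First, the PCC of 3-point vectors is invariant to affine
rescaling, so several {0.2, 0.5, 0.8} templates correlate identically with
any observation; ties (within 1e-9) are broken by minimal Euclidean
distance and then catalog order, which restores the magnitude semantics
the levels encode. Second, a constant observed vector has undefined
correlation; such DDMRs are reported in an unassigned residual bin rather
than forced onto a template.

The exact 12 published template vectors are not recoverable from available
text, so `default_pattern_catalog()` is an explicit reconstruction covering
the named shapes (developmental loss kept low in the knockout, maintenance
lost only in the knockout, developmental gain, knockout-insensitive
dynamics, paradoxical knockout gain). The catalog is data, not code: any
table with columns `id, proB, WT, KO` can be passed in its place
(`read_pattern_catalog()`).

## 5hmC estimation from paired WGBS and TAB-Seq

WGBS cannot distinguish 5mC from 5hmC (both protect from conversion);
TAB-Seq glucosylates 5hmC (protection efficiency $g$) and TET-oxidises 5mC
(efficiency $f$) so that, after bisulfite conversion at rate $c$, only
5hmC reads as C. The forward model used in both the simulator and the
estimator is

$$p_\mathrm{wgbs} = (m + h) + u(1 - c), \qquad
  p_\mathrm{tab} = h g + m (1 - f) + (u + m f)(1 - c),$$

with $u + m + h = 1$. The wet-lab protocol fixes the chemistry but not the
read-level bookkeeping, so this forward model is stated here as the
package's own: unprotected 5hmC is treated as converting, and oxidised 5mC
converts at $c$. The spike-in controls identify the three efficiencies
(`estimate_efficiencies()`): $g$ from the pure-5hmC control, $c$ from the
unmethylated control, and $f$ from the pure-5mC control's protected
fraction $(1-f) + f(1-c)$. The linear system is then solved per CpG or,
preferably at ~5x coverage, per region after aggregating counts
(`estimate_5hmc_track(..., regions = )`). The system degenerates when
$g = 1 - fc$ (the 5hmC channel becomes indistinguishable from the 5mC
one); this is detected and reported as an identifiability failure rather
than silently inverted. Out-of-simplex solutions are Euclidean-projected
onto the simplex; `project = FALSE` reports raw solutions, and both raw
and corrected values are available since it is not documented whether
published region-level 5hmC values were efficiency-corrected. In the ideal
limit $f = g = c = 1$ the estimator reduces exactly to
$h = p_\mathrm{tab}$, $m = p_\mathrm{wgbs} - p_\mathrm{tab}$ (tested).

## Interval statistics

`interval_jaccard()` is base-pair intersection over union after merging
each set. `reciprocal_overlap()` reads "over 50% overlap" as strictly
greater than `min_frac` of *both* intervals; the one-line provenance of
that rule is ambiguous, so the single-sided reading is available as
`either_side = TRUE`. `nearest_tss()` signs distances by TSS strand
(positive downstream). `annotate_features()` labels by overlap under the
precedence promoter > TTS > 5'UTR > 3'UTR > exon > intron > intergenic,
with promoter = TSS ± 1 kb and TTS ± 100 bp as configurable defaults
(the original annotation was delegated to an external tool whose windows
are not restated here). `gene_set_overlap_test()` is a two-sided Fisher
exact test on the membership table over an explicit background.
`bin_signal()` builds interval-by-bin matrices in midpoint-anchored or
body-scaled mode; empty bins are missing, not zero, and are excluded from
column means so that coverage gaps at 5x do not drag meta-profiles toward
zero. `correlate_over_intervals()` reports Spearman correlation by default
(Pearson behind a flag).

## The synthetic study and what it does (not) show

`simulate_methylome_study()` generates the validation substrate. Its
defaults are the study conditions, fixed once: mean coverage 5x (Poisson),
bisulfite conversion 0.985 (within the observed 98–99% band), a 0.85
hypermethylated background carrying foundational HMRs at level 0.05,
TAB-Seq efficiencies $f = 0.90$, $g = 0.97$, $c = 0.98$ (the reported ~90%
oxidation and ~98% conversion), and two lineages × three conditions. CpG
positions have geometric spacing (mean 100 bp) over 2 chromosomes of
1.2 Mb — about 24,000 CpGs per track, a size chosen so the full two-lineage
pipeline runs in about a minute while leaving most of the genome as
background for specificity checks. Twenty foundational HMRs (four above
the 3.5 kb canyon cutoff) and 120 DME intervals of 18–30 CpGs are planted
without overlap. Pattern ids are allocated by largest-remainder rounding of
the configured weights and shuffled over positions, so the realised
composition equals the weights up to rounding; the default B1a weights put
75% of the mass on loss-of-modification shapes, echoing the qualitative
dominance of demethylation in B1a development — a configuration choice,
not a claim. Read counts are Poisson–binomial with protection probability
`level + (1 - level)(1 - conversion)`; fully unmethylated non-CpG sites
are included solely to exercise conversion-rate estimation (real non-CpG
methylation, <2%, is treated as 0). The 5hmC truth is a baseline (0.03)
plus a Gaussian bump (amplitude 0.10, sd 500 bp) at foundational HMR
boundaries, reflecting TET activity concentrated at HMR edges.

Everything is a pure function of the configuration seed, and the planted
truth table is emitted alongside the tracks (`emit_fixture()`).

What passing on this fixture does *not* show: the generator has no
sequence content, no SNPs, no mapping artefacts, no copy-number or
cell-mixture effects, no spatially varying coverage, and its interval
boundaries are crisp where real HMR edges are ragged. Recovery rates on it
are therefore upper bounds on real-data behaviour, and the headline
region counts of any real study are not reproducible from it — the
validation claims are about correctness of the machinery (oracle
equivalence, planted-truth recovery, filter exactness), not about
reproducing biological numbers.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, including BED output;
  methcounts positions are taken as 0-based.
* Methylated counts are reconstructed from (level, coverage) with
  round-half-to-even, since the source format stores a ratio.
* Merged-dyad CpGs are the default downstream substrate;
  `merge_symmetric_cpgs()` is idempotent and count-conserving, and
  per-strand analysis remains possible by skipping it.
* Forward–backward uses per-site scaling; posterior ties at exactly 0.5
  decode as hyper (strict inequality for hypo).
* EM on data with a vanishing state keeps the previous emission
  parameters when a state's total posterior weight underflows.
* `beta_diff_score` requires positive coverage on both sides; zero-coverage
  sites are skipped and counted, never scored.
* Empty interval sets: Jaccard of two empty sets is an error (0/0), an
  empty HMR set has no length statistics, and empty inputs elsewhere
  return empty outputs of the right shape.

## Known limitations

* The HMM is two-state; partially methylated domains and allele-specific
  methylation are out of scope.
* No genome-wide FDR across CpGs: the DMR filter counts significant CpGs,
  matching the upstream convention it mirrors.
* Per-CpG 5hmC estimates at 5x are dominated by sampling noise; use the
  region mode for interpretable numbers.
* `annotate_features()` implements one precedence convention; other
  annotators order UTRs and TTS differently and will disagree on edge
  cases.
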
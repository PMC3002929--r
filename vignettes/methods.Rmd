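---
title: "Methods: kernel-convolution aCGH comparison and TP53 mutation classification"
author: "cnacompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel-convolution aCGH comparison and TP53 mutation classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnacompare)
```

# Scope

`cnacompare` implements the comparative-genomics toolkit used to contrast
BRCA1-mutated, basal-like (BLBC) and luminal breast tumors on two axes:

1. **TP53 mutation spectrum** — a rule-based parser and classifier for the
   compact mutation dialect of clinical sequencing tables, tumor-level group
   summaries, and exact 2x2 group statistics.
2. **Copy-number profile** — kernel-convolution smoothing of BAC-array
   log2 ratios (KC-SMART-style), per-position signal-to-noise ratios (SNR)
   between tumor groups with class-label permutation FDR control,
   CNA-burden sweeps, and hierarchical clustering on region-mean smoothed
   signal.

A synthetic-cohort generator reproduces the statistical structure the
analyses assume, so every stage is testable without access to the original
arrays (which were never deposited). The `analysis/` scripts run the whole
pipeline over a simulated study-sized cohort.

# The smoothing model

Each probe contributes a Gaussian kernel centred on its genomic
midposition $x_i$ and scaled by its log2 ratio $a_i$. The kernel smoothed
estimate at genomic position $x$ is the locally normalized
(Nadaraya–Watson) sum over the probes of $x$'s chromosome:

$$\mathrm{KSE}(x) \;=\; \frac{\sum_i a_i \, K(x - x_i)}{\sum_i K(x - x_i)},
\qquad K(d) = \exp\!\left(-\frac{d^2}{2\sigma^2}\right)\ \text{for } |d| \le c\,\sigma .$$

*Why locally normalized?* The normalization keeps the curve in log2-ratio
units, so the burden cutoffs (0.02–1.00) are commensurate with SD-1
normalized input data; a raw convolution sum would scale with local probe
density and tumor count. The original tool's exact estimator is not
recoverable from its description, so this is a documented package choice.

**Kernel width.** The "kernel width" parameter $W$ (default 20 Mb) is
interpreted as the total effective support: $\sigma = W/4$ and truncation
at $c = 2$ standard deviations per side, so the default kernel reaches
±10 Mb. 20 Mb is the width at which smoothed single-tumor BAC profiles
visually recapitulate the raw data. Kernels never cross chromosome
boundaries, so perturbing one chromosome leaves all others bit-identical.

**Grid.** Curves are evaluated on a fixed grid (default step 100 kb,
window midpoints) per chromosome; positions beyond kernel reach of any
probe are marked absent. The analysis scripts use a 1 Mb grid (0.25 Mb for
region means, so that the narrowest catalogued region, 0.25 Mb wide,
always contains a grid point): at 1 Mb probe spacing and a 20 Mb kernel a
finer grid adds no information.

**Group curves.** Gains and losses are smoothed separately across a group:
the positive parts $\max(a_i, 0)$ of all tumors are pooled and smoothed
(equivalently, the mean of per-tumor smoothed positive parts, since the
local denominator is shared), and analogously for losses. A gains curve is
therefore everywhere $\ge 0$ and a losses curve $\le 0$, and the signed
curve decomposes exactly into the two components.

**Single-group significance.** The null model permutes each tumor's log2
ratios across probe positions independently — each tumor's value
distribution is preserved, genomic localization is destroyed. The gain
threshold is the $(1-\alpha)$ quantile (default $\alpha = 0.05$) of the
genome-wide maximum of the null gains curve over permutations (default
1000), and symmetrically for losses; significant intervals are maximal
supra-threshold grid runs. Controlling the genome-wide maximum makes the
test family-wise over the genome, which is why pure-noise cohorts yield a
significant interval in roughly a fraction $\alpha$ of simulations.

# Comparative analysis

For two groups $A$, $B$ the per-position statistic is

$$\mathrm{SNR}(x) = \frac{\mu_A(x) - \mu_B(x)}{\sigma_A(x) + \sigma_B(x) + \varepsilon},$$

over the per-tumor smoothed values, with within-group population SDs and
$\varepsilon = 10^{-8}$ guarding degenerate positions. The sum-of-SDs
denominator is the standard signal-to-noise statistic of class-comparison
genomics; the source method names the SNR without printing a formula.
The statistic is antisymmetric under group swap.

**FDR control.** Group labels are shuffled over the tumors of the
comparison (default 6000 permutations; when fewer distinct label
assignments exist the sampler draws with replacement and warns). For a
candidate threshold $t$, scanned over the observed values of each tail
separately,

$$\widehat{\mathrm{FDR}}(t) =
\frac{\text{mean}_\pi \#\{x : \mathrm{SNR}_\pi(x) \ge t\}}
     {\max(1, \#\{x : \mathrm{SNR}(x) \ge t\})},$$

and the threshold is the smallest $t$ with
$\widehat{\mathrm{FDR}}(t) \le 0.05$ (infinite if none). Positive and
negative tails get separate thresholds, mirroring the separate display of
gains and losses; whether the original tool used one two-sided or two
one-sided thresholds is not recoverable, and the one-sided form is what
the per-direction region calls need. Raising the FDR target can only grow
the significant set.

**Regions and peaks.** Differential regions are maximal supra-threshold
grid runs (runs separated by one sub-threshold grid point are merged — a
single dip at 100 kb resolution is not evidence of two distinct events).
Each region is annotated with the direction (sign of the favored group's
mean KSE inside) and with peaks: local maxima of $|\mu_A - \mu_B|$ inside
the region, reported in Mb. Peaks are maxima of the group-mean difference
rather than of the SNR so that peak positions live in signal units, not
noise-rescaled units. Overlaps between two comparisons intersect
same-direction intervals and carry both comparisons' peaks; a peak falling
just outside the shared interval is kept but flagged, because a recurrent
aberration summit slightly beyond the overlap is still informative.

# Burden and clustering

**Burden.** Each tumor's signed profile is smoothed once; for every cutoff
$t$ in 0.02–1.00 (step 0.02, the grid implied by the cutoffs quoted with
the published sweeps) the aberrations exceeding $+t$ or falling below
$-t$ are counted. The counting unit is a *local summit* of the smoothed
curve (local maximum above $+t$, local minimum below $-t$, plateaus
collapsed). Counting summits rather than threshold crossings makes the
per-tumor count exactly non-increasing in the cutoff — with run counting a
noise dip splits one aberration into two as the cutoff rises, breaking
monotonicity — and the two definitions coincide on clean, unimodal
aberrations. Group medians are reported as the headline summary while a
two-sided Welch t-test compares group means per cutoff, matching the
published figure's use of medians in the text and a t-test in the legend.
Cutoffs where a group's counts are constant (typically zero, at high
cutoffs) yield no p-value.

**Clustering.** For each catalogued region the mean KSE value per tumor
forms the feature matrix. Distance is $1 - r$ (Pearson) between tumors —
note Pearson is location- and scale-free, so architectures must differ in
*pattern* — with complete linkage, two-dimensional (tumors and regions),
leaf order refined by dendrogram reordering on mean feature values (the
original GUI tool's exact leaf-ordering algorithm is unpublished; branch
composition, not leaf order, is the tested contract). The tree is cut into
two branches and the per-group branch composition reported.

# TP53 mutation classification

The parser accepts the compact dialect of clinical TP53 tables:
`RefPosAlt` protein changes (`G266E`; nonsense when Alt is `X`),
nucleotide-level indels whose payload length modulo 3 sets the frame
(`239 insT` frameshift, `218delGTG` in-frame), whole-codon deletions
(`del 155-156`), and splice-site changes (`224 splice G > A`, `IVS5-2
A > C (splice)`). Unparseable tokens are hard errors — silent skipping
would bias group counts.

Classification follows the published rules: **complex/truncating** =
frameshift, splice or nonsense mutation, or in-frame insertion/deletion;
**hotspot** = missense change matching one of the 29 recurrently mutated
codons (reference residue and codon both). The printed per-tumor hotspot
flags of the transcribed table conflict with the 29-codon catalog for a
few rows (e.g. I195T, Q286K); the catalog is authoritative here and the
printed flags are stored but unused. Missense-effect verdicts
(SIFT / "EffectGroup3") are consumed as an externally supplied
`predicted_deleterious` flag — the predictors are out of scope.

Group summaries count *tumors*, not mutations, exclude unsequenced
tumors, and apply the >25% mutant-allele abundance filter when abundance
estimates are present (the packaged table already reflects that filter,
so its abundances are unset and pass).

**Exact tests.** `fisher_exact_two_tailed()` enumerates the
hypergeometric distribution over all tables with the observed margins.
The default two-tailed rule sums the probabilities of tables no more
likely than the observed one (relative tie tolerance $10^{-12}$); the
`"central"` option doubles the smaller one-sided tail. Both conventions
are in active use and differ by up to a factor of two; the two source
cohorts were analyzed in different laboratories and their published
p-values are only jointly reproducible with mixed conventions, which is
why both are exposed. Any zero margin returns p = 1.

# The synthetic-cohort generator

The generator emulates a ~3,500-clone BAC/PAC array: hg18 chromosome
lengths (autosomes + X, Mb-rounded; Y is excluded since breast-tumor
cohorts are effectively all female), 1 Mb probe spacing with optional
jitter, giving 3,020 probes. Tumors carry recurrent segments drawn with
group-specific penetrance; a present segment's amplitude is
$N(\mu, \tau)$ attenuated by a per-tumor tumor-cell fraction drawn
uniformly from a configurable range, modelling normal-DNA admixture as a
single multiplicative factor. Probe noise is i.i.d. Gaussian (default SD
0.15 log2 units, a typical BAC-array residual; probe-level noise
magnitudes were never published for either platform, so this is a free
parameter). A per-platform multiplicative scale (defaults FFPE 1.5 vs
fresh-frozen 1.0) reproduces the consistently wider FFPE log2-ratio
distributions that motivate the per-platform standardization. Every
presence draw, amplitude and fraction is recorded in a truth table, and
identical spec + seed reproduces outputs bit-for-bit.

What the generator does **not** model: GC/replication-timing waves,
probe-specific biases, segmentation-scale breakpoint structure below probe
spacing, and correlated aberrations (e.g. the 1q-gain/16q-loss
co-occurrence of luminal tumors arises only through shared penetrance).
Passing tests on synthetic cohorts therefore demonstrate correctness of
the machinery under the stated noise model, not performance on raw
clinical arrays.

# Normalization and merging

Log2 ratios are standardized per *platform dataset* — all probes of all
samples of a platform pooled to mean 0, SD 1. Scaling datasets rather
than individual tumors preserves between-tumor differences in aberration
burden, which the burden sweep depends on. The map is affine per platform
and hence idempotent. Scaling precedes deduplication of tumors measured
on both platforms (the published order is unstated; scaling first keeps
each platform's moments estimated from its full dataset), and duplicates
are kept from the FFPE (luminal-J) side, as published. Probes with more
than 20% missing values are dropped and remaining gaps imputed with the
chromosome median within sample — the source is silent on missing data,
so this conservative policy is the package's own.

# Numerical choices and problem sizes

* Coordinates are 0-based half-open bp internally; all reports use Mb
  with two decimals.
* All permutation machinery takes explicit seeds; identical seeds give
  bit-identical thresholds and regions.
* Ties in the Fisher enumeration use a $10^{-12}$ relative tolerance;
  the smoother is validated against a brute-force double loop at
  $10^{-12}$ absolute.
* The test suite runs the stochastic calibrations at deliberately compact
  problem sizes chosen to keep the suite quick while leaving Monte-Carlo
  bands meaningful: FDR calibration and spike-in recovery use 50
  replicates of 20 + 20 tumors on a 3 x 100 Mb genome with 500
  permutations; clustering separation uses 25 replicates of 20 + 20
  tumors on the full hg18 platform over the packaged 39-region catalog;
  the burden contrast uses 20 + 20 tumors with 8 vs 2 segments of
  amplitude 0.8 at noise SD 0.2. The analysis scripts run the
  study-sized configuration (96 tumors, 6000 permutations).

# Known limitations

* The KSE estimator and the one- vs two-sided threshold convention are
  reconstructions from an informal description; both are documented
  choices above.
* Hotspot calling ignores the transcribed per-tumor hotspot flags where
  they contradict the 29-codon catalog, so hotspot counts differ from
  the published figure for two groups.
* The deleterious-missense counts depend entirely on the transcribed
  SIFT/EffectGroup3 typography and are not independently recomputable.
* Sex-chromosome handling in the source is unstated; X is processed like
  an autosome when present, Y is not modelled.
* FDR thresholds scan observed SNR values only; with very coarse grids
  the threshold granularity is limited by the number of grid points.
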
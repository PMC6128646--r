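---
title: "Methods: Bar-seq toxicogenomic scoring, enrichment, clustering and flow competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bar-seq toxicogenomic scoring, enrichment, clustering and flow competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqtox)
```

# Scope

barseqtox implements the quantitative pipeline of a pooled
deletion-library toxicant screen: barcode counting from reads, growth
inhibition (GI) scoring, robust standardization and tail-area FDR calling
of sensitive mutants, hypergeometric term enrichment, toxicogenomic
profile clustering, and a flow-cytometry competitive growth assay. A
synthetic-data layer generates inputs with the statistical structure each
stage assumes, so the whole pipeline is testable without sequencing or
cytometry archives. This vignette records the models, the parameters that
matter, the numerical choices, and the limits of what the synthetic tests
demonstrate.

# The pooled growth model and GI scores

A pool of deletion mutants with inoculation composition $a_{0,i}$ grows
for $g$ pool doublings. Under treatment, mutant $i$ achieves a fraction
$\rho_i \in [0, 1]$ of those doublings, so its abundance is proportional
to $a_{0,i} \, 2^{g\rho_i}$; in the control every mutant doubles $g$
times. The GI score estimates the per-doubling log2 depletion from the
relative frequencies $f_i$ in both samples:

$$\mathrm{GI}_i = \frac{\log_2\!\big(f_i^{\mathrm{ctrl}} / f_i^{\mathrm{trt}}\big)}{g}.$$

For a mutant whose abundance is small relative to the pool, the
renormalization terms cancel and $\mathrm{GI}_i \to 1 - \rho_i$: a
non-grower ($\rho = 0$) scores about 1, a neutral mutant exactly 0. This
identity is the package's primary correctness anchor (tested to within
0.005 for mutants below $10^{-3}$ pool fraction, and to within 0.01 for
the canonical 1000-mutant, $g = 5$ configuration). Because frequencies
rather than counts are compared, constitutively slow growers — depleted
in *both* samples — are normalized away; only treatment-specific
depletion registers.

Parameters: `doublings` ($g$, dimensionless, default 5 — the value used
by the screens this package models) and `pseudocount` (counts, default
0.5, added to every mutant before frequencies). The pseudocount exists
because the strongest hits drop to zero treatment reads, where the raw
log-ratio is undefined; 0.5 is the conventional half-count that biases
extreme GI scores mildly toward zero (a mutant's maximal observable GI is
then set by sequencing depth, not infinity). The scoring functions refuse
zero frequencies rather than silently producing infinities.

# Robust standardization and the tail-area FDR

Screens differ in depth and noise, so GI scores are standardized
robustly: $z_i = (\mathrm{GI}_i - \mathrm{median}) / \mathrm{NIQR}$ with
$\mathrm{NIQR} = \mathrm{IQR} / (\Phi^{-1}(0.75) - \Phi^{-1}(0.25))
\approx \mathrm{IQR}/1.349$, which estimates the standard deviation under
normality while ignoring the sensitive tail. Quantiles use linear
interpolation (R type 7); the constant and the quantile type are the two
numerical choices that change third-digit behavior, and both are fixed
rather than configurable per call so that screens are comparable.
Degenerate inputs (fewer than 4 finite scores, or IQR = 0) are rejected:
a screen whose bulk has zero spread cannot be standardized meaningfully.

Sensitivity is the upper tail, so one-sided p-values
$p_i = 1 - \Phi(z_i)$ are formed under the standard-normal null implied
by the standardization, and the tail-area FDR is realized as the
Benjamini–Hochberg step-up envelope
$q_i = \min_{j: p_j \ge p_i} \pi_0 M p_j / \mathrm{rank}_j$, clipped to
$[0,1]$. The null proportion $\pi_0$ defaults to 1 (conservative); a
Storey-type estimate at $\lambda = 0.5$ is available as `pi0 = "auto"`.
A density-based local-FDR fit (Grenander estimator) is deliberately not
reproduced: the procedure this package standardizes on is the tail-area
quantity with a 0.1 cutoff, and the BH envelope is the transparent,
oracle-checkable realization of that quantity (the suite verifies
equivalence with `p.adjust(..., "BH")` on all inputs up to size 50).

Calls combine screens: a mutant passing $q \le 0.1$ in every screen with
data (at least two) is `sensitive_both`; passing somewhere but not
everywhere, or covered by a single library version, is at best
`sensitive_one`. Mutant sets may differ between screens (library
versions differ in practice), so coverage is tracked per mutant rather
than assumed. Expressivity labels (high/medium/low) default to GI
tertiles among called mutants; they are advisory ordinal summaries, not
calibrated quantities, and they are deliberately `NA` for uncalled
mutants.

# Barcode counting

Reads are `flank5 | barcode | flank3`; the default layout uses a 20-mer
barcode extracted at a fixed offset, with 5'-flank anchoring available
for shifted reads. Assignment uses Hamming (substitution-only) distance
with `max_mismatch` default 1: barcode sequencing error is
substitution-dominated, and an indel would shift the fixed layout rather
than corrupt one base. Matching is by iterative neighborhood hashing
(exact, then distance 1, then 2), which scales with the number of
distinct observed barcodes rather than the library size. Two rules keep
counting conservative: a window tied between two library barcodes at the
minimal distance is unassigned, and reads matching a duplicated library
barcode are always unassigned. Conservation (assigned + unassigned =
input reads) and order independence are asserted properties.

# Term enrichment

Over-representation of a term of size $K$ in a list of size $n$ on a
background of $N$ genes is the hypergeometric upper tail
$P(X \ge k)$, computed via `phyper` (log-space internally, so
$10^{-20}$-scale tails are exact). Correction is Bonferroni over the
number $m$ of terms actually tested (terms within the configured size
bounds); $m$ is recorded in the result's metadata because published
tables rarely print it — consequently printed corrected values can only
be *upper-bounded* by recomputed raw tails, and that is exactly the
direction the acceptance checks test. Only enrichment is tested
(one-sided), matching screen logic; genes absent from the background are
dropped with a warning rather than grafted in, because the background
defines the null. No ontology-graph propagation is performed: terms are
taken as flat sets (GMT in/out).

# Profile clustering

Similarity between GI profiles is the uncentered correlation
$r = \sum x y / \sqrt{\sum x^2 \sum y^2}$ — cosine similarity without
mean-centering. Centering is wrong for GI profiles because 0 is a
meaningful origin ("unaffected"); two mutants sensitive to the same
toxins should be similar even if one is uniformly more sensitive.
Clustering is agglomerative with unweighted average linkage (UPGMA) on
$d = 1 - r$, the Cluster 3.0 pairing. Numerical choices: missing cells
are handled by pairwise deletion with a minimum overlap of 2 shared
finite entries per pair (fewer is an error, not a guess); ties in the
minimum merge distance are broken by the lexicographically smallest pair
of smallest original leaf indices, making trees deterministic; leaf order
is plain left-first traversal (no optimal leaf ordering — the export
formats do not require it). Merge heights are checked for monotonicity on
every run; UPGMA cannot invert. Output is TreeView-compatible CDT/GTR/ATR
plus Newick per axis. The implementation is the
straightforward $O(n^3)$ agglomerator; it is intended for the hundreds of
called mutants that toxicogenomic figures cluster, not for
whole-deletome matrices.

# Flow-cytometry competition

Events carry six intensities (FSC-A, FSC-H, SSC, DAPI/450-50,
FITC/530-30, PE/585-42; linear arbitrary units). Three hard gates with
intersection semantics remove dead cells (DAPI above threshold), debris
(outside the FSC/SSC box) and doublets (FSC-A/FSC-H ratio outside
[0.8, 1.4] — a ratio band is the standard realization of area-versus-
height doublet discrimination, and the default band tolerates the cell
elongation some mutants show under genotoxins). Intersection semantics
make the retained set independent of gate order, which is asserted as a
property. GFP classification then splits on FITC with the 10²–10³ band
excluded as unresolvable GFP⁺/GFP⁻.

Fitness follows the four-sample normalization: mutant fractions
$W_m = \mathrm{M\text{-}GFP^-} / (\mathrm{M\text{-}GFP^-} +
\mathrm{WT\text{-}GFP^+})$ with and without toxicant, reference fractions
$W_r$ from the untagged-versus-tagged wild-type competition, corrected
ratios $W_n = W_m / W_r$ and $W_n^* = W_m^*/W_r^*$, and growth ratio
$W_n^*/W_n$. The reference run absorbs the GFP-loss rate: a fraction
$\ell$ of GFP⁺ cells scores GFP⁻, inflating both $W_m$ and $W_r$ by the
same mechanism, so the ratio cancels it to first order. Treated raw
count ratios $W_M/W_R$ below 0.03 are *flagged* below the assay's
detection floor but never clamped — downstream statistics can censor
explicitly. Replicate comparisons use the pooled-variance Student t-test
(two-tailed) by default with Welch available by flag; both
"mutant-versus-reference" and "ratio-versus-1" comparisons are possible
with the same function since the test takes two replicate vectors.

# What the synthetic generators emulate — and what they do not

The pool generator is the growth model above, exactly and noise-free;
noise enters only at read/count sampling (multinomial at the configured
depth) and through optional lognormal replicate jitter on $\rho$
(sd 0.02 per screen, the package's stand-in for biological replicate
variability, for which no published noise model exists; jittered rates
may slightly exceed 1 because modest faster-than-pool growth is real and
clamping would distort the null). Read simulation applies i.i.d. base
substitutions; the flow generator draws log10-normal intensity clusters
per event class with truth labels retained. Default mixture fractions
(1% dead, 2% doublets, 2% debris, ~0.5% GFP loss) sit inside the ranges
the assay literature reports (3–5% scatter/doublet attrition, 0.1–1% GFP
loss).

Passing tests therefore demonstrate: correctness of the estimators on
data satisfying the model (GI recovers $1-\rho$; calls recover planted
mutants at depth $2\times 10^6$ with zero false positives in the median
seed; the FDR is calibrated under the null; gating recovers known
mixture compositions; the growth ratio recovers its closed form within
5% at $10^5$ events). They do not demonstrate robustness to what real
data add: PCR amplification bias and barcode GC effects, overdispersion
beyond multinomial (biological replicates of the same screen), index
hopping, spectral spillover and autofluorescence drift, or instrument-
specific scatter geometry. The gate defaults are simulator-calibrated;
on real FCS data they must be set from the instrument's controls.

# Problem sizes and runtime choices

The test suite exercises the screen-scale configuration where the
statistics need it (2000 mutants, two screens, depth $2\times 10^6$,
30 planted mutants at $\rho = 0.5$; 100-seed null calibration at depth
$2\times 10^5$; 100-seed gating attrition at 20000 events; $10^5$ events
for the flow closed form) and small exhaustively-checkable instances for
the oracles (all hypergeometric parameter sets with $N \le 12$; BH
inputs up to size 50; UPGMA against a from-scratch agglomerator for
$n \le 8$). These sizes were chosen so each property is tested at the
scale where its failure mode would appear, while keeping the suite a
desk-scale computation.

# Known limitations

* The tail-area FDR assumes the robust z-scores are standard normal in
  the null bulk; heavy-tailed count noise at low depth makes the calls
  conservative rather than anticonservative, but calibration is only
  asserted under the generator's model.
* Bonferroni's divisor depends on the term universe; comparisons against
  published corrected p-values are one-directional bounds by design.
* The clustering is exact but cubic; use it on called-mutant matrices.
* FCS binary files are not parsed; events enter as CSV with the six
  named columns.
* Expressivity categories from GI tertiles are not comparable to
  categories assigned by plate-based assays.
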
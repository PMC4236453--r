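---
title: "Detecting conditional regulation in expanded transcription factor families"
author: "condregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conditional regulation in expanded transcription factor families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condregulon)
```

## The problem

Prokaryotic genomes often carry several paralogous copies of one
transcription-factor family. The archaeal feast/famine regulatory proteins
(FFRPs, the Lrp/AsnC family) are the motivating case: *Halobacterium
salinarum* NRC-1 encodes eight full-length homologs with overlapping
DNA-binding repertoires. Overexpression ChIP maps tell us *where* each
factor can bind, but not *when* a binding event is functional. The central
question this package addresses is: in which environmental contexts does a
factor actually regulate (activate or repress) the genes whose promoters it
binds, and which subset of those targets responds?

The answer is assembled from five kinds of evidence, each with its own
module:

1. **Binding maps** (`assign_targets()`): ChIP peak lists are turned into
   per-factor target-gene sets via strand-aware promoter windows with
   operon propagation.
2. **Sequence divergence** (`theta_to_distance()`,
   `cluster_divergence()`): pairwise type-I functional divergence
   coefficients are transformed into distances and clustered.
3. **Contextual divergence** (`ffrp_coexpression()`,
   `effector_clusters()`): co-expression of the factors across the
   compendium, and BLOSUM62 clustering of the nine effector-specifying
   residues of the ligand-binding domain.
4. **Conditional regulons** (`call_regulons()`): the headline statistic,
   described next.
5. **Validation** (`perturbation_test()`, `compare_strains()`):
   deletion-strain expression contrasts and growth-curve phenotypes.

## The conditional-regulon statistic

The expression substrate is a genes × arrays matrix of log2 ratios against
a common reference, with arrays grouped into named *condition sets*
(the motivating compendium has 466 arrays in 35 sets). For a factor
$f$ with binding-target set $T_f$ and a condition set $c$ with arrays
$A_c$:

1. **Fold-change filter.** $c$ is considered only when
   $\max_{a \in A_c} x_{f,a} - \min_{a \in A_c} x_{f,a} \ge \log_2 1.75
   \approx 0.807$ — a factor that does not move cannot show correlated
   regulation. All fold-change arithmetic is in log2 space.
2. **Median correlation.** For every target $g \in T_f$, compute the
   Spearman correlation $r_g$ between the factor's and the target's
   profiles over $A_c$ (pairwise-complete). The statistic is
   $M = \mathrm{median}_g\, r_g$; positive $M$ proposes activation,
   negative $M$ repression. Both tails are always tested, because a single
   factor can act as activator in one context and repressor in another.
3. **Permutation null.** $M$ is compared with the medians of random gene
   sets of size $|T_f|$ drawn without replacement from all genes on the
   array (the factor itself excluded). With $N$ permutations the p-value
   is the add-one estimator $(1 + \#\{M^{\ast} \ge M\})/(N+1)$, whose
   floor $1/(N+1)$ reproduces the convention of reporting strongest
   results as $p < 10^{-5}$ at $N = 10^5$. The per-gene correlation
   vector is computed once per (factor, set); each permutation is then
   just a median of sampled entries, so the default $10^5$ draws are
   cheap (the sampling loop is compiled code driven by R's RNG, so
   results are reproducible from a seed).
4. **Multiple testing.** Benjamini–Hochberg across all
   factor × set × tail tests jointly (a per-factor family is a
   defensible alternative; the joint family is the stricter default).
5. **Dispersion coupling.** A genuine regulon should not only co-vary on
   average: the spread *across* the targets at each array (their
   per-array variance) should track the factor's expression. The
   statistic is the absolute Spearman correlation between the per-array
   target variance and the factor profile, tested against the same
   random-gene-set null and BH-adjusted across (factor, set) pairs. The
   "variance coupled to the factor" requirement is stated loosely in the
   source methods; the per-array-dispersion reading implemented here is
   one defensible interpretation, and degenerate cases (constant
   targets) fail closed.
6. **Call and gene selection.** A (factor, set, role) is called when
   `bh_q <= 0.05`, `|M| >= 0.4`, the sign matches the role, and the
   dispersion filter passes. Within a call, the conditionally regulated
   subset keeps targets with $r_g$ strictly above the median (activators)
   or strictly below it (repressors) — with distinct correlations that is
   exactly $\lfloor |T_f|/2 \rfloor$ genes.

Thresholds (1.75-fold, $|M| \ge 0.4$, BH $\le 0.05$, $10^5$ permutations)
are the established operating point of this analysis; all are arguments.

### Numerical choices

* Correlation type within sets is Spearman by default (consistent with the
  co-expression module); Pearson is available via `method =`. The source
  methods say only "correlation coefficient".
* Spearman with missing data is computed by ranking each vector once (NAs
  kept) and correlating ranks pairwise-complete — the standard fast
  variant. It equals exact Spearman on complete data; with missing values
  ranks are not re-computed per pair. Genes with fewer than 3 complete
  pairs give NA; condition sets with fewer than 6 arrays of factor data
  are excluded with a warning (a rank correlation over fewer arrays is
  not meaningful).
* `call_regulons()` sorts genes, arrays, factors and condition sets
  before consuming random numbers, so results are invariant to input
  row/column order and fully reproducible from `seed`.
* Permutation p-values never return 0; the add-one estimator bounds them
  below by $1/(N+1)$.

## What the synthetic generator emulates

`sim_config()` + `sim_study()` generate a complete study: a ~2,400-gene
genome packed into ~1,400 operons (mean size ~1.7 genes, typical of
prokaryotes), 8 TFs whose target repertoires (drawn from a shared pool of
operon heads, hence overlapping) span roughly the 34–356-gene range of
real FFRP binding maps, peak lists with p-values and ~50 bp placement
jitter, a compendium of 35 condition sets of 6–20 arrays (~460 arrays
total, matching the 466-array compendium the method was built for), and
lagged-logistic growth curves sampled every 30 minutes for 96 h from
OD 0.09 in technical duplicate and biological triplicate.

Key generator decisions, with the reasoning:

* **Planted regulons.** A planted (TF, set, role) gives the TF a one-sided
  induction ramp over $[0, 2 \cdot tf_{amp}]$ (permuted across arrays)
  within that set, so the 1.75-fold filter passes by construction, and
  sets `coupled = round(fraction_coupled * |targets|)` targets to
  `sign(role) * beta * TF + N(0, noise_sd)`. Default `beta = 0.8`,
  `fraction_coupled = 0.75`, `noise_sd = 0.25` log2 units: strong but
  noisy partial coupling, the regime a detectable real regulon occupies.
  The one-sided ramp also makes the across-target dispersion increase
  with TF expression, so the dispersion filter can pass for true
  regulons.
* **Background condition response.** In every condition set each gene
  responds with probability 0.3 (amplitude sd 0.6 log2 units) along a
  set-specific latent profile independent of all TFs. Real compendia are
  full of co-regulated modules; without this structure random gene sets
  contain nothing but noise plus the planted genes, and their variance
  series would track the tested TF almost as well as the true targets
  do, leaving the dispersion filter without contrast. With it, random
  sets track the *condition*, true target sets track the *factor*.
* **Unambiguous planted promoters.** Divergently transcribed gene pairs
  share intergenic space, so a site in one promoter legitimately also
  sits in the neighbour's window. Planted target heads are therefore
  sampled only among genes whose promoter neighbourhood (site jitter
  ±3σ, jitter truncated at 3σ) touches no other gene's window; that
  makes exact round-trip recovery a meaningful test of the assignment
  logic rather than of genome packing luck. TF genes (and operons
  containing them) are excluded from target sets — a TF's matrix row is
  its regulator profile and cannot double as a target observation.
* **Noise models.** Expression noise is i.i.d. Gaussian in log2 space
  with 2% missing values injected to exercise pairwise-complete
  handling; growth noise is multiplicative log-normal (plate readers err
  proportionally) floored at OD 0.01.

What passing tests on this generator do **not** show: robustness to
normalisation artefacts, batch structure, correlated noise between
arrays, probe effects, or operon mis-annotation — none of which the
generator simulates. They demonstrate the statistical machinery
(calibration under the null, power and selection accuracy under planted
signal, exact agreement of the small statistics with closed forms).

## Binding-map geometry

The promoter window is 250 bp upstream to 50 bp downstream of the
annotated start codon, oriented along the gene's strand (for a `-` strand
gene with start codon at $e$, the genomic interval $[e-50, e+250]$) with
inclusive bounds; sites are point estimates and are "in" a window by
position alone. The window derives from the ~200 bp mean upstream
intergenic distance of compact prokaryotic genomes plus a 50 bp buffer for
peak resolution. The start codon anchors the window because annotation
provides it universally; where long 5' UTRs exist a transcription-start
anchor would shift windows, which is a known limitation. Operon
propagation adds every member downstream of a promoter hit; membership and
order come from the operon table, never from prediction.

Binding-map comparison uses the upper-tail hypergeometric $P(X \ge k)$
with percent overlap normalised by the smaller set; the ≥2-factor
promoter enrichment preserves each factor's target count and redraws the
sets uniformly from the universe (default: all annotated genes).

## Divergence and effector clustering

Type-I divergence coefficients $\theta$ (supplied, not estimated — the
table for the eight FFRPs ships with the package, `ffrp_theta()`) become
distances via $d = -\ln(1-\theta)$. Trees use `stats::hclust`: complete
linkage for divergence trees, average linkage (UPGMA) for effector
clusters. Tie-breaks among equal merge heights follow `hclust`'s
deterministic (input-order) behaviour.

Nine-residue effector profiles are scored positionwise with BLOSUM62 (as
shipped with Biostrings); similarity becomes a distance by
$d_{ij} = (S_{ii}+S_{jj})/2 - S_{ij}$, which is zero iff two profiles are
score-identical — the similarity-to-distance rule is not fixed by the
source methods, and this form is the simplest one compatible with
diagonal-dominant substitution matrices (non-negativity is verified
empirically in tests, not assumed). Gap characters score as the row
minimum (a conservative penalty, configurable).

## Validation statistics

Deletion-strain validation computes a per-gene delta between two defined
samples (early vs late after oxidative-stress onset for activators; high
vs low culture density for repressors), reduces each biological replicate
to the median delta over the selected gene set, and compares mutant vs
control replicate medians with a one-sided exact Wilcoxon rank-sum test —
with triplicates the smallest attainable one-sided p is exactly
$1/\binom{6}{3} = 0.05$, which is why replicate-median testing (rather
than gene-level testing) is the implemented reading.

Growth curves are collapsed over technical replicates (pointwise mean),
then each biological replicate yields three parameters: `mu_max` (the
largest least-squares slope of ln OD over a sliding 5-point ≙ 2 h
window — the standard specific-growth-rate definition; raw-OD slope via
`rate_scale = "linear"`), `t_mu_max` (centre of the earliest maximising
window; earliest wins ties for determinism) and `auc` (trapezoid over the
full observed window, no baseline subtraction). Note that a logistic
culture launched at OD$_0$ has true maximum specific rate
$r(1 - \mathrm{OD}_0/K)$, slightly below the nominal $r$; recovery tests
compare against that analytic value. Strains are compared by two-sided
unpaired t-tests per parameter, Bonferroni-corrected by the number of
strains in the screen (default 8 — the correction factor is ambiguous
between strains and parameters in the source, so it is an argument), and
combined by Stouffer's Z-score method
($Z = \sum_i \Phi^{-1}(1-p_i)/\sqrt{k}$).

## Problem sizes used by the test suite

The shipped tests run the full pipeline at the study's native scale
(2,400 genes × ~460 arrays × 8 TFs × 35 sets) with permutations scaled to
5,000 (from the 100,000 production default): 20 independent null studies
for calibration and one 10-regulon planted study for power. Exhaustive
enumeration oracles (gene subsets, rank assignments, redraw pairs) are
used wherever the universe is small enough, so the Monte-Carlo machinery
is always checked against exact answers. `scripts/acceptance.R` re-runs
the same computations from scratch and writes the resulting numbers as
JSON.

## Known limitations

* θ estimation, motif discovery/comparison, GO enrichment and microarray
  normalisation are out of scope; their outputs are consumed as inputs.
* The dispersion-coupling filter implements one reading of an ambiguous
  methods sentence; with `dispersion_filter = FALSE` the scan runs
  without it.
* The promoter anchor is the start codon, not the transcription start
  site.
* Counts reported for real data in the source study (e.g. 158 or 47
  selected genes) depend on its deposited microarray data and are not
  reproduced here; the package reproduces the procedure and its
  statistical behaviour, not those dataset-specific numbers.
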
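---
title: "Methods: weighted co-abundance network analysis of stage-resolved proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted co-abundance network analysis of stage-resolved proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coabnet)
```

## The problem

Quantitative proteomics of a tissue sampled across developmental stages
produces a protein × sample intensity matrix together with per-animal
phenotypes (here: carcass traits such as fat percentage, lean-meat
percentage, bone percentage and backfat thickness). The scientific questions
this package addresses are: which proteins change abundance across stages;
whether stage explains the global structure of the proteome; which groups of
proteins co-vary as modules; which modules track the phenotypes; and which
protein is the most central ("hub") representative of each module. The
design the package is built around is a TMT-style time-course: six stages
(60–360 days of age) with three biological replicates each, i.e. 18
samples, and a complete intensity matrix.

## Pipeline model, stage by stage

**Normalization.** Raw intensities are log2-transformed and normalized by
fast cyclic loess: each sample's log-difference from the row-mean reference
is regressed on the reference with a degree-1 tricube-weighted local fit
(span 0.7, three passes) and subtracted. This removes intensity-dependent
offsets between samples while preserving within-protein contrasts. The
implementation delegates the smoothing to the limma package's fast cyclic
loess and then restores the grand mean, so absolute log2 levels remain
interpretable. Two numerical caveats are deliberate: the procedure is a
smoother, not a projection, so a second application still changes values by
roughly an order of magnitude less than the first (it is contractive, not
idempotent to machine precision); and missing values must be resolved first
(`filter_missing()`, default policy `drop_any`) because loess, correlation
and PCA all require complete rows.

**Differential abundance.** Per protein, a one-way ANOVA of log2 abundance
on stage gives `F = MS_between / MS_within` on (g − 1, N − g) degrees of
freedom, computed row-wise from sums of squares (vectorized over thousands
of proteins). Benjamini–Hochberg q-values control the FDR across the
testable family; proteins with no variance at all are flagged and excluded
from the family (the family size shrinks accordingly) rather than being
assigned p = 1, which would distort the step-up. Proteins whose group means
differ with exactly zero within-group variance receive the smallest
representable positive p with a warning. Pairwise stage contrasts use the
Tukey–Kramer studentized-range statistic, which reduces to the balanced
Tukey HSD here and to the pooled-variance t-test when only two stages are
compared. The default gate for the differentially-abundant set is q < 0.05;
a raw-p gate is available (`dap_threshold = "p"`), since published
stage-wise analyses are often ambiguous about which threshold defined their
list.

**Ordination.** PCA treats samples as observations and proteins as
variables, centered but not scaled; component signs follow a deterministic
convention (largest-magnitude loading positive). Stage grouping is validated
by PERMANOVA on Euclidean distances: `SS_total` is the sum of squared
pairwise distances over N, within-group sums use within-group pairs over
group size, and the p-value is the +1-corrected fraction of label
permutations whose pseudo-F reaches the observed one, so the smallest
attainable p is 1/(n_perm + 1). Euclidean distance is the package's choice
(not an inference about any particular study): it is the only metric under
which PERMANOVA interrogates the same geometry as the PCA beside it. The
permutation stream is seeded and therefore reproducible.

**The network core.** Pearson correlations among protein profiles are
soft-thresholded to an adjacency `a_ij = |cor_ij|^β` (unsigned by default; a
signed variant `((1 + cor)/2)^β` is available). When `beta = "auto"`, β is
the smallest candidate power whose connectivity distribution fits a
scale-free law with signed R² at or above the 0.8 target — the signed fit
multiplies R² by the negative sign of the log–log slope so that only
decreasing laws score positively; if no power qualifies, the best-fitting
power is used with a warning. The topological overlap
`ω_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` combines direct
adjacency with shared neighborhood; `1 − ω` is the clustering
dissimilarity. Modules come from average-linkage hierarchical clustering cut
at a fixed fraction (default 0.99) of the maximal merge height, with
clusters below `min_module_size` left unassigned (label 0). A static height
cut was chosen over dynamic tree cutting because it is deterministic and
directly testable against the block-diagonal limit; the cut height and
minimum size are exposed (the synthetic experiments in this package use
`min_module_size = 10`, appropriate for 50-protein planted modules; 30 is
the default for real proteome-scale matrices).

A module's eigengene is the first principal component across samples of its
standardized member profiles, scaled to unit variance and oriented to
correlate non-negatively with the module's mean profile. Modules whose
eigengenes correlate above 0.8 are merged iteratively — always the currently
most-correlated pair, recomputing eigengenes after every merge — which
removes any dependence on module ordering. Module membership (kME) is the
correlation of each protein with each eigengene; each module's hub is its
member with maximal own-module kME (lexicographic tie-break), reported with
its strongest-adjacency neighbors.

**Module–trait inference.** Eigengenes are correlated with each trait
(Pearson); the parametric p uses `t = r·sqrt((n − 2)/(1 − r²))` on n − 2
df, two-sided, and a pair is flagged significant when |r| > 0.7 and
p < 0.05. Because n = 18 makes parametric tails optimistic under
non-normality, every correlation is also validated against a permutation
null: the trait vector's sample order is permuted B = 1000 times and the
two-sided empirical p is `(1 + #{|r_perm| ≥ |r_obs|})/(B + 1)`, with floor
1/(B + 1) ≈ 0.000999. The permutation unit is the trait vector (not the
eigengene matrix): under the null of no module–trait association, samples
are exchangeable with respect to the trait, and permuting the trait once
per draw keeps all modules comparable against the same null draw. Traits
are permuted independently of one another.

**Enrichment.** Module member lists are tested against user-supplied
annotation sets by the one-sided hypergeometric tail
`p = P(X ≥ k | N, K, n)` with BH correction across terms. The universe
defaults to the analyzed matrix's proteins — the measured proteome — rather
than the annotation file's union, because over-representation must be judged
against what could have been observed. No ontology retrieval or graph
propagation is performed; the statistical test is deliberately decoupled
from any annotation service.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes, not any real cohort. Defaults: 18 samples (6 stages × 3
replicates), 500 proteins, four planted modules of 50 with stage trends
increasing / increasing / decreasing / peaked (peak at 300 d), target
protein-to-seed correlation 0.8 within modules, and one trait coupled to
each module with |loading| 0.9 and alternating signs — mirroring the
structure in which fat-associated and lean-associated modules correlate with
carcass traits in opposite directions — plus one uncoupled trait.

The signal model is a single common factor per module: member protein
`i` of module `m` is `baseline_i + background_sd·(r·s_m + sqrt(1 − r²)·e)`,
so the population correlation of each member with the seed profile `s_m` is
exactly `r` and the expected pairwise within-module correlation is `r²`
(0.64 at the default 0.8) — which makes eigengene recovery directly
assertable. Background proteins are independent noise.

Seed profiles need one design choice that is easy to miss: if two modules
shared the same deterministic trend, their seeds would be identical, their
eigengene correlation would be 1 — above the 0.8 merge criterion — and the
"two modules" would be one module by the pipeline's own definition;
similarly an unsigned network cannot distinguish a ramp from its negation.
Each seed is therefore the deterministic trend plus a module-specific
replicate-level component, centered within each stage so that stage means
follow the ramp/triangle exactly (the monotone and interior-peak properties
hold by construction). The trend carries `trend_share = 0.3` of the seed
variance, keeping population cross-seed correlations at or below 0.3 in
magnitude — clearly separated from the 0.8 merge threshold even after the
sampling noise of correlations at n = 18 (sd ≈ 0.2). "Flat" modules have
purely replicate-level seeds: co-abundance without a stage trend. Traits are
`loading·s_m + N(0, sqrt(1 − loading²))`, so the expected trait–eigengene
correlation equals the loading. All randomness flows from one integer seed;
identical seeds give bit-identical datasets.

**What the generator does not emulate.** Peptide/spectrum-level effects,
TMT channel effects, heteroskedastic intensity-dependent noise, missingness
mechanisms, and — importantly — the global variance structure of a real
aging proteome. In real data the large majority of proteins carry some
age-correlated variation, so sample-level ordination shows strong stage
separation; here 60% of proteins are stage-unrelated background and module
trends carry only 30% of seed variance, so PC1 explains ~15% of variance
and stage PERMANOVA is weak on synthetic defaults. Passing the recovery
tests therefore demonstrates that the network machinery recovers planted
covariance structure and trait couplings; it does not certify ordination
effect sizes on real data, whose validation here is by oracle equivalence
(eigendecomposition, exhaustive permutation enumeration) and type-I
calibration instead.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `span`, `iterations` | 0.7, 3 | loess window (fraction of proteins) and cyclic passes |
| `beta` | `"auto"` (target R² 0.8, powers 1–20) | soft-threshold; emphasizes strong correlations |
| `cut_height` | 0.99 | tree-cut fraction of max merge height |
| `min_module_size` | 30 (10 in synthetic experiments) | smallest cluster kept as a module |
| `merge_cor_threshold` | 0.8 | eigengene correlation above which modules merge |
| `trait_cor_threshold`, `alpha` | 0.7, 0.05 | significance gate for module–trait pairs |
| `n_permutations` | 1000 | module–trait permutation null size (p floor ≈ 0.000999) |
| `n_perm` (PERMANOVA) | 999 | label permutations (p floor 0.001) |

Degenerate inputs are handled explicitly: zero-variance proteins are
rejected by the correlation step (filter first), constant traits are
errors naming the trait, an isolated node pair has TOM 0, a single-member
module's eigengene is its standardized profile, and kME ties break
lexicographically so hub identities are deterministic.

## Problem sizes used in validation

The test-suite experiments run at 500 proteins × 18 samples (ten generator
seeds for recovery), 2000 null proteins for ANOVA calibration, 400 null
replicates for permutation-test calibration, and 5–15-node graphs for the
brute-force TOM oracle — sizes at which every closed form can be checked
exhaustively and the full suite runs in well under a minute. These are the
package's validation conditions, chosen so that oracles (enumeration,
triple loops, eigendecompositions) remain exact.

## Known limitations

- Static height cut, not dynamic hybrid tree cutting; very unequal module
  sizes on real data may need `cut_height`/`min_module_size` adjustment.
- Plain ANOVA without variance moderation; at three replicates per stage an
  empirical-Bayes approach would gain power, but plain ANOVA is the
  documented contract.
- PERMANOVA is Euclidean-only, with no pairwise stage contrasts.
- Enrichment requires user-supplied annotation sets; no database access.
- No blockwise decomposition: dense protein × protein matrices bound the
  practical problem size to ~20k proteins in memory.
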
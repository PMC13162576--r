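# coabnet

Weighted protein co-abundance network analysis for stage-resolved
quantitative proteomics.

`coabnet` is built for the canonical TMT-style developmental time-course: a
protein × sample intensity matrix over several ages with a few biological
replicates per age, plus per-animal phenotypes (carcass traits such as fat
percentage, lean-meat percentage, bone percentage, backfat thickness). It
answers, in one pipeline: which proteins change across stages, whether stage
structures the whole proteome, which proteins co-vary as modules, which
modules track the phenotypes, and which protein is each module's hub.

## The model

After log2 transformation and fast cyclic loess normalization, the network
core follows the weighted co-abundance framework:

- adjacency `a_ij = |cor(x_i, x_j)|^β`, with β chosen as the smallest power
  whose connectivity distribution fits a scale-free law (signed R² ≥ 0.8);
- topological overlap `ω_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`
  with `l_ij = Σ_u a_iu a_uj`, `k_i = Σ_j a_ij`; modules are
  average-linkage clusters of `1 − ω`, merged when eigengene correlation
  exceeds 0.8;
- a module eigengene is the first principal component of its standardized
  member profiles; kME is each protein's correlation with an eigengene, and
  the hub is the member with maximal own-module kME;
- module–trait associations are Pearson correlations with a parametric
  two-sided p (`t = r√((n−2)/(1−r²))`) flagged at |r| > 0.7 and p < 0.05,
  each validated against a 1000-permutation null with empirical
  `p = (1 + #{|r_perm| ≥ |r_obs|}) / (B + 1)`.

Around the core: per-protein one-way ANOVA across stages with
Benjamini–Hochberg FDR and Tukey HSD post hoc contrasts; PCA with a
PERMANOVA (pseudo-F, R², permutation p on Euclidean distances) validation
of stage grouping; Fisher's exact over-representation test against
user-supplied annotation sets; and a seeded synthetic-data generator with
planted modules, stage trends and trait couplings that makes the whole
pipeline testable offline. See the methods vignette
(`vignettes/coabundance-methods.Rmd`) for assumptions and design choices.

## Worked example

```r
library(coabnet)

sim  <- generate_dataset(syn_params(seed = 42))   # 500 proteins, 18 samples
norm <- cyclic_loess_normalize(sim$abundance)

res <- anova_per_protein(norm, sim$design)
sum(res$p_value < 0.05)   # 17 proteins at raw p < 0.05
sum(res$q_value < 0.05)   # 0 survive the FDR gate

coab_pca(norm)
#> PCA of 18 samples on 500 proteins
#>   PC1: 15.0% variance
#>   PC2: 11.0% variance
#>   PC3: 9.4% variance

coab_permanova(norm, sim$design$stage_days, n_perm = 999, seed = 42)
#> PERMANOVA (Euclidean): pseudo-F = 0.989, R2 = 0.292, p = 0.563 (999 permutations)

fit <- coab(norm, sim$traits, min_module_size = 10,
            n_permutations = 1000, seed = 42)
fit
#> Weighted co-abundance network
#>   500 proteins, 18 samples; beta = 6 (unsigned)
#>   5 module(s): M1=78, M2=71, M3=70, M4=66, M5=10; 205 unassigned
#>   4 significant module-trait pair(s)

subset(fit$module_trait, significant)
#>    module        trait      r  p_value significant   perm_p
#> 2      M2   backfat_mm -0.922 5.33e-08        TRUE 0.000999
#> 9      M4 bone_percent  0.857 5.67e-06        TRUE 0.000999
#> 18     M3  fat_percent  0.896 4.82e-07        TRUE 0.000999
#> 21     M1 lean_percent -0.857 5.43e-06        TRUE 0.000999
```

Reading the output: the generator planted four 50-protein modules, each
coupled to one trait with |loading| 0.9 and alternating signs. The fit
recovers four large modules (plus a small spurious one), selects β = 6 by
the scale-free criterion, and each planted trait's strongest module
association carries the planted sign at the permutation floor
p = 1/1001 ≈ 0.000999. Per-protein ANOVA, by contrast, finds almost nothing
at three replicates per stage — individually weak stage effects are exactly
what the module level resolves by borrowing strength across correlated
proteins. The weak global PERMANOVA is a property of the synthetic
conditions (most proteins are background noise), not of the method; see the
vignette's discussion of what the generator does and does not emulate.

The full pipeline — normalize → differential abundance → ordination →
network → optional enrichment, with a JSON manifest and bit-reproducible
outputs — runs from one configuration:

```r
run_pipeline(list(matrix = "abundance.tsv", design = "design.tsv",
                  traits = "traits.tsv", out_dir = "run",
                  matrix_scale = "raw", seed = 11))
```

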
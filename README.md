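# simplexomics

Analysis of gene or protein expression matrices measured over **multiple
phenotypic groups** ("biologically diverse samples"): K ≥ 2 tissue types,
cell types, disease stages. Three problems dominate such data, and this
package implements one coherent toolchain for them:

1. **Informative missingness.** Signature proteins are censored below the
   lower limit of detection (LLOD) precisely in the groups where they are
   silent, while their missing values in high-expression groups are
   random (MAR). Generic imputers ignore the group structure and erase the
   signal. `mgpi_impute()` performs *mechanism-integrated group-wise
   pre-imputation*: per gene *i* and group *k* it estimates the censoring
   probability from the normal lower tail below the global log-space floor
   ε,

       α_k(i) = Φ((ε − x̄_k(i)) / σ_k(i))

   and fills each missing cell with the blend

       x̃_k(i) = α_k(i)·ε/2 + [1 − α_k(i)]·x̄_k(i),

   interpolating between the classical half-minimum fill (censoring) and
   the group-mean fill (MAR). Seven classical comparators ship behind the
   same interface: half-minimum, mean, sample-wise kNN, PPCA, NIPALS,
   EM-SVD and singular value thresholding.

2. **Downregulated signature genes (DSGs).** A DSG of group *k* is
   uniquely *silent* in *k* and expressed everywhere else — ideal pattern
   ê_k ⊕ 1⃗ (zero at *k*, one elsewhere). `cosine_scores()` implements the
   cosine one-sample test on the group-mean "super-sample" vector x(i):

       t(i) = max_k cos(x(i), ê_k ⊕ 1⃗),   1/√(K−1) ≤ t ≤ 1

   (SG direction uses the vertex references ê_k). The statistic is
   magnitude-invariant and cannot be fooled by the one-versus-rest failure
   mode, where a gene silent in two of three groups looks like an extreme
   "DSG" to a fold-change ratio. Empirical-null p-values and BH q-values
   come from `empirical_null_pvalues()`; `ovr_ttest_scores()` and
   `ovr_fc_scores()` provide the standard baselines.

3. **Comparable heatmaps.** `build_layout()` projects each gene onto the
   scatter simplex (x̂(i) = x(i)/Σ_k x̄_k(i)), log-standardizes with
   group-balanced statistics after clamping at one shared floor — so zero
   expression has a **common display origin** across genes, unlike
   per-gene z-scoring — and orders rows/columns by cosine score.

Ground-truth simulators (`simulate_simplex_profiles()`,
`generate_sg_panel()`, `inject_missingness()`) and evaluation metrics
(`rmse()`, `nrmse()`, `proc_pauc()`, benchmark harnesses) make every claim
testable without external data.

## Worked example

```r
library(simplexomics)

# benchmark design: 1200 + 1200 Dirichlet nulls, 20 SGs and 50 DSGs per
# group on the K = 3 simplex, expanded to 10 samples per group
cfg  <- simplex_sim_config(K = 3, seed = 42)
sim  <- simulate_simplex_profiles(cfg)
expd <- expand_to_samples(sim$profiles, cfg)
expd$matrix
#> omics_matrix: 2610 genes x 30 samples (linear space), 0.0% missing

scores <- empirical_null_pvalues(
  cosine_scores(supersample(expd$matrix, expd$labels), "DSG"))
head(scores, 3)
#>   gene_id direction assigned_group     score      p_value rank q_value
#> 1  g02485       DSG             G1 0.9998458 0.0003831418    1       1
#> 2  g02556       DSG             G2 0.9997877 0.0007662835    2       1
#> 3  g02491       DSG             G1 0.9997773 0.0011494253    3       1
```

The three top-ranked genes are true planted DSGs (ids ≥ g02461 are the DSG
block in this design); their scores sit just below the ideal 1, and the
self-inclusive empirical p-value of the top gene is 1/2610. Of the 150
top-ranked genes, 103 are planted DSGs at the default cluster noise.

Imputation under 50% missingness (40% of it MAR, the rest LLOD censoring),
SG-focused accuracy over 3 seeds of the proteomics-style design (713
features, 120 signature genes, groups of 10/20/30/10 samples, log2 scale):

```r
bench <- run_imputation_benchmark(seeds = 1:3,
                                  methods = c("mgpi", "min2", "mean", "swknn"))
aggregate(cbind(rmse_overall, rmse_sg, nrmse_sg) ~ method, bench, mean)
#>   method rmse_overall rmse_sg nrmse_sg
#> 1   mean         2.61    2.39    1.108
#> 2   mgpi         1.45    1.34    0.620
#> 3   min2         2.27    2.24    1.037
#> 4  swknn         2.30    2.08    0.966
```

The group-wise blend roughly halves the signature-gene RMSE relative to
every single-mechanism fill, because it imputes near the group mean where
missingness is random and near the floor where it is censored.

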
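# mincoex

Robust system- and tissue-level gene coexpression from bulk RNA-seq.

## The problem

Gene pairs can be coexpressed in two quite different senses. At the **system
level**, two genes rise and fall together across the whole body because
tissues that express one tend to express the other — a signal carried by
between-tissue differences in mean expression. At the **tissue level**, two
genes covary across samples *within* a tissue, a signal that survives after
each tissue's mean is removed. Standard coexpression databases z-score
expression per tissue and therefore only see the second kind; unscaled
estimation sees the first, and the two rankings disagree substantially.
`mincoex` estimates both, side by side, from one TPM matrix with sample
metadata, for people building coexpression networks, prioritizing functional
partners of a gene, or benchmarking association metrics.

## The estimator

For genes *x* and *y* and tissue clusters *c* with *n* samples each:

1. **Filter**: keep genes with ≥ 0.1 TPM in at least 20% of samples, then
   *rescue* tissue-specific genes whose best tissue has mean > 5 TPM and
   > 66% of samples at ≥ 1 TPM.
2. **Normalize**: log10(TPM + 1), quantile normalization, then ComBat run in
   series for the extraction and sequencing batches, preserving tissue, sex
   and age.
3. **Purify tissue clusters**: PCA with a permutation test for the number of
   components; Louvain clustering of Jaccard-weighted kNN graphs over
   k = 1..100, matched to tissues by the purity score P = (I/T)·(I/C);
   mixed/divergent samples removed, co-occupying tissue pairs merged; then a
   t-SNE medoid-kNN vote removes remaining outliers.
4. **Estimate**: draw 70 samples per cluster, uniformly without repetition,
   20 times. In every replicate compute Pearson, Spearman, and a modified
   G-statistic `G = 2 Σ O_ij ln(O_ij / E_ij)` on a 3-level k-means
   discretization of each gene (trimmed at the 0.2/99.8 percentiles, with
   E floored at 1 or 0.5 depending on whether O > 4).
5. **Aggregate pessimistically**: a pair's final value is its weakest
   association over the 20 replicates — the smallest |r| with sign kept for
   correlations, the smallest G.

The **tpm modality** runs this on the normalized matrix (system level); the
**zscore modality** first standardizes each gene within its tissue cluster,
`z = (x − m)/s` (tissue level). Pearson matrices are additionally computed
within covariate strata (sex; age <50 / 50–59 / >59; low/high ischemia split
by 2-means). The default configuration yields 140 matrices.

Validation statistics included: hypergeometric pathway-enrichment counts for
the top/bottom 5% of a gene's ranking, ROC/AUROC against probabilistic
network edges, top-n overlap and median-rank comparisons between rankings,
and the D-score measuring how front-loaded ChIP peaks are in a coexpression
ranking.

## Worked example

```r
library(mincoex)

# a cohort with one pair coexpressed only at the system level and one only
# at the tissue level
pairs  <- rbind(planted_pair(1, 2, "SYS_ONLY"), planted_pair(3, 4, "TISSUE_ONLY"))
cfg    <- cohort_config(n_tissues = 8, samples_per_tissue = 60, n_genes = 80,
                        planted_pairs = pairs, seed = 7)
cohort <- generate_cohort(cfg)
cohort$expr
#> <expr_matrix> 80 genes x 480 samples, scale = TPM

filt <- apply_gene_filter(cohort$expr, cohort$samples$tissue)
table(filt$report$status)
#>    PASS RESCUED
#>      75       5

norm     <- combat_serial(log_quantile_normalize(filt$expr), cohort$samples)
clusters <- setNames(cohort$samples$tissue, cohort$samples$sample_id)
design   <- make_subsample_design(clusters, n_per = 48, n_reps = 5, base_seed = 7)

sys_min <- aggregate_minimum(estimate_all(norm, design, metrics = "pearson",
                                          modality = "tpm"))
z       <- zscore_by_cluster(norm, clusters)
tis_min <- aggregate_minimum(estimate_all(z, design, metrics = "pearson",
                                          modality = "zscore"))
round(rbind(
  system_level = c(sys_pair = sys_min$values["G0001", "G0002"],
                   tissue_pair = sys_min$values["G0003", "G0004"]),
  tissue_level = c(tis_min$values["G0001", "G0002"],
                   tis_min$values["G0003", "G0004"])), 3)
#>              sys_pair tissue_pair
#> system_level    0.761       0.064
#> tissue_level    0.002       0.771
```

Each modality recovers exactly the pair planted for it: the system-level
pair keeps a strong minimum correlation on the unscaled matrix (0.761) and
vanishes after per-cluster z-scoring (0.002); the tissue-level pair is the
mirror image. The 5 RESCUED genes are the tissue-specific ones the plain
low-expression filter would have discarded.

The full pipeline (filter → normalize → purify → estimate → strata) runs
from one config: `run_pipeline(pipeline_config(synthetic = cfg))`, or from
the shell via `Rscript inst/cli/mincoex.R run --config cfg.yaml`.

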
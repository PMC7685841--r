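# mhcprofiler

Classifies molecular cancer subtypes into **MHC-low / MHC-intermediate /
MHC-high** expression clusters after suppressing the confounding effect of
immune infiltration — a pan-cancer workflow for finding "immune cold"
tumor subtypes whose antigen processing and presentation machinery (MHC
genes: proteasome subunits, peptide transporters, HLA molecules) is
concordantly downregulated in the tumor-cell fraction.

The pipeline, for each cancer type:

1. **Preprocess** raw RNA-seq counts: low-expression filter,
   GC-stratified + between-sample quantile normalization,
   log2(CPM + 0.25), PCA outlier removal, small-batch removal,
   empirical-Bayes batch correction (ComBat), exclusion of subtypes with
   < 10 tumors.
2. **Deconvolve** bulk DNA-methylation betas into epithelial / fibroblast
   / immune fractions by robust partial correlations (Huber regression,
   truncate-and-renormalize to the simplex); optionally infer CD4/CD8
   T-cell levels from an extended reference.
3. **Select the panel**: from an immunomodulator panel (cancer germline
   antigens, immunoinhibitors, MHC genes), remove genes lowly expressed in
   any subtype or with strong (ρ ≥ 0.4), significant (BH q ≤ 0.05)
   Spearman correlation with the immune fraction in any type.
4. **Relative effects**: for every subtype and variable (panel-gene
   expression, nonsilent mutation burden, T-cell levels), the probability
   that a normal-tissue observation falls below a subtype observation,
   estimated by midrank counts — 0.5 means "unchanged vs normal",
   with reporting bands lower ≤ 0.4 and higher ≥ 0.6. A permutation
   ANOVA-type statistic `T = Σ_v Σ_i n_i (p̂_iv − 0.5)²` tests overall
   group differences.
5. **Cluster** the subtype × MHC-gene probability matrix with hierarchical
   clustering, k-means and PAM over K = 2..5, select K by rank aggregation
   of a 12-index validity battery, form the Hungarian-aligned majority
   consensus, and label clusters MHC-low / intermediate / high by
   ascending mean probability.
6. **Summarize mutations** (per-subtype % of tumors with ≥ 1 nonsilent
   mutation in an MHC gene set) and the signed pan-cancer correlation
   matrix among retained immunomodulators (±1 per type, summed).

Because the original cohorts are controlled-access, the package includes a
first-class **synthetic cohort generator** (`generate_cohort()`) that
emulates their statistical structure — negative-binomial counts with
library-size/GC/batch effects, a latent immune fraction driving a subset
of genes, planted per-subtype MHC archetypes over a 13-type / 55-subtype
layout (`table1_composition()`), methylation betas as cell-type mixtures,
and archetype-linked mutation burdens — with full ground truth for
validation. See `vignettes/mhc-profiling-methods.Rmd` for the models,
parameter choices and limitations.

## Worked example

The `analysis/` directory is the narrative workflow: numbered scripts that
simulate the cohort, run each stage and write tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_deconvolve.R
Rscript analysis/04_select_panel.R
Rscript analysis/05_relative_effects.R
Rscript analysis/06_cluster_subtypes.R
Rscript analysis/07_mutations_correlations.R
```

Selected output of a run (seed 1):

```
immune fraction: mean 0.212; MAE vs truth 0.0043 (max 0.0196)
inferred CD4T vs truth: Spearman r = 0.998
inferred CD8T vs truth: Spearman r = 0.994

panel: 162 genes in, 12 flagged lowly expressed, 74 immune-correlated
retained: 76 genes (CAG=52, immunoinhibitor=11, MHC=13)
of 81 planted immune-driven panel genes, 2 survived the filter

mean validity ranks per K: 2:2.81  3:1.69  4:2.78  5:2.72
selected K = 3
cluster sizes: MHC-high=8, MHC-intermediate=20, MHC-low=27
              assigned
planted        MHC-high MHC-intermediate MHC-low
  high                8                0       0
  intermediate        0               20       0
  low                 0                0      27
cluster means (low/int/high): 0.076 / 0.416 / 0.931

MHC mutation frequency across 55 subtypes: 0% - 15%
```

Reading this: deconvolution recovers the latent immune fractions almost
exactly (MAE 0.004); the immune-correlation filter cuts the 162-gene panel
to 76 genes, removing 79 of the 81 genes whose expression was planted to
track infiltration; rank aggregation picks K = 3 decisively (mean rank
1.69 vs ≥ 2.7 for other K); and the consensus clusters reproduce the
planted archetype layout exactly — 27 MHC-low, 20 MHC-intermediate and
8 MHC-high subtypes, with cluster mean probabilities 0.08 / 0.42 / 0.93
(clearly below / near / clearly above the 0.5 "unchanged vs normal"
anchor).

The same computation is available programmatically:

```r
library(mhcprofiler)
res <- run_pipeline(pipeline_config(out_dir = "pipeline_out", seed = 1))
table(res$clusters$mhc_class)
```

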
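# scFetalLiver

Marker-free single-cell RNA-seq analysis of the developing mouse fetal
liver, for researchers studying liver stem/progenitor cells (LSPCs):
hepatoblasts — the bipotential embryonic progenitors of hepatocytes and
cholangiocytes — profiled across embryonic stages (E11.5 … P2.5) together
with the other major fetal-liver cell types. The package takes gene × cell
FPKM matrices with ERCC spike-in rows and provides the full analysis chain:

1. **Cell QC** — detected-gene counts (FPKM > 1), spike-in cross-cell
   correlation, robust outlier flagging, and a two-stage QC for FACS-sorted
   populations (library-complexity outliers, then atypical expression
   profiles).
2. **Technical-noise gene filtering** — the squared coefficient of variation
   of each gene is modelled as CV² = a₁/μ + a₀; the constants are estimated
   by a gamma-family GLM of CV² on 1/μ over genes with μ above a data-driven
   floor μ_th (chosen so that at most 5 % of genes above it have CV² > 0.3).
   A gene is retained iff (1) μ − 1.96·√σ₀² > 0, with σ₀² = a₀μ² + a₁μ the
   noise variance at its mean, and (2) its observed variance exceeds σ₀².
3. **Marker-free cell typing** — two-pass hierarchical clustering
   (1 − Pearson on log₂(FPKM+1), average linkage) on the top-400
   PCA-ranked genes: pass 1 splits hepatoblasts from the rest, pass 2 cuts
   the remainder into six clusters and merges clusters whose top marker
   panel coincides (e.g. two macrophage sub-clusters). Marker panels,
   GO-style hypergeometric over-representation with Bonferroni correction,
   per-stage type proportions and t-SNE maps support cluster identity.
4. **Developmental trajectory** — one-way ANOVA of hepatoblast expression
   across stages (genes expressed in ≥ 3 cells), top-30 track genes,
   monotone trend calls (Spearman ρ of stage means vs stage ordinal, ±0.8),
   and nearest-stage assignment of query cells by correlation to stage
   centroids — e.g. showing that sorted cholangiocytes resemble the
   earliest hepatoblast stage.
5. **TF covariance networks** — Wilcoxon screen of differentially expressed
   transcription factors (raw p < 0.01), pairwise Pearson correlations, and
   a thresholded graph (edges at r > 0.35; nodes need ≥ 3 such partners).
6. **Isolation-marker scoring** — per gene, cell type and stage: sensitivity
   (fraction of target cells that are marker-positive) and specificity
   (purity of the marker-positive pool), plus prediction of new membrane
   markers passing a 0.5 cutoff on both at every stage.

A bundled synthetic-data generator (`simulate_fetal_liver()`,
`simulate_cholangiocytes()`, `inject_outliers()`) emulates the study design
with known ground truth — six cell types in stage-varying proportions,
trajectory genes with monotone trends, 92 spike-ins, gamma noise following
the CV² law, and logistic drop-out — so the whole pipeline is testable
without external data.

## Worked example

```r
library(scFetalLiver)

cfg <- sim_config(seed = 1)            # 2000 genes + 92 spike-ins, 7 stages x 60 cells
sim <- simulate_fetal_liver(cfg)
sim$matrix
#> ExpressionMatrix: 2092 genes (92 spike-ins) x 420 cells

identify_outlier_cells(sim$matrix)
#> QcReport: 420 cells in, 419 retained (99.8%)

dec <- two_pass_decomposition(sim$matrix)
table(dec$cell_labels)
#>   endothelial   erythrocyte   hepatoblast    macrophage megakaryocyte   mesenchymal
#>            41            89           153            44            20            73
mclust::adjustedRandIndex(dec$cell_labels,
                          setNames(sim$annotation$true_type, sim$annotation$cell_id)[names(dec$cell_labels)])
#> [1] 1
```

All 420 simulated cells are assigned to the six types in agreement with the
generator's ground truth (adjusted Rand index 1); the two macrophage
sub-populations are clustered apart in pass 2 and re-merged by their shared
marker panel.

The noise model, fitted on a dedicated simulation of 2000 neutral genes ×
200 cells generated with a₀ = 0.05, a₁ = 4:

```r
tp  <- matrix(c(1, 0, 0, 0, 0, 0), 1, dimnames = list("E11.5", liver_cell_types()))
cfg_n <- sim_config(n_genes = 2005, stages = "E11.5", cells_per_stage = 200,
                    type_proportions = tp, noise_a0 = 0.05, noise_a1 = 4,
                    n_trajectory_genes = 0, n_marker_genes_per_type = 0, seed = 2)
noise_filter_pipeline(simulate_fetal_liver(cfg_n)$matrix)$model
#> NoiseModel: CV^2 = 4.274/mu + 0.0505  (mu_th = 16.05, 767 genes, glm_gamma_identity)
```

Both generating constants are recovered (the slight upward slope bias comes
from drop-out; see the methods vignette). Finally, the hepatoblast
trajectory and the stage affinity of simulated sorted cholangiocytes:

```r
hb_cells <- names(dec$cell_labels)[dec$cell_labels == "hepatoblast"]
hb  <- ExpressionMatrix(sim$matrix$values[, hb_cells], spikein = sim$matrix$spikein)
stv <- setNames(sim$annotation$stage, sim$annotation$cell_id)
ser <- stage_anova(hb, stv[hb_cells], stage_order = cfg$stages)
chol <- simulate_cholangiocytes(cfg, 52, base = sim)
nsa  <- nearest_stage_assignment(chol$matrix, hb, ser, stv[hb_cells])
nsa$modal_stage
#> [1] "E11.5"
round(nsa$fractions, 3)
#> E11.5 E12.5 E13.5 E14.5 E16.5 E18.5  P2.5
#> 0.942 0.058 0.000 0.000 0.000 0.000 0.000
```

94 % of the cholangiocyte cells correlate best with the earliest (E11.5)
hepatoblast stage — the expected signature of a population that branches
off the progenitor pool early.

`make_demo(dir)` writes a complete desk-scale dataset plus configuration,
and `run_pipeline(config, out_dir)` executes QC → noise filter → typing →
trajectory → network → markers end to end (≈ 8 s), writing per-stage TSV
outputs and a run report.

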
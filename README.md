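# mvsubtype

Unsupervised disease subtyping from multiview (multimodal) feature data,
with deep generalized canonical correlation analysis at its core.

## The problem

Cohort studies of progressive diseases — the motivating case is mild
cognitive impairment (MCI), the prodromal stage of Alzheimer's disease —
measure the same participants through several imaging modalities
(e.g. structural MRI gray-matter density, amyloid PET, FDG PET), each
summarized as mean signal over ~116 brain regions of interest. Clinical
staging (early vs late MCI) is coarse and partly arbitrary; the goal is to
learn data-driven *subtypes* from the imaging views alone, then test
whether they differ in cognition, brain volumes, conversion hazard, and
genetic risk.

## The model

**GCCA.** Given `J` views `X_j ∈ R^{N×p_j}`, generalized canonical
correlation analysis finds a shared orthonormal embedding
`G ∈ R^{N×k}` and per-view projections `U_j` minimizing

    Σ_j ‖G − X_j U_j‖²_F    s.t.  GᵀG = I_k

The solution is closed form: `G` holds the top-k eigenvectors of
`M = Σ_j X_j (X_jᵀX_j)⁻¹ X_jᵀ`, `U_j = (X_jᵀX_j)⁻¹X_jᵀG`, and the
optimal objective equals `J·k − Σ_{i≤k} λ_i(M)`.

**DGCCA.** Each view first passes through its own feedforward network
`O_j = f_{θ_j}(X_j)` (default: two ReLU hidden layers of width 96,
dropout 0.1, linear output of the input width). The networks are trained
with full-batch Adam to maximize the eigen-sum loss
`L = Σ_{i≤k} λ_i(Σ_j O_j(O_jᵀO_j)⁻¹O_jᵀ)`, using the analytic gradient

    ∂L/∂O_j = 2 [I − O_j(O_jᵀO_j)⁻¹O_jᵀ] G Gᵀ O_j (O_jᵀO_j)⁻¹

followed by ordinary backpropagation, with early stopping on a held-out
split. Embeddings are clustered (Ward agglomerative, 2 clusters) and the
clusters validated by a Wilcoxon rank-sum battery over 11 clinical
measures (Bonferroni at α/11), an elastic-net Cox conversion model with
log-rank tests, and per-SNP case-control logistic association under
Benjamini–Hochberg FDR control.

A synthetic-data module generates all of these inputs with known ground
truth (shared latent clusters behind nonlinear view maps, subtype-shifted
clinical measures, subtype-dependent exponential hazards, genotypes with
shifted case allele frequencies), so the whole pipeline is testable
without any restricted data.

## Worked example

```r
library(mvsubtype)

cfg <- synthetic_config(n_samples = 150, n_views = 3, view_dims = 20,
                        latent_dim = 2, cluster_separation = 5,
                        nonlinearity = "tanh", noise_sd = 0.5,
                        n_snps = 100, n_causal_snps = 10,
                        causal_af_shift = 0.2, n_controls = 100, seed = 42)
gen <- generate_multiview(cfg)

specs <- lapply(gen$dataset$views,
                function(v) network_spec(ncol(v), c(32, 32), 0.1, ncol(v)))
model <- train_dgcca(gen$dataset, specs,
                     train_config(k = 2, max_epochs = 50, seed = 42))
emb <- dgcca_embed(model, gen$dataset)
subtype <- cluster_agglomerative(emb$G, 2)
ami_score(subtype, gen$truth$cluster_labels)
#> [1] 1
ch_score(emb$G, subtype); silhouette_score(emb$G, subtype)
#> [1] 2777.4
#> [1] 0.858

clin <- generate_clinical(gen$truth$cluster_labels, cfg)
head(ranksum_battery(clin[, 2:12], subtype)[, c("measure", "p", "significant")], 3)
#>   measure            p significant
#> 1  ADAS13 0.0004599008        TRUE
#> 2    MMSE 0.0002228243        TRUE
#> 3   CDRSB 0.0001891332        TRUE

sv <- generate_survival(gen$truth$cluster_labels, cfg)
logrank_test(sv$time, sv$event, subtype)
#> log-rank chi-square 14.8, p = 0.00012

g <- generate_genotypes(gen$truth$cluster_labels, cfg$n_controls, cfg)
res <- case_control_assoc(g$genotypes, g$phenotype, g$covariates)
sum(bh_fdr(res$p_value, 0.05), na.rm = TRUE)
#> [1] 10          # exactly the 10 truly causal SNPs
```

The subtypes recover the planted clusters exactly (AMI = 1), every
clinical measure shifted in truth is detected, the subtype-2 conversion
hazard shows up in the log-rank test, and BH at q = 0.05 recovers the 10
causal SNPs with no false positives in this run.

The full five-experiment design (one experiment per raw view, one on the
GCCA embedding with variance-matched component count, one on the DGCCA
embedding) runs end to end with

```r
run_pipeline(pipeline_config(synthetic = cfg, outdir = "out", seed = 1))
```

writing subtype assignments, validity metrics, cross-experiment AMI,
confusion tables, the rank-sum battery, survival tests and conversion
curves, the SNP association table, and a manifest with file hashes.
A thin CLI wrapper is in `inst/scripts/` (`simulate`, `run-all`).

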
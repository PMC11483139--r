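# deconvae

Deconfounding variational autoencoders for multi-omics clustering.

## The problem

Unsupervised patient stratification — clustering individuals from paired
omics views such as gene expression and DNA methylation — is easily
distorted by *confounders*: variables like age, BMI or batch that shape
the measurements but are unrelated to the biology of interest. A
clustering algorithm happily partitions patients by sequencing centre
instead of disease subtype, and nothing in the loss function tells it
not to. `deconvae` provides, as a tested library plus CLI:

* an **X-shaped variational autoencoder (XVAE)**: per-view encoder
  branches fused into one latent space `z`, a mirrored decoder
  reconstructing both views, and the loss

  `L(φ, θ; x₁, x₂) = −E_{z∼q_φ(z|x₁,x₂)}[log p_θ(x₁, x₂ | z)] + β · MMD(q_φ(z) ‖ N(0, I))`

  with Gaussian reconstruction terms, a multi-scale Gaussian-kernel
  maximum mean discrepancy in place of the KL term, and `β = 1`;
* four **deconfounding strategies** built on it:
  * **cXVAE** — confounder covariates fed to the network as auxiliary
    conditioning inputs (`embed`, `input`, `fused` or `input_embed`
    levels);
  * **adv-XVAE** — alternating training against an adversary MLP that
    predicts the confounder classes from the embedding;
  * **cr-XVAE** — a loss penalty on the association between latent
    dimensions and confounders (|r|, r², or differentiable mutual
    information via soft histogram or KDE);
  * **XVAE+FS** — post-hoc removal of latent dimensions correlated with
    confounders (p < 0.05, |r| > 0.3 or |r| > 0.5);
* the conventional **LR+PCA baseline** (per-feature least-squares
  residualisation on the confounders, PCA to 50 components, KMeans with
  10 initialisations);
* **confounder simulators** with measurable ground truth on `[0,1]`-scaled
  views: linear `(c+5) ⊗ w`, quadratic `c² ⊗ w`, categorical class shifts
  `diag(w)·C`, and their mixture — all purely additive;
* **consensus clustering**: 50 embeddings sampled from the latent
  posterior, KMeans on each, co-assignment frequencies averaged into a
  consensus matrix `Ā` (Ā = 1/50 Σ Aᵢ), partitioned by normalised
  spectral clustering;
* **metrics**: relative reconstruction error per view and combined,
  consensus dispersion `4·mean((Ā − ½)²)`, adjusted Rand index and
  normalised mutual information against true and confounder labels;
* a **synthetic-data generator** for paired views (continuous
  expression-like + bimodal-beta methylation-like) with known clusters,
  so the whole pipeline is testable offline.

## Worked example

```r
library(deconvae)
# 1. simulate a paired dataset with 6 true clusters, rescale to [0,1]
d <- generate_paired_omics(n = 600, p = 50, q = 50, k = 6, signal = 1.5, seed = 1)
d$view1 <- rescale_unit(d$view1)
d$view2 <- rescale_unit(d$view2)

# 2. add a categorical (batch-like) confounding effect
eff <- categorical_effect(600, 50, 50, seed = 101)
cd  <- apply_effects(d, eff)

# 3. train a vanilla XVAE and a conditional XVAE on the confounded data
cfg <- xvae_config(view_hidden = 128, fused_hidden = 128, latent_dim = 16,
                   epochs = 50, learning_rate = 5e-3,
                   early_stop_patience = 20, seed = 11)
xvae  <- train_xvae(build_xvae(50, 50, cfg), cd)
cxvae <- train_xvae(build_cxvae(50, 50, cfg,
                                encode_confounders(factor(eff$confounder_label))), cd)

# 4. consensus-cluster the sampled latent embeddings (50 draws, spectral)
cc_x <- consensus_cluster_pipeline(xvae,  cd, k = 6, n_draws = 50, seed = 5)
cc_c <- consensus_cluster_pipeline(cxvae, cd, k = 6, n_draws = 50, seed = 5)

# 5. evaluate against the true clusters and the confounder classes
for (fit in list(XVAE = cc_x, cXVAE = cc_c)) {
  cat(sprintf("true-ARI %.3f | confounder-ARI %.3f | dispersion %.3f\n",
              ari(fit$labels, d$true_labels),
              ari(fit$labels, eff$confounder_label),
              dispersion(fit$consensus)))
}
```

Output (R 4.3, this repository):

```
true-ARI 0.437 | confounder-ARI 0.116 | dispersion 0.936
true-ARI 0.918 | confounder-ARI 0.002 | dispersion 0.976
```

The vanilla XVAE's clustering is dragged towards the simulated batch
(true-ARI 0.44, confounder-ARI 0.12); the conditional model recovers the
true six-cluster structure almost perfectly while its clustering is
independent of the confounder — the qualitative ordering the benchmark
is designed to detect.

`run_scenario(benchmark_config(...))` repeats this protocol across
models, repetitions and confounding scenarios and reports mean ± sd
tables; the `deconvae` CLI (`inst/cli/deconvae`) exposes `simulate`,
`train`, `cluster`, `evaluate` and `benchmark` subcommands.

## Documentation

`vignettes/deconfounded-clustering.Rmd` describes the model, the
simulators, every tunable parameter with its default and rationale, the
numerical choices, and what the synthetic benchmark does and does not
establish.
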
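Package: deconvae
Title: Deconfounding Variational Autoencoders for Multi-Omics Clustering
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for patient stratification from paired omics views
    (e.g. gene expression and DNA methylation) in the presence of
    confounders such as age or batch. Implements an X-shaped variational
    autoencoder (XVAE) that fuses two omics views into one latent space
    with maximum-mean-discrepancy regularisation, four deconfounding
    strategies built on it (conditional inputs, adversarial training,
    correlation/mutual-information penalties, and post-hoc latent feature
    selection), a linear-regression plus PCA baseline, simulators for
    linear, quadratic, categorical and mixed confounding effects,
    consensus clustering of sampled embeddings with spectral partitioning,
    and evaluation metrics (relative reconstruction error, consensus
    dispersion, adjusted Rand index, normalised mutual information).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
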
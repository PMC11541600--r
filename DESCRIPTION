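Package: stgendiff
Title: Conditional Diffusion Imputation of Spatial Gene Expression from
    scRNA-seq References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts unmeasured gene expression in spatial transcriptomics
    (ST) data using a paired scRNA-seq reference as a prior condition. The
    core is a conditional denoising diffusion probabilistic model whose
    denoiser is a small diffusion transformer: each gene is a sample whose
    spatial profile is generated by ancestral sampling, guided by a latent
    token built from the gene's (masked) spatial profile and its single-cell
    profile, and by a global condition embedding computed from the full
    scRNA-seq matrix with landmark-reduced attention. Includes the matching
    preprocessing (QC, median-count log normalization, coefficient-of-
    variation gene selection, 7:2:1 gene splits), a synthetic paired-data
    generator with planted 2-D spatial patterns, an imputation metric suite
    (PCC, SSIM, RMSE, Jensen-Shannon divergence, composite accuracy score),
    and a binomial-downsampling robustness protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
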
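# stgendiff

Conditional diffusion imputation of spatial gene expression from a paired
scRNA-seq reference.

Image-based spatial transcriptomics (ST) measures expression at spatially
located spots for only tens to hundreds of genes; a paired scRNA-seq
reference covers the transcriptome but has no coordinates. `stgendiff`
predicts the spatial profiles of genes missing from the ST panel. It is
aimed at computational biologists who have a paired ST + scRNA-seq dataset
(sharing a gene panel) and want unmeasured genes imputed on the spot grid,
plus the matching benchmarking metrics.

## Method

Each **gene** is a sample: its observation is the normalized expression
vector over `p` spots. A denoising diffusion probabilistic model corrupts a
profile with the closed form
`x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps` and learns a
transformer denoiser `eps_theta(x_t, t | c)` with the simplified objective
`E || eps - eps_theta ||^2` over masked entries. Conditioning `c` combines

* a per-gene **latent token** `x_phi = x_st_hat (+) x_sc_hat` — feed-forward
  projections of the gene's (masked) spatial profile and its scRNA-seq
  profile — and
* a global **condition embedding**
  `X_psi = softmax(Q Phi_K(K)' / sqrt(d_k)) Phi_V(V)` of the full
  scRNA-seq matrix, computed with landmark-reduced attention (exact or
  memory-tiled "flash" evaluation, numerically identical), injected as
  extra key/value rows in every transformer layer.

Blocks are timestep-modulated (adaptive layer norm) and zero-initialized so
an untrained network is the identity. Unmeasured genes are generated by
ancestral sampling from pure noise; any observed entries are clamped to
their (noised) true values at each reverse step. Preprocessing follows
standard single-cell practice: QC by detected-gene thresholds, median-count
log normalization of ST, LogNormalize of SC, coefficient-of-variation gene
selection, and a deterministic 7:2:1 train/validation/test split over
genes. The metric suite reports per-gene PCC, SSIM, RMSE, base-2
Jensen-Shannon divergence, a rank-composite Accuracy Score across methods,
and a binomial-downsampling Robustness Score.

## A worked example

Everything below runs on simulated data with known ground truth — no
downloads. The generator plants smooth 2-D expression programs (blobs,
stripes, gradients) shared between 500 cells and an 8 x 8 spot lattice,
with 60%/70% ST/SC dropout:

```r
library(stgendiff)

synth <- generate_paired(synth_config(seed = 0))
synth$dataset
#> <paired_dataset> ST 64 spots x 120 genes | SC 500 cells x 300 genes | 120 shared

cfg <- run_config(d_model = 32, n_heads = 4, n_layers = 4, d_cond = 32,
                  r_landmarks = 16, T_steps = 50, schedule = "cosine",
                  full_mask_frac = 1, epochs = 30, batch_size = 12,
                  reps_per_epoch = 12, lr = 1e-2, aux_weight = 1,
                  n_samples = 32, qc_min_genes_sc = 30,
                  seed = 1, split_seed = 1)
ck <- train_model(synth$dataset, cfg)          # ~1 min on one CPU core
prep <- stgendiff:::prepare_data(synth$dataset, cfg)
test_genes <- intersect(split_partition(prep$ds, "test"), ck$shared_genes)
pred <- predict_genes(ck, synth$dataset, test_genes, seed = 99)

truth <- synth$truth$st_log_mean[prep$ds$st$obs_ids, ]
pccs <- sapply(test_genes, function(g)
  pcc(pred$values[, g], truth[, g]))
round(median(pccs), 2)
#> [1] 0.42
```

The imputed held-out genes recover the planted spatial patterns with a
median Pearson correlation around 0.4–0.6 (seed-dependent), against a
measurement ceiling of about 0.3 — the correlation between the *measured*
60%-dropout data and its own generating pattern — and a per-gene
mean-predictor baseline of 0. `metric_report(pred, truth)` produces the
full per-gene metric table.

A thin command-line front end ships in `inst/cli/stgendiff`
(`synth | preprocess | train | predict | evaluate | ablate`, YAML configs,
Matrix-Market or CSV matrices).

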
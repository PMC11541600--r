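# Shared fixtures. Everything is generated in code; heavyweight objects
# (trained checkpoints on the reference synthetic task) are cached in this
# environment so several tests can share one training run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache, inherits = FALSE)
}

# Reference synthetic task: the generator defaults (300 SC genes, 120
# shared, 64 spots, 500 cells, 60% ST dropout), generator seed 0.
ref_synth <- function() cached("ref_synth", generate_paired(synth_config(seed = 0)))

config_with <- function(base, overrides) {
  do.call(run_config, utils::modifyList(base, overrides))
}

# Reference training configuration for the end-to-end recovery runs.
ref_config <- function(seed, ...) {
  config_with(list(d_model = 32L, n_heads = 4L, n_layers = 4L,
                   d_cond = 32L, r_landmarks = 16L, T_steps = 50L,
                   schedule = "cosine", full_mask_frac = 1, epochs = 30L,
                   batch_size = 12L, reps_per_epoch = 12L, lr = 1e-2,
                   aux_weight = 1, n_samples = 32L, patience = 30L,
                   qc_min_genes_sc = 30L, seed = seed, split_seed = seed),
              list(...))
}

ref_checkpoint <- function(seed) {
  cached(paste0("ck_ref_", seed),
         train_model(ref_synth()$dataset, ref_config(seed)))
}

# Per-gene PCC of a predicted spots x genes matrix against a truth matrix.
per_gene_pcc <- function(pred_vals, truth_vals, genes) {
  vapply(genes, function(gn)
    suppressWarnings(pcc(pred_vals[, gn], truth_vals[, gn])), numeric(1))
}

# The planted ground-truth profile (log-mean surface) restricted to the
# spots surviving QC.
ref_truth_matrix <- function(prep) {
  ref_synth()$truth$st_log_mean[prep$ds$st$obs_ids, , drop = FALSE]
}

# Deliberately tiny training task (16 spots, 60 SC genes, 30 shared) so a
# full train/predict cycle takes seconds.
tiny_synth <- function() cached("tiny_synth", generate_paired(
  synth_config(n_cells = 120L, n_spots = 16L, grid_side = 4L,
               n_sc_genes = 60L, n_shared_genes = 30L, n_factors = 3L,
               dropout_sc = 0.5, dropout_st = 0.4, seed = 11)))

tiny_config <- function(seed = 1, ...) {
  config_with(list(d_model = 16L, n_heads = 2L, n_layers = 2L, d_cond = 8L,
                   r_landmarks = 4L, T_steps = 10L, schedule = "cosine",
                   epochs = 3L, batch_size = 8L, reps_per_epoch = 2L,
                   lr = 5e-3, n_samples = 1L, patience = 5L,
                   qc_min_genes_sc = 5L, seed = seed, split_seed = seed),
              list(...))
}

# Tiny model + data for gradient and shape tests.
micro_setup <- function(seed = 42, cond_kind = "attention", ...) {
  set.seed(seed)
  cfg <- run_config(d_model = 8L, n_heads = 2L, n_layers = 2L, d_cond = 6L,
                    r_landmarks = 3L, T_steps = 10L, cond_kind = cond_kind,
                    seed = 1, ...)
  p <- 5L; q <- 7L; m <- 6L
  x_sc_cond <- matrix(rnorm(m * q), m, q)
  mdl <- stgendiff:::init_model(cfg, p, q, m, q, x_sc_cond = x_sc_cond)
  v <- stgendiff:::tree_flatten(mdl$params)
  mdl$params <- stgendiff:::tree_unflatten(mdl$params,
                                           v + rnorm(length(v), sd = 0.05))
  data <- list(Xst_std = matrix(rnorm(4 * p), 4, p),
               Ssc_lat = matrix(rnorm(4 * q), 4, q),
               x_sc_cond = x_sc_cond)
  sched <- make_schedule(cfg$T_steps)
  list(cfg = cfg, mdl = mdl, data = data, sched = sched, p = p, q = q, m = m)
}
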
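#' Run configuration for training and inference
#'
#' Collects every tunable of the pipeline with desk-scale defaults:
#' diffusion schedule (`T = 1000` linear betas `1e-4..2e-2`), masking
#' proportions (half of each stratum), backbone size (4 layers, 4 heads,
#' `d_model` 128), condition embedding (flash attention over landmark
#' key/values, 64 landmarks), optimizer (AdamW, lr `1e-3`, cosine decay) and
#' model selection (best validation PCC, early stopping patience 10).
#'
#' @param d_model token width of the backbone and latent projections.
#' @param n_heads,n_layers backbone attention heads and depth.
#' @param d_cond condition embedding width.
#' @param r_landmarks landmark rows for the condition attention reduction.
#' @param cond_kind condition variant: `"flash_attention"` (default),
#'   `"attention"`, `"mlp"`, `"pca"`, `"zeros"`.
#' @param cond_common_genes compute the condition from shared genes only
#'   (ablation) instead of the full SC feature space.
#' @param concat_latent concatenate the SC projection into the latent token
#'   (`FALSE` gives the "no concat" ablation).
#' @param T_steps,beta_start,beta_end,schedule diffusion schedule settings.
#' @param rho_zero,rho_nonzero training mask fractions per stratum.
#' @param include_zero_mask include masked zero entries in the loss target.
#' @param full_mask_frac fraction of training genes whose profile is fully
#'   masked in a batch (the inference condition: the gene is entirely
#'   unmeasured and must be generated from its SC profile and the global
#'   condition alone); the rest are partially masked via
#'   `rho_zero`/`rho_nonzero`.
#' @param dropout backbone MLP dropout during training.
#' @param covariance_head enable the diagonal covariance decoder.
#' @param loss_weighting `"snr_trunc"` (default) weights each sample's noise
#'   loss by the clipped inverse signal-to-noise ratio of its timestep
#'   (an x0-reconstruction emphasis); `"uniform"` is the plain objective.
#' @param snr_clip clip value for the inverse-SNR weight.
#' @param aux_weight weight of the auxiliary latent-token reconstruction
#'   loss (a linear head regressing the clean profile from the latent
#'   token; trains the conditioning representation, unused at sampling).
#' @param lr,weight_decay,epochs,batch_size AdamW settings; the learning
#'   rate follows a cosine decay over epochs.
#' @param reps_per_epoch number of passes over the training genes per epoch
#'   (each with fresh timesteps, noise and masks).
#' @param patience early-stopping patience on the validation PCC.
#' @param n_samples reverse-diffusion chains averaged at inference.
#' @param hvg_frac fraction of SC genes kept (by coefficient of variation)
#'   as the condition feature space.
#' @param qc_min_genes_sc,qc_min_genes_st QC thresholds forwarded to
#'   [qc_filter()]. The defaults suit transcriptome-scale panels; scale
#'   `qc_min_genes_sc` down for small simulated panels.
#' @param seed global seed for initialization, masking, training noise.
#' @param split_seed seed for the 7:2:1 gene split when the dataset has
#'   none yet.
#' @return a `run_config` list.
#' @export
run_config <- function(d_model = 128L, n_heads = 4L, n_layers = 4L,
                       d_cond = 128L, r_landmarks = 64L,
                       cond_kind = "flash_attention",
                       cond_common_genes = FALSE, concat_latent = TRUE,
                       T_steps = 1000L, beta_start = 1e-4, beta_end = 2e-2,
                       schedule = "linear", rho_zero = 0.5, rho_nonzero = 0.5,
                       include_zero_mask = TRUE, full_mask_frac = 0.5,
                       dropout = 0,
                       covariance_head = FALSE,
                       loss_weighting = "snr_trunc", snr_clip = 5,
                       aux_weight = 0.5, lr = 1e-3,
                       weight_decay = 1e-4, epochs = 30L, batch_size = 16L,
                       reps_per_epoch = 4L, patience = 10L, n_samples = 1L,
                       hvg_frac = 0.25, qc_min_genes_sc = 500L,
                       qc_min_genes_st = 1L, seed = 0L, split_seed = 0L) {
  cfg <- as.list(environment())
  cfg$cond_kind <- match.arg(cond_kind,
                             c("flash_attention", "attention", "mlp", "pca",
                               "zeros"))
  class(cfg) <- "run_config"
  cfg
}

# QC + normalization + split + condition-panel selection shared by the
# trainer and the predictor. Returns gene-major matrices ready for the
# model.
prepare_data <- function(ds, cfg) {
  stopifnot(inherits(ds, "paired_dataset"))
  ds <- qc_filter(ds, min_genes_sc = cfg$qc_min_genes_sc,
                  min_genes_st = cfg$qc_min_genes_st)
  st_norm <- normalize_st(ds$st)
  sc_norm <- normalize_sc(ds$sc)
  if (is.null(ds$split))
    ds <- split_genes(ds, cfg$split_seed)
  cond_panel <- if (cfg$cond_common_genes) ds$shared_genes
                else select_hvg(sc_norm, cfg$hvg_frac)
  list(ds = ds, st_norm = st_norm, sc_norm = sc_norm,
       Xst_gm = gene_major(st_norm),
       Ssc_shared = gene_major(sc_norm, ds$shared_genes),
       x_sc_cond = gene_major(sc_norm, cond_panel),
       cond_panel = cond_panel)
}

#' Train the conditional diffusion model
#'
#' Runs the full training loop: preprocesses the paired counts (QC,
#' normalization, 7:2:1 gene split when absent), builds per-gene latent
#' tokens and the global condition embedding, and minimizes the masked
#' noise-prediction objective with AdamW over batches of shared training
#' genes. Each epoch the validation genes are imputed by full ancestral
#' sampling and scored by mean PCC against their measured profiles; the
#' checkpoint with the best validation PCC is returned (early stopping on a
#' patience of `cfg$patience` epochs). Fully deterministic under
#' `cfg$seed`.
#'
#' @param ds a [paired_dataset()] of raw counts.
#' @param cfg a [run_config()].
#' @param verbose print per-epoch progress.
#' @param log_file optional path for a JSON-lines event log.
#' @return a `stgendiff_checkpoint` with fitted parameters, schedule,
#'   scaler, gene panels and the training log.
#' @export
train_model <- function(ds, cfg = run_config(), verbose = FALSE,
                        log_file = NULL) {
  prep <- prepare_data(ds, cfg)
  ds <- prep$ds
  train_genes <- intersect(split_partition(ds, "train"), ds$shared_genes)
  val_genes <- intersect(split_partition(ds, "val"), ds$shared_genes)
  if (length(train_genes) == 0) stop("empty training split")
  sched <- make_schedule(cfg$T_steps, cfg$beta_start, cfg$beta_end,
                         cfg$schedule)
  mu <- mean(prep$Xst_gm[train_genes, ])
  sdv <- stats::sd(prep$Xst_gm[train_genes, ])
  if (sdv == 0) stop("training genes are constant; cannot standardize")
  Xst_std <- (prep$Xst_gm - mu) / sdv
  data <- list(Xst_std = Xst_std[train_genes, , drop = FALSE],
               Ssc_lat = prep$Ssc_shared[train_genes, , drop = FALSE],
               x_sc_cond = prep$x_sc_cond)
  p <- ncol(prep$Xst_gm)
  q_lat <- ncol(prep$Ssc_shared)
  n_train <- length(train_genes)
  log_event <- function(...) {
    if (!is.null(log_file))
      cat(jsonlite::toJSON(list(...), auto_unbox = TRUE), "\n",
          file = log_file, append = TRUE)
  }
  with_seed(cfg$seed, {
    mdl <- init_model(cfg, p, q_lat, nrow(prep$x_sc_cond),
                      ncol(prep$x_sc_cond), x_sc_cond = prep$x_sc_cond)
    params <- mdl$params
    opt <- adamw_init(params)
    best <- list(metric = -Inf, params = params, epoch = 0L)
    wait <- 0L
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_pcc = numeric())
    for (epoch in seq_len(cfg$epochs)) {
      lr_e <- cfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs))
      losses <- numeric(0)
      for (rep in seq_len(cfg$reps_per_epoch)) {
        perm <- sample.int(n_train)
        starts <- seq(1, n_train, by = cfg$batch_size)
        for (s in starts) {
          idx <- perm[s:min(s + cfg$batch_size - 1, n_train)]
          B <- length(idx)
          tvec <- sample.int(sched$T_steps, B, replace = TRUE)
          eps <- matrix(stats::rnorm(B * p), B, p)
          full <- stats::runif(B) < cfg$full_mask_frac
          target <- t(vapply(seq_along(idx), function(k) {
            if (full[k]) return(rep(TRUE, p))
            mk <- make_masks(data$Xst_std[idx[k], ], cfg$rho_zero,
                             cfg$rho_nonzero,
                             seed = sample.int(2147483646L, 1))
            if (cfg$include_zero_mask) mk$m1 | mk$m2 else mk$m2
          }, logical(p)))
          res <- model_loss_grad(params, cfg, mdl$fixed, mdl$bcfg, data,
                                 list(idx = idx, tvec = tvec, eps = eps,
                                      target = target, sched = sched))
          if (!is.finite(res$loss))
            stop("training diverged: non-finite loss at epoch ", epoch,
                 " (lr = ", lr_e, "); lower the learning rate")
          st <- adamw_step(params, res$grads, opt, lr = lr_e,
                           weight_decay = cfg$weight_decay)
          params <- st$params
          opt <- st$state
          losses <- c(losses, res$loss)
        }
      }
      val_pcc <- if (length(val_genes) >= 1) {
        pred <- sample_profiles(params, cfg, mdl$bcfg, sched,
                                genes = val_genes, prep = prep,
                                scaler = c(mu, sdv), n_samples = 1L,
                                fixed = mdl$fixed)
        truth <- prep$Xst_gm[val_genes, , drop = FALSE]
        mean(vapply(seq_along(val_genes), function(i)
          suppressWarnings(pcc(pred[i, ], truth[i, ])), numeric(1)))
      } else -mean(losses)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_pcc = val_pcc))
      log_event(event = "epoch", epoch = epoch, train_loss = mean(losses),
                val_pcc = val_pcc, lr = lr_e)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val PCC %.3f", epoch,
                        mean(losses), val_pcc))
      if (val_pcc > best$metric + 1e-6) {
        best <- list(metric = val_pcc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          log_event(event = "early_stop", epoch = epoch)
          break
        }
      }
    }
    structure(list(params = best$params, fixed = mdl$fixed, cfg = cfg,
                   bcfg = mdl$bcfg, sched = sched,
                   scaler = c(mu = mu, sd = sdv),
                   shared_genes = ds$shared_genes,
                   cond_panel = prep$cond_panel,
                   split = ds$split, best_epoch = best$epoch,
                   best_val_pcc = best$metric, log = log),
              class = "stgendiff_checkpoint")
  })
}

# Batched ancestral sampling of gene profiles with observed-entry
# replacement, on the standardized scale. Uses the current RNG stream.
# observed/observed_mask: genes x spots (standardized scale), or NULL for
# fully-unobserved generation.
sample_profiles_std <- function(params, cfg, bcfg, sched, Phi, C, B, p,
                                n_samples = 1L, observed = NULL,
                                observed_mask = NULL) {
  has_obs <- !is.null(observed_mask) && any(observed_mask)
  acc <- matrix(0, B, p)
  for (s in seq_len(n_samples)) {
    X <- matrix(stats::rnorm(B * p), B, p)
    if (has_obs) {
      E <- matrix(stats::rnorm(B * p), B, p)
      Xr <- forward_diffuse(observed, rep(sched$T_steps, B), E, sched)
      X[observed_mask] <- Xr[observed_mask]
    }
    for (t in seq(sched$T_steps, 1)) {
      out <- backbone_fwd(params$backbone, bcfg, X,  Phi,
                          rep(t, B), C)
      eps_hat <- out$eps_pred
      mu_t <- (X - sched$beta[t] / sqrt(1 - sched$alpha_bar[t]) * eps_hat) /
        sqrt(sched$alpha_hat[t])
      if (t > 1) {
        sig <- sqrt(sched$sigma2[t])
        if (!is.null(out$logvar_pred)) {
          lv <- pmin(pmax(out$logvar_pred, log(sched$sigma2[t])),
                     log(sched$beta[t]))
          sig <- exp(0.5 * lv)
        }
        X <- mu_t + sig * matrix(stats::rnorm(B * p), B, p)
      } else X <- mu_t
      if (has_obs) {
        if (t > 1) {
          E <- matrix(stats::rnorm(B * p), B, p)
          Xr <- forward_diffuse(observed, rep(t - 1L, B), E, sched)
          X[observed_mask] <- Xr[observed_mask]
        } else X[observed_mask] <- observed[observed_mask]
      }
    }
    acc <- acc + X
  }
  out <- acc / n_samples
  if (has_obs) out[observed_mask] <- observed[observed_mask]
  out
}

# Impute genes on the normalized scale (wraps standardization and the
# latent/condition contexts). Returns genes x spots.
sample_profiles <- function(params, cfg, bcfg, sched, genes, prep, scaler,
                            n_samples = 1L, observed = NULL,
                            observed_mask = NULL, fixed = list()) {
  p <- ncol(prep$Xst_gm)
  B <- length(genes)
  obs_std <- NULL
  if (!is.null(observed_mask)) {
    obs_std <- (observed - scaler[1]) / scaler[2]
    obs_std[!observed_mask] <- 0
  }
  Sst <- if (is.null(obs_std)) matrix(0, B, p) else obs_std
  lat <- latent_fwd(params$latent, Sst,
                    prep$Ssc_shared[genes, , drop = FALSE],
                    concat = cfg$concat_latent)
  cnd <- cond_tokens_fwd(params, cfg, fixed, prep$x_sc_cond)
  std <- sample_profiles_std(params, cfg, bcfg, sched, lat$phi, cnd$C, B, p,
                             n_samples = n_samples, observed = obs_std,
                             observed_mask = observed_mask)
  out <- std * scaler[2] + scaler[1]
  if (!is.null(observed_mask)) out[observed_mask] <- observed[observed_mask]
  rownames(out) <- genes
  out
}

#' Impute gene expression profiles with a trained checkpoint
#'
#' For each requested gene, builds the latent token from its SC profile
#' (and any observed spatial entries), conditions on the global SC
#' embedding, and runs the reverse diffusion chain; results are averaged
#' over `n_samples` chains and returned on the normalized scale.
#'
#' @param checkpoint a trained `stgendiff_checkpoint` (see [train_model()]).
#' @param ds the [paired_dataset()] of raw counts (same pipeline as
#'   training is applied).
#' @param gene_ids genes to impute; must be ST genes with an SC profile
#'   (shared genes).
#' @param n_samples chains to average (default from the checkpoint config).
#' @param seed sampling seed.
#' @param observed optional spots x genes matrix of known normalized values.
#' @param observed_mask optional spots x genes logical matrix marking which
#'   entries of `observed` are known; known entries are returned unchanged.
#' @return an [expression_matrix()] (spots x genes, normalized layer).
#' @export
predict_genes <- function(checkpoint, ds, gene_ids,
                          n_samples = checkpoint$cfg$n_samples,
                          seed = checkpoint$cfg$seed, observed = NULL,
                          observed_mask = NULL) {
  ck <- checkpoint
  stopifnot(inherits(ck, "stgendiff_checkpoint"))
  if (is.null(ck$params)) stop("checkpoint has no fitted parameters")
  prep <- prepare_data(ds, ck$cfg)
  unknown <- setdiff(gene_ids, prep$ds$st$gene_ids)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  no_sc <- setdiff(gene_ids, prep$ds$shared_genes)
  if (length(no_sc))
    stop("gene(s) without an SC profile: ",
         paste(utils::head(no_sc, 5), collapse = ", "))
  om <- if (!is.null(observed_mask)) t(observed_mask[, gene_ids, drop = FALSE])
  ob <- if (!is.null(observed)) t(observed[, gene_ids, drop = FALSE])
  pred <- with_seed(seed,
    sample_profiles(ck$params, ck$cfg, ck$bcfg, ck$sched, gene_ids, prep,
                    ck$scaler, n_samples = n_samples, observed = ob,
                    observed_mask = om, fixed = ck$fixed))
  out <- t(pred)
  rownames(out) <- prep$ds$st$obs_ids
  expression_matrix(out, modality = "ST", layer = "normalized")
}

#' Per-gene mean-predictor baseline
#'
#' The reference predictor the diffusion model must beat: each target gene
#' is predicted as a constant over spots (the mean normalized expression of
#' the training genes, the best constant guess for an unmeasured gene). A
#' constant profile carries no spatial information, so its PCC is 0 under
#' the package's convention. Set `profile = TRUE` for the stronger
#' mean-spatial-profile variant (the average training-gene profile per
#' spot), reported alongside in the package's own evaluations.
#'
#' @param st_norm normalized ST [expression_matrix()].
#' @param train_genes genes the baseline may look at.
#' @param target_genes genes to "predict".
#' @param profile use the per-spot average profile instead of a constant.
#' @return an [expression_matrix()] (spots x target genes, normalized).
#' @export
mean_baseline <- function(st_norm, train_genes, target_genes,
                          profile = FALSE) {
  prof <- if (profile)
    rowMeans(st_norm$values[, train_genes, drop = FALSE])
  else
    rep(mean(st_norm$values[, train_genes]), length(st_norm$obs_ids))
  vals <- matrix(prof, nrow = length(prof), ncol = length(target_genes))
  colnames(vals) <- target_genes
  rownames(vals) <- st_norm$obs_ids
  expression_matrix(vals, modality = "ST", layer = "normalized")
}

#' Train an ablated model variant
#'
#' Applies one of the ablation switches to the configuration and trains:
#' `no_flash_attention` replaces the attention condition with an MLP,
#' `no_condition` zeroes the condition embedding, `common_gene_condition`
#' computes the condition from shared genes only, and `no_concat` drops the
#' SC part of the latent token.
#'
#' @param ds a [paired_dataset()] of raw counts.
#' @param cfg base [run_config()].
#' @param switch one of `"no_flash_attention"`, `"no_condition"`,
#'   `"common_gene_condition"`, `"no_concat"`.
#' @param ... forwarded to [train_model()].
#' @return a trained checkpoint.
#' @export
ablate <- function(ds, cfg, switch, ...) {
  cfg <- switch(switch,
    no_flash_attention = { cfg$cond_kind <- "mlp"; cfg },
    no_condition = { cfg$cond_kind <- "zeros"; cfg },
    common_gene_condition = { cfg$cond_common_genes <- TRUE; cfg },
    no_concat = { cfg$concat_latent <- FALSE; cfg },
    stop("unknown ablation switch: ", switch))
  train_model(ds, cfg, ...)
}

#' Save / load a checkpoint
#'
#' Checkpoints bundle the fitted parameters, the backbone and run
#' configuration, the noise schedule, the standardization scaler and the
#' gene panels, so `save -> load -> predict` reproduces in-memory
#' predictions bit for bit.
#'
#' @param checkpoint a `stgendiff_checkpoint`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "stgendiff_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "stgendiff_checkpoint"))
  ck
}
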
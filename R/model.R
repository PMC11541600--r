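# Full-model assembly: latent embedding + condition embedding + DiT
# backbone, with a fused loss/gradient path used by the trainer. Trainable
# parameters live in one nested list (latent / cond / backbone) so the
# optimizer and the finite-difference checks can treat the model as a
# single parameter tree; non-trainable pieces (e.g. the PCA projection of
# the "pca" condition variant) are kept in a separate `fixed` list.

init_model <- function(cfg, p, q_lat, m_cond, q_cond, x_sc_cond = NULL) {
  d <- cfg$d_model
  bcfg <- backbone_config(n_layers = cfg$n_layers, n_heads = cfg$n_heads,
                          d_model = d, d_cond = cfg$d_cond,
                          dropout = cfg$dropout,
                          covariance_head = cfg$covariance_head)
  d_phi <- if (cfg$concat_latent) 2L * d else d
  kind <- cfg$cond_kind
  trainable_cond <- kind %in% c("attention", "flash_attention", "mlp")
  cond <- if (trainable_cond)
    init_condition_params(kind, m_cond, q_cond, d_k = cfg$d_cond,
                          d_cond = cfg$d_cond, r_landmarks = cfg$r_landmarks)
  else list()
  fixed <- list()
  if (kind == "pca")
    fixed$cond <- init_condition_params("pca", m_cond, q_cond,
                                        d_k = cfg$d_cond, d_cond = cfg$d_cond,
                                        r_landmarks = cfg$r_landmarks,
                                        x_sc = x_sc_cond)
  params <- list(latent = init_latent_params(p, q_lat, d),
                 cond = cond,
                 backbone = init_backbone_params(p, d_phi, bcfg))
  list(params = params, fixed = fixed, bcfg = bcfg)
}

# Condition tokens for the backbone: embed the SC condition matrix with the
# configured variant, then project to d_model. The flash variant shares the
# exact path here (identical values) so the attention matrix is available
# for the backward pass.
cond_tokens_fwd <- function(params, cfg, fixed, x_sc_cond) {
  kind <- cfg$cond_kind
  emb <- switch(kind,
    attention = ,
    flash_attention = embed_condition(x_sc_cond, params$cond, flash = FALSE),
    mlp = cond_mlp_fwd(x_sc_cond, params$cond),
    pca = condition_variant("pca", x_sc_cond, fixed$cond),
    zeros = condition_variant("zeros", x_sc_cond, d_cond = cfg$d_cond),
    stop("unknown condition kind: ", kind))
  C <- linear_fwd(emb$x_psi, params$backbone$cond_proj)
  list(emb = emb, C = C)
}

cond_bwd <- function(dXpsi, emb, params, kind) {
  switch(kind,
    attention = ,
    flash_attention = cond_attention_bwd(dXpsi, emb, params$cond),
    mlp = cond_mlp_bwd(dXpsi, emb, params$cond),
    list())
}

# Fused forward + loss + full gradient for one training batch.
# data: Xst_std (train genes x p, standardized), Ssc_lat (genes x q_lat),
#       x_sc_cond (m x q_cond)
# batch: idx (gene rows), tvec, eps (B x p), target (B x p logical)
model_loss_grad <- function(params, cfg, fixed, bcfg, data, batch,
                            grads = TRUE, training = TRUE) {
  idx <- batch$idx
  x0 <- data$Xst_std[idx, , drop = FALSE]
  target <- batch$target
  Sst <- x0 * !target
  lat <- latent_fwd(params$latent, Sst, data$Ssc_lat[idx, , drop = FALSE],
                    concat = cfg$concat_latent)
  cnd <- cond_tokens_fwd(params, cfg, fixed, data$x_sc_cond)
  XT <- forward_diffuse(x0, batch$tvec, batch$eps, batch$sched)
  bb <- backbone_fwd(params$backbone, bcfg, XT, lat$phi, batch$tvec, cnd$C,
                     training = training, keep_cache = grads)
  if (sum(target) == 0) {
    warning("empty mask target; loss defined as 0")
    return(list(loss = 0, grads = if (grads) tree_zeros(params) else NULL))
  }
  # per-sample timestep weight (min-SNR truncation): full weight on
  # high-noise steps, where the noise loss carries the conditioning signal,
  # and down-weighted low-noise steps whose noise target is dominated by
  # trivially recoverable structure
  wt <- if (identical(cfg$loss_weighting, "snr_trunc")) {
    ab <- batch$sched$alpha_bar[batch$tvec]
    pmin(1, cfg$snr_clip * (1 - ab) / ab)
  } else rep(1, length(batch$tvec))
  Wm <- wt * target
  n_target <- sum(Wm)
  resid <- (bb$eps_pred - batch$eps) * target
  loss <- sum(wt * resid^2) / n_target
  # auxiliary reconstruction: a linear head reads the clean profile off the
  # latent token. It injects a full-strength supervised signal into the
  # conditioning representation (the noise objective carries the
  # conditioning only as a small fraction of its variance); the sampling
  # path never uses this head.
  aux_w <- cfg$aux_weight
  if (aux_w > 0) {
    aux_resid <- bb$aux_out - x0
    loss <- loss + aux_w * mean(aux_resid^2)
  }
  dlogvar <- NULL
  if (bcfg$covariance_head) {
    # hybrid term: Gaussian NLL with the noise-prediction error detached,
    # small weight, gradient only through the log-variance head
    w <- 1e-3
    lv <- bb$logvar_pred
    err2 <- (bb$eps_pred - batch$eps)^2
    loss <- loss + w * 0.5 * sum((lv + err2 / exp(lv)) * target) / n_target
    dlogvar <- w * 0.5 * (1 - err2 / exp(lv)) * target / n_target
  }
  if (!grads) return(list(loss = loss))
  deps <- 2 * wt * resid / n_target
  bbb <- backbone_bwd(params$backbone, bcfg, bb$cache, deps, dlogvar)
  gb <- bbb$grads
  dPhi <- bbb$dPhi
  if (aux_w > 0) {
    daux <- 2 * aux_w * aux_resid / length(aux_resid)
    ba <- linear_bwd(daux, lat$phi, params$backbone$aux_dec)
    gb$aux_dec$W <- gb$aux_dec$W + ba$dW
    gb$aux_dec$b <- gb$aux_dec$b + ba$db
    dPhi <- dPhi + ba$dx
  }
  if (!is.null(bbb$dC)) {
    gb$cond_proj <- list(W = crossprod(cnd$emb$x_psi, bbb$dC),
                         b = colSums(bbb$dC))
    dXpsi <- bbb$dC %*% t(params$backbone$cond_proj$W)
  } else {
    gb$cond_proj <- list(W = params$backbone$cond_proj$W * 0,
                         b = params$backbone$cond_proj$b * 0)
    dXpsi <- NULL
  }
  gb <- gb[names(params$backbone)]
  gl <- latent_bwd(dPhi, lat, params$latent, concat = cfg$concat_latent)
  gc <- if (!is.null(dXpsi) &&
            cfg$cond_kind %in% c("attention", "flash_attention", "mlp"))
    cond_bwd(dXpsi, cnd$emb, params, cfg$cond_kind)
  else tree_zeros(params$cond)
  list(loss = loss,
       grads = list(latent = gl, cond = gc, backbone = gb),
       eps_pred = bb$eps_pred)
}

# Denoiser closure over fitted parameters for one batch of genes whose
# latent tokens and condition tokens are fixed during sampling. Accepts a
# matrix (genes x p) or a single profile vector.
make_denoiser <- function(params, cfg, bcfg, Phi, C) {
  function(x_t, t, condition = NULL) {
    vec_in <- !is.matrix(x_t)
    if (vec_in) x_t <- matrix(x_t, 1)
    tvec <- if (length(t) == 1) rep(as.integer(t), nrow(x_t)) else as.integer(t)
    out <- backbone_fwd(params$backbone, bcfg, x_t, Phi, tvec, C)
    if (!is.null(out$logvar_pred)) {
      eps <- out$eps_pred
      lv <- out$logvar_pred
      if (vec_in) { eps <- drop(eps); lv <- drop(lv) }
      list(eps = eps, logvar = lv)
    } else {
      if (vec_in) drop(out$eps_pred) else out$eps_pred
    }
  }
}
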
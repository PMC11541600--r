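# Diffusion-transformer denoiser. Tokens are per-gene: the noisy spatial
# profile and the latent token are embedded into d_model and form a
# two-token sequence; the condition embedding contributes extra key/value
# rows to every self-attention layer. Timestep information enters through
# adaptive modulation (shift/scale/gate) of every residual branch; the
# modulation and the final decoder are zero-initialized so an untrained
# block is exactly the identity map. The backward pass is hand-derived and
# finite-difference checked in the tests.

#' Backbone configuration
#'
#' @param n_layers number of transformer blocks.
#' @param n_heads attention heads; must divide `d_model`.
#' @param d_model token width.
#' @param d_cond width of the condition embedding tokens.
#' @param dropout dropout fraction on the MLP hidden layer during training.
#' @param covariance_head also decode a per-entry log-variance (diagonal
#'   covariance) prediction; off by default (the training objective is pure
#'   noise MSE and the reverse variance then comes from the schedule).
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(n_layers = 4L, n_heads = 4L, d_model = 128L,
                            d_cond = 128L, dropout = 0, covariance_head = FALSE) {
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_cond = as.integer(d_cond),
                 dropout = dropout, covariance_head = isTRUE(covariance_head)),
            class = "backbone_config")
}

init_block_params <- function(d, hidden = 2L * d) {
  list(ada = init_linear(d, 6L * d, zero = TRUE),
       Wq = init_linear(d, d)$W,
       Wk = init_linear(d, d)$W,
       Wv = init_linear(d, d)$W,
       attn_out = init_linear(d, d),
       mlp = list(l1 = init_linear(d, hidden), l2 = init_linear(hidden, d)))
}

init_backbone_params <- function(p, d_phi, cfg) {
  d <- cfg$d_model
  bp <- list(x_in = init_linear(p, d),
             phi_proj = init_linear(d_phi, d),
             aux_dec = init_linear(d_phi, p),
             skip_a = init_linear(d, 1L, zero = TRUE),
             skip_b = init_linear(d, 1L, zero = TRUE),
             tmlp = list(l1 = init_linear(d, d), l2 = init_linear(d, d)),
             cond_proj = init_linear(cfg$d_cond, d),
             blocks = lapply(seq_len(cfg$n_layers), function(i) init_block_params(d)),
             final_ada = init_linear(d, 2L * d, zero = TRUE),
             dec = init_linear(d, p, zero = TRUE))
  if (cfg$covariance_head) bp$dec_logvar <- init_linear(d, p, zero = TRUE)
  bp
}

mod_split <- function(mod, d) {
  lapply(0:5, function(k) mod[, k * d + seq_len(d), drop = FALSE])
}

# One DiT block, batched: tokens is a list of B x d matrices (one per
# sequence position), C is the (possibly NULL) m x d condition token matrix
# shared across the batch, te is the B x d processed timestep embedding.
block_fwd <- function(bp, tokens, te, C, n_heads, dropout = 0,
                      training = FALSE, keep_cache = FALSE) {
  d <- ncol(tokens[[1]])
  n_tok <- length(tokens)
  dh <- d / n_heads
  m <- if (is.null(C)) 0L else nrow(C)
  mod <- linear_fwd(te, bp$ada)
  ms <- mod_split(mod, d)  # sh1, sc1, g1, sh2, sc2, g2
  ln1 <- lapply(tokens, layernorm_fwd)
  U <- lapply(ln1, function(l) l$y * (1 + ms[[2]]) + ms[[1]])
  Q <- lapply(U, function(u) u %*% bp$Wq)
  K <- lapply(U, function(u) u %*% bp$Wk)
  V <- lapply(U, function(u) u %*% bp$Wv)
  Kc <- if (m > 0) C %*% bp$Wk else NULL
  Vc <- if (m > 0) C %*% bp$Wv else NULL
  A <- vector("list", n_tok)
  OH <- vector("list", n_tok)
  for (i in seq_len(n_tok)) {
    A[[i]] <- vector("list", n_heads)
    OHi <- matrix(0, nrow(Q[[i]]), d)
    for (h in seq_len(n_heads)) {
      idx <- (h - 1) * dh + seq_len(dh)
      Qh <- Q[[i]][, idx, drop = FALSE]
      S_own <- vapply(seq_len(n_tok), function(j)
        rowSums(Qh * K[[j]][, idx, drop = FALSE]), numeric(nrow(Qh)))
      S_own <- matrix(S_own, nrow = nrow(Qh))
      S <- if (m > 0)
        cbind(S_own, Qh %*% t(Kc[, idx, drop = FALSE])) else S_own
      Ah <- softmax_rows(S / sqrt(dh))
      Oh <- matrix(0, nrow(Qh), dh)
      for (j in seq_len(n_tok))
        Oh <- Oh + Ah[, j] * V[[j]][, idx, drop = FALSE]
      if (m > 0)
        Oh <- Oh + Ah[, n_tok + seq_len(m), drop = FALSE] %*%
          Vc[, idx, drop = FALSE]
      A[[i]][[h]] <- Ah
      OHi[, idx] <- Oh
    }
    OH[[i]] <- OHi
  }
  O <- lapply(OH, function(oh) linear_fwd(oh, bp$attn_out))
  Tmid <- lapply(seq_len(n_tok), function(i) tokens[[i]] + ms[[3]] * O[[i]])
  ln2 <- lapply(Tmid, layernorm_fwd)
  Vv <- lapply(ln2, function(l) l$y * (1 + ms[[5]]) + ms[[4]])
  z <- lapply(Vv, function(v) linear_fwd(v, bp$mlp$l1))
  hh <- lapply(z, gelu)
  drop_mask <- NULL
  if (training && dropout > 0) {
    drop_mask <- lapply(hh, function(h)
      matrix(stats::rbinom(length(h), 1, 1 - dropout), nrow(h)) / (1 - dropout))
    hh <- lapply(seq_len(n_tok), function(i) hh[[i]] * drop_mask[[i]])
  }
  M <- lapply(hh, function(h) linear_fwd(h, bp$mlp$l2))
  out <- lapply(seq_len(n_tok), function(i) Tmid[[i]] + ms[[6]] * M[[i]])
  cache <- NULL
  if (keep_cache)
    cache <- list(tokens = tokens, te = te, C = C, ms = ms, ln1 = ln1, U = U,
                  Q = Q, K = K, V = V, Kc = Kc, Vc = Vc, A = A, OH = OH,
                  O = O, Tmid = Tmid, ln2 = ln2, Vv = Vv, z = z, hh = hh,
                  M = M, drop_mask = drop_mask, n_heads = n_heads)
  list(out = out, cache = cache)
}

# Backward of block_fwd. dout: list of B x d gradients per position.
# Returns list(dtokens, dte, dC, grads) with grads matching the block's
# parameter structure.
block_bwd <- function(bp, cache, dout) {
  ms <- cache$ms
  n_tok <- length(dout)
  d <- ncol(dout[[1]])
  n_heads <- cache$n_heads
  dh <- d / n_heads
  m <- if (is.null(cache$C)) 0L else nrow(cache$C)
  g <- list(ada = list(W = matrix(0, d, 6 * d), b = numeric(6 * d)),
            Wq = matrix(0, d, d), Wk = matrix(0, d, d), Wv = matrix(0, d, d),
            attn_out = list(W = matrix(0, d, d), b = numeric(d)),
            mlp = list(l1 = list(W = bp$mlp$l1$W * 0, b = bp$mlp$l1$b * 0),
                       l2 = list(W = bp$mlp$l2$W * 0, b = bp$mlp$l2$b * 0)))
  B <- nrow(dout[[1]])
  zero_bd <- matrix(0, B, d)
  dsh1 <- dsc1 <- dg1 <- dsh2 <- dsc2 <- dg2 <- zero_bd
  dC <- if (m > 0) matrix(0, m, d) else NULL
  dTmid <- vector("list", n_tok)
  # MLP branch
  for (i in seq_len(n_tok)) {
    dTi <- dout[[i]]
    dg2 <- dg2 + dTi * cache$M[[i]]
    dM <- dTi * ms[[6]]
    b2 <- linear_bwd(dM, cache$hh[[i]], bp$mlp$l2)
    g$mlp$l2$W <- g$mlp$l2$W + b2$dW
    g$mlp$l2$b <- g$mlp$l2$b + b2$db
    dhh <- b2$dx
    if (!is.null(cache$drop_mask)) dhh <- dhh * cache$drop_mask[[i]]
    dz <- dhh * gelu_grad(cache$z[[i]])
    b1 <- linear_bwd(dz, cache$Vv[[i]], bp$mlp$l1)
    g$mlp$l1$W <- g$mlp$l1$W + b1$dW
    g$mlp$l1$b <- g$mlp$l1$b + b1$db
    dVv <- b1$dx
    dsc2 <- dsc2 + dVv * cache$ln2[[i]]$y
    dsh2 <- dsh2 + dVv
    dxhat2 <- dVv * (1 + ms[[5]])
    dTmid[[i]] <- dTi +
      layernorm_bwd(dxhat2, cache$ln2[[i]]$y, cache$ln2[[i]]$s)
  }
  # attention branch
  dU <- replicate(n_tok, zero_bd, simplify = FALSE)
  dQ <- replicate(n_tok, zero_bd, simplify = FALSE)
  dK <- replicate(n_tok, zero_bd, simplify = FALSE)
  dV <- replicate(n_tok, zero_bd, simplify = FALSE)
  dKc <- if (m > 0) matrix(0, m, d) else NULL
  dVc <- if (m > 0) matrix(0, m, d) else NULL
  dtokens <- vector("list", n_tok)
  for (i in seq_len(n_tok)) {
    dTi <- dTmid[[i]]
    dg1 <- dg1 + dTi * cache$O[[i]]
    dO <- dTi * ms[[3]]
    bo <- linear_bwd(dO, cache$OH[[i]], bp$attn_out)
    g$attn_out$W <- g$attn_out$W + bo$dW
    g$attn_out$b <- g$attn_out$b + bo$db
    dOH <- bo$dx
    for (h in seq_len(n_heads)) {
      idx <- (h - 1) * dh + seq_len(dh)
      dOh <- dOH[, idx, drop = FALSE]
      Ah <- cache$A[[i]][[h]]
      dA_own <- vapply(seq_len(n_tok), function(j)
        rowSums(dOh * cache$V[[j]][, idx, drop = FALSE]), numeric(B))
      dA_own <- matrix(dA_own, nrow = B)
      dA <- if (m > 0)
        cbind(dA_own, dOh %*% t(cache$Vc[, idx, drop = FALSE])) else dA_own
      for (j in seq_len(n_tok))
        dV[[j]][, idx] <- dV[[j]][, idx, drop = FALSE] + Ah[, j] * dOh
      if (m > 0) {
        Ac <- Ah[, n_tok + seq_len(m), drop = FALSE]
        dVc[, idx] <- dVc[, idx, drop = FALSE] + crossprod(Ac, dOh)
      }
      dS <- softmax_rows_bwd(dA, Ah) / sqrt(dh)
      Qh <- cache$Q[[i]][, idx, drop = FALSE]
      dQh <- matrix(0, B, dh)
      for (j in seq_len(n_tok)) {
        dQh <- dQh + dS[, j] * cache$K[[j]][, idx, drop = FALSE]
        dK[[j]][, idx] <- dK[[j]][, idx, drop = FALSE] + dS[, j] * Qh
      }
      if (m > 0) {
        dSc <- dS[, n_tok + seq_len(m), drop = FALSE]
        dQh <- dQh + dSc %*% cache$Kc[, idx, drop = FALSE]
        dKc[, idx] <- dKc[, idx, drop = FALSE] + crossprod(dSc, Qh)
      }
      dQ[[i]][, idx] <- dQ[[i]][, idx, drop = FALSE] + dQh
    }
    dtokens[[i]] <- dTi  # residual path
  }
  for (j in seq_len(n_tok)) {
    g$Wq <- g$Wq + crossprod(cache$U[[j]], dQ[[j]])
    g$Wk <- g$Wk + crossprod(cache$U[[j]], dK[[j]])
    g$Wv <- g$Wv + crossprod(cache$U[[j]], dV[[j]])
    dU[[j]] <- dQ[[j]] %*% t(bp$Wq) + dK[[j]] %*% t(bp$Wk) +
      dV[[j]] %*% t(bp$Wv)
  }
  if (m > 0) {
    g$Wk <- g$Wk + crossprod(cache$C, dKc)
    g$Wv <- g$Wv + crossprod(cache$C, dVc)
    dC <- dKc %*% t(bp$Wk) + dVc %*% t(bp$Wv)
  }
  for (i in seq_len(n_tok)) {
    dUi <- dU[[i]]
    dsc1 <- dsc1 + dUi * cache$ln1[[i]]$y
    dsh1 <- dsh1 + dUi
    dxhat1 <- dUi * (1 + ms[[2]])
    dtokens[[i]] <- dtokens[[i]] +
      layernorm_bwd(dxhat1, cache$ln1[[i]]$y, cache$ln1[[i]]$s)
  }
  dmod <- cbind(dsh1, dsc1, dg1, dsh2, dsc2, dg2)
  g$ada$W <- crossprod(cache$te, dmod)
  g$ada$b <- colSums(dmod)
  dte <- dmod %*% t(bp$ada$W)
  list(dtokens = dtokens, dte = dte, dC = dC, grads = g)
}

#' One diffusion-transformer block
#'
#' Applies a single DiT block to a token sequence: layer norm with adaptive
#' shift/scale from the timestep embedding, multi-head self-attention whose
#' key/value set is augmented with the condition tokens, gated residual
#' connection, then a gated MLP branch. The gates are zero at initialization
#' so a fresh block is exactly the identity.
#'
#' @param tokens numeric matrix, sequence positions x `d_model`.
#' @param condition optional condition token matrix (m x `d_model`), or
#'   `NULL`.
#' @param t_embed processed timestep embedding (length `d_model`).
#' @param params block parameters (see the trainer); `n_heads` attribute
#'   read from `params$n_heads` or the `n_heads` argument.
#' @param n_heads number of attention heads.
#' @return token matrix of the same shape.
#' @export
dit_block <- function(tokens, condition, t_embed, params, n_heads = 4L) {
  tok_list <- lapply(seq_len(nrow(tokens)), function(i)
    matrix(tokens[i, ], 1))
  out <- block_fwd(params, tok_list, matrix(t_embed, 1), condition, n_heads)
  do.call(rbind, lapply(out$out, drop))
}

# Full-network forward. XT: B x p noisy profiles; Phi: B x d_phi latent
# tokens; tvec: B steps; C: condition tokens (m x d) or NULL.
backbone_fwd <- function(bp, cfg, XT, Phi, tvec, C, training = FALSE,
                         keep_cache = FALSE) {
  d <- cfg$d_model
  TE0 <- timestep_embed(tvec, d)
  if (!is.matrix(TE0)) TE0 <- matrix(TE0, 1)
  zt <- linear_fwd(TE0, bp$tmlp$l1)
  ht <- gelu(zt)
  te <- linear_fwd(ht, bp$tmlp$l2)
  # token 1 fuses the noisy profile with the gene's latent token (the
  # diffused object and its conditioning summary share the residual
  # stream); token 2 exposes the latent token to attention separately
  hphi <- linear_fwd(Phi, bp$phi_proj)
  tokens <- list(linear_fwd(XT, bp$x_in) + hphi, hphi)
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    res <- block_fwd(bp$blocks[[l]], tokens, te, C, cfg$n_heads,
                     dropout = cfg$dropout, training = training,
                     keep_cache = keep_cache)
    tokens <- res$out
    caches[[l]] <- res$cache
  }
  modf <- linear_fwd(te, bp$final_ada)
  shf <- modf[, seq_len(d), drop = FALSE]
  scf <- modf[, d + seq_len(d), drop = FALSE]
  lnf <- layernorm_fwd(tokens[[1]])
  Y <- lnf$y * (1 + scf) + shf
  # preconditioned output: the transformer refines two analytic skip terms
  # (timestep-gated multiples of the noisy input and of the latent token's
  # linear profile readout), which span the optimal denoiser of a
  # conditionally Gaussian profile; both gates start at zero
  aux_out <- linear_fwd(Phi, bp$aux_dec)
  gate_a <- drop(linear_fwd(te, bp$skip_a))
  gate_b <- drop(linear_fwd(te, bp$skip_b))
  eps_pred <- linear_fwd(Y, bp$dec) + gate_a * XT + gate_b * aux_out
  logvar <- if (cfg$covariance_head) linear_fwd(Y, bp$dec_logvar) else NULL
  cache <- NULL
  if (keep_cache)
    cache <- list(XT = XT, Phi = Phi, TE0 = TE0, zt = zt, ht = ht, te = te,
                  caches = caches, lnf = lnf, scf = scf, Y = Y,
                  tokens = tokens, aux_out = aux_out, gate_a = gate_a,
                  gate_b = gate_b)
  list(eps_pred = eps_pred, logvar_pred = logvar, aux_out = aux_out,
       cache = cache)
}

# Full-network backward given d(loss)/d(eps_pred) (and optionally logvar
# gradient). Returns parameter gradients plus dC (condition tokens) and
# dPhi (latent tokens).
backbone_bwd <- function(bp, cfg, cache, deps, dlogvar = NULL) {
  d <- cfg$d_model
  g <- list()
  # skip-term gradients
  da <- rowSums(deps * cache$XT)
  db <- rowSums(deps * cache$aux_out)
  g$skip_a <- list(W = crossprod(cache$te, cbind(da)), b = sum(da))
  g$skip_b <- list(W = crossprod(cache$te, cbind(db)), b = sum(db))
  dte_skip <- cbind(da) %*% t(bp$skip_a$W) + cbind(db) %*% t(bp$skip_b$W)
  daux <- deps * cache$gate_b
  baux <- linear_bwd(daux, cache$Phi, bp$aux_dec)
  g$aux_dec <- list(W = baux$dW, b = baux$db)
  dPhi_skip <- baux$dx
  bdec <- linear_bwd(deps, cache$Y, bp$dec)
  g$dec <- list(W = bdec$dW, b = bdec$db)
  dY <- bdec$dx
  if (!is.null(dlogvar)) {
    bdl <- linear_bwd(dlogvar, cache$Y, bp$dec_logvar)
    g$dec_logvar <- list(W = bdl$dW, b = bdl$db)
    dY <- dY + bdl$dx
  } else if (cfg$covariance_head) {
    g$dec_logvar <- list(W = bp$dec_logvar$W * 0, b = bp$dec_logvar$b * 0)
  }
  dshf <- dY
  dscf <- dY * cache$lnf$y
  dxhat <- dY * (1 + cache$scf)
  dmodf <- cbind(dshf, dscf)
  g$final_ada <- list(W = crossprod(cache$te, dmodf), b = colSums(dmodf))
  dte <- dmodf %*% t(bp$final_ada$W) + dte_skip
  dT1 <- layernorm_bwd(dxhat, cache$lnf$y, cache$lnf$s)
  dtokens <- list(dT1, matrix(0, nrow(dT1), d))
  m <- if (is.null(cache$caches[[1]]$C)) 0L else nrow(cache$caches[[1]]$C)
  dC <- if (m > 0) matrix(0, m, d) else NULL
  g$blocks <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    bb <- block_bwd(bp$blocks[[l]], cache$caches[[l]], dtokens)
    dtokens <- bb$dtokens
    dte <- dte + bb$dte
    if (m > 0) dC <- dC + bb$dC
    g$blocks[[l]] <- bb$grads
  }
  bx <- linear_bwd(dtokens[[1]], cache$XT, bp$x_in)
  g$x_in <- list(W = bx$dW, b = bx$db)
  dhphi <- dtokens[[1]] + dtokens[[2]]  # latent projection feeds both tokens
  bphi <- linear_bwd(dhphi, cache$Phi, bp$phi_proj)
  g$phi_proj <- list(W = bphi$dW, b = bphi$db)
  dPhi <- bphi$dx + dPhi_skip
  bt2 <- linear_bwd(dte, cache$ht, bp$tmlp$l2)
  dzt <- bt2$dx * gelu_grad(cache$zt)
  bt1 <- linear_bwd(dzt, cache$TE0, bp$tmlp$l1)
  g$tmlp <- list(l1 = list(W = bt1$dW, b = bt1$db),
                 l2 = list(W = bt2$dW, b = bt2$db))
  # order must match init_backbone_params
  g <- g[names(bp)[names(bp) %in% names(g)]]
  list(grads = g, dC = dC, dPhi = dPhi)
}

#' Run the denoiser on a batch of noisy gene profiles
#'
#' Stacks the configured number of DiT blocks over the two-token sequence
#' (embedded noisy profile + latent token), applies the final adaptive layer
#' norm and the linear decoder, and returns the noise prediction rearranged
#' to the input layout (and the diagonal log-variance prediction when the
#' covariance head is enabled).
#'
#' @param x_t_tokens numeric matrix, genes x spots: noisy profiles at step
#'   `t`.
#' @param t integer step (scalar or one per row).
#' @param condition list with `phi` (genes x d_phi latent tokens) and
#'   optional `cond_tokens` (m x d_model condition key/value rows).
#' @param config a [backbone_config()].
#' @param params backbone parameters.
#' @return list with `eps_pred` (same shape as input) and `logvar_pred`
#'   (`NULL` unless the covariance head is on).
#' @export
denoise <- function(x_t_tokens, t, condition, config, params) {
  if (!is.matrix(x_t_tokens)) x_t_tokens <- matrix(x_t_tokens, 1)
  tvec <- if (length(t) == 1) rep(as.integer(t), nrow(x_t_tokens))
          else as.integer(t)
  out <- backbone_fwd(params, config, x_t_tokens, condition$phi, tvec,
                      condition$cond_tokens)
  list(eps_pred = out$eps_pred, logvar_pred = out$logvar_pred)
}

# --- backbone registry ------------------------------------------------------

.backbone_registry <- new.env(parent = emptyenv())

#' Register a denoiser backbone factory
#'
#' Extension hook: a factory is `function(params, config)` returning a
#' denoiser `function(x_t, t, condition)`. The `"transformer"` backbone is
#' registered at load time; `"unet"` and `"mamba"` are declared extension
#' points without implementations.
#'
#' @param kind backbone name.
#' @param factory factory function, or `NULL` to declare a hook only.
#' @export
register_backbone <- function(kind, factory) {
  assign(kind, factory, envir = .backbone_registry)
  invisible(kind)
}

#' Look up a denoiser backbone
#'
#' @param kind one of the registered backbones (`"transformer"` built in;
#'   `"unet"` and `"mamba"` raise a clear not-implemented error unless a
#'   user has registered a factory under that name with
#'   [register_backbone()]).
#' @return the factory function.
#' @export
backbone_variant <- function(kind) {
  if (exists(kind, envir = .backbone_registry, inherits = FALSE))
    return(get(kind, envir = .backbone_registry))
  if (kind %in% c("unet", "mamba"))
    stop("backbone '", kind, "' is a registered extension point without an ",
         "implementation; supply a factory via register_backbone()")
  stop("unknown backbone kind: ", kind)
}

transformer_factory <- function(params, config) {
  function(x_t, t, condition) {
    out <- denoise(x_t, t, condition, config, params)
    if (is.matrix(x_t)) out$eps_pred else drop(out$eps_pred)
  }
}
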
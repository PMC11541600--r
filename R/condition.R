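# Condition embedding: compresses the full scRNA-seq matrix (gene-major,
# genes x cells) into one token per gene via attention against a small set
# of learned landmark keys/values. The landmark maps Phi_K / Phi_V are
# learnable linear projections along the gene (token) axis, reducing the
# attention targets to `r` rows, so cost is linear in the gene count.

# Initialize condition-embedding parameters for `m` condition genes over
# `q` cells. For kind "pca" the projection is computed from the data and is
# not trained. Draws from the current RNG stream.
init_condition_params <- function(kind, m, q, d_k, d_cond, r_landmarks,
                                  x_sc = NULL) {
  switch(kind,
    attention = ,
    flash_attention = list(
      Wq = init_linear(q, d_k)$W,
      Wk = init_linear(q, d_k)$W,
      Wv = init_linear(q, d_cond)$W,
      Pk = matrix(stats::rnorm(r_landmarks * m, sd = 1 / sqrt(m)),
                  r_landmarks, m),
      Pv = matrix(stats::rnorm(r_landmarks * m, sd = 1 / sqrt(m)),
                  r_landmarks, m)),
    mlp = {
      h <- 2 * d_cond
      list(l1 = init_linear(q, h), l2 = init_linear(h, d_cond))
    },
    pca = {
      if (is.null(x_sc)) stop("pca condition init needs the SC matrix")
      ctr <- colMeans(x_sc)
      xc <- sweep(x_sc, 2, ctr)
      sv <- svd(xc, nu = 0, nv = min(d_cond, min(dim(xc)) - 1))
      rot <- sv$v
      if (ncol(rot) < d_cond)
        rot <- cbind(rot, matrix(0, q, d_cond - ncol(rot)))
      list(center = ctr, rotation = rot)
    },
    zeros = list(),
    stop("unknown condition kind: ", kind))
}

#' Condition embedding of an scRNA-seq matrix by landmark attention
#'
#' Computes `Q = X W^Q`, `K = X W^K`, `V = X W^V` from the gene-major SC
#' matrix `X` (genes x cells), reduces the token count of `K` and `V` to a
#' small set of landmark rows with the learnable linear maps `Phi_K`,
#' `Phi_V`, and returns
#' `X_psi = softmax(Q Phi_K(K)^T / sqrt(d_k)) Phi_V(V)`:
#' one `d_cond`-dimensional token per SC gene. Softmax rows sum to 1, so
#' every output token is a convex combination of the landmark value rows.
#'
#' @param sc_matrix gene-major numeric matrix (genes x cells), normalized.
#' @param params parameter list with `Wq`, `Wk`, `Wv`, `Pk`, `Pv` (see
#'   [condition_variant()] for construction via the trainer).
#' @param flash compute the softmax-weighted sum in landmark tiles with an
#'   online (streaming) softmax; numerically equal to the exact path.
#' @param tile tile width for the flash path.
#' @return a `condition_embedding` list: `x_psi` (genes x d_cond), `d_k`,
#'   and (exact path only) the attention matrix `attn`.
#' @export
embed_condition <- function(sc_matrix, params, flash = FALSE, tile = 16L) {
  if (any(!is.finite(sc_matrix))) stop("non-finite values in SC matrix")
  X <- sc_matrix
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  Kr <- params$Pk %*% K
  Vr <- params$Pv %*% V
  d_k <- ncol(Q)
  S <- (Q %*% t(Kr)) / sqrt(d_k)
  if (!flash) {
    A <- softmax_rows(S)
    x_psi <- A %*% Vr
    structure(list(x_psi = x_psi, d_k = d_k, attn = A,
                   cache = list(X = X, Q = Q, K = K, V = V, Kr = Kr,
                                Vr = Vr, A = A)),
              class = "condition_embedding")
  } else {
    x_psi <- flash_softmax_matmul(S, Vr, tile)
    structure(list(x_psi = x_psi, d_k = d_k),
              class = "condition_embedding")
  }
}

# Streaming softmax(S) %*% Vr over column tiles of S: keeps a running row
# maximum and normalizer so no full attention matrix is materialized.
flash_softmax_matmul <- function(S, Vr, tile = 16L) {
  n <- nrow(S)
  r <- ncol(S)
  acc <- matrix(0, n, ncol(Vr))
  mx <- rep(-Inf, n)
  den <- rep(0, n)
  for (start in seq(1L, r, by = tile)) {
    idx <- start:min(start + tile - 1L, r)
    Sb <- S[, idx, drop = FALSE]
    mx_new <- pmax(mx, apply(Sb, 1, max))
    scale <- exp(mx - mx_new)
    Eb <- exp(Sb - mx_new)
    acc <- acc * scale + Eb %*% Vr[idx, , drop = FALSE]
    den <- den * scale + rowSums(Eb)
    mx <- mx_new
  }
  acc / den
}

# Backward of the exact landmark-attention embedding. Returns gradients for
# all trainable parameters given d(loss)/d(x_psi).
cond_attention_bwd <- function(dXpsi, emb, params) {
  cc <- emb$cache
  d_k <- emb$d_k
  dA <- dXpsi %*% t(cc$Vr)
  dVr <- crossprod(cc$A, dXpsi)
  dS <- softmax_rows_bwd(dA, cc$A)
  dQ <- dS %*% cc$Kr / sqrt(d_k)
  dKr <- crossprod(dS, cc$Q) / sqrt(d_k)
  dK <- crossprod(params$Pk, dKr)
  dV <- crossprod(params$Pv, dVr)
  list(Wq = crossprod(cc$X, dQ),
       Wk = crossprod(cc$X, dK),
       Wv = crossprod(cc$X, dV),
       Pk = dKr %*% t(cc$K),
       Pv = dVr %*% t(cc$V))
}

# Forward + cache for the MLP condition variant.
cond_mlp_fwd <- function(sc_matrix, params) {
  z1 <- linear_fwd(sc_matrix, params$l1)
  h1 <- gelu(z1)
  x_psi <- linear_fwd(h1, params$l2)
  structure(list(x_psi = x_psi, d_k = ncol(x_psi),
                 cache = list(X = sc_matrix, z1 = z1, h1 = h1)),
            class = "condition_embedding")
}

cond_mlp_bwd <- function(dXpsi, emb, params) {
  cc <- emb$cache
  b2 <- linear_bwd(dXpsi, cc$h1, params$l2)
  dz1 <- b2$dx * gelu_grad(cc$z1)
  b1 <- linear_bwd(dz1, cc$X, params$l1)
  list(l1 = list(W = b1$dW, b = b1$db), l2 = list(W = b2$dW, b = b2$db))
}

#' Condition embedding variants
#'
#' Dispatches over the condition-embedding ablations: `attention` (exact
#' landmark attention), `flash_attention` (same computation, memory-tiled,
#' numerically equal), `mlp` (two-layer feed-forward reduction), `pca`
#' (fixed top principal-component scores) and `zeros` (all-zero embedding of
#' the right shape, the "no condition" ablation).
#'
#' @param kind one of `"mlp"`, `"pca"`, `"attention"`, `"flash_attention"`,
#'   `"zeros"`.
#' @param sc_matrix gene-major numeric matrix (genes x cells).
#' @param params parameters from `init_condition_params()` (managed by the
#'   trainer); ignored for `"zeros"`.
#' @param d_cond output dimension for the `"zeros"` kind.
#' @return a `condition_embedding` with field `x_psi` (genes x d_cond).
#' @export
condition_variant <- function(kind, sc_matrix, params = NULL, d_cond = 128L) {
  switch(kind,
    attention = embed_condition(sc_matrix, params, flash = FALSE),
    flash_attention = embed_condition(sc_matrix, params, flash = TRUE),
    mlp = cond_mlp_fwd(sc_matrix, params),
    pca = {
      sco <- sweep(sc_matrix, 2, params$center) %*% params$rotation
      structure(list(x_psi = sco, d_k = ncol(sco)),
                class = "condition_embedding")
    },
    zeros = structure(list(x_psi = matrix(0, nrow(sc_matrix), d_cond),
                           d_k = d_cond),
                      class = "condition_embedding"),
    stop("unknown condition kind: ", kind))
}
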
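# Latent embedding: per-gene tokens. Each modality has its own
# single-hidden-layer feed-forward projection into d_model; the latent token
# is the concatenation x_phi = x_st_hat (+) x_sc_hat. During training the ST
# input is the gene's spatial profile with the prediction-target entries
# zeroed, so the token only ever sees the observed part.

init_latent_params <- function(p, q, d_model, hidden = 2L * d_model) {
  list(st = list(l1 = init_linear(p, hidden), l2 = init_linear(hidden, d_model)),
       sc = list(l1 = init_linear(q, hidden), l2 = init_linear(hidden, d_model)))
}

# Batched forward: Sst (B x p), Ssc (B x q) -> list(phi (B x 2d or B x d),
# caches). With concat = FALSE only the ST projection is used (the
# "no concat" ablation).
latent_fwd <- function(params, Sst, Ssc, concat = TRUE) {
  z1s <- linear_fwd(Sst, params$st$l1)
  h1s <- gelu(z1s)
  hst <- linear_fwd(h1s, params$st$l2)
  if (concat) {
    z1c <- linear_fwd(Ssc, params$sc$l1)
    h1c <- gelu(z1c)
    hsc <- linear_fwd(h1c, params$sc$l2)
    phi <- cbind(hst, hsc)
  } else {
    z1c <- h1c <- hsc <- NULL
    phi <- hst
  }
  list(phi = phi, hst = hst, hsc = hsc,
       cache = list(Sst = Sst, Ssc = Ssc, z1s = z1s, h1s = h1s,
                    z1c = z1c, h1c = h1c))
}

latent_bwd <- function(dphi, fwd, params, concat = TRUE) {
  d <- ncol(fwd$hst)
  cc <- fwd$cache
  dhst <- dphi[, seq_len(d), drop = FALSE]
  g <- list()
  b2 <- linear_bwd(dhst, cc$h1s, params$st$l2)
  dz1 <- b2$dx * gelu_grad(cc$z1s)
  b1 <- linear_bwd(dz1, cc$Sst, params$st$l1)
  g$st <- list(l1 = list(W = b1$dW, b = b1$db), l2 = list(W = b2$dW, b = b2$db))
  if (concat) {
    dhsc <- dphi[, d + seq_len(d), drop = FALSE]
    c2 <- linear_bwd(dhsc, cc$h1c, params$sc$l2)
    dz1c <- c2$dx * gelu_grad(cc$z1c)
    c1 <- linear_bwd(dz1c, cc$Ssc, params$sc$l1)
    g$sc <- list(l1 = list(W = c1$dW, b = c1$db),
                 l2 = list(W = c2$dW, b = c2$db))
  } else {
    g$sc <- tree_zeros(params$sc)
  }
  g
}

#' Latent token for one gene
#'
#' Projects a gene's spatial profile (over spots) and its single-cell
#' profile (over cells) through two modality-specific single-hidden-layer
#' feed-forward networks into `d_model` each, and concatenates them into the
#' latent token `x_phi = x_st_hat (+) x_sc_hat`. Deterministic given the
#' parameters.
#'
#' @param st_gene_vector numeric vector over spots (normalized scale;
#'   unobserved entries zeroed).
#' @param sc_gene_vector numeric vector over cells (normalized scale).
#' @param params latent parameters (`init` via the trainer; fields `st`,
#'   `sc`, each with `l1`, `l2`).
#' @param concat concatenate the SC projection (default `TRUE`); `FALSE`
#'   gives the "no concat" ablation token (`x_st_hat` only).
#' @return a `latent_token` list: `x_phi`, `x_st_hat`, `x_sc_hat`.
#' @export
embed_latent <- function(st_gene_vector, sc_gene_vector, params,
                         concat = TRUE) {
  if (length(st_gene_vector) != nrow(params$st$l1$W))
    stop("ST vector length does not match the fitted projection")
  if (concat && length(sc_gene_vector) != nrow(params$sc$l1$W))
    stop("SC vector length does not match the fitted projection")
  fwd <- latent_fwd(params, matrix(st_gene_vector, 1),
                    matrix(sc_gene_vector, 1), concat = concat)
  structure(list(x_phi = drop(fwd$phi), x_st_hat = drop(fwd$hst),
                 x_sc_hat = if (concat) drop(fwd$hsc) else NULL),
            class = "latent_token")
}
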
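# Neural-network primitives: initializers, activations, row-wise layer norm
# and softmax with their exact backward passes, and an AdamW optimizer over
# nested parameter lists. All tensors are plain base-R matrices; gradients
# are hand-derived and checked against finite differences in the test suite.

# Xavier/Glorot normal initializer (draws from the current RNG stream).
init_linear <- function(n_in, n_out, zero = FALSE) {
  if (zero) {
    list(W = matrix(0, n_in, n_out), b = numeric(n_out))
  } else {
    sd <- sqrt(2 / (n_in + n_out))
    list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
         b = numeric(n_out))
  }
}

linear_fwd <- function(x, p) sweep(x %*% p$W, 2, p$b, "+")

# Backward of y = x W + b. Returns dx and accumulates into `grad`.
linear_bwd <- function(dy, x, p) {
  list(dx = dy %*% t(p$W), dW = crossprod(x, dy), db = colSums(dy))
}

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Row-wise layer norm without learned affine (eps inside the sqrt).
layernorm_fwd <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + eps)
  xhat <- xc / s
  list(y = xhat, s = s)
}

# dx for y = (x - mean) / sqrt(var + eps), given xhat and s from forward.
layernorm_bwd <- function(dy, xhat, s) {
  (dy - rowMeans(dy) - xhat * rowMeans(dy * xhat)) / s
}

softmax_rows <- function(s) {
  mx <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - mx)
  e / rowSums(e)
}

# dS for A = softmax_rows(S).
softmax_rows_bwd <- function(dA, A) A * (dA - rowSums(dA * A))

# --- nested parameter-tree helpers -----------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

# Flatten a parameter tree to one numeric vector (and back); used by the
# finite-difference gradient checks.
tree_flatten <- function(tree) {
  if (is.list(tree)) unlist(lapply(tree, tree_flatten), use.names = FALSE)
  else as.numeric(tree)
}

tree_unflatten <- function(tree, v) {
  i <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- x
    out[] <- v[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  rebuild(tree)
}

# --- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  n <- length(tree_flatten(params))
  list(m = numeric(n), v = numeric(n), step = 0L)
}

# Decoupled weight decay; lr supplied per call (cosine decay in the
# trainer). Moments are kept as flat vectors so the update is one
# vectorized pass over all parameters.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  g <- tree_flatten(grads)
  p <- tree_flatten(params)
  state$step <- state$step + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  p <- p - lr * (state$m / bc1) / (sqrt(state$v / bc2) + eps)
  if (weight_decay > 0) p <- p * (1 - lr * weight_decay)
  list(params = tree_unflatten(params, p), state = state)
}

#' Sinusoidal timestep embedding
#'
#' Interleaved sine/cosine features of the diffusion step:
#' `[sin(t w_1), cos(t w_1), sin(t w_2), cos(t w_2), ...]` with
#' geometrically spaced frequencies `w_k = 10000^(-(k-1)/(dim/2))`.
#' Deterministic; distinct steps map to distinct vectors.
#'
#' @param t integer step (scalar or vector), `t >= 0`.
#' @param dim embedding dimension (even).
#' @return numeric vector of length `dim`, or a `length(t) x dim` matrix.
#' @export
timestep_embed <- function(t, dim) {
  if (dim %% 2 != 0) stop("dim must be even")
  if (any(t < 0)) stop("t must be >= 0")
  half <- dim / 2
  w <- 10000^(-(seq_len(half) - 1) / half)
  out <- matrix(0, length(t), dim)
  arg <- outer(t, w)
  out[, seq(1, dim, by = 2)] <- sin(arg)
  out[, seq(2, dim, by = 2)] <- cos(arg)
  if (length(t) == 1) drop(out) else out
}
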
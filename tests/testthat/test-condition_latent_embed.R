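test_that("latent tokens concatenate the two modality projections", {
  set.seed(1)
  p <- 6L; q <- 9L; d <- 4L
  lp <- stgendiff:::init_latent_params(p, q, d)
  st <- rnorm(p); sc <- rnorm(q)
  tok <- embed_latent(st, sc, lp)
  expect_length(tok$x_phi, 2 * d)
  expect_equal(tok$x_phi, c(tok$x_st_hat, tok$x_sc_hat))
  # replay determinism
  tok2 <- embed_latent(st, sc, lp)
  expect_identical(tok$x_phi, tok2$x_phi)
  # zero inputs with zero biases give a zero token (gelu(0) = 0)
  lp0 <- stgendiff:::tree_map(function(x) x * 0, lp)
  lp0$st$l1$W <- lp$st$l1$W; lp0$st$l2$W <- lp$st$l2$W
  lp0$sc$l1$W <- lp$sc$l1$W; lp0$sc$l2$W <- lp$sc$l2$W
  tok0 <- embed_latent(rep(0, p), rep(0, q), lp0)
  expect_equal(tok0$x_phi, rep(0, 2 * d))
  # no-concat ablation keeps only the spatial projection
  tokn <- embed_latent(st, sc, lp, concat = FALSE)
  expect_length(tokn$x_phi, d)
  expect_error(embed_latent(rnorm(p + 1), sc, lp), "does not match")
})

test_that("condition embedding softmax is a proper convex combination", {
  set.seed(2)
  m <- 12L; q <- 8L
  X <- matrix(rnorm(m * q), m, q)
  prm <- stgendiff:::init_condition_params("attention", m, q, d_k = 5L,
                                           d_cond = 4L, r_landmarks = 3L)
  emb <- embed_condition(X, prm)
  expect_equal(rowSums(emb$attn), rep(1, m), tolerance = 1e-6)
  # convexity: every output coordinate lies within the landmark value range
  Vr <- prm$Pv %*% (X %*% prm$Wv)
  for (j in seq_len(ncol(emb$x_psi))) {
    expect_true(all(emb$x_psi[, j] >= min(Vr[, j]) - 1e-9))
    expect_true(all(emb$x_psi[, j] <= max(Vr[, j]) + 1e-9))
  }
  expect_error(embed_condition(X * NA, prm), "non-finite")
})

test_that("a single landmark row degenerates softmax to the identity weight", {
  set.seed(3)
  m <- 5L; q <- 4L
  X <- matrix(rnorm(m * q), m, q)
  prm <- stgendiff:::init_condition_params("attention", m, q, d_k = 3L,
                                           d_cond = 4L, r_landmarks = 1L)
  emb <- embed_condition(X, prm)
  Vr <- prm$Pv %*% (X %*% prm$Wv)
  expect_equal(emb$attn, matrix(1, m, 1), ignore_attr = TRUE)
  for (i in seq_len(m))
    expect_equal(emb$x_psi[i, ], drop(Vr), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("a 2-token toy with hand-set weights matches hand evaluation", {
  # 2 genes x 1 cell, 1-dim queries/keys/values, 2 landmark rows
  X <- matrix(c(1, 2), 2, 1)
  prm <- list(Wq = matrix(1), Wk = matrix(1), Wv = matrix(1),
              Pk = matrix(c(1, 0, 0, 1), 2, 2),
              Pv = matrix(c(1, 0, 0, 1), 2, 2))
  emb <- embed_condition(X, prm)
  # Q = (1,2); Kr = (1,2); Vr = (1,2); scores S = Q Kr^T / 1
  S <- matrix(c(1, 2, 2, 4), 2, 2, byrow = TRUE)
  A <- exp(S) / rowSums(exp(S))
  hand <- A %*% matrix(c(1, 2), 2, 1)
  expect_equal(emb$x_psi, hand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("flash attention equals exact attention", {
  set.seed(4)
  for (i in 1:20) {
    m <- sample(3:20, 1); q <- sample(2:10, 1); r <- sample(1:8, 1)
    X <- matrix(rnorm(m * q, sd = 2), m, q)
    prm <- stgendiff:::init_condition_params("attention", m, q,
                                             d_k = sample(2:6, 1),
                                             d_cond = 3L, r_landmarks = r)
    exact <- embed_condition(X, prm, flash = FALSE)$x_psi
    flash <- embed_condition(X, prm, flash = TRUE, tile = sample(1:4, 1))$x_psi
    expect_lt(max(abs(exact - flash)), 1e-10)
  }
})

test_that("condition variants cover the ablation kinds", {
  set.seed(5)
  m <- 10L; q <- 6L
  X <- matrix(rnorm(m * q), m, q)
  z <- condition_variant("zeros", X, d_cond = 7L)
  expect_equal(z$x_psi, matrix(0, m, 7))
  mp <- stgendiff:::init_condition_params("mlp", m, q, d_k = 4L, d_cond = 4L,
                                          r_landmarks = 2L)
  emb_mlp <- condition_variant("mlp", X, mp)
  expect_identical(dim(emb_mlp$x_psi), c(m, 4L))
  # pca on a rank-1 matrix reconstructs the score direction up to sign
  u <- rnorm(m); v <- rnorm(q)
  X1 <- u %o% v
  pp <- stgendiff:::init_condition_params("pca", m, q, d_k = 1L, d_cond = 1L,
                                          r_landmarks = 2L, x_sc = X1)
  sco <- condition_variant("pca", X1, pp)$x_psi[, 1]
  uc <- u - mean(u)
  expect_gt(abs(cor(sco, uc)), 1 - 1e-8)
  expect_error(condition_variant("fft", X), "unknown condition")
})
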
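test_that("timestep embedding is sinusoidal, deterministic and injective", {
  e0 <- timestep_embed(0, 8)
  expect_equal(e0, rep(c(0, 1), 4))
  expect_identical(timestep_embed(17, 16), timestep_embed(17, 16))
  # exhaustive distinctness over a T = 50 chain
  E <- timestep_embed(1:50, 16)
  expect_equal(nrow(unique(round(E, 10))), 50)
  expect_error(timestep_embed(1, 7), "even")
  expect_error(timestep_embed(-1, 8), "t must")
})

test_that("a freshly initialized block is exactly the identity", {
  set.seed(5)
  d <- 16L
  blk <- stgendiff:::init_block_params(d)
  tokens <- matrix(rnorm(3 * d), 3, d)
  cond <- matrix(rnorm(4 * d), 4, d)
  te <- rnorm(d)
  out <- dit_block(tokens, cond, te, blk, n_heads = 4L)
  expect_identical(out, tokens)   # bit-exact: gates start at zero
  out0 <- dit_block(tokens, NULL, te, blk, n_heads = 4L)
  expect_identical(out0, tokens)
})

test_that("attention over condition tokens is permutation-invariant", {
  set.seed(6)
  d <- 16L
  blk <- stgendiff:::init_block_params(d)
  # randomize parameters so attention actually mixes
  v <- stgendiff:::tree_flatten(blk)
  blk <- stgendiff:::tree_unflatten(blk, v + rnorm(length(v), sd = 0.1))
  tokens <- matrix(rnorm(2 * d), 2, d)
  cond <- matrix(rnorm(5 * d), 5, d)
  te <- rnorm(d)
  out1 <- dit_block(tokens, cond, te, blk, n_heads = 4L)
  out2 <- dit_block(tokens, cond[c(3, 1, 5, 2, 4), ], te, blk, n_heads = 4L)
  expect_equal(out1, out2, tolerance = 1e-12)
  # condition changes the output when gates are non-zero
  out3 <- dit_block(tokens, cond * 2, te, blk, n_heads = 4L)
  expect_gt(max(abs(out1 - out3)), 1e-8)
})

test_that("denoise respects the initialization contract and shapes", {
  set.seed(7)
  cfg <- backbone_config(n_layers = 2L, n_heads = 2L, d_model = 12L,
                         d_cond = 6L)
  p <- 9L; d_phi <- 24L
  bp <- stgendiff:::init_backbone_params(p, d_phi, cfg)
  xt <- matrix(rnorm(4 * p), 4, p)
  cond <- list(phi = matrix(rnorm(4 * d_phi), 4, d_phi),
               cond_tokens = matrix(rnorm(5 * 12), 5, 12))
  out <- denoise(xt, 3L, cond, cfg, bp)
  # zero-initialized decoder and skip gates -> zero noise prediction
  expect_equal(out$eps_pred, matrix(0, 4, p), ignore_attr = TRUE)
  expect_identical(dim(out$eps_pred), dim(xt))
  expect_null(out$logvar_pred)
  # batch of identical rows gives identical outputs (no cross-sample mixing)
  v <- stgendiff:::tree_flatten(bp)
  bp2 <- stgendiff:::tree_unflatten(bp, v + rnorm(length(v), sd = 0.05))
  xt2 <- matrix(rep(rnorm(p), each = 3), 3, p, byrow = FALSE)
  xt2 <- matrix(rep(xt[1, ], 3), 3, p, byrow = TRUE)
  cond2 <- list(phi = matrix(rep(cond$phi[1, ], 3), 3, d_phi, byrow = TRUE),
                cond_tokens = cond$cond_tokens)
  o2 <- denoise(xt2, 3L, cond2, cfg, bp2)
  expect_equal(o2$eps_pred[1, ], o2$eps_pred[2, ], tolerance = 1e-12)
  expect_equal(o2$eps_pred[1, ], o2$eps_pred[3, ], tolerance = 1e-12)
  # covariance head produces a matching log-variance block
  cfg3 <- backbone_config(n_layers = 1L, n_heads = 2L, d_model = 12L,
                          d_cond = 6L, covariance_head = TRUE)
  bp3 <- stgendiff:::init_backbone_params(p, d_phi, cfg3)
  o3 <- denoise(xt, 2L, cond, cfg3, bp3)
  expect_identical(dim(o3$logvar_pred), dim(xt))
})

test_that("model gradients agree with finite differences", {
  ms <- micro_setup(seed = 42)
  batch <- list(idx = 1:3, tvec = c(1L, 5L, 10L),
                eps = matrix(rnorm(15), 3, 5),
                target = matrix(runif(15) < 0.6, 3, 5), sched = ms$sched)
  res <- stgendiff:::model_loss_grad(ms$mdl$params, ms$cfg, ms$mdl$fixed,
                                     ms$mdl$bcfg, ms$data, batch)
  g_an <- stgendiff:::tree_flatten(res$grads)
  v0 <- stgendiff:::tree_flatten(ms$mdl$params)
  f <- function(v)
    stgendiff:::model_loss_grad(stgendiff:::tree_unflatten(ms$mdl$params, v),
                                ms$cfg, ms$mdl$fixed, ms$mdl$bcfg, ms$data,
                                batch, grads = FALSE)$loss
  idx <- sort(sample(length(v0), 60))
  h <- 1e-5
  g_fd <- vapply(idx, function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (f(vp) - f(vm)) / (2 * h)
  }, numeric(1))
  rel <- abs(g_fd - g_an[idx]) / pmax(1e-6, abs(g_fd) + abs(g_an[idx]))
  expect_lt(max(rel), 1e-4)
  # gradient is finite and non-trivial on random init
  expect_true(all(is.finite(g_an)))
  expect_gt(mean(abs(g_an)), 0)
})

test_that("backbone registry exposes the transformer and extension hooks", {
  f <- backbone_variant("transformer")
  ms <- micro_setup(seed = 9)
  den <- f(ms$mdl$params$backbone, ms$mdl$bcfg)
  lat <- stgendiff:::latent_fwd(ms$mdl$params$latent, ms$data$Xst_std[1:2, ],
                                ms$data$Ssc_lat[1:2, ])
  cnd <- stgendiff:::cond_tokens_fwd(ms$mdl$params, ms$cfg, ms$mdl$fixed,
                                     ms$data$x_sc_cond)
  out <- den(ms$data$Xst_std[1:2, ], 3L,
             list(phi = lat$phi, cond_tokens = cnd$C))
  expect_identical(dim(out), c(2L, ms$p))
  expect_error(backbone_variant("unet"), "extension point")
  expect_error(backbone_variant("mamba"), "extension point")
  expect_error(backbone_variant("perceptron"), "unknown backbone")
  # user-registered factories are routed
  register_backbone("echo", function(params, config)
    function(x_t, t, condition) x_t * 0 + 42)
  echo <- backbone_variant("echo")(NULL, NULL)
  expect_equal(echo(matrix(0, 2, 3), 1, NULL), matrix(42, 2, 3))
})
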
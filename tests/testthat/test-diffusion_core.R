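test_that("noise schedules satisfy their closed-form invariants", {
  s1 <- make_schedule(1, 0.1, 0.1)
  expect_equal(s1$alpha_bar, 1 - 0.1)
  expect_equal(s1$sigma2, 0.1)
  # constant betas give the closed form alpha_bar = (1 - b)^t
  sc <- make_schedule(20, 0.05, 0.05)
  expect_equal(sc$alpha_bar, (1 - 0.05)^(1:20), tolerance = 1e-12)
  # canonical linear schedule: direct cumulative-product oracle
  sl <- make_schedule(1000, 1e-4, 2e-2)
  beta_hand <- seq(1e-4, 2e-2, length.out = 1000)
  expect_equal(sl$alpha_bar, cumprod(1 - beta_hand), tolerance = 1e-12)
  expect_lt(sl$alpha_bar[1000], 1e-4)
  for (k in c("linear", "cosine")) {
    s <- make_schedule(50, kind = k)
    expect_true(all(s$beta > 0 & s$beta < 1))
    expect_true(all(diff(s$alpha_bar) < 0))
    bt <- (1 - c(1, s$alpha_bar[-50])) / (1 - s$alpha_bar) * s$beta
    bt[1] <- s$beta[1]
    expect_equal(s$sigma2, bt, tolerance = 1e-12)
  }
  expect_error(make_schedule(10, 0.5, 0.1), "beta")
  expect_error(make_schedule(10, 0, 0.1), "beta")
})

test_that("forward diffusion matches its Gaussian marginal", {
  sched <- make_schedule(50, kind = "cosine")
  x0 <- rnorm(10)
  # alpha_bar -> 1 limit: x_t ~ x0; alpha_bar -> 0 limit: x_t ~ eps
  eps <- rnorm(10)
  x1 <- forward_diffuse(x0, 1, eps, sched)
  expect_equal(x1, sqrt(sched$alpha_bar[1]) * x0 +
                 sqrt(1 - sched$alpha_bar[1]) * eps, tolerance = 1e-12)
  expect_lt(max(abs(x1 - x0)), 0.35)
  xT <- forward_diffuse(x0, 50, eps, sched)
  expect_lt(max(abs(xT - eps)), 0.1)
  # Monte-Carlo variance at x0 = 0: Var(x_t) = 1 - alpha_bar within 3 SE
  set.seed(11)
  t_mid <- 25L
  n <- 1e5
  draws <- forward_diffuse(rep(0, n), t_mid, rnorm(n), sched)
  v_target <- 1 - sched$alpha_bar[t_mid]
  se <- v_target * sqrt(2 / (n - 1))
  expect_lt(abs(var(draws) - v_target), 3 * se)
  expect_error(forward_diffuse(x0, 51, eps, sched), "out of range")
})

test_that("make_masks samples the strata with floor rounding, deterministically", {
  x0 <- c(rep(0, 10), rnorm(10))
  mk <- make_masks(x0, rho_zero = 0.5, rho_nonzero = 1, seed = 4)
  expect_equal(sum(mk$m1), 5)                 # floor(0.5 * 10)
  expect_true(all(x0[mk$m1] == 0))
  expect_true(all(mk$m2 == (x0 != 0)))        # rho 1 covers the stratum
  expect_true(!any(mk$m1 & mk$m2))
  expect_identical(mk$observed, !(mk$m1 | mk$m2))
  expect_identical(make_masks(x0, 0.5, 1, seed = 4), mk)
  # no zeros -> empty m1 regardless of rho_zero
  mk2 <- make_masks(abs(rnorm(8)) + 1, rho_zero = 1, rho_nonzero = 0.5,
                    seed = 1)
  expect_equal(sum(mk2$m1), 0)
  expect_error(make_masks(x0, -0.1, 0.5), "fractions")
})

test_that("training_loss targets only the masked entries", {
  sched <- make_schedule(10)
  x0 <- c(0, 0, 1.5, -2, 0.5)
  masks <- make_masks(x0, 1, 1, seed = 1)
  eps <- rnorm(5)
  oracle <- function(xt, t, cond) eps        # perfect denoiser
  expect_equal(training_loss(oracle, x0, NULL, masks, 3, eps, sched), 0)
  zero_model <- function(xt, t, cond) rep(0, length(xt))
  # eps_hat = 0: chi-square expectation, loss = mean(eps^2) over targets
  expect_equal(training_loss(zero_model, x0, NULL, masks, 3, eps, sched),
               mean(eps^2), tolerance = 1e-12)
  # and over many draws the expected loss is 1 (unit-variance noise)
  set.seed(2)
  losses <- replicate(400, {
    e <- rnorm(5)
    training_loss(zero_model, x0, NULL, masks, 3, e, sched)
  })
  expect_lt(abs(mean(losses) - 1), 3 * sd(losses) / sqrt(length(losses)))
  # loss ignores unmasked entries
  m2 <- make_masks(x0, 0, 1, seed = 1)  # only non-zero entries masked
  capture <- function(x0v) training_loss(zero_model, x0v, NULL, m2, 3, eps,
                                         sched)
  x0b <- x0
  x0b[m2$observed] <- x0b[m2$observed] * 2
  expect_equal(capture(x0), capture(x0b), tolerance = 1e-12)
  empty <- make_masks(x0, 0, 0, seed = 1)
  expect_warning(l0 <- training_loss(zero_model, x0, NULL, empty, 3, eps,
                                     sched), "empty")
  expect_equal(l0, 0)
})

test_that("reverse_step inverts a one-step chain with a perfect denoiser", {
  sched <- make_schedule(1, 0.2, 0.2)
  x0 <- rnorm(6)
  eps <- rnorm(6)
  x1 <- forward_diffuse(x0, 1, eps, sched)
  oracle <- function(xt, t, cond) eps
  out <- reverse_step(oracle, list(x = x1, t = 1L, condition = NULL), sched)
  expect_equal(out$x, x0, tolerance = 1e-6)
  expect_equal(out$t, 0L)
  # eps_hat = 0 at x_t = 0 gives mu = 0
  zero_model <- function(xt, t, cond) rep(0, length(xt))
  out0 <- reverse_step(zero_model, list(x = rep(0, 4), t = 1L,
                                        condition = NULL), sched)
  expect_equal(out0$x, rep(0, 4))
  expect_error(reverse_step(zero_model, list(x = x0, t = 0L,
                                             condition = NULL), sched),
               "t >= 1")
})

test_that("a deterministic chain (supplied z) is reproducible", {
  sched <- make_schedule(5, kind = "cosine")
  model <- function(xt, t, cond) 0.5 * xt
  run <- function() {
    st <- list(x = c(1, -1), t = 5L, condition = NULL)
    while (st$t >= 1) st <- reverse_step(model, st, sched,
                                         z = rep(0, 2))
    st$x
  }
  expect_identical(run(), run())
})

test_that("oracle reverse sampling reproduces a Gaussian x0 distribution", {
  # x0 ~ N(m0, s0^2); the exact conditional denoiser is linear in x_t
  sched <- make_schedule(50, kind = "cosine")
  m0 <- 0.7; s0 <- 0.5
  oracle <- function(xt, t, cond) {
    ab <- sched$alpha_bar[t]
    post_x0 <- m0 + (sqrt(ab) * s0^2 / (ab * s0^2 + 1 - ab)) *
      (xt - sqrt(ab) * m0)
    (xt - sqrt(ab) * post_x0) / sqrt(1 - ab)
  }
  set.seed(21)
  n <- 3000
  st <- list(x = rnorm(n), t = 50L, condition = NULL)
  while (st$t >= 1) st <- reverse_step(oracle, st, sched)
  expect_lt(abs(mean(st$x) - m0), 3 * sd(st$x) / sqrt(n))
  expect_lt(abs(sd(st$x) - s0), 0.05)
})

test_that("conditional sampling clamps observed entries and is deterministic", {
  sched <- make_schedule(10, kind = "cosine")
  model <- function(xt, t, cond) rep(0, length(xt))
  obs <- c(1, 2, 3, 4)
  # all entries observed -> replacement dominates
  out <- conditional_sample(model, NULL, obs, rep(TRUE, 4), sched,
                            n_samples = 1, seed = 3)
  expect_identical(out, obs)
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  a <- conditional_sample(model, NULL, obs, mask, sched, n_samples = 2,
                          seed = 9)
  b <- conditional_sample(model, NULL, obs, mask, sched, n_samples = 2,
                          seed = 9)
  expect_identical(a, b)
  expect_identical(a[mask], obs[mask])
  expect_false(any(a[!mask] == obs[!mask]))
})
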
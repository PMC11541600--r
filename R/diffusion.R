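#' Build a DDPM noise schedule
#'
#' Returns the per-step noise levels of a denoising diffusion probabilistic
#' model: `beta[t]`, `alpha_hat[t] = 1 - beta[t]`, the cumulative product
#' `alpha_bar[t]` and the reverse-process variances
#' `sigma2[t] = (1 - alpha_bar[t-1]) / (1 - alpha_bar[t]) * beta[t]`
#' (with `sigma2[1] = beta[1]`). The linear schedule interpolates
#' `beta_start .. beta_end`; the cosine schedule follows the squared-cosine
#' `alpha_bar` curve (offset 0.008, betas clipped at 0.999).
#'
#' @param T_steps number of diffusion steps (`T`).
#' @param beta_start,beta_end linear schedule endpoints,
#'   `0 < beta_start <= beta_end < 1`. Defaults 1e-4 and 2e-2.
#' @param kind `"linear"` or `"cosine"`.
#' @return a `noise_schedule` list.
#' @export
make_schedule <- function(T_steps, beta_start = 1e-4, beta_end = 2e-2,
                          kind = c("linear", "cosine")) {
  kind <- match.arg(kind)
  T_steps <- as.integer(T_steps)
  if (T_steps < 1) stop("T_steps must be >= 1")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("need 0 < beta_start <= beta_end < 1")
  if (kind == "linear") {
    beta <- if (T_steps == 1) beta_start
            else seq(beta_start, beta_end, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(u) cos((u / T_steps + s) / (1 + s) * pi / 2)^2
    abar <- f(0:T_steps) / f(0)
    beta <- pmin(1 - abar[-1] / abar[-(T_steps + 1)], 0.999)
  }
  alpha_hat <- 1 - beta
  alpha_bar <- cumprod(alpha_hat)
  abar_prev <- c(1, alpha_bar[-T_steps])
  sigma2 <- (1 - abar_prev) / (1 - alpha_bar) * beta
  sigma2[1] <- beta[1]
  structure(list(T_steps = T_steps, beta = beta, alpha_hat = alpha_hat,
                 alpha_bar = alpha_bar, sigma2 = sigma2, kind = kind),
            class = "noise_schedule")
}

#' Forward diffusion (closed form)
#'
#' Samples `x_t` from `q(x_t | x_0) = N(sqrt(alpha_bar_t) x_0,
#' (1 - alpha_bar_t) I)` via
#' `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps`.
#'
#' @param x0 numeric vector or matrix (rows = independent samples).
#' @param t integer step in `1..T`, or a vector of steps (one per row of a
#'   matrix `x0`).
#' @param eps standard-normal noise, same shape as `x0`.
#' @param sched a [make_schedule()] schedule.
#' @return noisy `x_t`, same shape as `x0`.
#' @export
forward_diffuse <- function(x0, t, eps, sched) {
  stopifnot(inherits(sched, "noise_schedule"))
  if (any(t < 1) || any(t > sched$T_steps)) stop("t out of range 1..T")
  ab <- sched$alpha_bar[t]
  if (is.matrix(x0)) {
    if (length(ab) == 1) ab <- rep(ab, nrow(x0))
    sqrt(ab) * x0 + sqrt(1 - ab) * eps
  } else {
    sqrt(ab) * x0 + sqrt(1 - ab) * eps
  }
}

#' Zero-part and non-zero-part training masks for a gene profile
#'
#' Splits the entries of `x0` into the zero-valued and non-zero strata and
#' samples a fraction of each (floor rounding, without replacement) to act
#' as the prediction target during training: `m1` marks masked zero entries,
#' `m2` masked non-zero entries, and `observed` is the complement. Masks are
#' deterministic under `seed`; empty strata yield empty masks.
#'
#' @param x0 numeric vector.
#' @param rho_zero,rho_nonzero fractions in `[0, 1]` of each stratum to mask.
#' @param seed integer seed.
#' @return a `mask_pair` list with logical vectors `m1`, `m2`, `observed`.
#' @export
make_masks <- function(x0, rho_zero = 0.5, rho_nonzero = 0.5, seed = 0L) {
  if (rho_zero < 0 || rho_zero > 1 || rho_nonzero < 0 || rho_nonzero > 1)
    stop("mask fractions must lie in [0, 1]")
  zero_idx <- which(x0 == 0)
  nz_idx <- which(x0 != 0)
  n1 <- floor(rho_zero * length(zero_idx))
  n2 <- floor(rho_nonzero * length(nz_idx))
  sel <- with_seed(seed, list(
    z = if (n1 > 0) sample(zero_idx, n1) else integer(0),
    n = if (n2 > 0) sample(nz_idx, n2) else integer(0)))
  m1 <- m2 <- rep(FALSE, length(x0))
  m1[sel$z] <- TRUE
  m2[sel$n] <- TRUE
  structure(list(m1 = m1, m2 = m2, observed = !(m1 | m2)),
            class = "mask_pair")
}

#' Masked noise-prediction training loss
#'
#' The simplified DDPM objective restricted to the masked (prediction
#' target) entries: `x_t` is the forward diffusion of the full profile and
#' the loss is the mean of `(eps - eps_hat)^2` over the target entries
#' (`m1 | m2` by default; only `m2` when `include_zero_mask = FALSE`).
#' Values at unmasked entries do not enter the loss.
#'
#' @param model denoiser: `function(x_t, t, condition)` returning a noise
#'   prediction of the same shape as `x_t` (or a list with field `eps`).
#' @param x0 numeric vector (a gene profile on the normalized scale).
#' @param condition conditioning context forwarded to `model`.
#' @param masks a [make_masks()] mask pair.
#' @param t integer diffusion step.
#' @param eps standard-normal noise vector, same length as `x0`.
#' @param sched a [make_schedule()] schedule.
#' @param include_zero_mask include the masked-zero entries (`m1`) in the
#'   target alongside `m2` (default `TRUE`).
#' @return scalar loss (0 with a warning when the target is empty).
#' @export
training_loss <- function(model, x0, condition, masks, t, eps, sched,
                          include_zero_mask = TRUE) {
  stopifnot(inherits(masks, "mask_pair"))
  target <- if (include_zero_mask) masks$m1 | masks$m2 else masks$m2
  if (!any(target)) {
    warning("empty mask target; loss defined as 0")
    return(0)
  }
  xt <- forward_diffuse(x0, t, eps, sched)
  eps_hat <- model(xt, t, condition)
  if (is.list(eps_hat)) eps_hat <- eps_hat$eps
  mean((eps - eps_hat)[target]^2)
}

#' One ancestral reverse-diffusion step
#'
#' Computes the posterior mean
#' `mu = (x_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_hat_t)`
#' and samples `x_{t-1} = mu + sigma_t z` with `z ~ N(0, I)` for `t > 1` and
#' `z = 0` at the final step. Noise draws come from the current RNG stream,
#' so callers seed once for a whole chain.
#'
#' @param model denoiser as in [training_loss()].
#' @param state list with fields `x` (current vector), `t` (step `>= 1`) and
#'   `condition`.
#' @param sched a [make_schedule()] schedule.
#' @param z optional pre-drawn standard normal vector (for testing).
#' @return the state at `t - 1`.
#' @export
reverse_step <- function(model, state, sched, z = NULL) {
  t <- state$t
  if (t < 1) stop("reverse_step() requires t >= 1")
  eps_hat <- model(state$x, t, state$condition)
  if (is.list(eps_hat)) eps_hat <- eps_hat$eps
  mu <- (state$x - sched$beta[t] / sqrt(1 - sched$alpha_bar[t]) * eps_hat) /
    sqrt(sched$alpha_hat[t])
  if (t > 1) {
    if (is.null(z)) z <- stats::rnorm(length(mu))
    x_prev <- mu + sqrt(sched$sigma2[t]) * z
  } else {
    x_prev <- mu
  }
  list(x = x_prev, t = t - 1L, condition = state$condition)
}

#' Conditional ancestral sampling with observed-entry replacement
#'
#' Generates a gene profile by running the reverse chain from pure noise.
#' After every step the observed entries are replaced by a fresh forward
#' diffusion of their known values at the current step (inpainting-style
#' replacement), so generation stays consistent with the measurements; at
#' `t = 0` observed entries are set to their input values exactly. The
#' unobserved part is averaged over `n_samples` independent chains.
#'
#' @param model denoiser as in [training_loss()].
#' @param condition conditioning context forwarded to `model`.
#' @param observed numeric vector of known values (normalized scale);
#'   entries where `observed_mask` is `FALSE` are ignored.
#' @param observed_mask logical vector marking the known entries.
#' @param sched a [make_schedule()] schedule.
#' @param n_samples number of chains to average (default 1).
#' @param seed integer seed for the whole sampling run.
#' @return numeric vector: sampled values at unobserved entries, input
#'   values at observed entries.
#' @export
conditional_sample <- function(model, condition, observed, observed_mask,
                               sched, n_samples = 1L, seed = 0L) {
  p <- length(observed)
  stopifnot(length(observed_mask) == p)
  obs <- which(observed_mask)
  with_seed(seed, {
    acc <- numeric(p)
    for (s in seq_len(n_samples)) {
      x <- stats::rnorm(p)
      if (length(obs)) {
        e <- stats::rnorm(p)
        x[obs] <- forward_diffuse(observed, sched$T_steps, e, sched)[obs]
      }
      state <- list(x = x, t = sched$T_steps, condition = condition)
      while (state$t >= 1) {
        state <- reverse_step(model, state, sched)
        if (length(obs)) {
          if (state$t >= 1) {
            e <- stats::rnorm(p)
            state$x[obs] <- forward_diffuse(observed, state$t, e, sched)[obs]
          } else {
            state$x[obs] <- observed[obs]
          }
        }
      }
      acc <- acc + state$x
    }
    out <- acc / n_samples
    if (length(obs)) out[obs] <- observed[obs]
    out
  })
}
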
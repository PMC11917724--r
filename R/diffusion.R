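# DDPM machinery: noise schedule, closed-form forward noising, ancestral
# reverse step, and the known-region compositing that turns reverse diffusion
# into a mask-constrained inpainter.

#' Build a DDPM noise schedule
#'
#' @param T_steps Number of diffusion timesteps (>= 2).
#' @param beta_start,beta_end Per-step variance endpoints, 0 < start <= end < 1.
#' @param kind "linear" (beta interpolated linearly, the canonical DDPM
#'   choice) or "cosine" (squared-cosine signal schedule).
#' @return A `noise_schedule`: list with `T`, `beta`, `alpha`, `alpha_bar`
#'   (with the convention that alpha_bar at t = 0 equals 1).
#' @export
build_schedule <- function(T_steps = 1000, beta_start = 1e-4, beta_end = 0.02,
                           kind = c("linear", "cosine")) {
  kind <- match.arg(kind)
  stopifnot_scalar(T_steps, "T_steps", positive = TRUE, integerish = TRUE)
  if (T_steps < 2) stop("T_steps must be >= 2", call. = FALSE)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    stop("need 0 < beta_start <= beta_end < 1", call. = FALSE)
  }
  if (kind == "linear") {
    beta <- seq(beta_start, beta_end, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:T_steps) / f(0)
    beta <- pmin(pmax(1 - ab[-1] / ab[-length(ab)], beta_start), 0.999)
    beta <- cummax(beta)  # enforce monotone non-decreasing variances
  }
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  sched <- structure(list(T = as.integer(T_steps), beta = beta, alpha = alpha,
                          alpha_bar = alpha_bar), class = "noise_schedule")
  stopifnot(all(diff(alpha_bar) < 0), alpha_bar[1] < 1, alpha_bar[T_steps] > 0)
  sched
}

check_t <- function(t, schedule) {
  stopifnot_scalar(t, "t", integerish = TRUE)
  if (t < 1 || t > schedule$T) {
    stop(sprintf("timestep t = %d out of range [1, %d]", as.integer(t), schedule$T),
         call. = FALSE)
  }
  as.integer(t)
}

#' Forward diffusion sample q(x_t | x_0)
#'
#' The exact marginal `x_t = sqrt(alpha_bar_t) x0 + sqrt(1 - alpha_bar_t) eps`.
#'
#' @param x0 Clean data scaled to \[-1, 1\] (any shape).
#' @param t Timestep in 1..T.
#' @param eps Standard-normal draw of the same shape as `x0`.
#' @param schedule A [build_schedule()] result.
#' @return Noisy sample of the same shape.
#' @export
forward_noise <- function(x0, t, eps, schedule) {
  t <- check_t(t, schedule)
  if (length(eps) != length(x0)) stop("eps must match x0 in length", call. = FALSE)
  if (max(abs(x0)) > 1 + 1e-8) {
    stop("x0 must be scaled to [-1, 1] before diffusion", call. = FALSE)
  }
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Ancestral reverse-diffusion step
#'
#' `x_{t-1} = (x_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t)
#'  + sigma_t z` with `sigma_t^2 = beta_t (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t)`.
#' By the alpha_bar_0 = 1 convention, sigma_1 = 0 and the final step is
#' deterministic regardless of `z`.
#'
#' @param x_t Current state.
#' @param t Timestep in 1..T.
#' @param eps_hat Predicted noise, same shape as `x_t`.
#' @param schedule A [build_schedule()] result.
#' @param z Standard-normal draw (same shape) or NULL to draw from the current
#'   RNG stream; ignored (forced to zero) at t = 1.
#' @return `x_{t-1}`, same shape as `x_t`.
#' @export
reverse_step <- function(x_t, t, eps_hat, schedule, z = NULL) {
  t <- check_t(t, schedule)
  if (length(eps_hat) != length(x_t)) {
    stop("eps_hat must match x_t in shape", call. = FALSE)
  }
  beta <- schedule$beta[t]
  alpha <- schedule$alpha[t]
  ab_t <- schedule$alpha_bar[t]
  ab_prev <- if (t > 1) schedule$alpha_bar[t - 1] else 1
  mean_prev <- (x_t - beta / sqrt(1 - ab_t) * eps_hat) / sqrt(alpha)
  sigma <- sqrt(beta * (1 - ab_prev) / (1 - ab_t))
  if (t == 1) {
    return(mean_prev)
  }
  if (is.null(z)) z <- stats::rnorm(length(x_t))
  out <- mean_prev + sigma * z
  if (!is.null(dim(x_t))) dim(out) <- dim(x_t)
  out
}

#' Composite the known region into a reverse-diffusion state
#'
#' Inside the lesion mask the sampled (unknown-path) state is kept; outside it
#' the state is replaced by a fresh forward-noise draw of the original data at
#' level t-1, so the known region always carries the correct marginal
#' distribution for the next reverse step. At t - 1 = 0 the outside region
#' equals `x0_known` exactly.
#'
#' @param x_prev_unknown State after the reverse step for timestep t (i.e., an
#'   x_{t-1} candidate).
#' @param x0_known Original clean data scaled to \[-1, 1\].
#' @param mask Binary array, 1 = unknown/lesion.
#' @param t The timestep that was just reversed (1..T).
#' @param schedule A [build_schedule()] result.
#' @param eps Standard-normal draw for the known-region forward noise, or NULL
#'   to draw from the current RNG stream.
#' @return Composited x_{t-1}.
#' @export
composite_known <- function(x_prev_unknown, x0_known, mask, t, schedule,
                            eps = NULL) {
  t <- check_t(t, schedule)
  if (!identical(dim(x_prev_unknown), dim(x0_known)) ||
      !identical(dim(x0_known), dim(mask))) {
    stop("x_prev_unknown, x0_known and mask must share the same grid", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  if (is.null(eps)) eps <- stats::rnorm(length(x0_known))
  known <- if (t - 1 >= 1) forward_noise(x0_known, t - 1, eps, schedule) else x0_known
  out <- mask * x_prev_unknown + (1 - mask) * known
  if (!is.null(dim(x0_known))) dim(out) <- dim(x0_known)
  out
}

#' Training configuration for the slab denoiser
#'
#' @param steps Optimizer iterations (>= 1).
#' @param batch Slabs per gradient step (>= 1).
#' @param lr Adam learning rate.
#' @param seed Integer seed covering parameter init, slab sampling, timestep
#'   sampling, and noise draws.
#' @param views Character subset of c("axial", "coronal", "sagittal").
#' @return A `train_config` list.
#' @export
train_config <- function(steps = 500, batch = 4, lr = 2e-3, seed = 1,
                         views = c("axial", "coronal", "sagittal")) {
  stopifnot_scalar(steps, "steps", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(batch, "batch", positive = TRUE, integerish = TRUE)
  views <- match.arg(views, c("axial", "coronal", "sagittal"), several.ok = TRUE)
  structure(list(steps = as.integer(steps), batch = as.integer(batch),
                 lr = lr, seed = as.integer(seed), views = views),
            class = "train_config")
}

#' Train a slab denoiser on clean slabs
#'
#' Minimizes the standard denoising objective `E || eps - eps_hat(x_t, t) ||^2`
#' over uniformly sampled timesteps: slabs are noised with the closed-form
#' forward marginal and the network predicts the injected noise. No lesion
#' mask is ever constructed during training; inpainting masks appear only at
#' inference time.
#'
#' @param slab_source Function of no arguments returning a list with `data`
#'   (H x W x slab_thickness array scaled to \[-1, 1\]) and `voxel_size` (mm).
#'   Called from within the seeded training RNG stream, so a sampler using
#'   `sample()`/`runif()` is deterministic under the training seed. See
#'   [phantom_slab_source()].
#' @param schedule A [build_schedule()] result.
#' @param config A [train_config()].
#' @param vinn_config A [vinn_config()]; used to build a fresh model when
#'   `model` is NULL.
#' @param model Optionally a pre-built [build_denoiser()] model to continue
#'   training.
#' @return The trained model (a `vinn_denoiser`); `model$loss` holds the
#'   per-step loss trajectory.
#' @export
train_denoiser <- function(slab_source, schedule, config,
                           vinn_config = vinn_config(), model = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(model)) model <- build_denoiser(vinn_config, seed = config$seed)
  cfg <- model$config
  loss_tr <- numeric(config$steps)
  with_seed(config$seed + 1L, {
    for (step in seq_len(config$steps)) {
      grads <- NULL
      loss_acc <- 0
      for (b in seq_len(config$batch)) {
        slab <- slab_source()
        x0 <- slab$data
        if (dim(x0)[3] != cfg$slab_thickness) {
          stop("slab thickness does not match denoiser configuration", call. = FALSE)
        }
        t <- sample.int(schedule$T, 1)
        eps <- array(stats::rnorm(length(x0)), dim(x0))
        x_t <- forward_noise(x0, t, eps, schedule)
        fw <- denoiser_forward(model, x_t, t, slab$voxel_size, keep_cache = TRUE)
        resid <- fw$out - eps
        loss_acc <- loss_acc + mean(resid^2)
        g <- denoiser_backward(model, fw, 2 * resid / length(resid))
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / config$batch)
      loss_tr[step] <- loss_acc / config$batch
      adam_update(model, grads, lr = config$lr, step = step)
    }
  })
  model$loss <- loss_tr
  model
}
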
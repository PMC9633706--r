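#' WGAN-GP training configuration
#'
#' Defaults follow the published training setup: 50-dimensional latent
#' input, gradient-penalty weight lambda = 10, four critic updates per
#' generator update (reading "three extra steps ahead" literally as 1 + 3),
#' Adam with learning rate 2e-4, beta1 0.5, beta2 0.9 and decay 1e-4
#' applied per optimizer step, batch size 32, 1000 epochs.
#'
#' @param latent_dim Latent dimension.
#' @param lambda_gp Gradient-penalty weight.
#' @param critic_steps_per_gen Critic updates per generator update.
#' @param epochs Training epochs.
#' @param batch_size Batch size (>= 2; interpolation needs pairs).
#' @param lr,beta1,beta2,decay Adam hyperparameters.
#' @param schedule Learning-rate decay: `"inverse_time"` (the legacy Adam
#'   decay convention), `"exponential"`, or `"constant"`.
#' @param seed RNG seed for the whole run.
#' @param checkpoint_every Save a checkpoint every this many epochs.
#' @return A `train_config` list.
#' @export
train_config <- function(latent_dim = 50, lambda_gp = 10,
                         critic_steps_per_gen = 4, epochs = 1000,
                         batch_size = 32, lr = 2e-4, beta1 = 0.5,
                         beta2 = 0.9, decay = 1e-4,
                         schedule = c("inverse_time", "exponential",
                                      "constant"),
                         seed = 1L, checkpoint_every = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(latent_dim >= 1, batch_size >= 2, lr > 0, lambda_gp >= 0,
            critic_steps_per_gen >= 1, epochs >= 1)
  structure(list(latent_dim = as.integer(latent_dim), lambda_gp = lambda_gp,
                 critic_steps_per_gen = as.integer(critic_steps_per_gen),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, decay = decay,
                 schedule = schedule, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Wasserstein GAN losses
#'
#' Critic loss `mean(fake_scores) - mean(real_scores)` (minimized drives
#' real scores up and fake scores down); generator loss
#' `-mean(fake_scores)`.
#'
#' @param real_scores,fake_scores Non-empty numeric critic scores.
#' @return List with `critic_loss` and `generator_loss`.
#' @export
wgan_loss <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0 || length(fake_scores) == 0)
    stop("empty score batch")
  list(critic_loss = mean(fake_scores) - mean(real_scores),
       generator_loss = -mean(fake_scores))
}

# Critic score gradient with respect to its input, at batch x.
critic_input_grad <- function(critic, x) {
  fw <- net_forward(critic, x, training = FALSE, dropout = FALSE)
  bk <- net_backward(critic, fw$caches, matrix(1, 1, ncol(fw$out)),
                     need_param_grads = FALSE)
  bk$dx
}

#' Gradient penalty of a critic over interpolated samples
#'
#' Draws one uniform epsilon per sample, forms the convex interpolates
#' `eps * real + (1 - eps) * fake`, computes the exact critic input
#' gradient by backpropagation, and returns
#' `lambda * mean((||grad||_2 - 1)^2)`. Dropout is disabled inside the
#' critic for this evaluation, so the penalty is a deterministic function
#' of the batches and the interpolation draws.
#'
#' @param critic An `nn_network` critic.
#' @param real_batch,fake_batch Arrays of identical shape (h, w, c, n).
#' @param lambda Penalty weight (>= 0).
#' @param seed Optional seed for the interpolation draws.
#' @return Non-negative scalar penalty.
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, lambda = 10,
                             seed = NULL) {
  real_batch <- as_batch(real_batch, critic$input_shape)
  fake_batch <- as_batch(fake_batch, critic$input_shape)
  stopifnot(identical(dim(real_batch), dim(fake_batch)), lambda >= 0)
  with_seed(seed, {
    gpd <- gp_directions(critic, real_batch, fake_batch, lambda)
    gpd$penalty
  })
}

# Shared machinery for the penalty value and its parameter gradient.
# Returns the penalty, the interpolates, the per-sample unit gradient
# directions and the chain coefficients 2*lambda*(||g||-1)/n.
gp_directions <- function(critic, real_batch, fake_batch, lambda) {
  n <- dim(real_batch)[4]
  eps <- stats::runif(n)
  epsb <- array(rep(eps, each = prod(dim(real_batch)[1:3])),
                dim(real_batch))
  xi <- epsb * real_batch + (1 - epsb) * fake_batch
  g <- critic_input_grad(critic, xi)
  gm <- matrix(g, ncol = n)
  norms <- sqrt(colSums(gm^2))
  penalty <- lambda * mean((norms - 1)^2)
  safe <- pmax(norms, 1e-12)
  units <- array(sweep(gm, 2, safe, "/"), dim(g))
  coef <- 2 * lambda * (norms - 1) / n
  list(penalty = penalty, xi = xi, units = units, coef = coef)
}

# Parameter gradient of the gradient penalty via the mixed-partials
# identity: d/dtheta of u^T grad_x D(x) equals d/dtheta of the directional
# derivative of D along u, estimated with a centered finite difference of
# two ordinary backprop passes (fd_eps on unit directions).
gp_param_grads <- function(critic, real_batch, fake_batch, lambda,
                           fd_eps = 1e-3) {
  gpd <- gp_directions(critic, real_batch, fake_batch, lambda)
  n <- dim(real_batch)[4]
  wplus <- matrix(gpd$coef / (2 * fd_eps), 1, n)
  xp <- gpd$xi + fd_eps * gpd$units
  xm <- gpd$xi - fd_eps * gpd$units
  fp <- net_forward(critic, xp, training = FALSE, dropout = FALSE)
  gp1 <- net_backward(critic, fp$caches, wplus)$grads
  fm <- net_forward(critic, xm, training = FALSE, dropout = FALSE)
  gm1 <- net_backward(critic, fm$caches, -wplus)$grads
  list(grads = add_grads(gp1, gm1), penalty = gpd$penalty)
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    for (nm in names(a[[i]]))
      if (!is.null(a[[i]][[nm]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

#' Sample images from a generator
#'
#' Latent vectors are i.i.d. standard normal (un-truncated); a fixed seed
#' gives identical outputs.
#'
#' @param generator Generator `nn_network`.
#' @param n Number of images (>= 1).
#' @param seed Optional seed.
#' @param latent_dim Latent dimension (default: the generator input).
#' @return List with `images` (array h, w, 1, n in \[-1, 1\]) and
#'   `latents` (latent_dim x n matrix).
#' @export
sample_images <- function(generator, n, seed = NULL,
                          latent_dim = generator$input_shape[1]) {
  stopifnot(n >= 1)
  z <- with_seed(seed, matrix(stats::rnorm(latent_dim * n), latent_dim, n))
  list(images = generate_from_latent(generator, z), latents = z)
}

#' Generate images from explicit latent vectors
#'
#' Inference-mode forward pass (batch norm uses moving statistics, dropout
#' inactive), hence deterministic.
#'
#' @param generator Generator `nn_network`.
#' @param z Latent matrix (latent_dim x n) or vector.
#' @return Array (h, w, 1, n) in \[-1, 1\].
#' @export
generate_from_latent <- function(generator, z) {
  if (!is.matrix(z)) z <- matrix(z, length(z), 1)
  net_forward(generator, z, training = FALSE)$out
}

#' Convert generator output in \[-1, 1\] to 8-bit gray levels
#'
#' @param x Array or matrix in \[-1, 1\].
#' @return Same shape, integer values in \[0, 255\] via `(x + 1) * 127.5`.
#' @export
tanh_to_uint8 <- function(x) clip8(round_half_up((x + 1) * 127.5))

#' Train a WGAN with gradient penalty
#'
#' Per generator update the critic is updated `critic_steps_per_gen` times
#' on fresh batches with the Wasserstein loss plus gradient penalty; the
#' generator then maximizes the critic's score of fresh fakes. Adam with
#' per-step learning-rate decay. Deterministic under a fixed seed.
#'
#' @param images Array (h, w, 1, n) in \[-1, 1\], or integer images in
#'   \[0, 255\] (auto-rescaled by `x / 127.5 - 1`).
#' @param gen_spec,critic_spec_ Architecture specs; defaults are the
#'   desk-scale 64x64 variants.
#' @param config A [train_config()].
#' @param checkpoint_dir Optional directory for on-disk checkpoints.
#' @return List of `wgan_checkpoint` objects (one per saved epoch), the
#'   last holding the final networks; each has `epoch`, `generator`,
#'   `critic`, `history` (per-generator-step critic/generator losses and
#'   the Wasserstein estimate) and `config`.
#' @export
train_wgan <- function(images, gen_spec = scaled_generator_spec(),
                       critic_spec_ = scaled_critic_spec(),
                       config = train_config(), checkpoint_dir = NULL) {
  if (max(images) > 1 + 1e-9) images <- images / 127.5 - 1
  d <- dim(images)
  stopifnot(length(d) == 4)
  n <- d[4]
  if (n < config$batch_size)
    stop("dataset smaller than batch_size (", n, " < ", config$batch_size, ")")
  gen <- build_network(gen_spec, seed = config$seed)
  critic <- build_network(critic_spec_, seed = config$seed + 1L)
  opt_g <- adam_state(gen); opt_c <- adam_state(critic)
  steps_per_epoch <- max(1L, n %/% config$batch_size)
  history <- list(critic_loss = numeric(0), generator_loss = numeric(0),
                  wasserstein = numeric(0), penalty = numeric(0))
  checkpoints <- list()
  upd <- function(net, grads, st) adam_update(net, grads, st,
    lr = config$lr, beta1 = config$beta1, beta2 = config$beta2,
    decay = config$decay, schedule = config$schedule)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      for (step in seq_len(steps_per_epoch)) {
        w_est <- NA_real_; pen <- NA_real_; closs <- NA_real_
        for (cs in seq_len(config$critic_steps_per_gen)) {
          idx <- sample.int(n, config$batch_size)
          real <- images[, , , idx, drop = FALSE]
          z <- matrix(stats::rnorm(config$latent_dim * config$batch_size),
                      config$latent_dim)
          fake <- net_forward(gen, z, training = TRUE)$out
          fw_r <- net_forward(critic, real, training = TRUE)
          fw_f <- net_forward(critic, fake, training = TRUE)
          nb <- config$batch_size
          g_r <- net_backward(critic, fw_r$caches, matrix(-1 / nb, 1, nb))$grads
          g_f <- net_backward(critic, fw_f$caches, matrix(1 / nb, 1, nb))$grads
          gpg <- gp_param_grads(critic, real, fake, config$lambda_gp)
          grads <- add_grads(add_grads(g_r, g_f), gpg$grads)
          losses <- wgan_loss(fw_r$out, fw_f$out)
          closs <- losses$critic_loss + gpg$penalty
          if (!is.finite(closs))
            stop("non-finite critic loss at epoch ", epoch, " step ", step)
          w_est <- mean(fw_r$out) - mean(fw_f$out)
          pen <- gpg$penalty
          res <- upd(critic, grads, opt_c)
          critic <- res$net; opt_c <- res$state
        }
        # generator update
        z <- matrix(stats::rnorm(config$latent_dim * config$batch_size),
                    config$latent_dim)
        fw_g <- net_forward(gen, z, training = TRUE)
        fw_s <- net_forward(critic, fw_g$out, training = TRUE)
        nb <- config$batch_size
        dfake <- net_backward(critic, fw_s$caches, matrix(-1 / nb, 1, nb),
                              need_param_grads = FALSE)$dx
        g_gen <- net_backward(gen, fw_g$caches, dfake)$grads
        gloss <- -mean(fw_s$out)
        if (!is.finite(gloss))
          stop("non-finite generator loss at epoch ", epoch, " step ", step)
        gen <- bn_update_moving(gen, fw_g$caches)
        res <- upd(gen, g_gen, opt_g)
        gen <- res$net; opt_g <- res$state
        history$critic_loss <- c(history$critic_loss, closs)
        history$generator_loss <- c(history$generator_loss, gloss)
        history$wasserstein <- c(history$wasserstein, w_est)
        history$penalty <- c(history$penalty, pen)
      }
      if (epoch %% config$checkpoint_every == 0 ||
          epoch == config$epochs) {
        ck <- structure(list(epoch = epoch, generator = gen,
                             critic = critic, history = history,
                             config = config),
                        class = "wgan_checkpoint")
        checkpoints[[length(checkpoints) + 1L]] <- ck
        if (!is.null(checkpoint_dir)) save_checkpoint(ck, checkpoint_dir)
      }
    }
  })
  checkpoints
}

#' Save / load a WGAN checkpoint
#'
#' The weight archive is a single RDS file; reloading and generating from
#' a fixed latent vector reproduces the pre-save output bit-exactly.
#'
#' @param checkpoint A `wgan_checkpoint`.
#' @param dir Directory (created if missing).
#' @return The file path (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, sprintf("checkpoint_epoch%04d.rds",
                                 checkpoint$epoch))
  saveRDS(checkpoint, path)
  path
}

#' @rdname save_checkpoint
#' @param path RDS file path.
#' @export
load_checkpoint <- function(path) readRDS(path)
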
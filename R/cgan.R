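#' Conditional instance normalization injection
#'
#' Instance-normalizes each feature channel and applies an affine whose scale
#' and shift are linear maps of the latent vector; this is how the generator
#' receives its stochastic input. Exposed for direct use/testing; inside the
#' generator the same operation runs at every block.
#'
#' @param features (H, W, N, C) array.
#' @param latent (N x latent_dim) matrix.
#' @param scale_W,scale_b linear map (latent_dim x C matrix, length-C bias)
#'   producing the per-channel scale.
#' @param shift_W,shift_b linear map producing the per-channel shift.
#' @return the normalized, modulated (H, W, N, C) array.
#' @export
cin_inject <- function(features, latent, scale_W, scale_b, shift_W, shift_b) {
  d <- dim(features)
  stop_if_not(ncol(latent) == nrow(scale_W), "latent length must match the learned map")
  gamma <- sweep(latent %*% scale_W, 2L, scale_b, "+")
  beta <- sweep(latent %*% shift_W, 2L, shift_b, "+")
  .instnorm_affine_infer_cpp(features, d, gamma, beta, 1e-5)
}

# critic scores for a batch; d is a scalar-head mrt_backbone or a
# list(f = function(x3, y3) -> numeric(N), grad_y = function(x3, y3) -> array)
critic_value <- function(d, x, y) {
  if (inherits(d, "mrt_backbone")) {
    as.numeric(backbone_forward(d, abind_ch(y, x)))
  } else {
    as.numeric(d$f(x, y))
  }
}

# per-sample gradient of the critic w.r.t. its target-image input
critic_grad_y <- function(d, x, y) {
  if (inherits(d, "mrt_backbone")) {
    tape <- tg_tape()
    leaf <- tg_leaf(tape, abind_ch(y, x))
    out <- backbone_forward(d, leaf, tape = tape)
    s <- op_wsum(tape, out, rep(1, dim(y)[3]))
    tg_zero_grads(d$params)
    tg_backward(tape, s)
    tg_zero_grads(d$params)
    leaf$grad[, , , 1L]
  } else {
    d$grad_y(x, y)
  }
}

gen_apply <- function(g, x, z) {
  if (inherits(g, "mrt_backbone")) {
    d <- dim(x)
    array(backbone_forward(g, array(x, c(d, 1L)), z = z), d)
  } else {
    g(x, z)
  }
}

#' Wasserstein critic loss with gradient penalty
#'
#' `-(E[d(x,y)] - E[d(x, y^g)]) + lambda * E[(||grad_y d(x, yhat)|| - 1)^2]`
#' with `yhat = eps * y + (1 - eps) * y^g`, `eps ~ U(0,1)` independently per
#' batch element. Minimizing this by gradient descent maximizes the penalized
#' Wasserstein objective of the critic. The penalty vanishes exactly when the
#' interpolate gradient norm is 1.
#'
#' @param d critic: scalar-head `mrt_backbone` or `list(f, grad_y)`.
#' @param g generator: `mrt_backbone` with a latent path, or
#'   `function(x, z)`.
#' @param x,y batch arrays (H, W, N).
#' @param z latent matrix (N x latent_dim); drawn standard normal if `NULL`.
#' @param lambda gradient-penalty weight (>= 0).
#' @param eps optional fixed per-sample interpolation weights.
#' @return scalar loss.
#' @export
critic_loss <- function(d, g, x, y, z = NULL, lambda = 10, eps = NULL) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  d3 <- dim(y)
  stop_if_not(length(d3) == 3 && d3[3] >= 1, "batch must be nonempty (H, W, N)")
  nb <- d3[3]
  if (is.null(z)) z <- matrix(stats::rnorm(nb * 128L), nb, 128L)
  yg <- gen_apply(g, x, z)
  sc_real <- critic_value(d, x, y)
  sc_fake <- critic_value(d, x, yg)
  base <- -(mean(sc_real) - mean(sc_fake))
  if (lambda == 0) return(base)
  if (is.null(eps)) eps <- stats::runif(nb)
  ef <- array(rep(eps, each = d3[1] * d3[2]), d3)
  yhat <- ef * y + (1 - ef) * yg
  u <- critic_grad_y(d, x, yhat)
  um <- u * u
  dim(um) <- c(d3[1] * d3[2], nb)
  norms <- sqrt(colSums(um))
  base + lambda * mean((norms - 1)^2)
}

#' Generator loss under a fixed critic
#'
#' `-E[d(x, g(x, z))]`: the generator part of the adversarial objective (the
#' real-data term has zero generator gradient and is omitted).
#'
#' @inheritParams critic_loss
#' @return scalar loss.
#' @export
generator_loss <- function(d, g, x, z = NULL) {
  d3 <- dim(x)
  nb <- d3[3]
  if (is.null(z)) z <- matrix(stats::rnorm(nb * 128L), nb, 128L)
  yg <- gen_apply(g, x, z)
  -mean(critic_value(d, x, yg))
}

#' Train a conditional Wasserstein GAN with gradient penalty
#'
#' Alternating optimization: `critic_steps` critic updates per generator
#' update, Adam with WGAN-GP betas (0, 0.9). The gradient-penalty value is
#' exact (one reverse pass for the interpolate gradient); its parameter
#' gradient uses a central finite difference along the detached gradient
#' direction, costing two extra critic passes that are batched with the
#' real/fake terms. The generator loss is purely adversarial (no pixel
#' reconstruction term).
#'
#' @param data training `paired_slice_dataset`.
#' @param latent_dim latent dimension injected via conditional instance
#'   normalization (128 by default).
#' @param gp_weight gradient-penalty weight lambda.
#' @param critic_steps critic updates per generator update (>= 1).
#' @param gen_steps number of generator updates.
#' @param batch_size,lr optimizer settings (`lr` drives the critic).
#' @param lr_gen generator learning rate (defaults to `lr`).
#' @param base_width,depth backbone size (shared by generator and critic).
#' @param fd_delta finite-difference step for the penalty gradient.
#' @param seed RNG seed.
#' @return a `cgan_model` with `generator`, `critic` and a history data frame
#'   (critic loss, generator loss, Wasserstein estimate).
#' @export
train_cgan <- function(data, latent_dim = 128L, gp_weight = 10, critic_steps = 5L,
                       gen_steps = 300L, batch_size = 8L, lr = 2e-4,
                       lr_gen = lr, base_width = 8L, depth = 2L,
                       fd_delta = 1e-3, seed = 1L) {
  np <- n_pairs(data)
  stop_if_not(np > 0, "empty training dataset")
  stop_if_not(critic_steps >= 1, "critic_steps must be >= 1")
  stop_if_not(gp_weight >= 0, "gp_weight must be >= 0")
  hw <- data$slice_shape
  m2 <- hw[1] * hw[2]
  gen <- build_backbone(backbone_config(in_channels = 1L, out_channels = 1L,
                                        base_width = base_width, depth = depth,
                                        latent_dim = latent_dim,
                                        image_size = hw[1], final = "sigmoid"),
                        seed = seed)
  cri <- build_backbone(backbone_config(in_channels = 2L, base_width = base_width,
                                        depth = depth, image_size = hw[1],
                                        norm = "none", head = "scalar"),
                        seed = seed + 1L)
  gopt <- adam_new(gen$params, lr = lr_gen, beta1 = 0, beta2 = 0.9)
  copt <- adam_new(cri$params, lr = lr, beta1 = 0, beta2 = 0.9)
  hist <- data.frame(step = seq_len(gen_steps), critic_loss = NA_real_,
                     gen_loss = NA_real_, wasserstein = NA_real_)
  with_seed(seed + 2L, {
    for (gs in seq_len(gen_steps)) {
      closs <- NA_real_; wass <- NA_real_
      for (cs in seq_len(critic_steps)) {
        idx <- sample.int(np, min(batch_size, np))
        x <- data$x[, , idx, drop = FALSE]
        y <- data$y[, , idx, drop = FALSE]
        nb <- length(idx)
        z <- matrix(stats::rnorm(nb * latent_dim), nb, latent_dim)
        yg <- gen_apply(gen, x, z)
        eps <- stats::runif(nb)
        ef <- array(rep(eps, each = m2), dim(y))
        yhat <- ef * y + (1 - ef) * yg
        u <- critic_grad_y(cri, x, yhat)
        um <- u * u; dim(um) <- c(m2, nb)
        norms <- pmax(sqrt(colSums(um)), 1e-12)
        cdir <- u / array(rep(norms, each = m2), dim(u))
        # one batched pass: real, fake, and the two penalty probes
        big_y <- array(0, c(hw, 4L * nb))
        big_y[, , seq_len(nb)] <- y
        big_y[, , nb + seq_len(nb)] <- yg
        big_y[, , 2L * nb + seq_len(nb)] <- yhat + fd_delta * cdir
        big_y[, , 3L * nb + seq_len(nb)] <- yhat - fd_delta * cdir
        big_x <- array(0, c(hw, 4L * nb))
        for (r in 0:3) big_x[, , r * nb + seq_len(nb)] <- x
        wpen <- gp_weight * (norms - 1) / (fd_delta * nb)
        wts <- c(rep(-1 / nb, nb), rep(1 / nb, nb), wpen, -wpen)
        tape <- tg_tape()
        out <- backbone_forward(cri, abind_ch(big_y, big_x), tape = tape)
        surr <- op_wsum(tape, out, wts)
        tg_zero_grads(cri$params)
        tg_backward(tape, surr)
        adam_step(copt)
        sc <- as.numeric(vof(out))
        wass <- mean(sc[seq_len(nb)]) - mean(sc[nb + seq_len(nb)])
        closs <- -wass + gp_weight * mean((norms - 1)^2)
        if (!is.finite(closs)) {
          stop("cGAN training diverged (non-finite critic loss at generator step ",
               gs, ")", call. = FALSE)
        }
      }
      # generator update: gradient flows through the critic into the generator
      idx <- sample.int(np, min(batch_size, np))
      x <- data$x[, , idx, drop = FALSE]
      nb <- length(idx)
      z <- matrix(stats::rnorm(nb * latent_dim), nb, latent_dim)
      tape <- tg_tape()
      gout <- backbone_forward(gen, array(x, c(hw, nb, 1L)), z = z, tape = tape)
      inp <- op_concat_ch(tape, gout, array(x, c(hw, nb, 1L)))
      dout <- backbone_forward(cri, inp, tape = tape)
      gloss <- op_wsum(tape, dout, rep(-1 / nb, nb))
      tg_zero_grads(gen$params)
      tg_zero_grads(cri$params)
      tg_backward(tape, gloss)
      adam_step(gopt)
      tg_zero_grads(cri$params)
      if (!is.finite(gloss$value)) {
        stop("cGAN training diverged (non-finite generator loss at step ", gs, ")",
             call. = FALSE)
      }
      hist$critic_loss[gs] <- closs
      hist$gen_loss[gs] <- gloss$value
      hist$wasserstein[gs] <- wass
    }
  })
  structure(list(generator = gen, critic = cri, history = hist,
                 latent_dim = latent_dim, seed = seed), class = "cgan_model")
}

#' Sample an ensemble from a trained cGAN generator
#'
#' Draws `n` independent latent vectors (one per generated volume; the same
#' latent conditions every slice of that volume) and generates `n`
#' transformed volumes.
#'
#' @param model a `cgan_model` (or an `mrt_backbone` generator).
#' @param input_volume a [volume()] or (S, H, W) array.
#' @param n number of samples (>= 1).
#' @param seed RNG seed; identical seeds give identical ensembles.
#' @param z optional fixed (n x latent_dim) latent matrix.
#' @return an `mrt_ensemble`.
#' @export
sample_cgan <- function(model, input_volume, n = 20L, seed = 1L, z = NULL) {
  stop_if_not(n >= 1, "n must be >= 1")
  gen <- if (inherits(model, "cgan_model")) model$generator else model
  latent_dim <- gen$cfg$latent_dim
  xarr <- if (inherits(input_volume, "volume")) input_volume$data else input_volume
  d <- dim(xarr)
  S <- d[1]
  if (is.null(z)) z <- with_seed(seed, matrix(stats::rnorm(n * latent_dim), n, latent_dim))
  xb <- array(0, c(d[2], d[3], S, 1L))
  for (s in seq_len(S)) xb[, , s, 1L] <- xarr[s, , ]
  vols <- vector("list", n)
  for (i in seq_len(n)) {
    zb <- matrix(rep(z[i, ], each = S), S, latent_dim)
    yb <- backbone_forward(gen, xb, z = zb)
    v <- array(0, d)
    for (s in seq_len(S)) v[s, , ] <- clip01(yb[, , s, 1L])
    vols[[i]] <- v
  }
  ens_summarize(vols, model_tag = "cgan",
                input_ref = if (inherits(input_volume, "volume")) input_volume$subject_id else "")
}
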
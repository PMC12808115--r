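#' Configure the shared encoder-decoder backbone
#'
#' All four models in the package (the deterministic baseline, the cGAN
#' generator, the NCSN score network and the DDPM denoiser) use the same
#' encoder-decoder ("U-Net") network family, so that model comparisons are not
#' confounded by architecture. The network maps a stack of input channels to an
#' output image of the same spatial size, with level-wise skip connections.
#' Optional conditioning paths: a sinusoidal step embedding injected as a
#' per-channel bias at every block (`time_conditioning`), and a latent vector
#' injected through conditional instance normalization (`latent_dim`).
#'
#' @param in_channels,out_channels image channels in and out.
#' @param base_width channels at the top level; level l uses `base_width * 2^l`.
#' @param depth number of downsamplings; `image_size` must be divisible by
#'   `2^depth`.
#' @param time_conditioning logical; accept a per-sample step index.
#' @param latent_dim dimension of the latent vector injected via conditional
#'   instance normalization, or `NULL` for none. The cGAN generator uses 128.
#' @param image_size square slice size in pixels.
#' @param norm `"instance"` for instance normalization with learned per-channel
#'   affine (replaced by the latent-driven affine when `latent_dim` is set),
#'   or `"none"` (used by the WGAN critic, where normalization interferes with
#'   the gradient penalty).
#' @param head `"image"` for a full-resolution image output, `"scalar"` for a
#'   pooled scalar output (critic).
#' @param final `"linear"` or `"sigmoid"` activation on an image head.
#' @param input_gate add a step-gated blend of the first input channel into
#'   the output: `out + sigmoid(w(t)) * input[,,,1]`. Gives denoising-style
#'   networks a direct, learnable path for "copy the noisy image" at small
#'   noise levels; requires `time_conditioning`.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(in_channels = 1L, out_channels = 1L, base_width = 8L,
                            depth = 2L, time_conditioning = FALSE,
                            latent_dim = NULL, image_size = 32L,
                            norm = c("instance", "none"),
                            head = c("image", "scalar"),
                            final = c("linear", "sigmoid"),
                            input_gate = FALSE) {
  norm <- match.arg(norm)
  head <- match.arg(head)
  final <- match.arg(final)
  stop_if_not(depth >= 1L, "depth must be >= 1")
  if (isTRUE(input_gate) && !isTRUE(time_conditioning)) {
    stop("input_gate requires time_conditioning", call. = FALSE)
  }
  if (image_size %% (2^depth) != 0) {
    stop("image_size (", image_size, ") is not divisible by 2^depth (", 2^depth, ")",
         call. = FALSE)
  }
  structure(list(
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
    base_width = as.integer(base_width), depth = as.integer(depth),
    time_conditioning = isTRUE(time_conditioning),
    latent_dim = if (is.null(latent_dim)) NULL else as.integer(latent_dim),
    image_size = as.integer(image_size), norm = norm, head = head, final = final,
    input_gate = isTRUE(input_gate), time_embed_dim = 32L
  ), class = "backbone_config")
}

bb_widths <- function(cfg) cfg$base_width * 2^(0:cfg$depth)

bb_block_channels <- function(cfg) {
  cw <- bb_widths(cfg)
  ch <- list(in0 = c(cfg$in_channels, cw[1]))
  for (l in seq_len(cfg$depth)) ch[[paste0("enc", l)]] <- c(cw[l], cw[l + 1])
  ch[["bott"]] <- c(cw[cfg$depth + 1], cw[cfg$depth + 1])
  if (cfg$head == "image") {
    for (l in seq.int(cfg$depth, 1L)) {
      above <- if (l == cfg$depth) cw[cfg$depth + 1] else cw[l + 1]
      ch[[paste0("dec", l)]] <- c(above + cw[l + 1], cw[l])
    }
  }
  ch
}

#' Build a backbone network with deterministically initialized weights
#'
#' @param cfg a [backbone_config()].
#' @param seed integer seed for weight initialization; identical seed and
#'   config give bit-identical networks.
#' @return an object of class `mrt_backbone` holding the config and a named
#'   list of parameters.
#' @export
build_backbone <- function(cfg, seed = 1L) {
  stop_if_not(inherits(cfg, "backbone_config"), "cfg must be a backbone_config")
  params <- list()
  with_seed(seed, {
    conv_init <- function(cin, cout) {
      tg_param(array(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                     c(3, 3, cin, cout)))
    }
    lin_init <- function(din, dout, sd = sqrt(2 / din)) {
      tg_param(matrix(stats::rnorm(din * dout, sd = sd), din, dout))
    }
    ch <- bb_block_channels(cfg)
    for (nm in names(ch)) {
      cin <- ch[[nm]][1]; cout <- ch[[nm]][2]
      params[[paste0(nm, "_c1_W")]] <- conv_init(cin, cout)
      params[[paste0(nm, "_c1_b")]] <- tg_param(numeric(cout))
      params[[paste0(nm, "_c2_W")]] <- conv_init(cout, cout)
      params[[paste0(nm, "_c2_b")]] <- tg_param(numeric(cout))
      if (cfg$time_conditioning) {
        params[[paste0(nm, "_t_W")]] <- lin_init(cfg$time_embed_dim, cout)
        params[[paste0(nm, "_t_b")]] <- tg_param(numeric(cout))
      }
      if (cfg$norm == "instance") {
        if (is.null(cfg$latent_dim)) {
          for (k in 1:2) {
            params[[paste0(nm, "_n", k, "_g")]] <- tg_param(rep(1, cout))
            params[[paste0(nm, "_n", k, "_b")]] <- tg_param(numeric(cout))
          }
        } else {
          for (k in 1:2) {
            params[[paste0(nm, "_n", k, "_gW")]] <- lin_init(cfg$latent_dim, cout, sd = 0.05)
            params[[paste0(nm, "_n", k, "_gb")]] <- tg_param(rep(1, cout))
            params[[paste0(nm, "_n", k, "_bW")]] <- lin_init(cfg$latent_dim, cout, sd = 0.05)
            params[[paste0(nm, "_n", k, "_bb")]] <- tg_param(numeric(cout))
          }
        }
      }
    }
    if (cfg$time_conditioning) {
      de <- cfg$time_embed_dim
      params[["te1_W"]] <- lin_init(de, de)
      params[["te1_b"]] <- tg_param(numeric(de))
      params[["te2_W"]] <- lin_init(de, de)
      params[["te2_b"]] <- tg_param(numeric(de))
    }
    cw <- bb_widths(cfg)
    if (cfg$head == "image") {
      params[["out_W"]] <- tg_param(matrix(stats::rnorm(cw[1] * cfg$out_channels,
                                                        sd = sqrt(1 / cw[1])),
                                           cw[1], cfg$out_channels))
      params[["out_b"]] <- tg_param(numeric(cfg$out_channels))
    } else {
      params[["head_W"]] <- lin_init(cw[cfg$depth + 1], 1L, sd = sqrt(1 / cw[cfg$depth + 1]))
      params[["head_b"]] <- tg_param(numeric(1))
    }
    if (isTRUE(cfg$input_gate)) {
      params[["gate_W"]] <- lin_init(cfg$time_embed_dim, 1L, sd = 0.01)
      params[["gate_b"]] <- tg_param(-2)   # gate starts mostly closed
    }
  })
  structure(list(cfg = cfg, params = params), class = "mrt_backbone")
}

# instance norm + affine for a block stage; the affine comes either from
# per-channel parameters or from the latent vector (conditional instance norm)
bb_norm <- function(tape, h, net, nm, k, z) {
  cfg <- net$cfg
  if (cfg$norm != "instance") return(h)
  p <- net$params
  if (is.null(cfg$latent_dim)) {
    op_instnorm_affine(tape, h, p[[paste0(nm, "_n", k, "_g")]], p[[paste0(nm, "_n", k, "_b")]])
  } else {
    gamma <- op_linear(tape, z, p[[paste0(nm, "_n", k, "_gW")]], p[[paste0(nm, "_n", k, "_gb")]])
    beta <- op_linear(tape, z, p[[paste0(nm, "_n", k, "_bW")]], p[[paste0(nm, "_n", k, "_bb")]])
    op_instnorm_affine(tape, h, gamma, beta)
  }
}

bb_block <- function(tape, x, net, nm, temb, z) {
  p <- net$params
  h <- op_conv3(tape, x, p[[paste0(nm, "_c1_W")]], p[[paste0(nm, "_c1_b")]])
  h <- bb_norm(tape, h, net, nm, 1L, z)
  if (!is.null(temb)) {
    # injected after normalization: instance norm would cancel a pure
    # per-channel bias added before it
    tb <- op_linear(tape, temb, p[[paste0(nm, "_t_W")]], p[[paste0(nm, "_t_b")]])
    h <- op_add_ncbias(tape, h, tb)
  }
  h <- op_silu(tape, h)
  h <- op_conv3(tape, h, p[[paste0(nm, "_c2_W")]], p[[paste0(nm, "_c2_b")]])
  h <- bb_norm(tape, h, net, nm, 2L, z)
  op_silu(tape, h)
}

#' Forward pass through a backbone
#'
#' @param net an `mrt_backbone`.
#' @param x input array of shape (H, W, N, in_channels) or a tape node.
#' @param t optional per-sample step index (length-N numeric); requires
#'   `time_conditioning`.
#' @param z optional latent matrix (N x latent_dim); required iff `latent_dim`
#'   is set in the config.
#' @param tape a `tg_tape` to record gradients on, or `NULL` for plain
#'   inference.
#' @return an (H, W, N, out_channels) array/node for an image head, or an
#'   (N, 1) matrix/node for a scalar head.
#' @export
backbone_forward <- function(net, x, t = NULL, z = NULL, tape = NULL) {
  cfg <- net$cfg
  p <- net$params
  d <- dim(vof(x))
  stop_if_not(length(d) == 4 && d[4] == cfg$in_channels,
              "input must be (H, W, N, in_channels)")
  if (!is.null(t) && !cfg$time_conditioning) {
    stop("a step index was supplied but the backbone was built without time conditioning",
         call. = FALSE)
  }
  if (cfg$time_conditioning && is.null(t)) stop("step index t is required", call. = FALSE)
  if (!is.null(cfg$latent_dim)) {
    stop_if_not(!is.null(z), "a latent matrix z is required for this backbone")
    zd <- dim(vof(z))
    stop_if_not(length(zd) == 2 && zd[2] == cfg$latent_dim && zd[1] == d[3],
                "z must be an (N x latent_dim) matrix")
  } else if (!is.null(z)) {
    stop("a latent vector was supplied but the backbone has no latent path", call. = FALSE)
  }
  temb <- NULL
  if (cfg$time_conditioning) {
    stop_if_not(length(t) == d[3], "t must have one entry per batch sample")
    e <- sin_embed(as.numeric(t), cfg$time_embed_dim)
    e <- op_linear(tape, e, p$te1_W, p$te1_b)
    e <- op_silu(tape, e)
    temb <- op_linear(tape, e, p$te2_W, p$te2_b)
  }
  h <- bb_block(tape, x, net, "in0", temb, z)
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    h <- bb_block(tape, h, net, paste0("enc", l), temb, z)
    skips[[l]] <- h
    h <- op_pool2(tape, h)
  }
  h <- bb_block(tape, h, net, "bott", temb, z)
  if (cfg$head == "scalar") {
    g <- op_gmeanpool(tape, h)
    return(op_linear(tape, g, p$head_W, p$head_b))
  }
  for (l in seq.int(cfg$depth, 1L)) {
    h <- op_up2(tape, h)
    h <- op_concat_ch(tape, h, skips[[l]])
    h <- bb_block(tape, h, net, paste0("dec", l), temb, z)
  }
  out <- op_conv1(tape, h, p$out_W, p$out_b)
  if (isTRUE(cfg$input_gate)) {
    gate <- op_sigmoid(tape, op_linear(tape, temb, p$gate_W, p$gate_b))
    ch1 <- vof(x)[, , , 1L, drop = FALSE]
    out <- op_add(tape, out, op_mul_nc(tape, ch1, gate))
  }
  if (cfg$final == "sigmoid") out <- op_sigmoid(tape, out)
  out
}

#' Extract / restore a serializable network state
#'
#' `net_state()` returns the configuration and plain-array weights;
#' `net_restore()` rebuilds the `mrt_backbone` from such a state. Useful for
#' checkpointing without environments.
#' @param net an `mrt_backbone`.
#' @export
net_state <- function(net) {
  list(cfg = net$cfg, weights = lapply(net$params, function(p) p$value))
}

#' @rdname net_state
#' @param state a list produced by `net_state()`.
#' @export
net_restore <- function(state) {
  params <- lapply(state$weights, tg_param)
  structure(list(cfg = state$cfg, params = params), class = "mrt_backbone")
}
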
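# A compact reverse-mode automatic-differentiation tape. Every operation either
# records a node with a backward closure (tape supplied) or, with tape = NULL,
# computes the plain value for gradient-free inference. Parameters are
# environments carrying $value/$grad, shared across tapes; node gradients are
# accumulated into them during the reverse sweep.

tg_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "tg_tape"
  e
}

tg_node <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

tg_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  class(p) <- "tg_param"
  p
}

tg_leaf <- function(tape, value) tg_node(tape, value)

vof <- function(x) if (is.environment(x)) x$value else x

tg_acc <- function(x, g) {
  if (is.null(x$grad)) x$grad <- g else x$grad <- x$grad + g
  invisible(NULL)
}

tg_backward <- function(tape, root, seed_grad = 1) {
  root$grad <- seed_grad
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

tg_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- tracked operations -------------------------------------------------

op_conv3 <- function(tape, x, W, b) {
  res <- conv3_fwd(vof(x), W$value, b$value)
  if (is.null(tape)) return(res$out)
  want_dx <- is.environment(x)
  nd <- tg_node(tape, res$out)
  Wv <- W$value
  nd$backfn <- function(g) {
    bw <- conv3_bwd(g, res$x, Wv, want_dx = want_dx)
    if (want_dx) tg_acc(x, bw$dx)
    tg_acc(W, bw$dW)
    tg_acc(b, bw$db)
  }
  nd
}

op_conv1 <- function(tape, x, W, b) {
  xv <- vof(x)
  out <- conv1_fwd(xv, W$value, b$value)
  if (is.null(tape)) return(out)
  want_dx <- is.environment(x)
  nd <- tg_node(tape, out)
  Wv <- W$value
  nd$backfn <- function(g) {
    bw <- conv1_bwd(g, xv, Wv)
    if (want_dx) tg_acc(x, bw$dx)
    tg_acc(W, bw$dW)
    tg_acc(b, bw$db)
  }
  nd
}

op_pool2 <- function(tape, x) {
  out <- pool2_fwd(vof(x))
  if (is.null(tape)) return(out)
  din <- dim(vof(x))
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) tg_acc(x, pool2_bwd(g, din))
  nd
}

op_up2 <- function(tape, x) {
  out <- up2_fwd(vof(x))
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) tg_acc(x, up2_bwd(g))
  nd
}

op_concat_ch <- function(tape, a, b) {
  av <- vof(a); bv <- vof(b)
  da <- dim(av); db <- dim(bv)
  out <- .concat_ch_cpp(av, bv, da, db)
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) {
    if (is.environment(a)) tg_acc(a, g[, , , seq_len(da[4]), drop = FALSE])
    if (is.environment(b)) tg_acc(b, g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  }
  nd
}

op_add <- function(tape, a, b) {
  out <- vof(a) + vof(b)
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) {
    if (is.environment(a)) tg_acc(a, g)
    if (is.environment(b)) tg_acc(b, g)
  }
  nd
}

# add a per-(sample, channel) bias (N x C matrix node) to an (H,W,N,C) map
op_add_ncbias <- function(tape, x, bias) {
  xv <- vof(x); bv <- vof(bias)
  d <- dim(xv)
  out <- .add_ncbias_cpp(xv, bv, d)
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) {
    if (is.environment(x)) tg_acc(x, g)
    if (is.environment(bias)) tg_acc(bias, .sum_nc_cpp(g, d))
  }
  nd
}

# fused instance normalization + affine. gamma/beta are either length-C
# parameter vectors (per-channel affine) or N x C nodes/matrices (CIN), or
# plain constants for an affine-free normalization.
op_instnorm_affine <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- vof(x)
  d <- dim(xv)
  gv <- vof(gamma); bv <- vof(beta)
  per_channel <- is.null(dim(gv))
  gm <- if (per_channel) matrix(gv, d[3], d[4], byrow = TRUE) else gv
  bm <- if (per_channel) matrix(bv, d[3], d[4], byrow = TRUE) else bv
  if (is.null(tape)) return(.instnorm_affine_infer_cpp(xv, d, gm, bm, eps))
  res <- .instnorm_affine_fwd_cpp(xv, d, gm, bm, eps)
  nd <- tg_node(tape, res$out)
  nd$backfn <- function(g) {
    want_dx <- is.environment(x)
    bw <- .instnorm_affine_bwd_cpp(g, res$xn, res$s, d, gm, want_dx)
    if (want_dx) tg_acc(x, bw$dx)
    if (is.environment(gamma))
      tg_acc(gamma, if (per_channel) colSums(bw$dgamma) else bw$dgamma)
    if (is.environment(beta))
      tg_acc(beta, if (per_channel) colSums(bw$dbeta) else bw$dbeta)
  }
  nd
}

# multiply an (H,W,N,C) map by a per-(sample, channel) gate (N x C node)
op_mul_nc <- function(tape, x, gate) {
  xv <- vof(x); gv <- vof(gate)
  d <- dim(xv)
  gfull <- aperm(array(gv, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  out <- xv * gfull
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) {
    if (is.environment(x)) tg_acc(x, g * gfull)
    if (is.environment(gate)) tg_acc(gate, .sum_nc_cpp(g * xv, d))
  }
  nd
}

op_silu <- function(tape, x) {
  xv <- vof(x)
  if (is.null(tape)) return(.silu_infer_cpp(xv))
  res <- .silu_fwd_cpp(xv)
  nd <- tg_node(tape, res$out)
  nd$backfn <- function(g) tg_acc(x, .silu_bwd_cpp(g, xv, res$s))
  nd
}

op_sigmoid <- function(tape, x) {
  s <- sigmoid_fwd(vof(x))
  if (is.null(tape)) return(s)
  nd <- tg_node(tape, s)
  nd$backfn <- function(g) tg_acc(x, g * s * (1 - s))
  nd
}

op_linear <- function(tape, x, W, b) {
  xv <- vof(x)
  out <- sweep(xv %*% W$value, 2L, b$value, "+")
  if (is.null(tape)) return(out)
  want_dx <- is.environment(x)
  nd <- tg_node(tape, out)
  Wv <- W$value
  nd$backfn <- function(g) {
    if (want_dx) tg_acc(x, g %*% t(Wv))
    tg_acc(W, crossprod(xv, g))
    tg_acc(b, colSums(g))
  }
  nd
}

op_gmeanpool <- function(tape, x) {
  xv <- vof(x)
  d <- dim(xv)
  xm <- xv; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(xm), d[3], d[4])
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) {
    gfull <- aperm(array(g / (d[1] * d[2]), c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
    tg_acc(x, gfull)
  }
  nd
}

# weighted mean of a column-vector output: sum(w * x) / 1
op_wsum <- function(tape, x, w) {
  xv <- vof(x)
  out <- sum(w * xv)
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) tg_acc(x, array(g * w, dim(xv)))
  nd
}

# mean over batch of the per-sample sum of squares of (x - target)
op_sq_residual <- function(tape, x, target, per_sample_weight = NULL, reduce = c("mean", "sumpix")) {
  reduce <- match.arg(reduce)
  xv <- vof(x)
  r <- xv - target
  d <- dim(xv)
  nb <- d[3]
  if (reduce == "mean") {
    wfac <- 1 / length(r)
    out <- mean(r * r)
    gr <- 2 * wfac
  } else {
    # per-sample squared l2 norm (summed over pixels/channels), averaged over batch,
    # optionally weighted per sample
    rm <- aperm(r, c(1, 2, 4, 3))
    dim(rm) <- c(d[1] * d[2] * d[4], nb)
    ss <- colSums(rm * rm)
    w <- if (is.null(per_sample_weight)) rep(1, nb) else per_sample_weight
    out <- mean(w * ss)
    gr <- NULL
  }
  if (is.null(tape)) return(out)
  nd <- tg_node(tape, out)
  nd$backfn <- function(g) {
    if (reduce == "mean") {
      tg_acc(x, g * gr * r)
    } else {
      w <- if (is.null(per_sample_weight)) rep(1, nb) else per_sample_weight
      wfull <- aperm(array(rep(w, each = d[1] * d[2] * d[4]), c(d[1], d[2], d[4], nb)), c(1, 2, 4, 3))
      tg_acc(x, g * 2 * wfull * r / nb)
    }
  }
  nd
}

## ---- optimizer ----------------------------------------------------------

adam_new <- function(params, lr = 2e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  class(st) <- "tg_adam"
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$value <- p$value - st$lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + st$eps)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
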
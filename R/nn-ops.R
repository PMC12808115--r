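# Low-level array primitives for the tape engine: forward computations paired
# with hand-derived backward passes. Feature maps are laid out as
# (height, width, batch, channel) arrays so that a reshape to a
# (H*W*N) x C matrix is a no-copy view in column-major order and every
# convolution reduces to nine BLAS matrix products (one per kernel offset).

conv3_fwd <- function(x, W, b) {
  out <- .conv3_fwd_cpp(x, W, b, dim(x))
  list(out = out, x = x)
}

conv3_bwd <- function(g, x, W, want_dx = TRUE) {
  .conv3_bwd_cpp(x, W, g, dim(x), dim(W)[4], want_dx)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  out <- sweep(xm %*% W, 2L, b, "+")
  dim(out) <- c(d[1:3], ncol(W))
  out
}

conv1_bwd <- function(g, x, W) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  gm <- g; dim(gm) <- c(prod(d[1:3]), ncol(W))
  dx <- gm %*% t(W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(xm, gm), db = colSums(gm))
}

pool2_fwd <- function(x) .pool2_cpp(x, dim(x))
pool2_bwd <- function(g, din) .pool2_bwd_cpp(g, din)
up2_fwd <- function(x) .up2_cpp(x, dim(x))
up2_bwd <- function(g) .up2_bwd_cpp(g, dim(g))

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

# sinusoidal embedding of (possibly fractional) step indices, one row per sample
sin_embed <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(t, freqs)
  cbind(sin(ang), cos(ang))
}
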
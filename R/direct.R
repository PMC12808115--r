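#' Empirical loss of the deterministic baseline
#'
#' `(1/2N) sum_i |y_i - f(x_i)|^2` with the squared norm summed over pixels
#' and the average taken over the N slice pairs.
#'
#' @param state a `direct_model` (or an `mrt_backbone`).
#' @param x,y arrays (H, W, N).
#' @return scalar loss.
#' @export
direct_loss <- function(state, x, y) {
  net <- if (inherits(state, "direct_model")) state$net else state
  d <- dim(x)
  out <- backbone_forward(net, array(x, c(d, 1L)))
  rm <- (array(out, d) - y)^2
  dim(rm) <- c(d[1] * d[2], d[3])
  mean(colSums(rm)) / 2
}

#' Train the deterministic baseline by mean-squared error
#'
#' Mini-batch gradient descent (Adam) on the mean-squared reconstruction
#' error between the network output and the target slice; per-epoch training
#' loss is recorded, with optional early stopping on validation MSE.
#'
#' @param data training `paired_slice_dataset` (nonempty).
#' @param val optional validation `paired_slice_dataset` for early stopping.
#' @param epochs,batch_size,lr optimizer settings.
#' @param patience epochs without validation improvement before stopping
#'   (ignored without `val`).
#' @param base_width,depth backbone size.
#' @param seed RNG seed; identical seeds give identical loss histories.
#' @return a `direct_model` with the trained net and loss histories.
#' @export
train_direct <- function(data, val = NULL, epochs = 40L, batch_size = 8L,
                         lr = 2e-4, patience = 10L, base_width = 8L,
                         depth = 2L, seed = 1L) {
  np <- n_pairs(data)
  stop_if_not(np > 0, "empty training dataset")
  hw <- data$slice_shape
  cfg <- backbone_config(in_channels = 1L, out_channels = 1L,
                         base_width = base_width, depth = depth,
                         image_size = hw[1])
  net <- build_backbone(cfg, seed = seed)
  opt <- adam_new(net$params, lr = lr)
  hist <- numeric(0)
  val_hist <- numeric(0)
  best_val <- Inf; best_state <- NULL; stall <- 0L
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(np)
      ep_loss <- 0; nb_count <- 0L
      for (st in seq.int(1L, np, by = batch_size)) {
        idx <- ord[st:min(st + batch_size - 1L, np)]
        x <- array(data$x[, , idx, drop = FALSE], c(hw, length(idx), 1L))
        y <- array(data$y[, , idx, drop = FALSE], c(hw, length(idx), 1L))
        tape <- tg_tape()
        out <- backbone_forward(net, x, tape = tape)
        loss <- op_sq_residual(tape, out, y, reduce = "mean")
        tg_zero_grads(net$params)
        tg_backward(tape, loss)
        adam_step(opt)
        ep_loss <- ep_loss + loss$value
        nb_count <- nb_count + 1L
      }
      hist <- c(hist, ep_loss / nb_count)
      if (!is.null(val)) {
        vmse <- direct_loss(structure(list(net = net), class = "direct_model"),
                            val$x, val$y)
        val_hist <- c(val_hist, vmse)
        if (vmse < best_val - 1e-10) {
          best_val <- vmse
          best_state <- net_state(net)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      }
    }
  })
  if (!is.null(best_state)) net <- net_restore(best_state)
  structure(list(net = net, loss_history = hist, val_history = val_hist,
                 seed = seed), class = "direct_model")
}

#' Deterministic slice-wise inference
#'
#' Applies the trained network to every axial slice and restacks the result;
#' the output is clipped to [0, 1] since inputs are min-max normalized.
#'
#' @param state a `direct_model`.
#' @param input_volume a [volume()] or (S, H, W) array.
#' @param max_batch largest slice batch per forward pass.
#' @return a [volume()] of the transformed contrast.
#' @export
infer_direct <- function(state, input_volume, max_batch = 64L) {
  xarr <- if (inherits(input_volume, "volume")) input_volume$data else input_volume
  d <- dim(xarr)
  sz <- state$net$cfg$image_size
  if (d[2] != sz || d[3] != sz) {
    stop("input slice shape ", d[2], "x", d[3],
         " does not match the training size ", sz, "x", sz, call. = FALSE)
  }
  out <- array(0, d)
  for (st in seq.int(1L, d[1], by = max_batch)) {
    en <- min(st + max_batch - 1L, d[1])
    nb <- en - st + 1L
    xb <- array(0, c(d[2], d[3], nb, 1L))
    for (k in seq_len(nb)) xb[, , k, 1L] <- xarr[st + k - 1L, , ]
    yb <- backbone_forward(state$net, xb)
    for (k in seq_len(nb)) out[st + k - 1L, , ] <- clip01(yb[, , k, 1L])
  }
  volume(out, mask = if (inherits(input_volume, "volume")) input_volume$mask else NULL,
         contrast = "transformed",
         subject_id = if (inherits(input_volume, "volume")) input_volume$subject_id else "")
}
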
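# the reverse-mode engine underlying all trainers: analytic gradients must
# agree with central finite differences through every op and conditioning path

num_grad <- function(lossfn, param, i, eps = 1e-6) {
  v0 <- param$value[i]
  param$value[i] <- v0 + eps
  lp <- lossfn()
  param$value[i] <- v0 - eps
  lm <- lossfn()
  param$value[i] <- v0
  (lp - lm) / (2 * eps)
}

test_that("backbone gradients match finite differences on every conditioning path", {
  set.seed(11)
  cases <- list(
    list(cfg = backbone_config(in_channels = 2, base_width = 4, depth = 2,
                               time_conditioning = TRUE, image_size = 16),
         t = c(3, 40, 97), z = NULL,
         params = c("in0_c1_W", "enc2_c2_W", "bott_n1_g", "dec1_t_W", "te1_W", "out_W")),
    list(cfg = backbone_config(in_channels = 1, base_width = 4, depth = 1,
                               latent_dim = 6, image_size = 16, final = "sigmoid"),
         t = NULL, z = matrix(rnorm(18), 3, 6),
         params = c("in0_n1_gW", "enc1_n2_bW", "bott_c1_W", "out_W")),
    list(cfg = backbone_config(in_channels = 2, base_width = 4, depth = 2,
                               norm = "none", head = "scalar", image_size = 16),
         t = NULL, z = NULL,
         params = c("in0_c1_W", "enc2_c1_b", "head_W"))
  )
  for (cs in cases) {
    net <- build_backbone(cs$cfg, seed = 5)
    x <- array(rnorm(16 * 16 * 3 * cs$cfg$in_channels),
               c(16, 16, 3, cs$cfg$in_channels))
    target <- if (cs$cfg$head == "scalar") NULL else
      array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
    lossfn <- function() {
      tape <- tg_tape()
      out <- backbone_forward(net, x, t = cs$t, z = cs$z, tape = tape)
      loss <- if (cs$cfg$head == "scalar") op_wsum(tape, out, c(1, -2, 0.5)) else
        op_sq_residual(tape, out, target, reduce = "mean")
      list(tape = tape, loss = loss)
    }
    r <- lossfn()
    tg_zero_grads(net$params)
    tg_backward(r$tape, r$loss)
    val <- function() lossfn()$loss$value
    for (nm in cs$params) {
      p <- net$params[[nm]]
      for (i in sample(length(p$value), 2)) {
        ng <- num_grad(val, p, i)
        expect_equal(p$grad[i], ng, tolerance = 1e-4,
                     label = paste("grad", nm, "entry", i))
      }
    }
  }
})

test_that("gradient flows through the critic into its image input", {
  cfg <- backbone_config(in_channels = 2, base_width = 4, depth = 2,
                         norm = "none", head = "scalar", image_size = 16)
  net <- build_backbone(cfg, seed = 7)
  set.seed(2)
  x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  tape <- tg_tape()
  leaf <- tg_leaf(tape, x)
  out <- backbone_forward(net, leaf, tape = tape)
  s <- op_wsum(tape, out, c(1, 1))
  tg_backward(tape, s)
  i <- 137
  eps <- 1e-6
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  ng <- (sum(backbone_forward(net, xp)) - sum(backbone_forward(net, xm))) / (2 * eps)
  expect_equal(leaf$grad[i], ng, tolerance = 1e-5)
  expect_true(all(is.finite(leaf$grad)))
  expect_gt(sum(leaf$grad != 0), 0)
})

test_that("backbone output shape matches the input spatial shape", {
  cfg <- backbone_config(in_channels = 3, out_channels = 2, base_width = 4,
                         depth = 2, image_size = 16)
  net <- build_backbone(cfg, seed = 1)
  x <- array(rnorm(16 * 16 * 5 * 3), c(16, 16, 5, 3))
  out <- backbone_forward(net, x)
  expect_identical(dim(out), c(16L, 16L, 5L, 2L))
})

test_that("conditioning contracts are enforced", {
  cfg <- backbone_config(in_channels = 1, base_width = 4, depth = 1, image_size = 16)
  net <- build_backbone(cfg, seed = 1)
  x <- array(0, c(16, 16, 1, 1))
  expect_error(backbone_forward(net, x, t = 1), "time conditioning")
  expect_error(backbone_forward(net, x, z = matrix(0, 1, 4)), "latent")
  expect_error(backbone_config(image_size = 30, depth = 2), "divisible")
  cfgz <- backbone_config(in_channels = 1, base_width = 4, depth = 1,
                          latent_dim = 4, image_size = 16)
  netz <- build_backbone(cfgz, seed = 1)
  expect_error(backbone_forward(netz, x), "latent")
  expect_error(backbone_forward(netz, x, z = matrix(0, 1, 5)), "latent_dim")
})

test_that("distinct latent vectors produce distinct outputs", {
  cfg <- backbone_config(in_channels = 1, base_width = 4, depth = 1,
                         latent_dim = 8, image_size = 16)
  net <- build_backbone(cfg, seed = 3)
  set.seed(4)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  z1 <- matrix(rnorm(8), 1, 8)
  z2 <- matrix(rnorm(8), 1, 8)
  o1 <- backbone_forward(net, x, z = z1)
  o2 <- backbone_forward(net, x, z = z2)
  expect_gt(max(abs(o1 - o2)), 1e-8)
})

test_that("initialization and state round-trip are deterministic", {
  cfg <- backbone_config(in_channels = 1, base_width = 4, depth = 1, image_size = 16)
  n1 <- build_backbone(cfg, seed = 9)
  n2 <- build_backbone(cfg, seed = 9)
  expect_identical(lapply(n1$params, function(p) p$value),
                   lapply(n2$params, function(p) p$value))
  st <- net_state(n1)
  n3 <- net_restore(st)
  x <- array(rnorm(256), c(16, 16, 1, 1))
  expect_identical(backbone_forward(n1, x), backbone_forward(n3, x))
})

test_that("conditional instance normalization has the documented structure", {
  set.seed(21)
  f <- array(rnorm(8 * 8 * 2 * 3, mean = 2, sd = 3), c(8, 8, 2, 3))
  z <- matrix(rnorm(2 * 4), 2, 4)
  # maps chosen so scale = 1 and shift = 0: plain instance normalization
  out <- cin_inject(f, z, scale_W = matrix(0, 4, 3), scale_b = rep(1, 3),
                    shift_W = matrix(0, 4, 3), shift_b = rep(0, 3))
  for (n in 1:2) for (c in 1:3) {
    expect_equal(mean(out[, , n, c]), 0, tolerance = 1e-6)
    expect_equal(mean(out[, , n, c]^2), 1, tolerance = 1e-3)
  }
  expect_error(cin_inject(f, matrix(0, 2, 5), matrix(0, 4, 3), rep(1, 3),
                          matrix(0, 4, 3), rep(0, 3)), "latent")
})
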
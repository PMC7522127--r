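test_that("network configs validate their invariants", {
  expect_error(net_config_2d(dilation_rates = c(1, 2, 4)),
               class = "petseg_bad_config")
  expect_error(net_config_2d(dilation_rates = c(1, 2, 2, 4)),
               class = "petseg_bad_config")
  expect_error(net_config_2d(depth = 1), class = "petseg_bad_config")
  expect_error(net_config_3d(down_filters = c(16, 8, 32, 64)),
               class = "petseg_bad_config")
  expect_error(net_config_3d(patch_edge = c(HEAD_NECK = 30, CHEST = 64,
                                            ABDOMEN_PELVIS = 96)),
               class = "petseg_bad_config")
})

test_that("the full-size 2D U-Net maps 448x512x2 to probabilities", {
  net <- build_unet2d(net_config_2d(), seed = 1)
  x <- array(rnorm(448 * 512 * 2), c(448, 512, 2))
  # batch statistics keep an untrained net's activations in range; running
  # statistics are meaningless before any training step
  p <- unet2d_forward(net, x, train = TRUE, keep_cache = FALSE)$prob
  expect_equal(dim(p), c(448, 512))
  expect_true(all(p > 0 & p < 1))
  expect_error(unet2d_forward(net, array(0, c(100, 100, 2))),
               class = "petseg_bad_input")
})

test_that("an untrained net with zero biases emits 0.5 on zero input", {
  net <- build_unet2d(net_config_2d(depth = 3, base_filters = 4), seed = 2)
  p <- unet2d_forward(net, array(0, c(32, 32, 2)), train = FALSE)$prob
  expect_equal(unique(as.numeric(p)), 0.5)
})

test_that("doubling base filters strictly increases the parameter count", {
  n8 <- n_params(build_unet2d(net_config_2d(depth = 3, base_filters = 8),
                              seed = 1))
  n16 <- n_params(build_unet2d(net_config_2d(depth = 3, base_filters = 16),
                               seed = 1))
  expect_gt(n16, n8)
})

test_that("V-Nets preserve the cube shape for every region patch size", {
  # full filter complement at the head-neck edge
  vf <- build_vnet3d("HEAD_NECK", net_config_3d(), seed = 3)
  x <- array(rnorm(32^3 * 2), c(32, 32, 32, 2))
  p <- vnet3d_forward(vf, x)$prob
  expect_equal(dim(p), c(32, 32, 32))
  expect_true(all(p > 0 & p < 1))

  # reduced filter complement across all three region edges
  cfg <- net_config_3d(down_filters = c(2, 3, 4, 5))
  for (edge in c(32, 64, 96)) {
    v <- build_vnet3d("CHEST", cfg, seed = 4)
    x <- array(rnorm(edge^3 * 2), c(edge, edge, edge, 2))
    expect_equal(dim(vnet3d_forward(v, x)$prob), c(edge, edge, edge))
  }
  expect_error(vnet3d_forward(vf, array(0, c(30, 30, 30, 2))),
               class = "petseg_bad_input")
})

test_that("backward passes agree with finite differences", {
  set.seed(42)
  # 2D: spot-check 6 random parameters
  net <- build_unet2d(net_config_2d(depth = 3, base_filters = 2), seed = 1)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  wr <- matrix(rnorm(256), 16, 16)
  lossf <- function(n) sum(unet2d_forward(n, x, train = TRUE)$prob * wr)
  fw <- unet2d_forward(net, x, train = TRUE, keep_cache = TRUE)
  bw <- unet2d_backward(net, fw$cache, wr)
  for (nm in sample(names(net$params), 6)) {
    i <- sample(length(net$params[[nm]]), 1)
    eps <- 1e-5
    np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps; up <- lossf(np)
    np$params[[nm]][i] <- np$params[[nm]][i] - 2 * eps; dn <- lossf(np)
    num <- (up - dn) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4)
  }

  # 3D
  cfg3 <- net_config_3d(down_filters = c(2, 3, 4, 5),
                        patch_edge = c(HEAD_NECK = 16, CHEST = 16,
                                       ABDOMEN_PELVIS = 16))
  v <- build_vnet3d("CHEST", cfg3, seed = 2)
  x3 <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  wr3 <- array(rnorm(16^3), c(16, 16, 16))
  lf3 <- function(n) sum(vnet3d_forward(n, x3)$prob * wr3)
  fw3 <- vnet3d_forward(v, x3, keep_cache = TRUE)
  bw3 <- vnet3d_backward(v, fw3$cache, wr3)
  for (nm in sample(names(v$params), 6)) {
    i <- sample(length(v$params[[nm]]), 1)
    eps <- 1e-5
    np <- v; np$params[[nm]][i] <- np$params[[nm]][i] + eps; up <- lf3(np)
    np$params[[nm]][i] <- np$params[[nm]][i] - 2 * eps; dn <- lf3(np)
    expect_equal(bw3$grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("the fused single-precision eval path matches double precision", {
  tr <- trained_2d()
  ph <- test_phantom(1)
  x1 <- normalize_channels(ph$study$pet$data[60, , ], ph$study$ct$data[60, , ])
  x2 <- normalize_channels(ph$study$pet$data[140, , ], ph$study$ct$data[140, , ])
  x4 <- array(0, c(dim(x1)[1:2], 2, 2))
  x4[, , 1, ] <- x1; x4[, , 2, ] <- x2
  pd <- petseg:::unet2d_forward_batch(tr$net, x4)
  pf <- petseg:::unet2d_eval_batch(tr$net, x4)
  p1 <- unet2d_forward(tr$net, x1, train = FALSE)$prob
  expect_equal(pd[, , 1], p1, tolerance = 1e-12)     # batching is exact
  expect_lt(max(abs(pf - pd)), 1e-5)                 # float path at rounding level
})

test_that("training reduces the loss by at least half (smoke property)", {
  h <- trained_2d()$history
  expect_lt(utils::tail(h$loss, 1), 0.5 * h$loss[1])
})

test_that("dilated blocks have strictly larger receptive fields", {
  rf_dilated <- receptive_field(c(1, 2, 4, 8))
  rf_plain <- receptive_field(c(1, 1, 1, 1))
  expect_gt(rf_dilated, rf_plain)
  expect_equal(rf_plain, 5)        # two chained 3x3 convolutions
  expect_equal(rf_dilated, 33)     # dilation 8 dominates
})

test_that("checkpoints restore predictions bit-for-bit", {
  tr <- trained_2d()
  dir <- file.path(tempdir(), "ckpt")
  save_checkpoint(tr$net, dir, "unet2d")
  back <- load_checkpoint(dir, "unet2d")
  ph <- test_phantom(1)
  x <- normalize_channels(ph$study$pet$data[60, , ], ph$study$ct$data[60, , ])
  expect_identical(unet2d_forward(back, x)$prob,
                   unet2d_forward(tr$net, x)$prob)
})
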
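# Reference implementations: naive per-voxel loops, kept deliberately
# independent of the vectorised package code.

ref_dice <- function(p, y) {
  eps <- 1e-6
  inter <- 0; sp <- 0; sy <- 0
  for (i in seq_along(p)) {
    inter <- inter + p[i] * y[i]; sp <- sp + p[i]; sy <- sy + y[i]
  }
  1 - (2 * inter + eps) / (sp + sy + eps)
}

ref_wbce <- function(p, y) {
  n <- length(y)
  w <- n / max(sum(y), 1)
  tot <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], 1e-7), 1 - 1e-7)
    tot <- tot - (w * y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  tot / n
}

ref_loss3d <- function(p, y) {
  eps <- 1e-6
  inter <- sum_p <- sum_y <- mae <- 0
  for (i in seq_along(p)) {
    inter <- inter + p[i] * y[i]; sum_p <- sum_p + p[i]; sum_y <- sum_y + y[i]
    mae <- mae + abs(y[i] - p[i])
  }
  (1 - (2 * inter + eps) / (sum_p + sum_y + eps)) +
    (1 - (inter + eps) / (sum_y + eps)) + mae / length(p)
}

test_that("compound losses match the per-voxel reference on random tensors", {
  set.seed(100)
  for (i in 1:100) {
    d <- sample(3:8, 2)
    p <- matrix(runif(prod(d)), d[1], d[2])
    y <- matrix(rbinom(prod(d), 1, runif(1, 0, 0.6)), d[1], d[2])
    l2 <- loss_2d(p, y)
    expect_equal(l2$dice_term, ref_dice(p, y), tolerance = 1e-6)
    expect_equal(l2$ce_term, ref_wbce(p, y), tolerance = 1e-6)
    expect_equal(l2$total, l2$dice_term + l2$ce_term, tolerance = 1e-9)

    d3 <- sample(3:5, 3, replace = TRUE)
    p3 <- array(runif(prod(d3)), d3)
    y3 <- array(rbinom(prod(d3), 1, 0.3), d3)
    l3 <- loss_3d(p3, y3)
    expect_equal(l3$total, ref_loss3d(p3, y3), tolerance = 1e-6)
    expect_equal(l3$total, l3$dice_term + l3$sensitivity_term + l3$mae_term,
                 tolerance = 1e-9)
  }
})

test_that("analytic loss anchors hold", {
  y <- array(0, c(4, 4, 4)); y[2:3, 2:3, 2:3] <- 1

  # perfect prediction
  expect_lt(loss_3d(y, y)$total, 1e-5)
  expect_lt(loss_2d(y[, , 1], y[, , 1])$total, 1e-5)

  # hard complement: each 3D term is maximal
  l <- loss_3d(1 - y, y)
  expect_equal(l$dice_term, 1, tolerance = 1e-5)
  expect_equal(l$sensitivity_term, 1, tolerance = 1e-5)
  expect_equal(l$mae_term, 1, tolerance = 1e-9)
  expect_equal(l$total, 3, tolerance = 1e-4)

  # disjoint hard prediction has Dice term 1
  p <- array(0, c(4, 4, 4)); p[1, 1, ] <- 1
  expect_equal(soft_dice_term(p, y), 1, tolerance = 1e-5)

  # both empty: Dice term defined as 0
  expect_equal(soft_dice_term(array(0, c(3, 3, 3)), array(0, c(3, 3, 3))), 0)
})

test_that("hand-computed values for the Dice bracket and weighted BCE", {
  # |P| = 4, |T| = 4, |P n T| = 2 -> 1 - 4/8 = 0.5
  p <- c(1, 1, 1, 1, 0, 0, 0, 0)
  y <- c(1, 1, 0, 0, 1, 1, 0, 0)
  dim(p) <- dim(y) <- c(2, 4)
  expect_equal(soft_dice_term(p, y), 0.5, tolerance = 1e-6)

  # 2-voxel case: w = 2, -(2 log .5 + log .5)/2 = 1.5 log 2
  expect_equal(weighted_bce_term(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)),
               1.5 * log(2), tolerance = 1e-9)

  # all-negative target: the weighted positive term vanishes
  expect_equal(weighted_bce_term(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               log(2), tolerance = 1e-9)

  # perfect hard prediction: clipped logs stay tiny
  yb <- matrix(c(1, 0, 0, 1), 2)
  expect_lt(weighted_bce_term(yb, yb), 1e-5)
})

test_that("the literal printed cross-entropy variant is exposed", {
  set.seed(12)
  p <- matrix(runif(36), 6); y <- matrix(rbinom(36, 1, 0.2), 6)
  w <- 36 / sum(y)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  manual <- -mean(w * (y * log(pc) + (1 - w) * (1 - y) * log(1 - pc)))
  expect_equal(weighted_bce_term(p, y, form = "printed"), manual,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(weighted_bce_term(p, y, form = "printed"),
                                weighted_bce_term(p, y))))
})

test_that("loss bounds and term ranges hold on random inputs", {
  set.seed(13)
  for (i in 1:25) {
    p <- array(runif(64), c(4, 4, 4))
    y <- array(rbinom(64, 1, runif(1)), c(4, 4, 4))
    l <- loss_3d(p, y)
    expect_gte(l$dice_term, 0); expect_lte(l$dice_term, 1)
    expect_gte(l$sensitivity_term, 0); expect_lte(l$sensitivity_term, 1)
    expect_gte(l$mae_term, 0); expect_lte(l$mae_term, 1)
    expect_gte(l$total, 0); expect_lte(l$total, 3)
  }
})

test_that("moving a prediction toward its target never increases the 3D loss", {
  set.seed(14)
  for (rep in 1:20) {
    p <- array(runif(27), c(3, 3, 3))
    y <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
    i <- sample(27, 1)
    p2 <- p
    p2[i] <- p[i] + 0.5 * (y[i] - p[i])     # halfway toward the target
    expect_lte(loss_3d(p2, y)$total, loss_3d(p, y)$total + 1e-12)
  }
})

test_that("shape mismatches are rejected", {
  expect_error(loss_2d(matrix(0, 2, 2), matrix(0, 2, 3)),
               class = "petseg_shape_mismatch")
  expect_error(loss_3d(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))),
               class = "petseg_shape_mismatch")
  expect_error(soft_dice_term(matrix(0, 2, 2), matrix(0, 3, 2)),
               class = "petseg_shape_mismatch")
})
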
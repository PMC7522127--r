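#' Configuration for the 2D dilated separable residual U-Net
#'
#' The slice-segmentation network is a U-Net whose convolutional blocks are
#' replaced by pairs of residual sub-blocks. Inside each sub-block the
#' convolutions are depthwise-separable and evaluated at four dilation rates
#' in parallel; the four scales are merged (concatenated, then fused by a
#' pointwise convolution -- additive merging is available as an alternative)
#' and batch-normalised. Downsampling is 2x2 max pooling, upsampling is
#' nearest-neighbour, skip connections concatenate encoder features into the
#' decoder, and a final pointwise convolution plus sigmoid emits a per-pixel
#' tumor probability.
#'
#' @param depth number of resolution levels (default 6; >= 2). The input
#'   height/width must be divisible by `2^(depth-1)`.
#' @param base_filters filters at the top level (doubled per level; default 8).
#' @param dilation_rates exactly 4 strictly increasing rates, default 1,2,4,8.
#' @param kernel spatial kernel size of the depthwise convolutions (odd).
#' @param in_channels input channels (2: PET and CT).
#' @param out_channels output channels (1 probability map).
#' @param merge `"concat"` (default) or `"add"` for the dilation branches.
#' @param input_hw nominal input size (rows, cols), default c(448, 512); used
#'   by [predict_2d()] when fitting slices. `NULL` means "pad each slice to
#'   the nearest valid size".
#' @return a `net_config_2d`.
#' @export
net_config_2d <- function(depth = 6, base_filters = 8,
                          dilation_rates = c(1, 2, 4, 8), kernel = 3,
                          in_channels = 2, out_channels = 1,
                          merge = c("concat", "add"),
                          input_hw = c(448, 512)) {
  merge <- match.arg(merge)
  if (length(dilation_rates) != 4 || any(diff(dilation_rates) <= 0))
    petseg_abort("dilation_rates must be 4 strictly increasing values",
                 "bad_config")
  if (depth < 2) petseg_abort("depth must be at least 2", "bad_config")
  if (kernel %% 2 != 1) petseg_abort("kernel must be odd", "bad_config")
  structure(list(depth = depth, base_filters = base_filters,
                 dilation_rates = as.integer(dilation_rates),
                 kernel = as.integer(kernel),
                 in_channels = in_channels, out_channels = out_channels,
                 merge = merge, input_hw = input_hw),
            class = "net_config_2d")
}

rb2_init <- function(penv, senv, prefix, Cin, Cout, cfg) {
  sepdil_init(penv, paste0(prefix, ".c1"), Cin, Cout, cfg)
  bn_init(penv, paste0(prefix, ".bn1"), Cout)
  bn_state_init(senv, paste0(prefix, ".bn1"), Cout)
  sepdil_init(penv, paste0(prefix, ".c2"), Cout, Cout, cfg)
  bn_init(penv, paste0(prefix, ".bn2"), Cout)
  bn_state_init(senv, paste0(prefix, ".bn2"), Cout)
  if (Cin != Cout)
    add_param(penv, paste0(prefix, ".proj"), he_init(c(Cin, Cout), Cin))
}

#' Build the 2D U-Net
#'
#' @param cfg a [net_config_2d()].
#' @param seed optional RNG seed for weight initialisation (He init).
#' @return a network object of class `unet2d` (list: cfg, params, state).
#' @export
build_unet2d <- function(cfg = net_config_2d(), seed = NULL) {
  stopifnot(inherits(cfg, "net_config_2d"))
  build <- function() {
    penv <- param_env(); senv <- param_env()
    ch <- cfg$base_filters * 2^(seq_len(cfg$depth) - 1)
    for (i in seq_len(cfg$depth)) {
      cin <- if (i == 1) cfg$in_channels else ch[i - 1]
      rb2_init(penv, senv, sprintf("enc%d.b1", i), cin, ch[i], cfg)
      rb2_init(penv, senv, sprintf("enc%d.b2", i), ch[i], ch[i], cfg)
    }
    for (i in rev(seq_len(cfg$depth - 1))) {
      cin <- ch[i + 1] + ch[i]       # upsampled + skip concat
      rb2_init(penv, senv, sprintf("dec%d.b1", i), cin, ch[i], cfg)
      rb2_init(penv, senv, sprintf("dec%d.b2", i), ch[i], ch[i], cfg)
    }
    add_param(penv, "final.w", he_init(c(ch[1], cfg$out_channels), ch[1]))
    add_param(penv, "final.b", numeric(cfg$out_channels))
    structure(list(cfg = cfg, params = env_to_list(penv),
                   state = env_to_list(senv)),
              class = "unet2d")
  }
  if (is.null(seed)) build() else withr_seed(seed, build())
}

#' @export
print.unet2d <- function(x, ...) {
  cat(sprintf("<unet2d> depth %d, base %d, rates %s, %s merge, %d parameters\n",
              x$cfg$depth, x$cfg$base_filters,
              paste(x$cfg$dilation_rates, collapse = ","),
              x$cfg$merge, n_params(x)))
  invisible(x)
}

rb2_fw <- function(net, prefix, x, train) {
  c1 <- sepdil_fw(net, paste0(prefix, ".c1"), x)
  b1 <- bn_fw(net, paste0(prefix, ".bn1"), c1$y, train)
  a1 <- .mask_pos_cpp(b1$y, b1$y)                     # ReLU
  c2 <- sepdil_fw(net, paste0(prefix, ".c2"), a1)
  b2 <- bn_fw(net, paste0(prefix, ".bn2"), c2$y, train)
  pj <- net$params[[paste0(prefix, ".proj")]]
  skip <- if (is.null(pj)) x else {
    s <- as_mat(x) %*% pj
    dim(s) <- c(dim(x)[1], dim(x)[2], ncol(pj))
    s
  }
  y <- .add_relu_cpp(b2$y, skip)
  list(y = y,
       cache = list(c1 = c1$cache, bn1 = b1$cache, a1 = a1,
                    c2 = c2$cache, bn2 = b2$cache, x = x, y = y,
                    has_proj = !is.null(pj)))
}

rb2_bw <- function(net, prefix, dy, cache, grads) {
  dpre <- .mask_pos_cpp(dy, cache$y)
  # skip path
  if (cache$has_proj) {
    pj <- net$params[[paste0(prefix, ".proj")]]
    dpm <- as_mat(dpre)
    grads[[paste0(prefix, ".proj")]] <- crossprod(as_mat(cache$x), dpm)
    dskip <- tcrossprod(dpm, pj)
    dim(dskip) <- dim(cache$x)
  } else {
    dskip <- dpre
  }
  # main path
  r <- bn_bw(net, cache$bn2, dpre, grads); grads <- r$grads
  r <- sepdil_bw(net, paste0(prefix, ".c2"), r$dx, cache$c2, grads)
  grads <- r$grads
  da1 <- .mask_pos_cpp(r$dx, cache$a1)
  r <- bn_bw(net, cache$bn1, da1, grads); grads <- r$grads
  r <- sepdil_bw(net, paste0(prefix, ".c1"), r$dx, cache$c1, grads)
  grads <- r$grads
  list(dx = r$dx + dskip, grads = grads)
}

#' Forward pass of the 2D U-Net
#'
#' @param net a `unet2d`.
#' @param x input array (H, W, in_channels); H and W divisible by
#'   `2^(depth-1)`.
#' @param train use batch statistics (TRUE) or running statistics (FALSE).
#' @param keep_cache retain intermediate tensors for [unet2d_backward()].
#' @return list with `prob` (H, W matrix in (0,1)) and (optionally) `cache`.
#' @export
unet2d_forward <- function(net, x, train = FALSE, keep_cache = train) {
  cfg <- net$cfg
  d <- dim(x)
  div <- 2^(cfg$depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    petseg_abort(sprintf("input %dx%d not divisible by %d", d[1], d[2], div),
                 "bad_input")
  if (d[3] != cfg$in_channels)
    petseg_abort("channel mismatch", "bad_input")

  enc <- list(); caches <- list()
  h <- x
  for (i in seq_len(cfg$depth)) {
    r1 <- rb2_fw(net, sprintf("enc%d.b1", i), h, train)
    r2 <- rb2_fw(net, sprintf("enc%d.b2", i), r1$y, train)
    enc[[i]] <- r2$y
    caches[[sprintf("enc%d", i)]] <- list(b1 = r1$cache, b2 = r2$cache)
    if (i < cfg$depth) {
      mp <- .maxpool2_fw_cpp(r2$y)
      caches[[sprintf("pool%d", i)]] <- list(idx = mp$idx, dims = dim(r2$y))
      h <- mp$y
    }
  }
  h <- enc[[cfg$depth]]
  for (i in rev(seq_len(cfg$depth - 1))) {
    u <- .up2_fw_cpp(h)
    d_u <- dim(u); d_s <- dim(enc[[i]])
    cat_in <- array(c(u, enc[[i]]), c(d_u[1], d_u[2], d_u[3] + d_s[3]))
    r1 <- rb2_fw(net, sprintf("dec%d.b1", i), cat_in, train)
    r2 <- rb2_fw(net, sprintf("dec%d.b2", i), r1$y, train)
    caches[[sprintf("dec%d", i)]] <- list(b1 = r1$cache, b2 = r2$cache,
                                          c_up = d_u[3])
    h <- r2$y
  }
  hm <- as_mat(h)
  logits <- hm %*% net$params[["final.w"]]
  logits <- logits + net$params[["final.b"]][1]
  dim(logits) <- d[1:2]
  prob <- sigmoid(logits)
  out <- list(prob = prob)
  if (keep_cache) out$cache <- list(layers = caches, h_final = h, prob = prob)
  out
}

#' Backward pass of the 2D U-Net
#'
#' @param net a `unet2d`; @param cache from [unet2d_forward()] with
#'   `keep_cache = TRUE`; @param dprob gradient of the loss w.r.t. the output
#'   probabilities (H, W matrix).
#' @return list with `grads` (flat named list) and `bn_updates` (running-stat
#'   updates to apply via the training loop).
#' @export
unet2d_backward <- function(net, cache, dprob) {
  cfg <- net$cfg
  caches <- cache$layers
  grads <- list()
  p <- cache$prob
  dlogits <- dprob * p * (1 - p)
  dlm <- matrix(as.numeric(dlogits), ncol = 1)
  grads[["final.w"]] <- crossprod(as_mat(cache$h_final), dlm)
  grads[["final.b"]] <- sum(dlm)
  dh <- tcrossprod(dlm, net$params[["final.w"]])
  dim(dh) <- dim(cache$h_final)

  bn_caches <- list()
  collect_bn <- function(cc) {
    bn_caches[[length(bn_caches) + 1]] <<- cc$bn1
    bn_caches[[length(bn_caches) + 1]] <<- cc$bn2
  }

  for (i in seq_len(cfg$depth - 1)) {
    cc <- caches[[sprintf("dec%d", i)]]
    collect_bn(cc$b1); collect_bn(cc$b2)
    r <- rb2_bw(net, sprintf("dec%d.b2", i), dh, cc$b2, grads); grads <- r$grads
    r <- rb2_bw(net, sprintf("dec%d.b1", i), r$dx, cc$b1, grads); grads <- r$grads
    dcat <- r$dx
    d_c <- dim(dcat)
    du <- array(dcat[, , seq_len(cc$c_up)], c(d_c[1], d_c[2], cc$c_up))
    dskip <- array(dcat[, , (cc$c_up + 1):d_c[3]],
                   c(d_c[1], d_c[2], d_c[3] - cc$c_up))
    dh_below <- .up2_bw_cpp(du)
    # encoder skip gradient is consumed when we reach that encoder level
    caches[[sprintf("enc%d", i)]]$dskip <- dskip
    dh <- dh_below
  }
  # dh now flows into the bottom encoder level
  for (i in rev(seq_len(cfg$depth))) {
    cc <- caches[[sprintf("enc%d", i)]]
    collect_bn(cc$b1); collect_bn(cc$b2)
    dtop <- if (i == cfg$depth) dh else {
      pl <- caches[[sprintf("pool%d", i)]]
      dpool <- .maxpool2_bw_cpp(pl$idx, dh, as.integer(pl$dims))
      dpool + cc$dskip
    }
    r <- rb2_bw(net, sprintf("enc%d.b2", i), dtop, cc$b2, grads); grads <- r$grads
    r <- rb2_bw(net, sprintf("enc%d.b1", i), r$dx, cc$b1, grads); grads <- r$grads
    dh <- r$dx
  }
  list(grads = grads, bn_caches = bn_caches)
}

#' Analytic receptive field of the dilated multi-scale block
#'
#' One depthwise 3x3 convolution at dilation r sees `2r + 1` pixels per axis;
#' a residual sub-block chains two such convolutions. The block's receptive
#' field is governed by the largest dilation rate, so a dilated block always
#' strictly exceeds an equally deep non-dilated block (rates all 1) whenever
#' `max(rates) > 1`.
#'
#' @param rates dilation rates; @param kernel kernel size;
#' @param n_convs chained convolutions (2 per residual sub-block).
#' @return receptive field edge length in pixels.
#' @export
receptive_field <- function(rates, kernel = 3, n_convs = 2) {
  1 + n_convs * (kernel - 1) * max(rates)
}

# Evaluation-mode batched forward: x4 is (H, W, B, in_channels) -- a stack of
# B same-shaped slices, channels last. Used by predict_2d to amortise
# per-slice overhead; results are identical to per-slice evaluation.
unet2d_forward_batch <- function(net, x4) {
  cfg <- net$cfg
  d <- dim(x4)
  div <- 2^(cfg$depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    petseg_abort("batched input not divisible by the pooling factor", "bad_input")

  sep_b <- function(prefix, x) {
    .sepdil_fw_batch_cpp(x, sepdil_params(net, prefix),
                         net$params[[paste0(prefix, ".pw")]],
                         net$params[[paste0(prefix, ".b")]],
                         cfg$dilation_rates, cfg$kernel)
  }
  bn_b <- function(prefix, x) {
    .bn_fw_cpp(x, net$params[[paste0(prefix, ".gamma")]],
               net$params[[paste0(prefix, ".beta")]],
               net$state[[paste0(prefix, ".run_mean")]],
               net$state[[paste0(prefix, ".run_var")]],
               FALSE, BN_EPS)$y
  }
  rb_b <- function(prefix, x) {
    h <- sep_b(paste0(prefix, ".c1"), x)
    h <- bn_b(paste0(prefix, ".bn1"), h)
    h <- .mask_pos_cpp(h, h)
    h2 <- bn_b(paste0(prefix, ".bn2"), sep_b(paste0(prefix, ".c2"), h))
    pj <- net$params[[paste0(prefix, ".proj")]]
    skip <- if (is.null(pj)) x else {
      s <- as_mat(x) %*% pj
      dim(s) <- c(dim(x)[1:3], ncol(pj))
      s
    }
    .add_relu_cpp(h2, skip)
  }
  pool_b <- function(x) {
    dd <- dim(x)
    dim(x) <- c(dd[1], dd[2], dd[3] * dd[4])
    y <- .maxpool2_fw_cpp(x)$y
    dim(y) <- c(dd[1] / 2, dd[2] / 2, dd[3], dd[4])
    y
  }
  up_b <- function(x) {
    dd <- dim(x)
    dim(x) <- c(dd[1], dd[2], dd[3] * dd[4])
    y <- .up2_fw_cpp(x)
    dim(y) <- c(dd[1] * 2, dd[2] * 2, dd[3], dd[4])
    y
  }

  enc <- list()
  h <- x4
  for (i in seq_len(cfg$depth)) {
    h <- rb_b(sprintf("enc%d.b1", i), h)
    h <- rb_b(sprintf("enc%d.b2", i), h)
    enc[[i]] <- h
    if (i < cfg$depth) h <- pool_b(h)
  }
  h <- enc[[cfg$depth]]
  for (i in rev(seq_len(cfg$depth - 1))) {
    u <- up_b(h)
    du <- dim(u); ds <- dim(enc[[i]])
    cat_in <- array(c(u, enc[[i]]), c(du[1:3], du[4] + ds[4]))
    h <- rb_b(sprintf("dec%d.b1", i), cat_in)
    h <- rb_b(sprintf("dec%d.b2", i), h)
  }
  logits <- as_mat(h) %*% net$params[["final.w"]] + net$params[["final.b"]][1]
  dim(logits) <- d[1:3]
  sigmoid(logits)
}

# Fold evaluation-mode batch norm (affine per channel) into the pointwise
# convolution weights, producing the layer list consumed by the fused
# single-precision C++ evaluation path.
unet2d_fold_eval <- function(net) {
  cfg <- net$cfg
  nr <- length(cfg$dilation_rates)
  fold_rb <- function(prefix) {
    fold_one <- function(cp, bp) {
      g <- net$params[[paste0(bp, ".gamma")]]
      be <- net$params[[paste0(bp, ".beta")]]
      mu <- net$state[[paste0(bp, ".run_mean")]]
      v <- net$state[[paste0(bp, ".run_var")]]
      s <- g / sqrt(v + BN_EPS)
      pw <- net$params[[paste0(cp, ".pw")]]
      b <- net$params[[paste0(cp, ".b")]]
      list(pw = sweep(pw, 2, s, `*`), b = (b - mu) * s + be)
    }
    f1 <- fold_one(paste0(prefix, ".c1"), paste0(prefix, ".bn1"))
    f2 <- fold_one(paste0(prefix, ".c2"), paste0(prefix, ".bn2"))
    list(dws1 = sepdil_params(net, paste0(prefix, ".c1")),
         pw1 = f1$pw, b1 = f1$b,
         dws2 = sepdil_params(net, paste0(prefix, ".c2")),
         pw2 = f2$pw, b2 = f2$b,
         proj = net$params[[paste0(prefix, ".proj")]])
  }
  enc <- lapply(seq_len(cfg$depth), function(i)
    list(fold_rb(sprintf("enc%d.b1", i)), fold_rb(sprintf("enc%d.b2", i))))
  dec <- lapply(rev(seq_len(cfg$depth - 1)), function(i)
    list(fold_rb(sprintf("dec%d.b1", i)), fold_rb(sprintf("dec%d.b2", i))))
  list(enc = enc, dec = dec,
       final_w = net$params[["final.w"]],
       final_b = net$params[["final.b"]][1])
}

# Batched single-precision evaluation (see src/unet_eval.cpp). `folded` may
# be precomputed with unet2d_fold_eval() to amortise the BN folding.
unet2d_eval_batch <- function(net, x4, folded = NULL) {
  if (is.null(folded)) folded <- unet2d_fold_eval(net)
  .unet2d_eval_cpp(x4, folded, net$cfg$dilation_rates, net$cfg$kernel,
                   net$cfg$depth)
}
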
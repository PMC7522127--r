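#' Configuration for the region-specific 3D V-Net
#'
#' The refinement network is a volumetric encoder/decoder with residual
#' stages. The encoder has four blocks with 16, 32, 64 and 128 filters; the
#' first operates at full resolution and each later block starts with a
#' stride-2 convolution, so three downsamplings are traversed and the three
#' upsampling blocks of the decoder restore full resolution (the output cube
#' matches the input cube). All convolutions are 3x3x3 with ReLU activations;
#' a final pointwise convolution plus sigmoid emits voxel probabilities.
#' Patch edges are region-specific, reflecting typical lesion sizes: 32 in
#' the head-neck, 64 in the chest, 96 in the abdomen-pelvis.
#'
#' @param down_filters strictly increasing filter counts, length 4
#'   (default c(16, 32, 64, 128)).
#' @param kernel kernel size (default 3).
#' @param in_channels input channels (2: PET and CT).
#' @param patch_edge named patch edge per region; each edge must be divisible
#'   by `2^3` (the downsamplings traversed).
#' @return a `net_config_3d`.
#' @export
net_config_3d <- function(down_filters = c(16, 32, 64, 128), kernel = 3,
                          in_channels = 2,
                          patch_edge = c(HEAD_NECK = 32, CHEST = 64,
                                         ABDOMEN_PELVIS = 96)) {
  if (length(down_filters) != 4 || any(diff(down_filters) <= 0))
    petseg_abort("down_filters must be 4 strictly increasing values",
                 "bad_config")
  n_down <- length(down_filters) - 1      # stride-2 stages traversed
  if (any(patch_edge %% 2^n_down != 0))
    petseg_abort(sprintf("patch edges must be divisible by %d", 2^n_down),
                 "bad_config")
  structure(list(down_filters = as.integer(down_filters),
                 n_up_blocks = n_down, kernel = as.integer(kernel),
                 in_channels = in_channels, patch_edge = patch_edge),
            class = "net_config_3d")
}

conv3_init <- function(env, prefix, Cin, Cout, k) {
  add_param(env, paste0(prefix, ".w"), he_init(c(k, k, k, Cin, Cout),
                                               k^3 * Cin))
  add_param(env, paste0(prefix, ".b"), numeric(Cout))
}

conv3_fw <- function(net, prefix, x, stride = 1L) {
  w <- net$params[[paste0(prefix, ".w")]]
  y <- .conv3_fw_cpp(x, w, net$params[[paste0(prefix, ".b")]],
                     dim(w)[1], as.integer(stride))
  list(y = y, cache = list(x = x, stride = as.integer(stride)))
}

conv3_bw <- function(net, prefix, dy, cache, grads) {
  w <- net$params[[paste0(prefix, ".w")]]
  g <- .conv3_bw_cpp(cache$x, w, dy, dim(w)[1], cache$stride)
  grads[[paste0(prefix, ".w")]] <- g$dw
  grads[[paste0(prefix, ".b")]] <- g$db
  list(dx = g$dx, grads = grads)
}

# Residual stage: two 3^3 convolutions with ReLU, additive identity skip
# (pointwise projection when the channel count changes).
rs3_init <- function(env, prefix, Cin, Cout, k) {
  conv3_init(env, paste0(prefix, ".c1"), Cin, Cout, k)
  conv3_init(env, paste0(prefix, ".c2"), Cout, Cout, k)
  if (Cin != Cout) conv3_init(env, paste0(prefix, ".proj"), Cin, Cout, 1L)
}

rs3_fw <- function(net, prefix, x) {
  c1 <- conv3_fw(net, paste0(prefix, ".c1"), x)
  a1 <- relu_fw(c1$y)
  c2 <- conv3_fw(net, paste0(prefix, ".c2"), a1)
  pj <- net$params[[paste0(prefix, ".proj.w")]]
  skip <- if (is.null(pj)) x else
    conv3_fw(net, paste0(prefix, ".proj"), x)$y
  pre <- c2$y + skip
  y <- relu_fw(pre)
  list(y = y, cache = list(c1 = c1$cache, a1pos = c1$y > 0, a1 = a1,
                           c2 = c2$cache, pre_pos = pre > 0, x = x,
                           has_proj = !is.null(pj)))
}

rs3_bw <- function(net, prefix, dy, cache, grads) {
  dpre <- dy * cache$pre_pos
  if (cache$has_proj) {
    r <- conv3_bw(net, paste0(prefix, ".proj"), dpre,
                  list(x = cache$x, stride = 1L), grads)
    grads <- r$grads
    dskip <- r$dx
  } else dskip <- dpre
  r <- conv3_bw(net, paste0(prefix, ".c2"), dpre, cache$c2, grads)
  grads <- r$grads
  da1 <- r$dx * cache$a1pos
  r <- conv3_bw(net, paste0(prefix, ".c1"), da1, cache$c1, grads)
  grads <- r$grads
  list(dx = r$dx + dskip, grads = grads)
}

#' Build a region-specific 3D V-Net
#'
#' @param region `"HEAD_NECK"`, `"CHEST"` or `"ABDOMEN_PELVIS"`; recorded on
#'   the model and used to select the patch edge.
#' @param cfg a [net_config_3d()].
#' @param seed optional RNG seed for initialisation.
#' @return a network object of class `vnet3d`.
#' @export
build_vnet3d <- function(region = c("HEAD_NECK", "CHEST", "ABDOMEN_PELVIS"),
                         cfg = net_config_3d(), seed = NULL) {
  region <- match.arg(region)
  stopifnot(inherits(cfg, "net_config_3d"))
  build <- function() {
    penv <- param_env()
    f <- cfg$down_filters
    k <- cfg$kernel
    conv3_init(penv, "stem", cfg$in_channels, f[1], k)
    rs3_init(penv, "enc1", f[1], f[1], k)
    for (i in 2:4) {
      conv3_init(penv, sprintf("down%d", i), f[i - 1], f[i], k)  # stride 2
      rs3_init(penv, sprintf("enc%d", i), f[i], f[i], k)
    }
    for (i in 3:1) {
      conv3_init(penv, sprintf("upc%d", i), f[i + 1], f[i], k)
      rs3_init(penv, sprintf("dec%d", i), 2 * f[i], f[i], k)
    }
    conv3_init(penv, "final", f[1], 1L, 1L)
    structure(list(cfg = cfg, region = region, params = env_to_list(penv),
                   state = list()),
              class = "vnet3d")
  }
  if (is.null(seed)) build() else withr_seed(seed, build())
}

#' @export
print.vnet3d <- function(x, ...) {
  cat(sprintf("<vnet3d %s> filters %s, patch %d, %d parameters\n",
              x$region, paste(x$cfg$down_filters, collapse = ","),
              x$cfg$patch_edge[[x$region]], n_params(x)))
  invisible(x)
}

#' Forward pass of the 3D V-Net
#'
#' @param net a `vnet3d`; @param x input array (D, H, W, in_channels) with
#'   spatial dims divisible by 8.
#' @param keep_cache retain intermediates for [vnet3d_backward()].
#' @return list with `prob` (D, H, W array in (0,1)) and optionally `cache`.
#' @export
vnet3d_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$cfg
  d <- dim(x)
  if (length(d) != 4 || d[4] != cfg$in_channels)
    petseg_abort("expected a (D, H, W, channels) input", "bad_input")
  if (any(d[1:3] %% 2^cfg$n_up_blocks != 0))
    petseg_abort(sprintf("spatial dims must be divisible by %d",
                         2^cfg$n_up_blocks), "bad_input")
  caches <- list()
  st <- conv3_fw(net, "stem", x)
  h <- relu_fw(st$y)
  caches$stem <- st$cache; caches$stem_pos <- st$y > 0
  enc <- list()
  for (i in 1:4) {
    if (i > 1) {
      dn <- conv3_fw(net, sprintf("down%d", i), h, stride = 2L)
      caches[[sprintf("down%d", i)]] <- dn$cache
      caches[[sprintf("down%d_pos", i)]] <- dn$y > 0
      h <- relu_fw(dn$y)
    }
    rs <- rs3_fw(net, sprintf("enc%d", i), h)
    caches[[sprintf("enc%d", i)]] <- rs$cache
    enc[[i]] <- rs$y
    h <- rs$y
  }
  for (i in 3:1) {
    u <- .up3_fw_cpp(h)
    uc <- conv3_fw(net, sprintf("upc%d", i), u)
    caches[[sprintf("upc%d", i)]] <- uc$cache
    caches[[sprintf("upc%d_pos", i)]] <- uc$y > 0
    a <- relu_fw(uc$y)
    ds <- dim(a)
    cat_in <- array(c(a, enc[[i]]), c(ds[1:3], 2 * ds[4]))
    caches[[sprintf("cat%d_c", i)]] <- ds[4]
    rs <- rs3_fw(net, sprintf("dec%d", i), cat_in)
    caches[[sprintf("dec%d", i)]] <- rs$cache
    h <- rs$y
  }
  fl <- conv3_fw(net, "final", h)
  logits <- fl$y
  dim(logits) <- d[1:3]
  prob <- sigmoid(logits)
  out <- list(prob = prob)
  if (keep_cache) out$cache <- list(layers = caches, h_final = h, prob = prob)
  out
}

#' Backward pass of the 3D V-Net
#'
#' @param net a `vnet3d`; @param cache from `vnet3d_forward(keep_cache=TRUE)`;
#' @param dprob loss gradient w.r.t. output probabilities (D, H, W array).
#' @return list with `grads`.
#' @export
vnet3d_backward <- function(net, cache, dprob) {
  caches <- cache$layers
  grads <- list()
  p <- cache$prob
  dlog <- dprob * p * (1 - p)
  dim(dlog) <- c(dim(p), 1L)
  r <- conv3_bw(net, "final", dlog, list(x = cache$h_final, stride = 1L), grads)
  grads <- r$grads
  dh <- r$dx
  denc <- list()   # gradient accumulators for encoder outputs
  for (i in 1:3) {
    r <- rs3_bw(net, sprintf("dec%d", i), dh, caches[[sprintf("dec%d", i)]], grads)
    grads <- r$grads
    cu <- caches[[sprintf("cat%d_c", i)]]
    dc <- r$dx
    ds <- dim(dc)
    da <- array(dc[, , , seq_len(cu)], c(ds[1:3], cu))
    denc[[i]] <- array(dc[, , , (cu + 1):ds[4]], c(ds[1:3], ds[4] - cu))
    duc <- da * caches[[sprintf("upc%d_pos", i)]]
    r <- conv3_bw(net, sprintf("upc%d", i), duc, caches[[sprintf("upc%d", i)]], grads)
    grads <- r$grads
    dh <- .up3_bw_cpp(r$dx)
  }
  # dh is now the gradient at enc4's output
  for (i in 4:1) {
    dtot <- if (i == 4) dh else dh + denc[[i]]
    r <- rs3_bw(net, sprintf("enc%d", i), dtot, caches[[sprintf("enc%d", i)]], grads)
    grads <- r$grads
    if (i > 1) {
      dd <- r$dx * caches[[sprintf("down%d_pos", i)]]
      r <- conv3_bw(net, sprintf("down%d", i), dd, caches[[sprintf("down%d", i)]], grads)
      grads <- r$grads
      dh <- r$dx
    } else {
      dstem <- r$dx * caches$stem_pos
      r <- conv3_bw(net, "stem", dstem, caches$stem, grads)
      grads <- r$grads
    }
  }
  list(grads = grads)
}
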
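# Minimal CNN engine backing the segmentation networks.
#
# Networks are plain R lists: `cfg` (architecture description), `params`
# (flat named list of numeric arrays) and `state` (flat named list of
# non-trainable buffers, i.e. batch-norm running statistics). Forward passes
# return caches that the matching backward passes consume; gradients come
# back as a flat named list parallel to `params`. All heavy kernels live in
# C++ (src/conv.cpp); everything here is deterministic given the R RNG state
# at initialisation.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

param_env <- function() new.env(parent = emptyenv())

add_param <- function(env, name, value) assign(name, value, envir = env)

env_to_list <- function(env) {
  nms <- sort(ls(env))
  stats::setNames(lapply(nms, function(n) get(n, env)), nms)
}

as_mat <- function(x) {
  d <- dim(x)
  matrix(x, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}

relu_fw <- function(x) {
  y <- x; y[y < 0] <- 0
  y
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ------------------------------------------------------------ sep-dil conv --
# Depthwise 3x3 convolutions at each dilation rate, merged (concatenation or
# addition) and fused by a pointwise convolution. Weights: dw<r> (k,k,Cin)
# per rate, pw (Cm, Cout), b (Cout) where Cm = 4*Cin for concat, Cin for add.

sepdil_init <- function(env, prefix, Cin, Cout, cfg) {
  k <- cfg$kernel
  for (r in seq_along(cfg$dilation_rates))
    add_param(env, paste0(prefix, ".dw", r), he_init(c(k, k, Cin), k * k))
  Cm <- if (cfg$merge == "concat") length(cfg$dilation_rates) * Cin else Cin
  add_param(env, paste0(prefix, ".pw"), he_init(c(Cm, Cout), Cm))
  add_param(env, paste0(prefix, ".b"), numeric(Cout))
}

sepdil_params <- function(net, prefix) {
  nr <- length(net$cfg$dilation_rates)
  lapply(seq_len(nr), function(i) net$params[[paste0(prefix, ".dw", i)]])
}

sepdil_fw <- function(net, prefix, x) {
  cfg <- net$cfg
  k <- cfg$kernel
  if (cfg$merge == "concat") {
    r <- .sepdil_fw_cpp(x, sepdil_params(net, prefix),
                        net$params[[paste0(prefix, ".pw")]],
                        net$params[[paste0(prefix, ".b")]],
                        cfg$dilation_rates, k)
    return(list(y = r$y, cache = list(x = x, mm = r$concat)))
  }
  # additive merge (config alternative): plain R composition
  d <- dim(x)
  branches <- lapply(seq_along(cfg$dilation_rates), function(i)
    .dwconv2_fw_cpp(x, net$params[[paste0(prefix, ".dw", i)]], k,
                    as.integer(cfg$dilation_rates[i])))
  merged <- Reduce(`+`, branches)
  mm <- as_mat(merged)
  pw <- net$params[[paste0(prefix, ".pw")]]
  y <- mm %*% pw
  y <- sweep(y, 2, net$params[[paste0(prefix, ".b")]], `+`)
  dim(y) <- c(d[1], d[2], ncol(pw))
  list(y = y, cache = list(x = x, mm = mm))
}

sepdil_bw <- function(net, prefix, dy, cache, grads) {
  cfg <- net$cfg
  k <- cfg$kernel
  x <- cache$x
  if (cfg$merge == "concat") {
    g <- .sepdil_bw_cpp(x, sepdil_params(net, prefix),
                        net$params[[paste0(prefix, ".pw")]], cache$mm,
                        dy, cfg$dilation_rates, k)
    for (i in seq_along(cfg$dilation_rates))
      grads[[paste0(prefix, ".dw", i)]] <- g$ddw[[i]]
    grads[[paste0(prefix, ".pw")]] <- g$dpw
    grads[[paste0(prefix, ".b")]] <- g$db
    return(list(dx = g$dx, grads = grads))
  }
  d <- dim(x)
  dym <- as_mat(dy)
  pw <- net$params[[paste0(prefix, ".pw")]]
  grads[[paste0(prefix, ".pw")]] <- crossprod(cache$mm, dym)
  grads[[paste0(prefix, ".b")]] <- colSums(dym)
  dmm <- tcrossprod(dym, pw)
  dx <- array(0, d)
  for (i in seq_along(cfg$dilation_rates)) {
    dbr <- array(dmm, d)
    g <- .dwconv2_bw_cpp(x, net$params[[paste0(prefix, ".dw", i)]], dbr, k,
                         as.integer(cfg$dilation_rates[i]))
    grads[[paste0(prefix, ".dw", i)]] <- g$dw
    dx <- dx + g$dx
  }
  list(dx = dx, grads = grads)
}

# ------------------------------------------------------------- batch norm --
# Statistics are computed per channel over the spatial positions of the
# current input (running averages, momentum 0.1, serve evaluation mode).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_init <- function(env, prefix, C) {
  add_param(env, paste0(prefix, ".gamma"), rep(1, C))
  add_param(env, paste0(prefix, ".beta"), numeric(C))
}

bn_state_init <- function(env, prefix, C) {
  add_param(env, paste0(prefix, ".run_mean"), numeric(C))
  add_param(env, paste0(prefix, ".run_var"), rep(1, C))
}

bn_fw <- function(net, prefix, x, train) {
  r <- .bn_fw_cpp(x, net$params[[paste0(prefix, ".gamma")]],
                  net$params[[paste0(prefix, ".beta")]],
                  net$state[[paste0(prefix, ".run_mean")]],
                  net$state[[paste0(prefix, ".run_var")]],
                  train, BN_EPS)
  updates <- NULL
  if (train) {
    updates <- list(
      mean = (1 - BN_MOMENTUM) * net$state[[paste0(prefix, ".run_mean")]] +
        BN_MOMENTUM * r$mu,
      var = (1 - BN_MOMENTUM) * net$state[[paste0(prefix, ".run_var")]] +
        BN_MOMENTUM * r$var)
  }
  list(y = r$y, cache = list(xhat = r$xhat, ivar = r$ivar, train = train,
                             prefix = prefix, updates = updates))
}

bn_bw <- function(net, cache, dy, grads) {
  prefix <- cache$prefix
  g <- .bn_bw_cpp(cache$xhat, cache$ivar,
                  net$params[[paste0(prefix, ".gamma")]], dy, cache$train)
  grads[[paste0(prefix, ".gamma")]] <- g$dgamma
  grads[[paste0(prefix, ".beta")]] <- g$dbeta
  list(dx = g$dx, grads = grads)
}

# ------------------------------------------------------------- optimizers --

#' Initialise an optimizer state for a network
#' @param params flat named list of parameter arrays.
#' @param kind `"rmsprop"`, `"adam"` or `"sgd"`.
#' @return opaque optimizer state for [opt_step()].
#' @export
opt_init <- function(params, kind = c("rmsprop", "adam", "sgd")) {
  kind <- match.arg(kind)
  zeros <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  list(kind = kind, t = 0L, m = zeros, v = zeros)
}

#' One optimizer update
#'
#' RMSProp: `v <- rho v + (1-rho) g^2; p <- p - lr g / (sqrt(v) + eps)` with
#' rho = 0.9. Adam uses the standard bias-corrected first/second moments
#' (beta1 = 0.9, beta2 = 0.999).
#'
#' @param opt state from [opt_init()]; @param params,grads parallel flat
#'   lists; @param lr learning rate.
#' @return list with updated `params` and `opt`.
#' @export
opt_step <- function(opt, params, grads, lr) {
  eps <- 1e-8
  opt$t <- opt$t + 1L
  for (n in names(params)) {
    g <- grads[[n]]
    if (is.null(g)) next
    if (opt$kind == "sgd") {
      params[[n]] <- params[[n]] - lr * g
    } else if (opt$kind == "rmsprop") {
      opt$v[[n]] <- 0.9 * opt$v[[n]] + 0.1 * g^2
      params[[n]] <- params[[n]] - lr * g / (sqrt(opt$v[[n]]) + eps)
    } else {
      opt$m[[n]] <- 0.9 * opt$m[[n]] + 0.1 * g
      opt$v[[n]] <- 0.999 * opt$v[[n]] + 0.001 * g^2
      mhat <- opt$m[[n]] / (1 - 0.9^opt$t)
      vhat <- opt$v[[n]] / (1 - 0.999^opt$t)
      params[[n]] <- params[[n]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, opt = opt)
}

#' Number of trainable parameters of a network
#' @param net a network built by [build_unet2d()] or [build_vnet3d()].
#' @return integer count.
#' @export
n_params <- function(net) sum(vapply(net$params, length, 0L))

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (n in names(b)) a[[n]] <- a[[n]] + b[[n]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

apply_bn_updates <- function(net, caches) {
  for (cc in caches) {
    if (!is.null(cc$updates)) {
      net$state[[paste0(cc$prefix, ".run_mean")]] <- cc$updates$mean
      net$state[[paste0(cc$prefix, ".run_var")]] <- cc$updates$var
    }
  }
  net
}

#' Save / load a network checkpoint
#'
#' Checkpoints are written with [saveRDS()] into a directory layout
#' `<dir>/<name>.rds`; the object holds cfg, params and state, so a reloaded
#' network reproduces predictions bit-for-bit.
#'
#' @param net network object; @param dir checkpoint directory;
#' @param name checkpoint name.
#' @return path (save) or network (load).
#' @export
save_checkpoint <- function(net, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".rds"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir, name) {
  readRDS(file.path(dir, paste0(name, ".rds")))
}
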
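#' Training plans
#'
#' [train_plan_2d()] encodes the 2D schedule: RMSProp, 25 epochs, batch 16,
#' learning rate 1e-5 held for 13 epochs then divided by 2 after every
#' further 3 epochs (repeated halving; a single-halving variant is available
#' via `schedule = "single"`). [train_plan_3d()] encodes the 3D schedule:
#' Adam, 100 epochs, batch 4, learning rate 1e-4 for 50 epochs, 1e-4/2 for
#' 25, 1e-4/4 for 25. Desk-scale runs may override epochs, batch, base rate
#' and schedule (`"constant"`) without touching the canonical defaults.
#'
#' @param epochs,batch,base_lr usual meaning.
#' @param plateau epochs at the base rate before halving starts (2D).
#' @param halve_every epochs between successive halvings (2D).
#' @param schedule `"repeated"` (default), `"single"` or `"constant"`.
#' @param optimizer optimizer name for [opt_init()].
#' @return a `train_plan` object.
#' @export
train_plan_2d <- function(epochs = 25, batch = 16, base_lr = 1e-5,
                          plateau = 13, halve_every = 3,
                          schedule = c("repeated", "single", "constant"),
                          optimizer = "rmsprop") {
  schedule <- match.arg(schedule)
  structure(list(kind = "2d", epochs = epochs, batch = batch,
                 base_lr = base_lr, plateau = plateau,
                 halve_every = halve_every, schedule = schedule,
                 optimizer = optimizer),
            class = c("train_plan_2d", "train_plan"))
}

#' @rdname train_plan_2d
#' @param breaks epoch indices where the 3D rate drops (default c(50, 75)).
#' @param divisors divisor applied in each segment (default c(1, 2, 4)).
#' @export
train_plan_3d <- function(epochs = 100, batch = 4, base_lr = 1e-4,
                          breaks = c(50, 75), divisors = c(1, 2, 4),
                          schedule = c("piecewise", "constant"),
                          optimizer = "adam") {
  schedule <- match.arg(schedule)
  structure(list(kind = "3d", epochs = epochs, batch = batch,
                 base_lr = base_lr, breaks = breaks, divisors = divisors,
                 schedule = schedule, optimizer = optimizer),
            class = c("train_plan_3d", "train_plan"))
}

#' Learning rate at a given epoch
#'
#' Pure schedule arithmetic. Epochs are 0-based: `lr_at(plan, 0)` is the rate
#' of the first epoch. For the 2D plan, `lr(e) = base` for `e < plateau` and
#' `base / 2^(1 + floor((e - plateau)/halve_every))` afterwards; the rate is
#' nonincreasing in e.
#'
#' @param plan a train plan; @param epoch 0-based epoch, `< plan$epochs`.
#' @return learning rate (scalar).
#' @export
lr_at <- function(plan, epoch) UseMethod("lr_at")

#' @export
lr_at.train_plan_2d <- function(plan, epoch) {
  check_epoch(plan, epoch)
  if (plan$schedule == "constant" || epoch < plan$plateau) return(plan$base_lr)
  if (plan$schedule == "single") return(plan$base_lr / 2)
  plan$base_lr / 2^(1 + floor((epoch - plan$plateau) / plan$halve_every))
}

#' @export
lr_at.train_plan_3d <- function(plan, epoch) {
  check_epoch(plan, epoch)
  if (plan$schedule == "constant") return(plan$base_lr)
  seg <- findInterval(epoch, plan$breaks) + 1
  plan$base_lr / plan$divisors[seg]
}

check_epoch <- function(plan, epoch) {
  if (epoch < 0 || epoch >= plan$epochs)
    petseg_abort(sprintf("epoch %s outside [0, %d)", epoch, plan$epochs),
                 "bad_epoch")
}

# ------------------------------------------------------------- 2D dataset --

#' Assemble a rebalanced 2D slice dataset
#'
#' Enumerates slices of the requested orientations over all studies, keeps
#' every tumor-containing slice, and subsamples tumor-free slices so that
#' they make up approximately `neg_fraction` of the dataset (whole-body scans
#' are dominated by tumor-free slices; without rebalancing a slice network
#' converges to the null prediction). Selection is deterministic per seed.
#'
#' @param studies list of `petct_study` objects (preprocessed).
#' @param truths list of `MASK` voxel grids aligned with `studies`.
#' @param orientations subset of c("axial", "sagittal", "coronal").
#' @param neg_fraction target fraction of tumor-free slices (default 0.10).
#' @param seed RNG seed for the negative-slice subsample.
#' @return a `slice_dataset`: index table plus accessors; see
#'   [get_slice()].
#' @export
build_slice_dataset <- function(studies, truths,
                                orientations = c("axial", "sagittal"),
                                neg_fraction = 0.10, seed = 0) {
  stopifnot(length(studies) == length(truths))
  rows <- list()
  for (s in seq_along(studies)) {
    mask <- truths[[s]]$data
    for (ori in orientations) {
      ax <- match(ori, c("axial", "coronal", "sagittal"))
      pos <- apply(mask, ax, function(sl) any(sl > 0))
      rows[[length(rows) + 1]] <- data.frame(
        study = s, orientation = ori, index = seq_along(pos), positive = pos)
    }
  }
  tab <- do.call(rbind, rows)
  pos_tab <- tab[tab$positive, , drop = FALSE]
  neg_tab <- tab[!tab$positive, , drop = FALSE]
  if (!nrow(pos_tab))
    petseg_abort("no tumor-containing slices in any study", "empty_dataset")
  n_neg <- round(neg_fraction / (1 - neg_fraction) * nrow(pos_tab))
  n_neg <- min(n_neg, nrow(neg_tab))
  keep_neg <- withr_seed(seed, sample(nrow(neg_tab), n_neg))
  sel <- rbind(pos_tab, neg_tab[keep_neg, , drop = FALSE])
  sel <- sel[order(sel$study, sel$orientation, sel$index), ]
  rownames(sel) <- NULL
  structure(list(index = sel, studies = studies, truths = truths),
            class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  cat(sprintf("<slice_dataset> %d slices (%.1f%% tumor-free)\n",
              nrow(x$index), 100 * mean(!x$index$positive)))
  invisible(x)
}

#' Fetch one training slice
#'
#' @param dataset a `slice_dataset`; @param i row of the index table.
#' @return list with `x` (H, W, 2 array: normalised PET, CT channels) and
#'   `y` (H, W binary matrix).
#' @export
get_slice <- function(dataset, i) {
  row <- dataset$index[i, ]
  st <- dataset$studies[[row$study]]
  tr <- dataset$truths[[row$study]]
  pet_sl <- extract_slice(st$pet$data, row$orientation, row$index)
  ct_sl <- extract_slice(st$ct$data, row$orientation, row$index)
  y <- extract_slice(tr$data, row$orientation, row$index)
  list(x = normalize_channels(pet_sl, ct_sl), y = y)
}

extract_slice <- function(arr, orientation, i) {
  switch(orientation,
         axial = arr[i, , ],
         coronal = arr[, i, ],
         sagittal = arr[, , i])
}

#' Channel normalisation for network inputs
#'
#' Fixed affine mapping applied to both training and inference inputs:
#' PET SUV is divided by 5 (typical tumor uptake maps near 1) and CT is
#' shifted/scaled as (HU + 1000)/1500 (air 0, soft tissue ~0.69).
#'
#' @param pet_sl,ct_sl aligned PET (SUV) and CT (HU) slices or volumes.
#' @return array with a trailing channel axis (PET, CT).
#' @export
normalize_channels <- function(pet_sl, ct_sl) {
  array(c(pet_sl / 5, (ct_sl + 1000) / 1500), c(dim(pet_sl), 2))
}

# pad a (H, W, C) slice so H, W are divisible by `div`; returns fitted + geom
pad_to_divisible <- function(x, div) {
  d <- dim(x)
  tgt <- c(ceiling(d[1] / div) * div, ceiling(d[2] / div) * div)
  fit_slice(x, tgt)
}

# --------------------------------------------------------------- 2D train --

#' Train the 2D U-Net
#'
#' Mini-batch training with the compound 2D loss (Dice + weighted BCE).
#' Gradients are averaged over each batch; slices are shuffled per epoch with
#' a seeded RNG so runs are reproducible. Slices are zero-padded to the
#' nearest valid input size. Training aborts with a diagnostic if the loss
#' turns non-finite.
#'
#' @param dataset a [build_slice_dataset()] result.
#' @param net a `unet2d` (modified copy returned).
#' @param plan a [train_plan_2d()].
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch summaries.
#' @return list with `net` (trained), `history` (epoch, lr, loss, dice).
#' @export
train_2d <- function(dataset, net, plan = train_plan_2d(), seed = 0,
                     verbose = FALSE) {
  n <- nrow(dataset$index)
  opt <- opt_init(net$params, plan$optimizer)
  div <- 2^(net$cfg$depth - 1)
  history <- data.frame()
  withr_seed(seed, {
    for (epoch in seq_len(plan$epochs) - 1L) {
      lr <- lr_at(plan, epoch)
      ord <- sample(n)
      ep_loss <- 0; ep_dice <- 0
      bstarts <- seq(1, n, by = plan$batch)
      for (b in bstarts) {
        ids <- ord[b:min(b + plan$batch - 1, n)]
        acc <- NULL
        bn_caches <- list()
        for (i in ids) {
          sl <- get_slice(dataset, i)
          fx <- pad_to_divisible(sl$x, div)
          fy <- fit_slice(sl$y, dim(fx$slice)[1:2])
          fw <- unet2d_forward(net, fx$slice, train = TRUE, keep_cache = TRUE)
          rep <- loss_2d(fw$prob, fy$slice)
          if (!is.finite(rep$total))
            petseg_abort(sprintf("non-finite 2D loss at epoch %d", epoch),
                         "diverged")
          ep_loss <- ep_loss + rep$total
          ep_dice <- ep_dice + (1 - rep$dice_term)
          dprob <- grad_loss_2d(fw$prob, fy$slice)
          bw <- unet2d_backward(net, cache = fw$cache, dprob = dprob)
          acc <- sum_grads(acc, bw$grads)
          bn_caches <- c(bn_caches, bw$bn_caches)
        }
        acc <- scale_grads(acc, 1 / length(ids))
        stp <- opt_step(opt, net$params, acc, lr)
        net$params <- stp$params; opt <- stp$opt
        net <- apply_bn_updates(net, bn_caches)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, loss = ep_loss / n, soft_dice = ep_dice / n))
      if (verbose)
        message(sprintf("2D epoch %d: lr %.2g, loss %.4f, soft dice %.3f",
                        epoch, lr, ep_loss / n, ep_dice / n))
    }
  })
  list(net = net, history = history)
}

# --------------------------------------------------------------- 3D train --

#' Assemble a 3D patch dataset from truth components
#'
#' Positive patches are cubes centred on the connected components of the
#' truth masks (one per component, jittered by up to 1/4 edge); an equal
#' number of random tumor-free patches is added so the refinement network
#' sees background anatomy. Patch edge is a single value for desk-scale runs
#' or taken per region from a region map.
#'
#' @param studies,truths aligned lists as in [build_slice_dataset()].
#' @param edge cube edge (divisible by 8).
#' @param seed RNG seed.
#' @return a `patch_dataset`: list of (x = (e,e,e,2) input, y = target cube).
#' @export
build_patch_dataset <- function(studies, truths, edge = 32, seed = 0) {
  patches <- list()
  withr_seed(seed, {
    for (s in seq_along(studies)) {
      st <- studies[[s]]; tr <- truths[[s]]$data
      d <- dim(tr)
      labels <- .label3_cpp(tr > 0, d, 26L)
      ncomp <- attr(labels, "n_components")
      centers <- list()
      if (ncomp > 0) {
        for (id in seq_len(ncomp)) {
          idx <- which(labels == id, arr.ind = TRUE)
          cen <- round(colMeans(idx) + stats::runif(3, -edge / 4, edge / 4))
          centers[[length(centers) + 1]] <- cen
        }
      }
      n_neg <- length(centers)
      for (j in seq_len(n_neg)) {
        for (tries in 1:50) {
          cen <- round(stats::runif(3, edge / 2, d - edge / 2))
          g <- gather_cube(tr, cen, edge)
          if (sum(g$cube) == 0) { centers[[length(centers) + 1]] <- cen; break }
        }
      }
      for (cen in centers) {
        gp <- gather_cube(st$pet$data, cen, edge)
        gc <- gather_cube(st$ct$data, cen, edge)
        gy <- gather_cube(tr, cen, edge)
        patches[[length(patches) + 1]] <-
          list(x = normalize_channels(gp$cube, gc$cube), y = gy$cube)
      }
    }
  })
  structure(list(patches = patches, edge = edge), class = "patch_dataset")
}

#' Train a 3D V-Net on patches
#'
#' Mini-batch training with the compound 3D loss (Dice + sensitivity + MAE).
#'
#' All three terms of the 3D loss reach the logits through the sigmoid
#' derivative, so a network whose output collapses toward zero early in
#' training receives vanishing gradients and cannot recover; with half the
#' patches tumor-free this failure mode dominates small training runs. The
#' `"positives_first"` curriculum (default) therefore trains on
#' tumor-containing patches alone for the first `warmup_frac` of the epochs
#' and on the full mixture afterwards; `"mixed"` uses every patch from the
#' start.
#'
#' @param dataset a [build_patch_dataset()] result.
#' @param net a `vnet3d`.
#' @param plan a [train_plan_3d()].
#' @param seed shuffling seed; @param verbose print per-epoch summaries.
#' @param curriculum `"positives_first"` or `"mixed"`.
#' @param warmup_frac fraction of epochs restricted to positive patches
#'   under the `"positives_first"` curriculum (default 0.5).
#' @return list with `net` and `history`.
#' @export
train_3d <- function(dataset, net, plan = train_plan_3d(), seed = 0,
                     verbose = FALSE,
                     curriculum = c("positives_first", "mixed"),
                     warmup_frac = 0.5) {
  curriculum <- match.arg(curriculum)
  n <- length(dataset$patches)
  pos_ids <- which(vapply(dataset$patches, function(p) sum(p$y) > 0, TRUE))
  if (curriculum == "positives_first" && !length(pos_ids))
    curriculum <- "mixed"
  warmup_epochs <- if (curriculum == "positives_first")
    ceiling(warmup_frac * plan$epochs) else 0L
  opt <- opt_init(net$params, plan$optimizer)
  history <- data.frame()
  withr_seed(seed, {
    for (epoch in seq_len(plan$epochs) - 1L) {
      lr <- lr_at(plan, epoch)
      neg_ids <- setdiff(seq_len(n), pos_ids)
      if (epoch < warmup_epochs || !length(neg_ids) || !length(pos_ids)) {
        pool <- if (epoch < warmup_epochs) pos_ids else seq_len(n)
        ord <- if (length(pool) > 1) sample(pool) else pool
      } else {
        # stratified interleaving: alternate positives and negatives so every
        # batch carries tumor signal (guards against the null-predictor
        # attractor of the 3D loss)
        po <- if (length(pos_ids) > 1) sample(pos_ids) else pos_ids
        ne <- if (length(neg_ids) > 1) sample(neg_ids) else neg_ids
        m <- max(length(po), length(ne))
        ord <- as.vector(rbind(po[((seq_len(m) - 1) %% length(po)) + 1],
                               ne[((seq_len(m) - 1) %% length(ne)) + 1]))
      }
      n_ep <- length(ord)
      ep_loss <- 0; ep_dice <- 0
      for (b in seq(1, n_ep, by = plan$batch)) {
        ids <- ord[b:min(b + plan$batch - 1, n_ep)]
        acc <- NULL
        for (i in ids) {
          p <- dataset$patches[[i]]
          fw <- vnet3d_forward(net, p$x, keep_cache = TRUE)
          rep <- loss_3d(fw$prob, p$y)
          if (!is.finite(rep$total))
            petseg_abort(sprintf("non-finite 3D loss at epoch %d", epoch),
                         "diverged")
          ep_loss <- ep_loss + rep$total
          ep_dice <- ep_dice + (1 - rep$dice_term)
          bw <- vnet3d_backward(net, fw$cache, grad_loss_3d(fw$prob, p$y))
          acc <- sum_grads(acc, bw$grads)
        }
        acc <- scale_grads(acc, 1 / length(ids))
        stp <- opt_step(opt, net$params, acc, lr)
        net$params <- stp$params; opt <- stp$opt
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, loss = ep_loss / n_ep,
        soft_dice = ep_dice / n_ep))
      if (verbose)
        message(sprintf("3D epoch %d: lr %.2g, loss %.4f, soft dice %.3f",
                        epoch, lr, ep_loss / n_ep, ep_dice / n_ep))
    }
  })
  list(net = net, history = history)
}

# Extract a cube of `edge` voxels centred at `cen` (zero-padded at borders),
# with the geometry needed to scatter values back.
gather_cube <- function(arr, cen, edge) {
  d <- dim(arr)
  half <- edge / 2
  lo <- round(cen - half + 1)
  hi <- lo + edge - 1
  src <- lapply(1:3, function(a) max(1, lo[a]):min(d[a], hi[a]))
  dst <- lapply(1:3, function(a) (src[[a]] - lo[a]) + 1)
  cube <- array(0, c(edge, edge, edge))
  cube[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  list(cube = cube, src = src, dst = dst)
}
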
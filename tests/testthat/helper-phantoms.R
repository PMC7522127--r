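# Shared fixtures: phantoms and desk-scale trained networks are expensive, so
# they are generated once per session and memoised in this environment.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# deterministic phantom bank; training uses seeds 1..8, evaluation 101..120
test_phantom <- function(seed) {
  memo(paste0("phantom_", seed), generate_phantom(phantom_spec(seed = seed)))
}

TRAIN_SEEDS <- 1:8
HOLDOUT_SEEDS <- 101:120

# Held-out phantoms vary tumor burden (counts cycling 1..6) so population
# statistics such as the TMTV rank correlation have real dynamic range;
# per-lesion size/uptake/noise follow the generator defaults.
holdout_spec <- function(seed) {
  k <- seed - 100
  phantom_spec(seed = seed, n_tumors = ((k - 1) %% 6) + 1)
}

holdout_phantom <- function(seed) {
  memo(paste0("holdout_", seed), generate_phantom(holdout_spec(seed)))
}

# One streaming pass over the 20 held-out phantoms: landmark recovery and
# the trained cascade's burden estimates, keeping only scalar summaries in
# memory (full phantoms are ~80 MB each and must not accumulate).
holdout_results <- function() {
  memo("holdout_results", {
    tr <- trained_2d()
    models3 <- trained_3d_models()
    rows <- list()
    tumor_regions <- character()
    for (k in seq_along(HOLDOUT_SEEDS)) {
      s <- HOLDOUT_SEEDS[k]
      ph <- if (exists(paste0("holdout_", s), .cache))
        holdout_phantom(s) else generate_phantom(holdout_spec(s))
      errs <- tryCatch({
        lm <- detect_landmarks(ph$study)
        vapply(c("brain", "liver", "lungs"), function(o)
          com_error(lm[[o]]$com_voxel, ph$truth[[o]]$com_voxel), 0)
      }, error = function(e) rep(Inf, 3))
      res <- run_pipeline(ph$study, tr$net, models3,
                          truth_mask = ph$truth$tumor_mask)
      rows[[k]] <- data.frame(
        seed = s, err_brain = errs[1], err_liver = errs[2],
        err_lungs = errs[3], tmtv_pred = res$metrics$tmtv_ml,
        tmtv_true = ph$truth$tmtv_ml, dice = res$dice,
        sensitivity = res$sensitivity)
      tumor_regions <- c(tumor_regions,
                         vapply(ph$truth$tumors, `[[`, "", "region"))
      rm(ph, res)
      invisible(gc(verbose = FALSE))
    }
    list(table = do.call(rbind, rows), tumor_regions = tumor_regions)
  })
}

train_bank <- function() lapply(TRAIN_SEEDS, test_phantom)

# Desk-scale study configuration: a depth-3, base-8 U-Net on ~200 rebalanced
# slices for 6 epochs (RMSProp, constant 1e-3), and one shared tiny V-Net
# (filters 4/8/16/32) on ~50 component patches for 30 epochs (Adam, 3e-4).
tiny_unet_cfg <- function() net_config_2d(depth = 3, base_filters = 8,
                                          input_hw = NULL)

tiny_vnet_cfg <- function() net_config_3d(
  down_filters = c(4, 8, 16, 32),
  patch_edge = c(HEAD_NECK = 32, CHEST = 64, ABDOMEN_PELVIS = 96))

tiny_slice_dataset <- function() {
  memo("slice_ds", {
    bank <- train_bank()[1:6]
    ds <- build_slice_dataset(lapply(bank, `[[`, "study"),
                              lapply(bank, function(p) p$truth$tumor_mask),
                              orientations = c("axial", "sagittal"),
                              neg_fraction = 0.1, seed = 1)
    keep <- petseg:::withr_seed(
      2, sort(sample(nrow(ds$index), min(200, nrow(ds$index)))))
    ds$index <- ds$index[keep, ]
    ds
  })
}

tiny_patch_dataset <- function() {
  memo("patch_ds", {
    bank <- train_bank()
    build_patch_dataset(lapply(bank, `[[`, "study"),
                        lapply(bank, function(p) p$truth$tumor_mask),
                        edge = 32, seed = 5)
  })
}

trained_2d <- function() {
  memo("trained_2d", {
    ds <- tiny_slice_dataset()
    plan <- train_plan_2d(epochs = 6, batch = 4, base_lr = 1e-3,
                          schedule = "constant")
    train_2d(ds, build_unet2d(tiny_unet_cfg(), seed = 7), plan, seed = 3)
  })
}

trained_3d <- function() {
  memo("trained_3d", {
    pds <- tiny_patch_dataset()
    plan <- train_plan_3d(epochs = 45, batch = 2, base_lr = 3e-4,
                          breaks = c(32), divisors = c(1, 3))
    train_3d(pds, build_vnet3d("CHEST", tiny_vnet_cfg(), seed = 8), plan,
             seed = 4, curriculum = "positives_first", warmup_frac = 0.45)
  })
}

trained_3d_models <- function() {
  net <- trained_3d()$net
  list(HEAD_NECK = net, CHEST = net, ABDOMEN_PELVIS = net)
}

# hard Dice over the slices of a dataset, aggregated across slices
holdout_slice_dice <- function(net, ds) {
  inter <- 0; ps <- 0; ts <- 0
  div <- 2^(net$cfg$depth - 1)
  for (i in seq_len(nrow(ds$index))) {
    sl <- get_slice(ds, i)
    fx <- petseg:::pad_to_divisible(sl$x, div)
    p <- unet2d_forward(net, fx$slice, train = FALSE)$prob
    p <- unfit_slice(p, fx$geom) >= 0.5
    inter <- inter + sum(p * sl$y); ps <- ps + sum(p); ts <- ts + sum(sl$y)
  }
  2 * inter / (ps + ts)
}

com_error <- function(a, b) sqrt(sum((a - b)^2))
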
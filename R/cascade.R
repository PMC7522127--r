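#' Pipeline configuration
#'
#' Collects every tunable default of the cascade in one object: landmark
#' detector thresholds, the orientations averaged by the 2D stage, the
#' component threshold, region patch edges and the fusion threshold.
#'
#' @param brain_threshold SUV threshold for brain detection (default 2.5).
#' @param brain_min_volume_ml minimal brain volume (default 500).
#' @param liver_threshold SUV threshold for the liver (default 1.0).
#' @param liver_window_mm liver search window below the brain (default
#'   c(100, 500)).
#' @param liver_erosion_mm liver erosion sphere radius (default 8).
#' @param liver_side `"patient_right"` (default) or `"patient_left"`.
#' @param lung_threshold_hu CT threshold (default -300).
#' @param lung_keep_top initial component count kept (default 8).
#' @param lung_erosion_box cubic erosion edge (default 3).
#' @param orientations 2D inference orientations to average (default axial +
#'   sagittal; coronal may be added).
#' @param component_threshold probability threshold for component labeling
#'   (default 0.5, ties positive).
#' @param patch_edges named per-region patch edge (default 32/64/96).
#' @param patch_overlap tiling overlap fraction for oversized components
#'   (default 0.5).
#' @param fusion_threshold threshold on the averaged 2D/3D probability
#'   (default 0.5, ties positive).
#' @param target_mm isotropic working resolution (default 2).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(brain_threshold = 2.5, brain_min_volume_ml = 500,
                            liver_threshold = 1.0,
                            liver_window_mm = c(100, 500),
                            liver_erosion_mm = 8,
                            liver_side = "patient_right",
                            lung_threshold_hu = -300, lung_keep_top = 8,
                            lung_erosion_box = 3,
                            orientations = c("axial", "sagittal"),
                            component_threshold = 0.5,
                            patch_edges = c(HEAD_NECK = 32, CHEST = 64,
                                            ABDOMEN_PELVIS = 96),
                            patch_overlap = 0.5,
                            fusion_threshold = 0.5,
                            target_mm = 2) {
  structure(as.list(environment()), class = "pipeline_config")
}

# ------------------------------------------------------------- prediction --

#' Predict a slice or patch with a model
#'
#' S3 generic dispatching on the model class, so trained networks and test
#' stubs are interchangeable throughout the cascade. `meta` carries the
#' orientation/slice index (2D) or cube geometry (3D) so that ground-truth
#' echo stubs can look up their answer.
#'
#' @param model a model object; @param x input array; @param meta list of
#'   geometry hints.
#' @return probability array matching the spatial shape of `x`.
#' @export
net_predict <- function(model, x, meta = list()) UseMethod("net_predict")

#' @export
net_predict.unet2d <- function(model, x, meta = list()) {
  unet2d_forward(model, x, train = FALSE)$prob
}

#' @export
net_predict.vnet3d <- function(model, x, meta = list()) {
  vnet3d_forward(model, x)$prob
}

#' @export
net_predict.stub_model <- function(model, x, meta = list()) {
  model$fn(x, meta)
}

#' Stub models for pipeline testing
#'
#' `stub_constant(v)` always emits probability `v`. `stub_echo_truth(truth)`
#' emits the ground-truth mask values for the requested slice/cube, which
#' turns the cascade into an identity pipeline (useful to validate all
#' geometry plumbing end to end).
#'
#' @param v constant probability.
#' @return a `stub_model` usable wherever a network is expected.
#' @export
stub_constant <- function(v) {
  structure(list(fn = function(x, meta) {
    d <- dim(x)
    array(v, d[-length(d)])
  }), class = "stub_model")
}

#' @rdname stub_constant
#' @param truth a `MASK` voxel grid.
#' @export
stub_echo_truth <- function(truth) {
  arr <- as_plain_array(truth)
  structure(list(fn = function(x, meta) {
    if (!is.null(meta$orientation)) {
      sl <- extract_slice(arr, meta$orientation, meta$index)
      fit_slice(sl, dim(x)[1:2])$slice
    } else if (!is.null(meta$cube_center)) {
      gather_cube(arr, meta$cube_center, meta$edge)$cube
    } else {
      petseg_abort("echo stub needs slice or cube geometry", "bad_input")
    }
  }), class = "stub_model")
}

#' 2D stage: orientation-averaged slice-wise tumor probabilities
#'
#' Runs the slice model over every slice of each configured reformation
#' (axial and sagittal by default), maps the per-slice predictions back onto
#' the volume lattice, and averages the orientation probability volumes
#' voxel-wise.
#'
#' Slices are fitted to the model's nominal input size (`cfg$input_hw`) when
#' set, else zero-padded to the nearest valid size; predictions are mapped
#' back through the exact inverse geometry.
#'
#' @param study a preprocessed `petct_study`.
#' @param model a 2D model (network or stub).
#' @param orientations orientations to average.
#' @return a `PROB` voxel grid.
#' @export
predict_2d <- function(study, model,
                       orientations = c("axial", "sagittal")) {
  d <- dim(study$pet$data)
  acc <- array(0, d)
  div <- if (inherits(model, "unet2d")) 2^(model$cfg$depth - 1) else 1L
  target <- if (inherits(model, "unet2d")) model$cfg$input_hw else NULL
  batched <- inherits(model, "unet2d")
  folded <- if (batched) unet2d_fold_eval(model)
  for (ori in orientations) {
    ax <- match(ori, c("axial", "coronal", "sagittal"))
    vol <- array(0, d)
    n_slices <- d[ax]
    if (batched) {
      # all slices of one orientation share a shape; run them in batches
      for (b0 in seq(1, n_slices, by = 24L)) {
        ids <- b0:min(b0 + 23L, n_slices)
        fits <- lapply(ids, function(i) {
          x <- normalize_channels(extract_slice(study$pet$data, ori, i),
                                  extract_slice(study$ct$data, ori, i))
          if (!is.null(target)) fit_slice(x, target)
          else pad_to_divisible(x, div)
        })
        hw <- dim(fits[[1]]$slice)[1:2]
        x4 <- array(0, c(hw, length(ids), 2L))
        for (j in seq_along(ids)) x4[, , j, ] <- fits[[j]]$slice
        pb <- unet2d_eval_batch(model, x4, folded)
        for (j in seq_along(ids)) {
          p <- unfit_slice(pb[, , j], fits[[j]]$geom)
          i <- ids[j]
          switch(ori,
                 axial = {vol[i, , ] <- p},
                 coronal = {vol[, i, ] <- p},
                 sagittal = {vol[, , i] <- p})
        }
      }
    } else {
      for (i in seq_len(n_slices)) {
        pet_sl <- extract_slice(study$pet$data, ori, i)
        ct_sl <- extract_slice(study$ct$data, ori, i)
        x <- normalize_channels(pet_sl, ct_sl)
        fitted <- if (!is.null(target)) fit_slice(x, target)
                  else pad_to_divisible(x, div)
        p_fit <- net_predict(model, fitted$slice,
                             meta = list(orientation = ori, index = i))
        p <- unfit_slice(p_fit, fitted$geom)
        switch(ori,
               axial = {vol[i, , ] <- p},
               coronal = {vol[, i, ] <- p},
               sagittal = {vol[, , i] <- p})
      }
    }
    acc <- acc + vol
  }
  voxel_grid(acc / length(orientations), study$pet$spacing,
             modality = "PROB")
}

# ------------------------------------------------------------- components --

#' Label candidate components of a probability volume
#'
#' Binarises at `threshold` (>= positive), labels 26-connected components and
#' assigns each to the region of its (rounded) centroid voxel.
#'
#' @param prob a `PROB` voxel grid; @param regions a `region_map`;
#' @param threshold binarisation threshold (default 0.5).
#' @return a `component_set`: data.frame of components (id, region, voxels,
#'   centroid, bbox) plus the label array.
#' @export
label_components <- function(prob, regions, threshold = 0.5) {
  p <- as_plain_array(prob)
  labels <- .label3_cpp(p >= threshold, dim(p), 26L)
  n <- attr(labels, "n_components")
  comps <- if (n == 0) data.frame() else do.call(rbind, lapply(seq_len(n), function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    cen <- colMeans(idx)
    data.frame(id = id, region = region_of_z(regions, cen[1]),
               voxels = nrow(idx),
               cz = cen[1], cy = cen[2], cx = cen[3],
               z0 = min(idx[, 1]), z1 = max(idx[, 1]),
               y0 = min(idx[, 2]), y1 = max(idx[, 2]),
               x0 = min(idx[, 3]), x1 = max(idx[, 3]))
  }))
  structure(list(components = comps, labels = labels, shape = dim(p)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d component(s)\n",
              if (is.null(x$components) || !nrow(x$components)) 0
              else nrow(x$components)))
  invisible(x)
}

#' Extract region-sized patches around candidate components
#'
#' One centred cube per component when its bounding box fits the region's
#' patch edge; otherwise a tiling of cubes with 50% overlap covering the box.
#' Cubes crossing the volume border are zero-padded; each patch records exact
#' inverse geometry.
#'
#' @param components a `component_set`; @param study the preprocessed study;
#' @param config a [pipeline_config()] (patch edges / overlap).
#' @return a `patch_set`: list of patches with `x` ((e,e,e,2) input), region,
#'   `center`, `edge` and scatter geometry.
#' @export
extract_patches <- function(components, study, config = pipeline_config()) {
  comps <- components$components
  patches <- list()
  d <- dim(study$pet$data)
  if (!is.null(comps) && nrow(comps)) {
    for (r in seq_len(nrow(comps))) {
      cm <- comps[r, ]
      edge <- config$patch_edges[[cm$region]]
      centers <- patch_centers(c(cm$z0, cm$y0, cm$x0), c(cm$z1, cm$y1, cm$x1),
                               c(cm$cz, cm$cy, cm$cx), edge,
                               config$patch_overlap)
      for (ci in seq_len(nrow(centers))) {
        cen <- centers[ci, ]
        gp <- gather_cube(study$pet$data, cen, edge)
        gc <- gather_cube(study$ct$data, cen, edge)
        patches[[length(patches) + 1]] <- list(
          x = normalize_channels(gp$cube, gc$cube),
          region = cm$region, component = cm$id,
          center = cen, edge = edge, src = gp$src, dst = gp$dst)
      }
    }
  }
  structure(list(patches = patches, shape = d), class = "patch_set")
}

# Cube centers covering a bbox: single centred cube when it fits, else a
# stride-(1-overlap)*edge tiling per axis including the far edge. A cube
# with center c spans voxels [c - edge/2 + 1, c + edge/2] (the gather_cube
# convention), so a cube starting at voxel s has center s + edge/2 - 1.
patch_centers <- function(lo, hi, centroid, edge, overlap) {
  half <- edge / 2
  axes <- lapply(1:3, function(a) {
    span <- hi[a] - lo[a] + 1
    if (span <= edge) {
      # centred on the centroid, shifted minimally so the cube covers the
      # whole bounding box even for asymmetric components
      return(min(max(round(centroid[a]), hi[a] - half), lo[a] + half - 1))
    }
    stride <- max(1, round(edge * (1 - overlap)))
    starts <- seq(lo[a], hi[a] - edge + 1, by = stride)
    if (utils::tail(starts, 1) < hi[a] - edge + 1)
      starts <- c(starts, hi[a] - edge + 1)
    starts + half - 1
  })
  as.matrix(expand.grid(z = axes[[1]], y = axes[[2]], x = axes[[3]]))
}

#' 3D stage: region-specific patch refinement
#'
#' Runs the matching region model on every patch and averages overlapping
#' patch predictions voxel-wise on the volume lattice; voxels outside every
#' patch get probability 0.
#'
#' @param patch_set from [extract_patches()].
#' @param models named list of 3D models (`HEAD_NECK`, `CHEST`,
#'   `ABDOMEN_PELVIS`); a model must exist for every region with patches.
#' @param spacing voxel spacing for the output grid.
#' @return a `PROB` voxel grid.
#' @export
refine_3d <- function(patch_set, models, spacing = c(2, 2, 2)) {
  d <- patch_set$shape
  num <- array(0, d); cnt <- array(0L, d)
  for (p in patch_set$patches) {
    model <- models[[p$region]]
    if (is.null(model))
      petseg_abort(sprintf("no 3D model for region %s", p$region),
                   "missing_model")
    prob <- net_predict(model, p$x,
                        meta = list(cube_center = p$center, edge = p$edge))
    num[p$src[[1]], p$src[[2]], p$src[[3]]] <-
      num[p$src[[1]], p$src[[2]], p$src[[3]]] +
      prob[p$dst[[1]], p$dst[[2]], p$dst[[3]]]
    cnt[p$src[[1]], p$src[[2]], p$src[[3]]] <-
      cnt[p$src[[1]], p$src[[2]], p$src[[3]]] + 1L
  }
  out <- num
  out[cnt > 0] <- num[cnt > 0] / cnt[cnt > 0]
  voxel_grid(out, spacing, modality = "PROB")
}

#' Fuse the 2D and 3D probability volumes into the final mask
#'
#' The final call is the voxel-wise average of the two probability volumes
#' thresholded at `threshold`, with ties (average exactly at the threshold)
#' positive.
#'
#' @param p2d,p3d aligned `PROB` voxel grids.
#' @param threshold default 0.5.
#' @return a `MASK` voxel grid.
#' @export
fuse_masks <- function(p2d, p3d, threshold = 0.5) {
  a <- as_plain_array(p2d); b <- as_plain_array(p3d)
  check_same_shape(a, b)
  sp <- if (inherits(p2d, "voxel_grid")) p2d$spacing else c(2, 2, 2)
  voxel_grid(((a + b) / 2 >= threshold) * 1, sp, modality = "MASK")
}

# --------------------------------------------------------------- pipeline --

#' Run the full cascade on a study
#'
#' Executes: (optional load) -> SUV conversion -> isotropic resampling ->
#' landmark detection -> region partition -> 2D orientation-averaged
#' segmentation -> component labeling -> region patch extraction -> 3D
#' refinement -> probability fusion -> burden metrics. If landmark detection
#' fails the pipeline degrades to a single whole-volume CHEST region with a
#' warning rather than failing.
#'
#' @param study a `petct_study`, or a list `list(pet = path, ct = path)`.
#' @param model_2d 2D model (network or stub).
#' @param models_3d named list of per-region 3D models.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory: writes the final mask and both
#'   probability volumes (NIfTI), metrics CSV and landmark JSON.
#' @param truth_mask optional ground-truth `MASK` grid for agreement metrics.
#' @param verbose log stage progress and timings via `message()`.
#' @return list with `mask`, `prob_2d`, `prob_3d`, `metrics`, `landmarks`
#'   (NULL if fallback), `regions`, `components`, `study` (preprocessed).
#' @export
run_pipeline <- function(study, model_2d, models_3d,
                         config = pipeline_config(), out_dir = NULL,
                         truth_mask = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    t <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      petseg_abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)), "pipeline"))
    if (verbose) message(sprintf("[%s] %.2fs", name,
                                 as.numeric(Sys.time() - t, units = "secs")))
    r
  }
  if (!inherits(study, "petct_study"))
    study <- stage("load", load_study(study$pet, study$ct))
  study <- stage("preprocess", preprocess_study(study, config$target_mm))

  landmarks <- tryCatch(detect_landmarks(study, config),
                        petseg_error = function(e) {
    warning(sprintf("landmark detection failed (%s); using whole-volume CHEST fallback",
                    conditionMessage(e)), call. = FALSE)
    NULL
  })
  regions <- if (is.null(landmarks)) {
    d <- dim(study$pet$data)
    region_map(d, 1L, d[1] + 1L)       # everything CHEST
  } else landmarks$regions

  p2d <- stage("predict_2d", predict_2d(study, model_2d, config$orientations))
  comps <- stage("label_components",
                 label_components(p2d, regions, config$component_threshold))
  if (verbose) message(sprintf("  %d candidate component(s)",
                               if (is.null(comps$components)) 0
                               else nrow(comps$components)))
  patches <- stage("extract_patches", extract_patches(comps, study, config))
  p3d <- stage("refine_3d", refine_3d(patches, models_3d, study$pet$spacing))
  mask <- stage("fuse", fuse_masks(p2d, p3d, config$fusion_threshold))
  metrics <- stage("metrics", tumor_metrics(mask, study$pet))

  dice <- if (!is.null(truth_mask)) dice_score(mask, truth_mask) else NA_real_
  sens <- if (!is.null(truth_mask)) voxel_sensitivity(mask, truth_mask) else NA_real_

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nifti_grid(mask, file.path(out_dir, "mask.nii.gz"))
    write_nifti_grid(p2d, file.path(out_dir, "prob_2d.nii.gz"))
    write_nifti_grid(p3d, file.path(out_dir, "prob_3d.nii.gz"))
    utils::write.csv(metrics_row(metrics, study$study_id, dice, sens),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(landmarks))
      write_landmark_report(landmarks, file.path(out_dir, "landmarks.json"))
  }
  if (verbose) message(sprintf("pipeline done in %.1fs",
                               as.numeric(Sys.time() - t0, units = "secs")))
  list(mask = mask, prob_2d = p2d, prob_3d = p3d, metrics = metrics,
       landmarks = landmarks, regions = regions, components = comps,
       study = study, dice = dice, sensitivity = sens)
}
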
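#' Anatomical landmark detection and body-region partition
#'
#' Whole-body FDG-PET/CT is highly heterogeneous along the body axis, so the
#' pipeline splits the volume into head-neck, chest and abdomen-pelvis slabs
#' before 3D refinement. The split is anchored on three deterministic
#' landmarks: the brain (large high-uptake component in PET), the liver
#' (moderate-uptake component on the patient-right side below the brain) and
#' the lungs (large air cavities in CT). All detectors are pure
#' threshold-and-morphology procedures: identical inputs give bit-identical
#' landmarks.
#'
#' @name anatomy
NULL

new_landmark <- function(name, mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  com <- colMeans(idx)
  bbox <- rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
  colnames(bbox) <- c("z", "y", "x")
  structure(list(
    name = name,
    com_voxel = unname(com),
    volume_ml = nrow(idx) * prod(grid$spacing) / 1000,
    bbox = bbox
  ), class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("<landmark %s> COM (z,y,x) = (%.1f, %.1f, %.1f), %.0f mL\n",
              x$name, x$com_voxel[1], x$com_voxel[2], x$com_voxel[3],
              x$volume_ml))
  invisible(x)
}

component_stats <- function(labels) {
  n <- attr(labels, "n_components")
  if (is.null(n)) n <- max(labels, 0L)
  if (n == 0L) return(data.frame(id = integer(), voxels = integer()))
  tab <- tabulate(labels, nbins = n)
  data.frame(id = seq_len(n), voxels = tab)
}

#' Detect the brain in an SUV volume
#'
#' Thresholds the PET at a high uptake level (default SUV 2.5), labels
#' 26-connected components and returns the most superior (smallest mean z)
#' component with volume at least `min_volume_ml` (default 500 mL, the
#' minimal plausible brain size). Physiological hotspots such as the bladder
#' are far smaller than 500 mL and are excluded by the volume gate; if both
#' qualify the more superior component wins.
#'
#' @param suv a `PET_SUV` voxel grid (2 mm isotropic recommended).
#' @param threshold SUV threshold (default 2.5).
#' @param min_volume_ml minimal component volume (default 500).
#' @return a `landmark` named `BRAIN`.
#' @export
detect_brain <- function(suv, threshold = 2.5, min_volume_ml = 500) {
  stopifnot(inherits(suv, "voxel_grid"))
  mask <- suv$data >= threshold
  labels <- .label3_cpp(mask, dim(mask), 26L)
  st <- component_stats(labels)
  vox_ml <- prod(suv$spacing) / 1000
  st <- st[st$voxels * vox_ml >= min_volume_ml, , drop = FALSE]
  if (!nrow(st))
    petseg_abort(sprintf("no component of at least %g mL above SUV %g",
                         min_volume_ml, threshold), "brain_not_found")
  # most superior = smallest mean z index
  mean_z <- vapply(st$id, function(id) {
    mean(which(labels == id, arr.ind = TRUE)[, 1])
  }, 0)
  pick <- st$id[which.min(mean_z)]
  new_landmark("BRAIN", labels == pick, suv)
}

# Offsets of a discretised sphere of radius r voxels (including center ring).
sphere_offsets <- function(r_vox) {
  r <- ceiling(r_vox)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r_vox^2, ]
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  as.matrix(g)
}

#' Detect the liver in an SUV volume
#'
#' Searches a window inferior to the brain restricted to the patient-right
#' half of the volume, thresholds at normal hepatic uptake (SUV 1.0), fills
#' 3D holes, erodes with a discretised sphere (radius 8 mm) to detach spurious
#' bridges, and among surviving 26-connected components whose center of mass
#' lies in the patient-right third of the x axis returns the largest-volume
#' one (ties broken by the more superior center of mass).
#'
#' The patient-right side corresponds to low x indices under the package axis
#' convention (radiological display left); `side = "patient_left"` flips the
#' window for situs-inversus style inputs.
#'
#' @param suv a `PET_SUV` voxel grid at isotropic spacing.
#' @param brain a `landmark` from [detect_brain()].
#' @param threshold SUV threshold (default 1.0).
#' @param window_mm window below the brain bounding box, mm (default
#'   c(100, 500)).
#' @param erosion_radius_mm radius of the spherical structuring element.
#' @param side which anatomical side to search.
#' @return a `landmark` named `LIVER`.
#' @export
detect_liver <- function(suv, brain, threshold = 1.0,
                         window_mm = c(100, 500), erosion_radius_mm = 8,
                         side = c("patient_right", "patient_left")) {
  side <- match.arg(side)
  stopifnot(inherits(suv, "voxel_grid"), inherits(brain, "landmark"))
  d <- dim(suv$data)
  sz <- suv$spacing[1]
  z0 <- min(d[1], brain$bbox["hi", "z"] + round(window_mm[1] / sz))
  z1 <- min(d[1], brain$bbox["hi", "z"] + round(window_mm[2] / sz))
  if (z0 >= z1) petseg_abort("liver search window empty", "liver_not_found")
  xs <- if (side == "patient_right") seq_len(floor(d[3] / 2))
        else (floor(d[3] / 2) + 1):d[3]

  mask <- array(FALSE, d)
  mask[z0:z1, , xs] <- suv$data[z0:z1, , xs] >= threshold
  mask <- .fill_holes3_cpp(mask, dim(mask))
  r_vox <- erosion_radius_mm / suv$spacing[3]
  eroded <- .erode3_cpp(mask, dim(mask), sphere_offsets(r_vox))
  labels <- .label3_cpp(eroded, dim(eroded), 26L)
  st <- component_stats(labels)
  if (!nrow(st)) petseg_abort("no liver candidate after erosion", "liver_not_found")
  third <- d[3] / 3
  info <- lapply(st$id, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    com <- colMeans(idx)
    ok <- if (side == "patient_right") com[3] <= third else com[3] >= 2 * third
    list(id = id, com = com, n = nrow(idx), ok = ok)
  })
  info <- Filter(function(i) i$ok, info)
  if (!length(info)) petseg_abort("no candidate in the patient-right third",
                                  "liver_not_found")
  n <- vapply(info, `[[`, 0, "n")
  comz <- vapply(info, function(i) i$com[1], 0)
  ord <- order(-n, comz)
  pick <- info[[ord[1]]]$id
  new_landmark("LIVER", labels == pick, suv)
}

#' Detect the lungs in a CT volume
#'
#' Thresholds the CT below -300 HU, keeps the 8 largest 3D components,
#' removes (per axial slice) 2D regions touching the slice boundary -- this
#' eliminates the air surrounding the patient -- erodes the remainder with a
#' 3x3x3 element to cut leakage through the airways, and keeps the two
#' largest surviving components. The landmark is the combined center of mass
#' of their union.
#'
#' @param ct a `CT_HU` voxel grid at isotropic spacing.
#' @param threshold_hu HU threshold (default -300).
#' @param keep_top number of 3D components retained initially (default 8).
#' @param erosion_box odd edge length of the cubic structuring element.
#' @return a `landmark` named `LUNGS` (volume = union volume).
#' @export
detect_lungs <- function(ct, threshold_hu = -300, keep_top = 8,
                         erosion_box = 3) {
  stopifnot(inherits(ct, "voxel_grid"))
  d <- dim(ct$data)
  mask <- ct$data < threshold_hu
  labels <- .label3_cpp(mask, d, 26L)
  st <- component_stats(labels)
  if (!nrow(st)) petseg_abort("no sub-threshold air components", "lungs_not_found")
  keep <- st$id[order(-st$voxels)][seq_len(min(keep_top, nrow(st)))]
  mask <- array(labels %in% keep, d)

  # remove per-axial-slice 2D regions touching the slice border
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    if (!any(sl)) next
    lab2 <- .label2_cpp(sl, dim(sl), 8L)
    border <- unique(c(lab2[1, ], lab2[d[2], ], lab2[, 1], lab2[, d[3]]))
    border <- border[border > 0]
    if (length(border)) mask[z, , ] <- sl & !(lab2 %in% border)
  }

  r <- (erosion_box - 1) / 2
  off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  mask <- .erode3_cpp(mask, d, off)
  labels <- .label3_cpp(mask, d, 26L)
  st <- component_stats(labels)
  if (nrow(st) < 2)
    petseg_abort("fewer than two lung candidates survive", "lungs_not_found")
  keep2 <- st$id[order(-st$voxels)][1:2]
  new_landmark("LUNGS", array(labels %in% keep2, d), ct)
}

#' Partition the body into three axial regions
#'
#' Head-neck / chest / abdomen-pelvis slabs are delimited by two axial planes:
#' the top of the lungs bounding box and the liver center-of-mass plane.
#' Slices above the lung top are `HEAD_NECK`, slices from there to (but
#' excluding) the liver COM are `CHEST`, the remainder `ABDOMEN_PELVIS`.
#'
#' @param shape grid shape (nz, ny, nx).
#' @param liver,lungs `landmark`s from the detectors.
#' @return a `region_map`: per-slab labels plus the two boundary planes.
#' @export
partition_regions <- function(shape, liver, lungs) {
  stopifnot(inherits(liver, "landmark"), inherits(lungs, "landmark"))
  if (lungs$com_voxel[1] >= liver$com_voxel[1])
    petseg_abort("liver COM is superior to lungs COM", "inconsistent_landmarks")
  z_top <- as.integer(lungs$bbox["lo", "z"])
  z_bot <- as.integer(round(liver$com_voxel[1]))
  if (z_top >= z_bot)
    petseg_abort("degenerate region planes", "inconsistent_landmarks")
  region_map(shape, z_top, z_bot)
}

REGION_LEVELS <- c("HEAD_NECK", "CHEST", "ABDOMEN_PELVIS")

#' Construct a region map from explicit chest planes
#'
#' @param shape grid shape (nz, ny, nx).
#' @param z_chest_top,z_chest_bottom axial plane indices,
#'   `z_chest_top < z_chest_bottom`; the chest slab is
#'   `[z_chest_top, z_chest_bottom)`.
#' @return a `region_map`.
#' @export
region_map <- function(shape, z_chest_top, z_chest_bottom) {
  stopifnot(z_chest_top < z_chest_bottom)
  z <- seq_len(shape[1])
  z_labels <- ifelse(z < z_chest_top, 1L, ifelse(z < z_chest_bottom, 2L, 3L))
  structure(list(shape = as.integer(shape),
                 z_labels = z_labels,
                 boundary_planes = c(z_chest_top = as.integer(z_chest_top),
                                     z_chest_bottom = as.integer(z_chest_bottom))),
            class = "region_map")
}

#' Region label of an axial slice index
#' @param regions a `region_map`; @param z axial indices.
#' @return character vector of region names.
#' @export
region_of_z <- function(regions, z) {
  REGION_LEVELS[regions$z_labels[pmin(pmax(as.integer(round(z)), 1L),
                                      regions$shape[1])]]
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %s; chest z in [%d, %d)\n",
              paste(x$shape, collapse = "x"),
              x$boundary_planes[1], x$boundary_planes[2]))
  invisible(x)
}

#' Expand a region map to a per-voxel integer label array
#' @param regions a `region_map`.
#' @return integer array (1 = HEAD_NECK, 2 = CHEST, 3 = ABDOMEN_PELVIS).
#' @export
region_array <- function(regions) {
  array(rep(regions$z_labels,
            times = regions$shape[2] * regions$shape[3]), regions$shape)
}

#' Detect all landmarks of a study
#'
#' Convenience wrapper running [detect_brain()], [detect_liver()],
#' [detect_lungs()] and [partition_regions()].
#'
#' @param study a preprocessed `petct_study` (PET in SUV, isotropic).
#' @param config a [pipeline_config()] controlling thresholds.
#' @return list with `brain`, `liver`, `lungs`, `regions`.
#' @export
detect_landmarks <- function(study, config = pipeline_config()) {
  brain <- detect_brain(study$pet, config$brain_threshold,
                        config$brain_min_volume_ml)
  liver <- detect_liver(study$pet, brain, config$liver_threshold,
                        config$liver_window_mm, config$liver_erosion_mm,
                        config$liver_side)
  lungs <- detect_lungs(study$ct, config$lung_threshold_hu,
                        config$lung_keep_top, config$lung_erosion_box)
  regions <- partition_regions(dim(study$pet$data), liver, lungs)
  list(brain = brain, liver = liver, lungs = lungs, regions = regions)
}

#' Write a landmark report as JSON
#'
#' @param landmarks result of [detect_landmarks()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmark_report <- function(landmarks, path) {
  as_plain <- function(lm) list(
    name = lm$name, com_voxel = lm$com_voxel, volume_ml = lm$volume_ml,
    bbox = list(lo = unname(lm$bbox["lo", ]), hi = unname(lm$bbox["hi", ])))
  rep <- list(
    brain = as_plain(landmarks$brain),
    liver = as_plain(landmarks$liver),
    lungs = as_plain(landmarks$lungs),
    boundary_planes = as.list(landmarks$regions$boundary_planes))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
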
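#' Synthetic whole-body PET/CT phantom specification
#'
#' Describes a seeded, eyes-to-thighs digital phantom: a soft-tissue body
#' envelope (elliptical cylinder, 40 HU) in air (-1000 HU) containing a
#' high-uptake brain sphere (SUV 6, > 500 mL), two air-filled lungs
#' (-700 HU, SUV 0.3), a moderate-uptake liver ellipsoid (SUV 2, ~1500 mL) on
#' the patient-right side, heart (SUV 5) and bladder (SUV 8) hotspots, a
#' mildly avid body background (SUV 0.7), and a configurable number of
#' ellipsoidal tumors with uptake sampled in `tumor_suv`. Organs are rendered
#' as hard-boundary ellipsoids (no partial volume); additive Gaussian noise is
#' applied per modality after rendering. Geometry follows the package axis
#' convention (z index 1 superior, x index 1 patient-right).
#'
#' The defaults (220 x 112 x 128 voxels at 2 mm) span 44 cm of body axis and
#' render in seconds, so a full pipeline run on one phantom stays well under a
#' minute on a single CPU.
#'
#' @param seed RNG seed (determines tumors and noise).
#' @param grid_shape (nz, ny, nx), default c(220, 112, 128).
#' @param spacing_mm isotropic voxel size, default 2.
#' @param n_tumors number of tumors, default 3.
#' @param tumor_radii_mm range of tumor semi-axes in mm, default c(4, 10).
#' @param tumor_suv range of tumor uptake, default c(3, 10).
#' @param region_weights placement weights for (head-neck, chest,
#'   abdomen-pelvis), default equal.
#' @param noise_sigma_pet,noise_sigma_ct additive Gaussian noise SD per
#'   modality (SUV / HU units), defaults 0.1 and 15.
#' @param organs named list overriding organ geometry/uptake defaults
#'   (see `phantom_organs()`).
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1,
                         grid_shape = c(220, 112, 128),
                         spacing_mm = 2,
                         n_tumors = 3,
                         tumor_radii_mm = c(4, 10),
                         tumor_suv = c(3, 10),
                         region_weights = c(1, 1, 1),
                         noise_sigma_pet = 0.1,
                         noise_sigma_ct = 15,
                         organs = list()) {
  org <- utils::modifyList(phantom_organs(), organs)
  structure(list(seed = seed, grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm, n_tumors = n_tumors,
                 tumor_radii_mm = tumor_radii_mm, tumor_suv = tumor_suv,
                 region_weights = region_weights / sum(region_weights),
                 noise_sigma_pet = noise_sigma_pet,
                 noise_sigma_ct = noise_sigma_ct,
                 organs = org),
            class = "phantom_spec")
}

# Canonical organ layout, in voxel units of the default 2 mm lattice: centers
# (z, y, x) and semi-axes (mm). Brain 523 mL; each lung 268 mL; liver 1470 mL
# (within the patient-right half so the liver detector window captures it);
# heart displaced patient-left; bladder inferior midline.
phantom_organs <- function() {
  list(
    body    = list(center_yx = c(56, 64), semi_mm = c(100, 120),
                   z_range = c(5, 215), hu = 40, suv = 0.7),
    brain   = list(center = c(35, 56, 64), semi_mm = c(50, 50, 50), suv = 6),
    lung_r  = list(center = c(90, 60, 40), semi_mm = c(50, 40, 32),
                   hu = -700, suv = 0.3),
    lung_l  = list(center = c(90, 60, 88), semi_mm = c(50, 40, 32),
                   hu = -700, suv = 0.3),
    heart   = list(center = c(100, 56, 78), semi_mm = c(30, 30, 30), suv = 5),
    liver   = list(center = c(150, 56, 38), semi_mm = c(75, 78, 60), suv = 2),
    bladder = list(center = c(195, 60, 64), semi_mm = c(24, 24, 24), suv = 8)
  )
}

# Separable ellipsoid rasteriser: returns the (z, y, x) index ranges and a
# logical sub-array of voxels whose centers fall inside the ellipsoid.
ellipsoid_patch <- function(center, semi_mm, spacing, shape) {
  semi_vox <- semi_mm / spacing
  lo <- pmax(1L, floor(center - semi_vox))
  hi <- pmin(shape, ceiling(center + semi_vox))
  ax <- lapply(1:3, function(a) ((lo[a]:hi[a]) - center[a])^2 / semi_vox[a]^2)
  f <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3], inside = f <= 1)
}

paint <- function(arr, patch, value) {
  sub <- arr[patch$z, patch$y, patch$x]
  sub[patch$inside] <- value
  arr[patch$z, patch$y, patch$x] <- sub
  arr
}

#' Generate a synthetic PET/CT phantom with ground truth
#'
#' Renders the CT (HU) and PET (SUV) volumes described by a [phantom_spec()],
#' placing tumors by rejection sampling: a region is drawn from
#' `region_weights`, then a center uniformly inside the body envelope of that
#' slab, rejecting positions that overlap the brain or a previously placed
#' tumor. Rendering is deterministic per seed; the ground truth (tumor mask,
#' organ centers-of-mass and volumes measured on the rendered masks, region
#' planes) is exact by construction and unaffected by the additive noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with `study` (a `petct_study`, PET in SUV) and `truth`
#'   (tumor mask grid, per-organ landmarks, region planes, per-tumor table).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr_seed(spec$seed, {
    d <- spec$grid_shape
    sp <- spec$spacing_mm
    org <- spec$organs

    ct <- array(-1000, d)
    pet <- array(0, d)

    # body envelope: elliptical cylinder over a z range
    b <- org$body
    zr <- max(1L, round(b$z_range[1])):min(d[1], round(b$z_range[2]))
    ay <- (seq_len(d[2]) - b$center_yx[1])^2 / (b$semi_mm[1] / sp)^2
    axx <- (seq_len(d[3]) - b$center_yx[2])^2 / (b$semi_mm[2] / sp)^2
    body_yx <- outer(ay, axx, "+") <= 1
    body <- array(FALSE, d)
    for (z in zr) body[z, , ] <- body_yx
    ct[body] <- b$hu
    pet[body] <- b$suv

    masks <- list()
    for (nm in c("brain", "lung_r", "lung_l", "heart", "liver", "bladder")) {
      o <- org[[nm]]
      p <- ellipsoid_patch(o$center, o$semi_mm, sp, d)
      m <- array(FALSE, d)
      sub <- m[p$z, p$y, p$x]; sub[p$inside] <- TRUE
      m[p$z, p$y, p$x] <- sub
      m <- m & body
      masks[[nm]] <- m
      if (!is.null(o$hu)) ct[m] <- o$hu
      pet[m] <- o$suv
    }

    # region planes implied by the rendered anatomy
    lung_union <- masks$lung_r | masks$lung_l
    z_top <- min(which(apply(lung_union, 1, any)))
    liver_idx <- which(masks$liver, arr.ind = TRUE)
    z_bot <- as.integer(round(mean(liver_idx[, 1])))

    # tumor placement
    tumor_mask <- array(FALSE, d)
    brain_c <- org$brain$center; brain_r <- max(org$brain$semi_mm) / sp
    tumors <- list()
    if (spec$n_tumors > 0) {
      slabs <- list(c(zr[1], z_top - 1), c(z_top, z_bot - 1), c(z_bot, zr[length(zr)]))
      for (t in seq_len(spec$n_tumors)) {
        placed <- FALSE
        for (try in 1:200) {
          reg <- sample.int(3, 1, prob = spec$region_weights)
          semi <- stats::runif(3, spec$tumor_radii_mm[1], spec$tumor_radii_mm[2])
          rv <- max(semi) / sp
          zlo <- slabs[[reg]][1] + ceiling(rv); zhi <- slabs[[reg]][2] - ceiling(rv)
          if (zlo >= zhi) next
          cz <- stats::runif(1, zlo, zhi)
          # uniform in the shrunken body ellipse so the tumor stays inside
          repeat {
            cy <- stats::runif(1, 1, d[2]); cx <- stats::runif(1, 1, d[3])
            if ((cy - b$center_yx[1])^2 / ((b$semi_mm[1] - max(semi)) / sp)^2 +
                (cx - b$center_yx[2])^2 / ((b$semi_mm[2] - max(semi)) / sp)^2 <= 1)
              break
          }
          cen <- c(cz, cy, cx)
          if (sqrt(sum((cen - brain_c)^2)) < brain_r + rv + 2) next
          clash <- any(vapply(tumors, function(tt)
            sqrt(sum((cen - tt$center)^2)) < max(tt$semi_mm) / sp + rv + 2, TRUE))
          if (clash) next
          suv_t <- stats::runif(1, spec$tumor_suv[1], spec$tumor_suv[2])
          p <- ellipsoid_patch(cen, semi, sp, d)
          sub <- tumor_mask[p$z, p$y, p$x]; sub[p$inside] <- TRUE
          tumor_mask[p$z, p$y, p$x] <- sub
          ct <- paint(ct, p, 40)            # tumors are soft tissue on CT
          pet <- paint(pet, p, suv_t)
          vol_ml <- sum(p$inside) * sp^3 / 1000
          tumors[[t]] <- list(center = cen, semi_mm = semi, suv = suv_t,
                              volume_ml = vol_ml, region = REGION_LEVELS[reg])
          placed <- TRUE
          break
        }
        if (!placed)
          petseg_abort(sprintf("could not place tumor %d without overlap", t),
                       "phantom_placement")
      }
    }

    if (spec$noise_sigma_ct > 0)
      ct <- ct + array(stats::rnorm(length(ct), 0, spec$noise_sigma_ct), d)
    if (spec$noise_sigma_pet > 0)
      pet <- pmax(pet + array(stats::rnorm(length(pet), 0, spec$noise_sigma_pet), d), 0)

    pet_grid <- voxel_grid(pet, sp, modality = "PET_SUV")
    ct_grid <- voxel_grid(ct, sp, modality = "CT_HU")
    study <- petct_study(pet_grid, ct_grid,
                         study_id = sprintf("phantom-%d", spec$seed),
                         check = TRUE)

    truth <- list(
      tumor_mask = voxel_grid(tumor_mask * 1, sp, modality = "MASK"),
      brain = new_landmark("BRAIN", masks$brain, pet_grid),
      liver = new_landmark("LIVER", masks$liver, pet_grid),
      lungs = new_landmark("LUNGS", lung_union, pet_grid),
      boundary_planes = c(z_chest_top = z_top, z_chest_bottom = z_bot),
      tumors = tumors,
      tmtv_ml = sum(tumor_mask) * sp^3 / 1000
    )
    list(study = study, truth = truth, spec = spec)
  })
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_studies` phantoms (PET, CT and truth mask as NIfTI; truth summary
#' as JSON) plus a manifest. Phantom i uses seed `seed + i - 1`, so the
#' dataset is reproducible from `(template, seed)`.
#'
#' @param n_studies number of phantoms.
#' @param template a [phantom_spec()] used for every study (its seed field is
#'   overridden).
#' @param seed base seed.
#' @param out_dir output directory (created if needed).
#' @return manifest data.frame (also written to `manifest.json`), invisibly.
#' @export
generate_dataset <- function(n_studies, template = phantom_spec(), seed = 1,
                             out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    sp <- template; sp$seed <- seed + i - 1
    ph <- generate_phantom(sp)
    id <- ph$study$study_id
    pet_p <- file.path(out_dir, paste0(id, "_pet.nii.gz"))
    ct_p <- file.path(out_dir, paste0(id, "_ct.nii.gz"))
    mask_p <- file.path(out_dir, paste0(id, "_truth_mask.nii.gz"))
    truth_p <- file.path(out_dir, paste0(id, "_truth.json"))
    write_nifti_grid(ph$study$pet, pet_p)
    write_nifti_grid(ph$study$ct, ct_p)
    write_nifti_grid(ph$truth$tumor_mask, mask_p)
    jsonlite::write_json(list(
      seed = sp$seed, tmtv_ml = ph$truth$tmtv_ml,
      n_tumors = length(ph$truth$tumors),
      brain_com = ph$truth$brain$com_voxel,
      liver_com = ph$truth$liver$com_voxel,
      lungs_com = ph$truth$lungs$com_voxel,
      boundary_planes = as.list(ph$truth$boundary_planes)),
      truth_p, auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(study_id = id, seed = sp$seed,
                            pet = pet_p, ct = ct_p, mask = mask_p,
                            truth = truth_p, tmtv_ml = ph$truth$tmtv_ml,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, dataframe = "rows")
  invisible(manifest)
}
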
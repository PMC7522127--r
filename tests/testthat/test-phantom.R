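test_that("phantom generation is deterministic per seed", {
  a <- generate_phantom(phantom_spec(seed = 42))
  b <- generate_phantom(phantom_spec(seed = 42))
  expect_identical(a$study$pet$data, b$study$pet$data)
  expect_identical(a$study$ct$data, b$study$ct$data)
  expect_identical(a$truth$tumor_mask$data, b$truth$tumor_mask$data)
  c_ <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(a$study$pet$data, c_$study$pet$data))
})

test_that("the requested number of disjoint tumors is rendered", {
  ph <- generate_phantom(phantom_spec(seed = 1, n_tumors = 3))
  labels <- petseg:::.label3_cpp(ph$truth$tumor_mask$data > 0,
                                 dim(ph$truth$tumor_mask$data), 26L)
  expect_equal(attr(labels, "n_components"), 3L)

  none <- generate_phantom(phantom_spec(seed = 2, n_tumors = 0))
  expect_equal(sum(none$truth$tumor_mask$data), 0)
})

test_that("a noiseless phantom renders tumor SUV exactly", {
  sp <- phantom_spec(seed = 5, n_tumors = 1, tumor_suv = c(5, 5),
                     noise_sigma_pet = 0, noise_sigma_ct = 0)
  ph <- generate_phantom(sp)
  suv_in_mask <- ph$study$pet$data[ph$truth$tumor_mask$data > 0]
  expect_equal(max(suv_in_mask), 5)
  expect_equal(min(suv_in_mask), 5)
})

test_that("rendered organs match their specification geometry", {
  ph <- test_phantom(1)
  org <- ph$spec$organs
  sp <- ph$spec$spacing_mm
  vol_sphere <- function(semi) 4 / 3 * pi * prod(semi) / 1000

  # centers within 1 voxel, volumes within 3% of the analytic ellipsoid
  expect_lt(com_error(ph$truth$brain$com_voxel, org$brain$center), 1)
  expect_lt(abs(ph$truth$brain$volume_ml - vol_sphere(org$brain$semi_mm)) /
            vol_sphere(org$brain$semi_mm), 0.03)
  expect_lt(com_error(ph$truth$liver$com_voxel, org$liver$center), 1)
  expect_lt(abs(ph$truth$liver$volume_ml - vol_sphere(org$liver$semi_mm)) /
            vol_sphere(org$liver$semi_mm), 0.03)
  lung_mid <- (org$lung_r$center + org$lung_l$center) / 2
  expect_lt(com_error(ph$truth$lungs$com_voxel, lung_mid), 1)
  expect_lt(abs(ph$truth$lungs$volume_ml - 2 * vol_sphere(org$lung_r$semi_mm)) /
            (2 * vol_sphere(org$lung_r$semi_mm)), 0.03)

  # anatomical ordering along the body axis
  expect_lt(ph$truth$brain$com_voxel[1], ph$truth$lungs$com_voxel[1])
  expect_lt(ph$truth$lungs$com_voxel[1], ph$truth$liver$com_voxel[1])
})

test_that("tumors avoid the brain and stay inside the body", {
  for (s in 1:6) {
    ph <- test_phantom(s)
    mask <- ph$truth$tumor_mask$data > 0
    brain_c <- ph$spec$organs$brain$center
    brain_r <- max(ph$spec$organs$brain$semi_mm) / ph$spec$spacing_mm
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx)) {
      d2 <- (idx[, 1] - brain_c[1])^2 + (idx[, 2] - brain_c[2])^2 +
            (idx[, 3] - brain_c[3])^2
      expect_true(all(d2 > brain_r^2))
      # tumor voxels carry soft-tissue CT (before noise, ~40 HU)
      expect_gt(min(ph$study$ct$data[mask]), 40 - 6 * 15)
    }
  }
})

test_that("the phantom population covers all three regions with tumors", {
  regions <- c(
    unlist(lapply(TRAIN_SEEDS, function(s)
      vapply(test_phantom(s)$truth$tumors, `[[`, "", "region"))),
    holdout_results()$tumor_regions)
  expect_true(all(c("HEAD_NECK", "CHEST", "ABDOMEN_PELVIS") %in% regions))
})

test_that("generate_dataset writes a reproducible manifest with valid truths", {
  dir1 <- file.path(tempdir(), "phantom_ds1")
  man <- generate_dataset(3, phantom_spec(n_tumors = 2), seed = 30,
                          out_dir = dir1)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$pet, man$ct, man$mask)))

  # written mask TMTV agrees with the manifest
  for (i in 1:3) {
    mask <- read_nifti_grid(man$mask[i], modality = "MASK")
    suv <- read_nifti_grid(man$pet[i], modality = "PET_SUV")
    tm <- tumor_metrics(mask, suv)
    expect_equal(tm$tmtv_ml, man$tmtv_ml[i], tolerance = 1e-9)
  }

  # re-running reproduces the same truths
  dir2 <- file.path(tempdir(), "phantom_ds2")
  man2 <- generate_dataset(3, phantom_spec(n_tumors = 2), seed = 30,
                           out_dir = dir2)
  expect_equal(man2$tmtv_ml, man$tmtv_ml)
})
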
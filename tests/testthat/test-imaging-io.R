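test_that("voxel_grid enforces its invariants", {
  expect_s3_class(voxel_grid(array(0, c(2, 3, 4)), 2, modality = "CT_HU"),
                  "voxel_grid")
  expect_error(voxel_grid(array(NA_real_, c(2, 2, 2)), 2, modality = "CT_HU"),
               class = "petseg_bad_grid")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), c(2, -1, 2), modality = "CT_HU"),
               class = "petseg_bad_grid")
  expect_error(voxel_grid(array(0.5, c(2, 2, 2)), 2, modality = "MASK"),
               class = "petseg_bad_grid")
  expect_error(voxel_grid(array(1.5, c(2, 2, 2)), 2, modality = "PROB"),
               class = "petseg_bad_grid")
  expect_equal(voxel_volume_ml(voxel_grid(array(0, c(2, 2, 2)), 2,
                                          modality = "CT_HU")), 0.008)
})

test_that("SUV conversion matches the closed form", {
  act <- voxel_grid(array(5000, c(4, 4, 4)), 4, modality = "PET_ACTIVITY")
  cal <- suv_calibration(injected_dose_bq = 3.5e8, patient_weight_g = 70000,
                         injection_time = 0, acquisition_time = 0)
  suv <- compute_suv(act, cal)
  expect_equal(suv$modality, "PET_SUV")
  expect_equal(unique(as.numeric(suv$data)), 1.0)

  # one half-life of decay doubles the SUV
  cal2 <- suv_calibration(injected_dose_bq = 3.5e8, patient_weight_g = 70000,
                          injection_time = 0, acquisition_time = 6586.2)
  expect_equal(unique(as.numeric(compute_suv(act, cal2)$data)), 2.0)

  # zero activity stays zero
  z <- voxel_grid(array(0, c(2, 2, 2)), 2, modality = "PET_ACTIVITY")
  expect_true(all(compute_suv(z, cal)$data == 0))
})

test_that("SUV conversion is linear in activity and validates inputs", {
  set.seed(11)
  a <- voxel_grid(array(runif(60, 0, 9000), c(3, 4, 5)), 2,
                  modality = "PET_ACTIVITY")
  cal <- suv_calibration(injected_dose_bq = 2e8, patient_weight_g = 80000,
                         injection_time = "100000",
                         acquisition_time = "101500")
  s1 <- compute_suv(a, cal)
  a3 <- voxel_grid(a$data * 3, 2, modality = "PET_ACTIVITY")
  expect_equal(compute_suv(a3, cal)$data, 3 * s1$data, tolerance = 1e-12)

  bad <- suv_calibration(injected_dose_bq = -1, patient_weight_g = 7e4,
                         injection_time = 0, acquisition_time = 0)
  expect_error(compute_suv(a, bad), class = "petseg_bad_calibration")
  neg_dt <- suv_calibration(injected_dose_bq = 1e8, patient_weight_g = 7e4,
                            injection_time = 100, acquisition_time = 0)
  expect_error(compute_suv(a, neg_dt), class = "petseg_bad_calibration")
  incomplete <- suv_calibration(injected_dose_bq = 1e8)
  expect_false(suv_calibration_complete(incomplete))
  expect_error(compute_suv(a, incomplete), class = "petseg_bad_calibration")
})

test_that("isotropic resampling meets its contract", {
  # constant volume: exact preservation, exact target spacing
  g <- voxel_grid(array(7, c(20, 22, 24)), 4, modality = "CT_HU")
  r <- resample_isotropic(g, 2)
  expect_identical(r$spacing, c(2, 2, 2))
  expect_true(all(r$data == 7))
  expect_equal(dim(r$data), c(40, 44, 48))

  # binary masks stay binary under nearest-neighbour
  set.seed(3)
  m <- voxel_grid(array(rbinom(20 * 22 * 24, 1, 0.3), c(20, 22, 24)), 4,
                  modality = "MASK")
  rm_ <- resample_isotropic(m, 2)
  expect_true(all(rm_$data %in% c(0, 1)))

  # smooth ramp: mean preserved within 1%
  ramp <- array(rep(seq(0, 100, length.out = 30), each = 1),
                c(30, 24, 20))
  for (z in 1:30) ramp[z, , ] <- z * 3
  gr <- voxel_grid(ramp, 3, modality = "PET_SUV")
  rr <- resample_isotropic(gr, 2)
  expect_lt(abs(mean(rr$data) - mean(ramp)) / mean(ramp), 0.01)

  # idempotence at target spacing
  r2 <- resample_isotropic(r, 2)
  expect_equal(r2$data, r$data, tolerance = 1e-6)
})

test_that("reformat produces correctly shaped stacks and restack inverts", {
  set.seed(4)
  g <- voxel_grid(array(rnorm(20 * 22 * 26), c(20, 22, 26)), 2,
                  modality = "PET_SUV")
  ax <- reformat(g, "axial")
  expect_length(ax$slices, 20)
  expect_equal(dim(ax$slices[[1]]), c(22, 26))
  co <- reformat(g, "coronal")
  expect_length(co$slices, 22)
  expect_equal(dim(co$slices[[1]]), c(20, 26))
  sa <- reformat(g, "sagittal")
  expect_length(sa$slices, 26)
  expect_equal(dim(sa$slices[[1]]), c(20, 22))
  for (p in c("axial", "coronal", "sagittal"))
    expect_identical(restack(reformat(g, p))$data, g$data)
})

test_that("fit_slice composes with its inverse to the identity", {
  set.seed(5)
  for (hw in list(c(224, 256), c(500, 600), c(448, 512), c(300, 520))) {
    sl <- matrix(rnorm(prod(hw)), hw[1], hw[2])
    f <- fit_slice(sl, c(448, 512))
    expect_equal(dim(f$slice), c(448, 512))
    back <- unfit_slice(f$slice, f$geom)
    expect_equal(dim(back), hw)
    # the inverse restores every value that survived the crop
    kept <- back[f$geom$src_r, f$geom$src_c]
    expect_identical(kept, sl[f$geom$src_r, f$geom$src_c])
    if (all(hw <= c(448, 512))) expect_identical(back, sl)
  }
  z <- fit_slice(matrix(0, 10, 10), c(16, 16))
  expect_true(all(z$slice == 0))
})

test_that("NIfTI round-trips preserve data, spacing and axis order", {
  set.seed(6)
  g <- voxel_grid(array(rnorm(10 * 12 * 14), c(10, 12, 14)),
                  c(2, 2.5, 3), modality = "CT_HU")
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_grid(g, path)
  back <- read_nifti_grid(path, "CT_HU")
  expect_equal(back$data, g$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, g$spacing, tolerance = 1e-6)
})

test_that("the DICOM reader decodes geometry, rescale and calibration", {
  dir <- file.path(tempdir(), "dcm_pet")
  dir.create(dir, showWarnings = FALSE)
  px1 <- matrix(100, 6, 8); px1[2, 3] <- 250
  px2 <- matrix(50, 6, 8)
  write_test_dicom(file.path(dir, "a.dcm"), px1, instance = 1, slope = 2,
                   intercept = 10)
  write_test_dicom(file.path(dir, "b.dcm"), px2, instance = 2, slope = 2,
                   intercept = 10)
  ser <- read_dicom_series(dir)
  expect_equal(dim(ser$data), c(2, 6, 8))
  expect_equal(ser$data[1, 2, 3], 2 * 250 + 10)   # slope/intercept applied
  expect_equal(ser$data[2, 1, 1], 110)
  expect_equal(ser$spacing, c(4, 4, 4))
  expect_true(suv_calibration_complete(ser$calibration))
  expect_equal(ser$calibration$patient_weight_g, 70000)
  expect_equal(ser$calibration$injected_dose_bq, 3.5e8)
  expect_equal(ser$patient_id, "P001")
})

test_that("a PET series without weight loads with incomplete calibration", {
  dir <- file.path(tempdir(), "dcm_noweight")
  dir.create(dir, showWarnings = FALSE)
  write_test_dicom(file.path(dir, "a.dcm"), matrix(10, 4, 4),
                   include_weight = FALSE)
  ser <- read_dicom_series(dir)
  expect_false(suv_calibration_complete(ser$calibration))
  expect_equal(dim(ser$data), c(1, 4, 4))
})

test_that("load_study flags patient ID mismatches and reads NIfTI pairs", {
  d1 <- file.path(tempdir(), "dcm_p1"); dir.create(d1, showWarnings = FALSE)
  d2 <- file.path(tempdir(), "dcm_p2"); dir.create(d2, showWarnings = FALSE)
  write_test_dicom(file.path(d1, "a.dcm"), matrix(1, 4, 4), patient_id = "A")
  write_test_dicom(file.path(d2, "a.dcm"), matrix(1, 4, 4), patient_id = "B")
  expect_error(load_study(d1, d2), class = "petseg_id_mismatch")

  # NIfTI pair with JSON sidecar calibration
  pet_p <- tempfile(fileext = ".nii.gz")
  ct_p <- tempfile(fileext = ".nii.gz")
  write_nifti_grid(voxel_grid(array(5000, c(6, 6, 6)), 4,
                              modality = "PET_SUV"), pet_p)
  write_nifti_grid(voxel_grid(array(40, c(6, 6, 6)), 4,
                              modality = "CT_HU"), ct_p)
  jsonlite::write_json(list(injected_dose_bq = 3.5e8, patient_weight_g = 7e4,
                            injection_time = 0, acquisition_time = 0),
                       paste0(sub("\\.nii\\.gz$", "", pet_p), ".json"),
                       auto_unbox = TRUE)
  st <- load_study(pet_p, ct_p)
  expect_s3_class(st, "petct_study")
  expect_true(suv_calibration_complete(st$calibration))
  pp <- preprocess_study(st, 2)
  expect_equal(unique(as.numeric(pp$pet$data)), 1.0)   # SUV closed form
  expect_equal(dim(pp$pet$data), dim(pp$ct$data))
})
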
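# Landmark detectors exercised on constructed volumes and on the phantom.

sphere_grid <- function(shape, centers, radii_vox, values, background = 0,
                        spacing = 2, modality = "PET_SUV") {
  arr <- array(background, shape)
  for (i in seq_along(values)) {
    c0 <- centers[[i]]; r <- radii_vox[i]
    zr <- max(1, floor(c0[1] - r)):min(shape[1], ceiling(c0[1] + r))
    yr <- max(1, floor(c0[2] - r)):min(shape[2], ceiling(c0[2] + r))
    xr <- max(1, floor(c0[3] - r)):min(shape[3], ceiling(c0[3] + r))
    for (z in zr) for (y in yr) for (x in xr)
      if ((z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2 <= r^2)
        arr[z, y, x] <- values[i]
  }
  voxel_grid(arr, spacing, modality = modality)
}

test_that("brain detection picks the most superior large component", {
  # 600 mL sphere: r = (3V/4pi)^(1/3) = 52.4 mm = 26.2 voxels at 2 mm
  g <- sphere_grid(c(120, 80, 80), list(c(30, 40, 40)), 26.2, 6,
                   background = 0.4)
  lm <- detect_brain(g)
  expect_equal(lm$name, "BRAIN")
  expect_gte(lm$volume_ml, 500)
  expect_lt(com_error(lm$com_voxel, c(30, 40, 40)), 2)

  # a 100 mL sphere (r = 14.4 vox) is below the volume gate
  small <- sphere_grid(c(120, 80, 80), list(c(30, 40, 40)), 14.4, 6)
  expect_error(detect_brain(small), class = "petseg_brain_not_found")

  # two qualifying components: the more superior one wins
  two <- sphere_grid(c(160, 80, 80), list(c(30, 40, 40), c(120, 40, 40)),
                     c(26.2, 26.2), c(6, 8))
  lm2 <- detect_brain(two)
  expect_lt(com_error(lm2$com_voxel, c(30, 40, 40)), 2)
})

test_that("liver detection finds the right-sided component below the brain", {
  ph <- test_phantom(1)
  brain <- detect_brain(ph$study$pet)
  liver <- detect_liver(ph$study$pet, brain)
  expect_lt(com_error(liver$com_voxel, ph$truth$liver$com_voxel), 2)

  # nothing above threshold -> not found
  flat <- voxel_grid(array(0.5, c(120, 60, 60)), 2, modality = "PET_SUV")
  expect_error(detect_liver(flat, brain), class = "petseg_liver_not_found")
})

test_that("a small spurious hot node does not displace the liver", {
  ph <- test_phantom(2)
  pet <- ph$study$pet
  # inject a 50 mL hot node in the search window, patient-right
  node <- sphere_grid(dim(pet$data), list(c(180, 56, 20)), 11.4, 3)
  pet2 <- voxel_grid(pmax(pet$data, node$data), 2, modality = "PET_SUV")
  brain <- detect_brain(pet2)
  liver <- detect_liver(pet2, brain)
  expect_lt(com_error(liver$com_voxel, ph$truth$liver$com_voxel), 2)
})

test_that("erosion output is a subset of its input", {
  set.seed(9)
  m <- array(runif(40 * 40 * 40) < 0.4, c(40, 40, 40))
  er <- petseg:::.erode3_cpp(m, dim(m), petseg:::sphere_offsets(2))
  expect_true(all(!er | m))           # eroded implies original
  expect_lte(sum(er), sum(m))
})

test_that("lung detection recovers the volume-weighted air-cavity midpoint", {
  ph <- test_phantom(1)
  lungs <- detect_lungs(ph$study$ct)
  expect_lt(com_error(lungs$com_voxel, ph$truth$lungs$com_voxel), 2)

  # background air touches every slice border on the phantom CT, so the
  # surviving components must be inside the body
  expect_gt(lungs$volume_ml, 100)
  expect_lt(lungs$volume_ml, 1000)

  flat <- voxel_grid(array(40, c(60, 40, 40)), 2, modality = "CT_HU")
  expect_error(detect_lungs(flat), class = "petseg_lungs_not_found")
})

test_that("region partition tiles the volume with ordered slabs", {
  ph <- test_phantom(1)
  lm <- detect_landmarks(ph$study)
  rg <- lm$regions
  d <- dim(ph$study$pet$data)

  labs <- region_array(rg)
  expect_equal(length(labs), prod(d))
  counts <- table(factor(labs, levels = 1:3))
  expect_equal(sum(counts), prod(d))          # labels tile the volume
  expect_true(all(counts > 0))

  expect_equal(region_of_z(rg, 1), "HEAD_NECK")
  expect_equal(region_of_z(rg, lm$lungs$com_voxel[1]), "CHEST")
  expect_equal(region_of_z(rg, lm$liver$com_voxel[1] + 5), "ABDOMEN_PELVIS")
  expect_lt(rg$boundary_planes["z_chest_top"],
            rg$boundary_planes["z_chest_bottom"])

  # inconsistent landmarks (liver above lungs) are rejected
  expect_error(partition_regions(d, lm$lungs, lm$liver),
               class = "petseg_inconsistent_landmarks")
})

test_that("detectors are deterministic", {
  ph <- test_phantom(3)
  a <- detect_landmarks(ph$study)
  b <- detect_landmarks(ph$study)
  expect_identical(a$brain$com_voxel, b$brain$com_voxel)
  expect_identical(a$liver$com_voxel, b$liver$com_voxel)
  expect_identical(a$lungs$com_voxel, b$lungs$com_voxel)
})

test_that("landmark reports serialise to JSON", {
  ph <- test_phantom(1)
  lm <- detect_landmarks(ph$study)
  path <- tempfile(fileext = ".json")
  write_landmark_report(lm, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$brain$name, "BRAIN")
  expect_equal(rep$liver$com_voxel, lm$liver$com_voxel, tolerance = 1e-9)
})
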
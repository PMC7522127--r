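test_that("predict_2d honours stub models and orientation averaging", {
  ph <- test_phantom(1)
  # constant emitter -> constant volume (averaging identical constants)
  p <- predict_2d(ph$study, stub_constant(0.5))
  expect_equal(unique(as.numeric(p$data)), 0.5)
  expect_equal(dim(p$data), dim(ph$study$pet$data))

  # orientations disagreeing 1 vs 0 average to 0.5
  d <- dim(ph$study$pet$data)
  flip <- structure(list(fn = function(x, meta)
    matrix(if (meta$orientation == "axial") 1 else 0, dim(x)[1], dim(x)[2])),
    class = "stub_model")
  p2 <- predict_2d(ph$study, flip)
  expect_equal(unique(as.numeric(p2$data)), 0.5)
})

test_that("component labeling assigns regions by centroid and handles ties", {
  rg <- region_map(c(40, 20, 20), 10, 25)
  prob <- array(0, c(40, 20, 20))
  prob[12:14, 5:7, 5:7] <- 0.9      # chest blob
  prob[30:32, 10:12, 10:12] <- 0.7  # abdomen blob
  cs <- label_components(voxel_grid(prob, 2, modality = "PROB"), rg)
  expect_equal(nrow(cs$components), 2)
  expect_setequal(cs$components$region, c("CHEST", "ABDOMEN_PELVIS"))

  # empty probability volume -> empty set
  cs0 <- label_components(voxel_grid(array(0, c(40, 20, 20)), 2,
                                     modality = "PROB"), rg)
  expect_equal(nrow(cs0$components), 0)

  # a blob centred exactly on the boundary plane goes to its centroid region
  prob2 <- array(0, c(40, 20, 20))
  prob2[24:26, 5:7, 5:7] <- 1       # centroid z = 25 = boundary
  cs2 <- label_components(voxel_grid(prob2, 2, modality = "PROB"), rg)
  expect_equal(cs2$components$region, "ABDOMEN_PELVIS")   # z 25 is below chest
})

test_that("patch extraction fits, tiles and inverts exactly", {
  ph <- test_phantom(1)
  rg <- region_map(dim(ph$study$pet$data), 65, 150)
  cfg <- pipeline_config(patch_edges = c(HEAD_NECK = 32, CHEST = 32,
                                         ABDOMEN_PELVIS = 32))

  # small component -> one centred cube
  prob <- array(0, dim(ph$study$pet$data))
  prob[80:85, 50:55, 60:65] <- 1
  cs <- label_components(voxel_grid(prob, 2, modality = "PROB"), rg)
  ps <- extract_patches(cs, ph$study, cfg)
  expect_length(ps$patches, 1)
  expect_equal(dim(ps$patches[[1]]$x), c(32, 32, 32, 2))

  # oversized component -> overlapping tiling covering the bbox
  prob2 <- array(0, dim(ph$study$pet$data))
  prob2[160:240 - 60, 50:55, 30:95] <- 1   # 81 x 6 x 66 bbox > 32
  cs2 <- label_components(voxel_grid(prob2, 2, modality = "PROB"), rg)
  ps2 <- extract_patches(cs2, ph$study, cfg)
  expect_gte(length(ps2$patches), 4)
  covered <- array(FALSE, dim(prob2))
  for (p in ps2$patches)
    covered[p$src[[1]], p$src[[2]], p$src[[3]]] <- TRUE
  expect_true(all(covered[prob2 > 0]))

  # gather/scatter round-trip is exact, including at the volume corner
  cube <- petseg:::gather_cube(ph$study$pet$data, c(2, 2, 2), 32)
  back <- array(0, dim(ph$study$pet$data))
  back[cube$src[[1]], cube$src[[2]], cube$src[[3]]] <-
    cube$cube[cube$dst[[1]], cube$dst[[2]], cube$dst[[3]]]
  expect_identical(back[cube$src[[1]], cube$src[[2]], cube$src[[3]]],
                   ph$study$pet$data[cube$src[[1]], cube$src[[2]],
                                     cube$src[[3]]])
})

test_that("refine_3d averages overlapping patches and zero-fills elsewhere", {
  shape <- c(40, 40, 40)
  mk_patch <- function(center, value) list(
    x = array(value, c(16, 16, 16, 2)), region = "CHEST",
    center = center, edge = 16,
    src = lapply(1:3, function(a) (center[a] - 7):(center[a] + 8)),
    dst = lapply(1:3, function(a) 1:16))
  ps <- structure(list(patches = list(mk_patch(c(12, 12, 12), 0.4),
                                      mk_patch(c(20, 12, 12), 0.8)),
                       shape = shape), class = "patch_set")
  const_model <- function(v) structure(list(fn = function(x, meta)
    array(v, dim(x)[1:3])), class = "stub_model")
  models <- list(CHEST = structure(list(fn = function(x, meta)
    array(mean(x), dim(x)[1:3]) * 0 + x[1, 1, 1, 1]), class = "stub_model"))
  # each patch predicts its constant input value
  p3 <- refine_3d(ps, models)
  expect_equal(p3$data[12, 12, 12], 0.4)       # only patch 1
  expect_equal(p3$data[25, 12, 12], 0.8)       # only patch 2
  expect_equal(p3$data[15, 12, 12], 0.6)       # overlap -> mean(0.4, 0.8)
  expect_equal(p3$data[39, 39, 39], 0)         # outside all patches

  # empty patch set -> all zeros
  p0 <- refine_3d(structure(list(patches = list(), shape = shape),
                            class = "patch_set"), models)
  expect_true(all(p0$data == 0))

  # missing region model is an error
  ps_hn <- ps; ps_hn$patches[[1]]$region <- "HEAD_NECK"
  expect_error(refine_3d(ps_hn, models), class = "petseg_missing_model")
})

test_that("mask fusion averages with ties positive and is idempotent", {
  m <- array(c(0, 1), c(4, 4, 4))
  g <- function(a) voxel_grid(a, 2, modality = "PROB")
  expect_identical(fuse_masks(g(m), g(m))$data, m)        # fuse(m, m) = m
  one <- array(1, c(2, 2, 2)); zero <- array(0, c(2, 2, 2))
  expect_true(all(fuse_masks(g(one), g(zero))$data == 1)) # 0.5 tie -> positive
  lo <- array(0.4, c(2, 2, 2))
  expect_true(all(fuse_masks(g(lo), g(lo))$data == 0))    # 0.4 < 0.5
  expect_error(fuse_masks(g(one), g(array(0, c(2, 2, 3)))),
               class = "petseg_shape_mismatch")
})

test_that("the identity cascade reproduces the phantom truth exactly", {
  ph <- test_phantom(4)
  truth <- ph$truth$tumor_mask
  echo2 <- stub_echo_truth(truth)
  echo3 <- stub_echo_truth(truth)
  models3 <- list(HEAD_NECK = echo3, CHEST = echo3, ABDOMEN_PELVIS = echo3)
  res <- run_pipeline(ph$study, echo2, models3, truth_mask = truth)
  expect_equal(res$dice, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$metrics$n_lesions, 3L)
})

test_that("a zero-tumor phantom with null stubs yields an empty mask", {
  ph <- generate_phantom(phantom_spec(seed = 77, n_tumors = 0))
  zero <- stub_constant(0)
  models3 <- list(HEAD_NECK = zero, CHEST = zero, ABDOMEN_PELVIS = zero)
  res <- run_pipeline(ph$study, zero, models3,
                      truth_mask = ph$truth$tumor_mask)
  expect_equal(sum(res$mask$data), 0)
  expect_equal(res$metrics$tmtv_ml, 0)
  expect_true(is.na(res$metrics$suv_max))
})

test_that("landmark failure degrades to a whole-volume chest fallback", {
  # a tiny all-soft-tissue study: no brain, no lungs
  pet <- voxel_grid(array(0.4, c(40, 32, 32)), 2, modality = "PET_SUV")
  ct <- voxel_grid(array(40, c(40, 32, 32)), 2, modality = "CT_HU")
  study <- petct_study(pet, ct, check = TRUE)
  zero <- stub_constant(0)
  models3 <- list(HEAD_NECK = zero, CHEST = zero, ABDOMEN_PELVIS = zero)
  expect_warning(
    res <- run_pipeline(study, zero, models3),
    "fallback")
  expect_null(res$landmarks)
  expect_equal(unique(region_of_z(res$regions, 1:40)), "CHEST")
})

test_that("pipeline outputs are written to disk when requested", {
  ph <- test_phantom(4)
  truth <- ph$truth$tumor_mask
  echo <- stub_echo_truth(truth)
  models3 <- list(HEAD_NECK = echo, CHEST = echo, ABDOMEN_PELVIS = echo)
  out <- file.path(tempdir(), "pipe_out")
  res <- run_pipeline(ph$study, echo, models3, out_dir = out,
                      truth_mask = truth)
  expect_true(file.exists(file.path(out, "mask.nii.gz")))
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "landmarks.json")))
  mask <- read_nifti_grid(file.path(out, "mask.nii.gz"), "MASK")
  expect_equal(mask$data, res$mask$data, ignore_attr = TRUE)
})

test_that("inference is deterministic for fixed inputs and weights", {
  ph <- test_phantom(5)
  # trained slice network: repeated evaluation is bit-identical
  tr <- trained_2d()
  p1 <- predict_2d(ph$study, tr$net, orientations = "axial")
  p2 <- predict_2d(ph$study, tr$net, orientations = "axial")
  expect_identical(p1$data, p2$data)
  # full cascade with deterministic models
  echo <- stub_echo_truth(ph$truth$tumor_mask)
  models3 <- list(HEAD_NECK = echo, CHEST = echo, ABDOMEN_PELVIS = echo)
  r1 <- run_pipeline(ph$study, echo, models3)
  r2 <- run_pipeline(ph$study, echo, models3)
  expect_identical(r1$mask$data, r2$mask$data)
})
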
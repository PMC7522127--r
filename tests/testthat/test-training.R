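test_that("the 2D learning-rate schedule reproduces the printed rule", {
  plan <- train_plan_2d()
  # independent arithmetic: 1e-5 held for 13 epochs, then halved every 3
  for (e in 0:24) {
    expected <- if (e < 13) 1e-5 else 1e-5 / 2^(1 + (e - 13) %/% 3)
    expect_equal(lr_at(plan, e), expected)
  }
  expect_equal(lr_at(plan, 0), 1e-5)
  expect_equal(lr_at(plan, 13), 5e-6)     # first halving step
  # nonincreasing
  lrs <- vapply(0:24, function(e) lr_at(plan, e), 0)
  expect_true(all(diff(lrs) <= 0))
  expect_error(lr_at(plan, 25), class = "petseg_bad_epoch")
  expect_error(lr_at(plan, -1), class = "petseg_bad_epoch")

  # single-halving variant
  single <- train_plan_2d(schedule = "single")
  expect_equal(lr_at(single, 20), 5e-6)
})

test_that("the 3D learning-rate schedule reproduces the printed rule", {
  plan <- train_plan_3d()
  expect_equal(plan$epochs, 100)
  for (e in 0:99) {
    expected <- if (e < 50) 1e-4 else if (e < 75) 1e-4 / 2 else 1e-4 / 4
    expect_equal(lr_at(plan, e), expected)
  }
  expect_equal(lr_at(plan, 60), 5e-5)
  expect_error(lr_at(plan, 100), class = "petseg_bad_epoch")
})

test_that("slice rebalancing hits the negative-slice target", {
  # synthetic boundary case: 900 tumor slices + 9000 empty -> keep 100 empty
  mk_mask <- function(nz, pos_z) {
    m <- array(0, c(nz, 8, 8))
    m[pos_z, 4, 4] <- 1
    voxel_grid(m, 2, modality = "MASK")
  }
  pet <- voxel_grid(array(1, c(9900, 8, 8)), 2, modality = "PET_SUV")
  ct <- voxel_grid(array(40, c(9900, 8, 8)), 2, modality = "CT_HU")
  study <- petct_study(pet, ct)
  truth <- mk_mask(9900, 1:900)
  ds <- build_slice_dataset(list(study), list(truth), orientations = "axial",
                            neg_fraction = 0.10, seed = 1)
  expect_equal(sum(ds$index$positive), 900)
  expect_equal(sum(!ds$index$positive), 100)

  # neg_fraction 0 keeps only tumor slices
  ds0 <- build_slice_dataset(list(study), list(truth), orientations = "axial",
                             neg_fraction = 0, seed = 1)
  expect_true(all(ds0$index$positive))

  # deterministic per seed
  ds_a <- build_slice_dataset(list(study), list(truth), orientations = "axial",
                              neg_fraction = 0.1, seed = 7)
  ds_b <- build_slice_dataset(list(study), list(truth), orientations = "axial",
                              neg_fraction = 0.1, seed = 7)
  expect_identical(ds_a$index, ds_b$index)

  # all-negative studies are an error
  expect_error(build_slice_dataset(list(study), list(mk_mask(9900, integer(0))),
                                   orientations = "axial"),
               class = "petseg_empty_dataset")
})

test_that("realized negative fraction stays within 0.02 of target on phantoms", {
  bank <- train_bank()[1:2]
  for (s in c(3, 17)) {
    ds <- build_slice_dataset(lapply(bank, `[[`, "study"),
                              lapply(bank, function(p) p$truth$tumor_mask),
                              orientations = c("axial", "sagittal"),
                              neg_fraction = 0.10, seed = s)
    expect_lt(abs(mean(!ds$index$positive) - 0.10), 0.02)
  }
})

test_that("get_slice returns aligned normalised channels and targets", {
  ds <- tiny_slice_dataset()
  sl <- get_slice(ds, 1)
  expect_equal(length(dim(sl$x)), 3)
  expect_equal(dim(sl$x)[3], 2)
  expect_equal(dim(sl$y), dim(sl$x)[1:2])
  expect_true(all(sl$y %in% c(0, 1)))
})

test_that("patch datasets pair component cubes with clean negatives", {
  pds <- tiny_patch_dataset()
  expect_gte(length(pds$patches), 40)
  npos <- sum(vapply(pds$patches, function(p) sum(p$y) > 0, TRUE))
  expect_equal(npos, length(pds$patches) - npos)    # 1:1 by construction
  for (p in pds$patches[1:5]) {
    expect_equal(dim(p$x), c(32, 32, 32, 2))
    expect_equal(dim(p$y), c(32, 32, 32))
  }
})

test_that("2D training histories are reproducible for a fixed seed", {
  ds <- tiny_slice_dataset()
  sub <- ds; sub$index <- sub$index[1:12, ]
  cfg <- net_config_2d(depth = 2, base_filters = 2, input_hw = NULL)
  plan <- train_plan_2d(epochs = 2, batch = 4, base_lr = 1e-3,
                        schedule = "constant")
  t1 <- train_2d(sub, build_unet2d(cfg, seed = 5), plan, seed = 9)
  t2 <- train_2d(sub, build_unet2d(cfg, seed = 5), plan, seed = 9)
  expect_identical(t1$history$loss, t2$history$loss)
  expect_lt(utils::tail(t1$history$loss, 1), t1$history$loss[1])
})
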
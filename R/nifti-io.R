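#' Read and write voxel grids as NIfTI
#'
#' NIfTI stores arrays as (x, y, z); the package convention is (z, y, x) with
#' z superior-first. `write_nifti_grid()` permutes accordingly and records the
#' spacing in `pixdim`, so `read_nifti_grid()` round-trips exactly. Files
#' written elsewhere are assumed to follow the same axis semantics; no
#' orientation-matrix reinterpretation is attempted.
#'
#' @param grid a `voxel_grid`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_nifti_grid()` returns `path` invisibly;
#'   `read_nifti_grid()` returns a `voxel_grid`.
#' @export
write_nifti_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- aperm(grid$data, c(3, 2, 1))           # (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(grid$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @param modality modality to stamp on the grid read from `path`.
#' @export
read_nifti_grid <- function(path, modality = "CT_HU") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    petseg_abort(sprintf("expected a 3D NIfTI volume in %s", path), "bad_grid")
  sp <- rev(RNifti::pixdim(img)[1:3])
  data <- aperm(arr, c(3, 2, 1))                # back to (z, y, x)
  if (modality == "MASK") data <- (data >= 0.5) * 1
  voxel_grid(data, sp, modality = modality)
}

#' Load a paired PET/CT study
#'
#' Each modality may be a NIfTI file (`.nii`/`.nii.gz`) or a directory holding
#' a DICOM series. CT values are returned in HU. PET values read from DICOM are
#' rescaled stored values, i.e. activity concentration (Bq/mL), with modality
#' `PET_ACTIVITY` pending SUV conversion; calibration metadata is populated
#' from the DICOM header where present. A NIfTI PET may be accompanied by a
#' JSON sidecar (`<file>.json`) with calibration fields
#' (`injected_dose_bq`, `patient_weight_g`, `injection_time`,
#' `acquisition_time`, `half_life_s`); without one the calibration is marked
#' incomplete and SUV conversion is refused later.
#'
#' @param pet_path,ct_path paths (NIfTI file or DICOM directory).
#' @param study_id optional identifier; defaults to the PET DICOM patient ID
#'   or the PET file name.
#' @return a `petct_study`: list with `pet`, `ct` (voxel grids), `study_id`,
#'   `calibration`.
#' @export
load_study <- function(pet_path, ct_path, study_id = NULL) {
  pet <- load_modality(pet_path, pet = TRUE)
  ct <- load_modality(ct_path, pet = FALSE)
  if (!is.null(pet$patient_id) && !is.null(ct$patient_id) &&
      !identical(pet$patient_id, ct$patient_id))
    petseg_abort(sprintf("patient IDs differ across modalities ('%s' vs '%s')",
                         pet$patient_id, ct$patient_id), "id_mismatch")
  if (is.null(study_id))
    study_id <- pet$patient_id %||% sub("\\.nii(\\.gz)?$", "", basename(pet_path))
  petct_study(pet$grid, ct$grid, study_id = study_id, calibration = pet$calibration)
}

#' Construct a PET/CT study container
#'
#' @param pet,ct voxel grids. After preprocessing both must share shape and
#'   spacing; the constructor enforces this only when both are already on the
#'   same lattice footprint (use [preprocess_study()] to co-resample).
#' @param study_id identifier string.
#' @param calibration optional [suv_calibration()].
#' @param check if TRUE, require identical shape and spacing.
#' @return a `petct_study`.
#' @export
petct_study <- function(pet, ct, study_id = "study", calibration = NULL,
                        check = FALSE) {
  stopifnot(inherits(pet, "voxel_grid"), inherits(ct, "voxel_grid"))
  if (check && (!identical(dim(pet$data), dim(ct$data)) ||
                any(abs(pet$spacing - ct$spacing) > 1e-6)))
    petseg_abort("PET and CT must share shape and spacing", "bad_grid")
  structure(list(pet = pet, ct = ct, study_id = study_id,
                 calibration = calibration),
            class = "petct_study")
}

#' @export
print.petct_study <- function(x, ...) {
  cat(sprintf("<petct_study '%s'>\n", x$study_id))
  print(x$pet); print(x$ct)
  if (!is.null(x$calibration)) print(x$calibration)
  invisible(x)
}

#' Preprocess a study: SUV conversion and isotropic resampling
#'
#' Applies [compute_suv()] when the PET grid is still in activity units (and
#' the calibration is complete), then resamples both modalities to the target
#' isotropic spacing so they share one lattice.
#'
#' @param study a `petct_study`.
#' @param target_mm isotropic spacing, default 2 mm.
#' @return a `petct_study` with PET in SUV at the target spacing.
#' @export
preprocess_study <- function(study, target_mm = 2.0) {
  pet <- study$pet
  if (pet$modality == "PET_ACTIVITY") {
    if (is.null(study$calibration) || !suv_calibration_complete(study$calibration))
      petseg_abort("PET is in activity units but calibration is incomplete",
                   "bad_calibration")
    pet <- compute_suv(pet, study$calibration)
  }
  pet <- resample_isotropic(pet, target_mm)
  ct <- resample_isotropic(study$ct, target_mm)
  petct_study(pet, ct, study$study_id, study$calibration, check = TRUE)
}

load_modality <- function(path, pet) {
  if (dir.exists(path)) {
    ser <- read_dicom_series(path)
    grid <- voxel_grid(ser$data, ser$spacing,
                       modality = if (pet) "PET_ACTIVITY" else "CT_HU")
    list(grid = grid, calibration = if (pet) ser$calibration else NULL,
         patient_id = ser$patient_id)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    grid <- read_nifti_grid(path, modality = if (pet) "PET_SUV" else "CT_HU")
    cal <- NULL
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
    if (pet && file.exists(sidecar)) {
      j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      cal <- suv_calibration(
        injected_dose_bq = j$injected_dose_bq %||% NA_real_,
        patient_weight_g = j$patient_weight_g %||% NA_real_,
        injection_time = j$injection_time %||% NA,
        acquisition_time = j$acquisition_time %||% NA,
        half_life_s = j$half_life_s %||% 6586.2)
      # sidecar-calibrated NIfTI PET is still activity pending conversion
      grid$modality <- "PET_ACTIVITY"
    }
    list(grid = grid, calibration = cal, patient_id = NULL)
  } else {
    petseg_abort(sprintf("cannot load '%s': not a NIfTI file or DICOM directory",
                         path), "bad_input")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
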
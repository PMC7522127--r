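#' Voxel grids
#'
#' A `voxel_grid` is a 3D scalar volume on a regular lattice with physical
#' spacing, carrying modality semantics. The array is indexed `(z, y, x)` with
#' a fixed anatomical convention: z index 1 is most superior (head), y index 1
#' is most anterior, and x index 1 is patient-right. Spacing is in mm per axis.
#'
#' Modalities: `CT_HU` (Hounsfield units), `PET_ACTIVITY` (Bq/mL),
#' `PET_SUV` (body-weight standardized uptake value), `MASK` (binary 0/1),
#' `PROB` (probabilities in \[0, 1\]).
#'
#' @param data 3D numeric array indexed (z, y, x).
#' @param spacing numeric length-3 vector of voxel sizes (sz, sy, sx) in mm,
#'   or a single value for isotropic grids.
#' @param origin physical coordinates (mm) of voxel (1, 1, 1); default c(0,0,0).
#' @param modality one of `"CT_HU"`, `"PET_ACTIVITY"`, `"PET_SUV"`, `"MASK"`,
#'   `"PROB"`.
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0),
                       modality = c("CT_HU", "PET_ACTIVITY", "PET_SUV", "MASK", "PROB")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) petseg_abort("voxel_grid data must be a 3D array", "bad_grid")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    petseg_abort("spacing must be three strictly positive values", "bad_grid")
  if (anyNA(data) || any(!is.finite(data)))
    petseg_abort("voxel_grid data must be finite everywhere", "bad_grid")
  if (modality == "MASK" && !all(data %in% c(0, 1)))
    petseg_abort("MASK grids may contain only 0 and 1", "bad_grid")
  if (modality == "PROB" && (min(data) < 0 || max(data) > 1))
    petseg_abort("PROB grids must lie in [0, 1]", "bad_grid")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         modality = modality),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid %s> %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume of a grid in mL
#' @param grid a `voxel_grid`
#' @return scalar voxel volume in mL (spacing product / 1000).
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

# Structured condition helper: every package error carries a petseg_<class>
# condition class so callers can catch specific failure modes.
petseg_abort <- function(message, class) {
  stop(structure(
    class = c(paste0("petseg_", class), "petseg_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_isotropic <- function(grid, tol = 1e-6) {
  diff(range(grid$spacing)) < tol
}
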
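#' Reformat a volume into an ordered stack of 2D slices
#'
#' Produces axial, coronal or sagittal reformations of an isotropic volume.
#' With the package's (z, y, x) convention the slice matrices are:
#' axial (indexed by z): (y, x); coronal (indexed by y): (z, x);
#' sagittal (indexed by x): (z, y). [restack()] exactly inverts the operation.
#'
#' @param grid a `voxel_grid` (isotropic recommended for reformations).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return a `slice_stack`: list with `slices` (list of matrices), `plane`,
#'   `grid_dim`, `spacing`, `modality`.
#' @export
reformat <- function(grid, plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  slices <- switch(plane,
    axial    = lapply(seq_len(d[1]), function(z) grid$data[z, , , drop = TRUE]),
    coronal  = lapply(seq_len(d[2]), function(y) grid$data[, y, , drop = TRUE]),
    sagittal = lapply(seq_len(d[3]), function(x) grid$data[, , x, drop = TRUE])
  )
  structure(list(slices = slices, plane = plane, grid_dim = d,
                 spacing = grid$spacing, modality = grid$modality),
            class = "slice_stack")
}

#' Restack slices into a volume
#'
#' Inverse of [reformat()]: `restack(reformat(g, p))` reproduces `g` exactly.
#'
#' @param stack a `slice_stack`.
#' @return a `voxel_grid`.
#' @export
restack <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- stack$grid_dim
  arr <- array(0, d)
  for (i in seq_along(stack$slices)) {
    switch(stack$plane,
      axial    = {arr[i, , ] <- stack$slices[[i]]},
      coronal  = {arr[, i, ] <- stack$slices[[i]]},
      sagittal = {arr[, , i] <- stack$slices[[i]]}
    )
  }
  voxel_grid(arr, stack$spacing, modality = stack$modality)
}

#' Fit a 2D slice to a fixed network input size
#'
#' Center-crops dimensions larger than the target, then zero-pads dimensions
#' smaller than the target, producing exactly `target_hw` (rows, cols). The
#' returned geometry record allows [unfit_slice()] to map a same-sized
#' prediction back onto the original lattice exactly (values discarded by the
#' crop come back as zeros).
#'
#' @param slice a 2D matrix (works for multi-channel (H, W, C) arrays too).
#' @param target_hw integer length-2 target (rows, cols); default c(448, 512).
#' @return list with `slice` (fitted array) and `geom` (geometry record).
#' @export
fit_slice <- function(slice, target_hw = c(448L, 512L)) {
  d <- dim(slice)
  stopifnot(length(d) %in% c(2L, 3L), length(target_hw) == 2L)
  plan_axis <- function(n, t) {
    if (n >= t) {
      src0 <- (n - t) %/% 2L           # crop start (0-based)
      list(src = src0 + seq_len(t), dst = seq_len(t))
    } else {
      dst0 <- (t - n) %/% 2L           # pad offset (0-based)
      list(src = seq_len(n), dst = dst0 + seq_len(n))
    }
  }
  pr <- plan_axis(d[1], target_hw[1])
  pc <- plan_axis(d[2], target_hw[2])
  if (length(d) == 2L) {
    out <- matrix(0, target_hw[1], target_hw[2])
    out[pr$dst, pc$dst] <- slice[pr$src, pc$src]
  } else {
    out <- array(0, c(target_hw, d[3]))
    out[pr$dst, pc$dst, ] <- slice[pr$src, pc$src, ]
  }
  list(slice = out,
       geom = list(orig_hw = d[1:2], src_r = pr$src, dst_r = pr$dst,
                   src_c = pc$src, dst_c = pc$dst))
}

#' Map a fitted slice (or a prediction on it) back to the original lattice
#'
#' @param fitted a 2D matrix of the fitted size.
#' @param geom geometry record from [fit_slice()].
#' @return matrix of the original slice shape; positions that were cropped
#'   away are zero.
#' @export
unfit_slice <- function(fitted, geom) {
  out <- matrix(0, geom$orig_hw[1], geom$orig_hw[2])
  out[geom$src_r, geom$src_c] <- fitted[geom$dst_r, geom$dst_c]
  out
}
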
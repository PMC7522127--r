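#' Overlap metrics and metabolic tumor burden
#'
#' Evaluation metrics for binary tumor masks plus the two burden statistics
#' reported per scan: total metabolic tumor volume (TMTV, mL) and the maximum
#' SUV inside the predicted mask (SUVmax).
#'
#' @name metrics
NULL

#' Dice similarity coefficient of two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`; defined as 1 when both masks are empty (flagged
#' with attribute `both_empty`).
#'
#' @param a,b binary masks (arrays or `voxel_grid`s) of one shape.
#' @return scalar in \[0, 1\].
#' @export
dice_score <- function(a, b) {
  a <- as_plain_array(a); b <- as_plain_array(b)
  check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a * b) / (sa + sb)
}

#' Voxel-level sensitivity (recall)
#'
#' `|P∩T| / |T|`. With an empty truth mask the ratio is undefined; it is
#' reported as 1 with attribute `empty_truth = TRUE` so the metric stays a
#' total function.
#'
#' @param pred,truth binary masks of one shape.
#' @return scalar in \[0, 1\].
#' @export
voxel_sensitivity <- function(pred, truth) {
  pred <- as_plain_array(pred); truth <- as_plain_array(truth)
  check_same_shape(pred, truth)
  st <- sum(truth)
  if (st == 0) return(structure(1, empty_truth = TRUE))
  sum(pred * truth) / st
}

#' Metabolic tumor burden of a mask
#'
#' TMTV is the positive voxel count times the voxel volume; SUVmax the
#' maximum SUV over positive voxels. Lesions are 26-connected components of
#' the mask, each reported with its own volume and SUVmax. TMTV equals the
#' sum of per-lesion volumes exactly, and is additive over disjoint masks.
#'
#' @param mask a `MASK` voxel grid (or binary array with `suv` a grid).
#' @param suv an aligned `PET_SUV` voxel grid.
#' @return a `tumor_metrics`: list with `tmtv_ml`, `suv_max` (NA for an empty
#'   mask, serialised as null), `n_lesions`, `per_lesion` data.frame.
#' @export
tumor_metrics <- function(mask, suv) {
  stopifnot(inherits(suv, "voxel_grid"))
  m <- as_plain_array(mask)
  check_same_shape(m, suv$data)
  vox_ml <- voxel_volume_ml(suv)
  labels <- .label3_cpp(m >= 0.5, dim(m), 26L)
  n <- attr(labels, "n_components")
  if (n == 0L) {
    per <- data.frame(lesion = integer(), volume_ml = numeric(),
                      suv_max = numeric())
    out <- list(tmtv_ml = 0, suv_max = NA_real_, n_lesions = 0L,
                per_lesion = per)
    return(structure(out, class = "tumor_metrics"))
  }
  counts <- tabulate(labels, nbins = n)
  suv_max_per <- vapply(seq_len(n), function(id) max(suv$data[labels == id]), 0)
  per <- data.frame(lesion = seq_len(n),
                    volume_ml = counts * vox_ml,
                    suv_max = suv_max_per)
  structure(list(tmtv_ml = sum(per$volume_ml),
                 suv_max = max(per$suv_max),
                 n_lesions = n,
                 per_lesion = per),
            class = "tumor_metrics")
}

#' @export
print.tumor_metrics <- function(x, ...) {
  cat(sprintf("<tumor_metrics> TMTV %.3f mL, SUVmax %s, %d lesion(s)\n",
              x$tmtv_ml,
              if (is.na(x$suv_max)) "NA" else sprintf("%.2f", x$suv_max),
              x$n_lesions))
  invisible(x)
}

#' Export per-scan metrics as a one-row data frame
#'
#' @param metrics a `tumor_metrics`.
#' @param study_id scan identifier.
#' @param dice,sensitivity optional agreement metrics vs a reference mask.
#' @return data.frame row suitable for CSV export.
#' @export
metrics_row <- function(metrics, study_id, dice = NA_real_,
                        sensitivity = NA_real_) {
  data.frame(study_id = study_id, tmtv_ml = metrics$tmtv_ml,
             suv_max = metrics$suv_max, n_lesions = metrics$n_lesions,
             dice = as.numeric(dice), sensitivity = as.numeric(sensitivity),
             stringsAsFactors = FALSE)
}
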
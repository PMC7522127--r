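#' SUV calibration metadata
#'
#' Holds the PET calibration quantities needed to convert an activity
#' concentration volume (Bq/mL) into body-weight standardized uptake values
#' (SUVbw). Times may be given as seconds since midnight or as DICOM `TM`
#' strings (`"HHMMSS"` or `"HHMMSS.FFFFFF"`).
#'
#' @param injected_dose_bq injected activity at injection time, Bq.
#' @param patient_weight_g patient body weight, grams.
#' @param injection_time,acquisition_time timestamps (seconds or DICOM TM).
#' @param half_life_s radionuclide half-life in seconds (F-18: 6586.2).
#' @param rescale_slope,rescale_intercept stored-value to activity mapping.
#' @return A `suv_calibration` object. Fields may be `NA` (incomplete
#'   calibration); completeness is checked by [suv_calibration_complete()].
#' @export
suv_calibration <- function(injected_dose_bq = NA_real_,
                            patient_weight_g = NA_real_,
                            injection_time = NA,
                            acquisition_time = NA,
                            half_life_s = 6586.2,
                            rescale_slope = 1,
                            rescale_intercept = 0) {
  structure(
    list(
      injected_dose_bq = as.numeric(injected_dose_bq),
      patient_weight_g = as.numeric(patient_weight_g),
      injection_time = parse_dicom_time(injection_time),
      acquisition_time = parse_dicom_time(acquisition_time),
      half_life_s = as.numeric(half_life_s),
      rescale_slope = as.numeric(rescale_slope),
      rescale_intercept = as.numeric(rescale_intercept)
    ),
    class = "suv_calibration"
  )
}

# DICOM TM "HHMMSS(.frac)" -> seconds since midnight; numerics pass through.
parse_dicom_time <- function(t) {
  if (length(t) != 1L || is.na(t)) return(NA_real_)
  if (is.numeric(t)) return(as.numeric(t))
  t <- trimws(as.character(t))
  if (!grepl("^\\d{6}(\\.\\d+)?$", t))
    petseg_abort(sprintf("cannot parse time '%s'", t), "bad_calibration")
  h <- as.numeric(substr(t, 1, 2)); m <- as.numeric(substr(t, 3, 4))
  s <- as.numeric(substring(t, 5))
  h * 3600 + m * 60 + s
}

#' Is a calibration complete enough for SUV conversion?
#' @param cal a `suv_calibration`
#' @return logical scalar
#' @export
suv_calibration_complete <- function(cal) {
  !anyNA(c(cal$injected_dose_bq, cal$patient_weight_g,
           cal$injection_time, cal$acquisition_time, cal$half_life_s))
}

#' @export
print.suv_calibration <- function(x, ...) {
  cat("<suv_calibration>",
      if (suv_calibration_complete(x)) "(complete)" else "(INCOMPLETE)", "\n")
  cat(sprintf("  dose %.4g Bq, weight %.4g g, half-life %.1f s, dt %s s\n",
              x$injected_dose_bq, x$patient_weight_g, x$half_life_s,
              if (anyNA(c(x$acquisition_time, x$injection_time))) "NA"
              else format(x$acquisition_time - x$injection_time)))
  invisible(x)
}

#' Convert PET activity concentration to body-weight SUV
#'
#' Computes SUVbw voxel-wise as
#' \deqn{SUV(v) = a(v) \cdot m / (D \cdot 2^{-\Delta t / t_{1/2}})}
#' where \eqn{a(v)} is the activity concentration (Bq/mL), \eqn{m} the body
#' weight in grams, \eqn{D} the injected dose (Bq) and \eqn{\Delta t} the
#' delay between injection and acquisition start; the denominator is the dose
#' decay-corrected to acquisition start. The conversion is linear in activity.
#'
#' @param pet_activity a `voxel_grid` of modality `PET_ACTIVITY` (Bq/mL).
#' @param cal a complete [suv_calibration()].
#' @return a `voxel_grid` of modality `PET_SUV`.
#' @export
compute_suv <- function(pet_activity, cal) {
  stopifnot(inherits(pet_activity, "voxel_grid"), inherits(cal, "suv_calibration"))
  if (pet_activity$modality != "PET_ACTIVITY")
    petseg_abort("compute_suv expects a PET_ACTIVITY grid", "bad_calibration")
  if (!suv_calibration_complete(cal))
    petseg_abort("SUV conversion refused: calibration incomplete", "bad_calibration")
  if (cal$injected_dose_bq <= 0 || cal$patient_weight_g <= 0 || cal$half_life_s <= 0)
    petseg_abort("dose, weight and half-life must be positive", "bad_calibration")
  dt <- cal$acquisition_time - cal$injection_time
  if (dt < 0)
    petseg_abort("acquisition time precedes injection time", "bad_calibration")
  decayed_dose <- cal$injected_dose_bq * 2^(-dt / cal$half_life_s)
  suv <- pet_activity$data * (cal$patient_weight_g / decayed_dose)
  voxel_grid(suv, pet_activity$spacing, pet_activity$origin, "PET_SUV")
}
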
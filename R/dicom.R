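# Minimal DICOM reader.
#
# Supports what the pipeline needs from PET/CT exports: explicit and implicit
# VR little-endian transfer syntaxes, single-frame 16-bit image files stored
# one-per-slice in a series directory, recursion into sequences (the
# radiopharmaceutical information lives in sequence (0054,0016)), and the
# calibration/geometry tags listed below. It is not a general DICOM
# implementation: big-endian and encapsulated (compressed) pixel data are
# rejected.

DICOM_TAGS <- list(
  transfer_syntax   = c(0x0002, 0x0010),
  acquisition_time  = c(0x0008, 0x0032),
  patient_id        = c(0x0010, 0x0020),
  patient_weight_kg = c(0x0010, 0x1030),
  injection_time    = c(0x0018, 0x1072),
  total_dose_bq     = c(0x0018, 0x1074),
  half_life_s       = c(0x0018, 0x1075),
  slice_thickness   = c(0x0018, 0x0050),
  instance_number   = c(0x0020, 0x0013),
  rows              = c(0x0028, 0x0010),
  cols              = c(0x0028, 0x0011),
  pixel_spacing     = c(0x0028, 0x0030),
  bits_allocated    = c(0x0028, 0x0100),
  pixel_rep         = c(0x0028, 0x0103),
  rescale_intercept = c(0x0028, 0x1052),
  rescale_slope     = c(0x0028, 0x1053),
  pixel_data        = c(0x7FE0, 0x0010)
)

#' Parse one DICOM file (minimal reader)
#'
#' Reads the subset of the header used for SUV calibration and slice geometry,
#' plus the 16-bit pixel data. See the package vignette for supported
#' transfer syntaxes.
#'
#' @param path a DICOM file.
#' @return named list of decoded elements; `pixels` is a (rows, cols) numeric
#'   matrix with rescale slope/intercept already applied.
#' @export
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    petseg_abort(sprintf("%s: missing DICM magic", path), "bad_dicom")

  u16 <- function(at) readBin(raw[at + 0:1], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) {
    v <- readBin(raw[at + 0:3], "integer", size = 4, endian = "little")
    if (v < 0) v + 2^32 else as.numeric(v)
  }

  found <- new.env(parent = emptyenv())
  tagmat <- do.call(rbind, DICOM_TAGS)
  tag_name <- function(g, e) {
    hit <- which(tagmat[, 1] == g & tagmat[, 2] == e)
    if (length(hit)) rownames(tagmat)[hit[1]] else NULL
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  # parse a dataset from pos (1-based) to limit; returns position after it
  parse_ds <- function(pos, limit, explicit) {
    while (pos + 7 <= limit) {
      g <- u16(pos); e <- u16(pos + 2)
      if (g == 0xFFFE) {                       # item / sequence delimiters
        pos <- pos + 8
        if (e %in% c(0xE00D, 0xE0DD)) return(pos)
        next
      }
      vr <- NULL
      if (explicit && g != 0xFFFE) {
        vr <- rawToChar(raw[(pos + 4):(pos + 5)])
        if (vr %in% long_vrs) { len <- u32(pos + 8); hdr <- 12 }
        else { len <- u16(pos + 6); hdr <- 8 }
      } else { len <- u32(pos + 4); hdr <- 8 }
      body <- pos + hdr
      nm <- tag_name(g, e)
      is_seq <- identical(vr, "SQ") || len == 0xFFFFFFFF
      if (is_seq) {
        if (len == 0xFFFFFFFF) {
          pos <- parse_seq_undef(body, limit, explicit)
        } else {
          parse_items(body, body + len, explicit)
          pos <- body + len
        }
        next
      }
      if (!is.null(nm) && len > 0) {
        val <- raw[body:(body + len - 1)]
        assign(nm, list(val = val, vr = vr), envir = found)
      }
      pos <- body + len
    }
    pos
  }

  parse_items <- function(pos, limit, explicit) {
    while (pos + 7 <= limit) {
      g <- u16(pos); e <- u16(pos + 2); len <- u32(pos + 4)
      pos <- pos + 8
      if (g != 0xFFFE) petseg_abort("malformed sequence item", "bad_dicom")
      if (e == 0xE0DD) return(pos)
      if (e == 0xE000) {
        if (len == 0xFFFFFFFF) pos <- parse_ds(pos, limit, explicit)
        else { parse_ds(pos, pos + len, explicit); pos <- pos + len }
      }
    }
    pos
  }

  parse_seq_undef <- function(pos, limit, explicit) {
    while (pos + 7 <= limit) {
      g <- u16(pos); e <- u16(pos + 2); len <- u32(pos + 4)
      if (g != 0xFFFE) petseg_abort("malformed undefined-length sequence", "bad_dicom")
      pos <- pos + 8
      if (e == 0xE0DD) return(pos)
      if (e == 0xE000) {
        if (len == 0xFFFFFFFF) pos <- parse_ds(pos, limit, explicit)
        else { parse_ds(pos, pos + len, explicit); pos <- pos + len }
      }
    }
    pos
  }

  # file meta group is always explicit VR
  pos <- 133
  g <- u16(pos)
  while (pos + 7 <= length(raw) && u16(pos) == 0x0002) {
    e <- u16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) { len <- u32(pos + 8); hdr <- 12 }
    else { len <- u16(pos + 6); hdr <- 8 }
    nm <- tag_name(0x0002, e)
    if (!is.null(nm) && len > 0)
      assign(nm, list(val = raw[(pos + hdr):(pos + hdr + len - 1)], vr = vr),
             envir = found)
    pos <- pos + hdr + len
  }
  raw_to_str <- function(val) trimws(rawToChar(val[val != as.raw(0)]))
  ts <- if (exists("transfer_syntax", found))
    raw_to_str(get("transfer_syntax", found)$val) else "1.2.840.10008.1.2.1"
  explicit <- switch(ts,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    petseg_abort(sprintf("unsupported transfer syntax '%s'", ts), "bad_dicom"))
  parse_ds(pos, length(raw), explicit)

  dec_str <- function(nm) {
    if (!exists(nm, found)) return(NULL)
    raw_to_str(get(nm, found)$val)
  }
  dec_num <- function(nm) {
    s <- dec_str(nm)
    if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
  }
  dec_u16 <- function(nm) {
    if (!exists(nm, found)) return(NULL)
    readBin(get(nm, found)$val, "integer", size = 2, endian = "little",
            signed = FALSE)
  }

  out <- list(
    patient_id = dec_str("patient_id"),
    patient_weight_kg = dec_num("patient_weight_kg"),
    total_dose_bq = dec_num("total_dose_bq"),
    half_life_s = dec_num("half_life_s"),
    injection_time = dec_str("injection_time"),
    acquisition_time = dec_str("acquisition_time"),
    instance_number = dec_num("instance_number"),
    rows = dec_u16("rows"), cols = dec_u16("cols"),
    pixel_spacing = dec_num("pixel_spacing"),
    slice_thickness = dec_num("slice_thickness"),
    rescale_slope = dec_num("rescale_slope") %||% 1,
    rescale_intercept = dec_num("rescale_intercept") %||% 0
  )
  if (exists("pixel_data", found)) {
    bits <- dec_u16("bits_allocated") %||% 16L
    if (bits != 16L) petseg_abort("only 16-bit pixel data supported", "bad_dicom")
    signed <- identical(dec_u16("pixel_rep"), 1L)
    v <- readBin(get("pixel_data", found)$val, "integer", size = 2,
                 n = out$rows * out$cols, endian = "little", signed = signed)
    # DICOM pixels are row-major; transpose into an R (rows, cols) matrix
    m <- t(matrix(as.numeric(v), nrow = out$cols, ncol = out$rows))
    out$pixels <- m * out$rescale_slope[1] + out$rescale_intercept[1]
  }
  out
}

#' Read a DICOM series directory as a volume
#'
#' Stacks all DICOM files of a directory into a (z, y, x) volume, ordered by
#' InstanceNumber (instance 1 is taken as the most superior slice). Rescale
#' slope/intercept are applied per file, so PET series come back in activity
#' concentration units. Calibration metadata is collected into an
#' [suv_calibration()]; missing fields leave it incomplete rather than failing.
#'
#' @param dir directory of single-frame DICOM files.
#' @return list with `data` (array), `spacing` (sz, sy, sx mm), `calibration`,
#'   `patient_id`.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) petseg_abort(sprintf("no files in %s", dir), "bad_dicom")
  parsed <- lapply(files, read_dicom_file)
  inst <- vapply(parsed, function(p) p$instance_number %||% NA_real_, 0)
  if (!anyNA(inst)) parsed <- parsed[order(inst)]
  first <- parsed[[1]]
  ids <- unique(unlist(lapply(parsed, `[[`, "patient_id")))
  if (length(ids) > 1)
    petseg_abort("multiple patient IDs within one series", "id_mismatch")
  data <- array(0, c(length(parsed), first$rows, first$cols))
  for (i in seq_along(parsed)) data[i, , ] <- parsed[[i]]$pixels
  spacing <- c(first$slice_thickness %||% 1,
               (first$pixel_spacing %||% c(1, 1))[1],
               (first$pixel_spacing %||% c(1, 1))[2])
  cal <- suv_calibration(
    injected_dose_bq = first$total_dose_bq %||% NA_real_,
    patient_weight_g = if (is.null(first$patient_weight_kg)) NA_real_
                       else first$patient_weight_kg * 1000,
    injection_time = first$injection_time %||% NA,
    acquisition_time = first$acquisition_time %||% NA,
    half_life_s = first$half_life_s %||% 6586.2,
    rescale_slope = first$rescale_slope[1],
    rescale_intercept = first$rescale_intercept[1])
  list(data = data, spacing = spacing, calibration = cal,
       patient_id = if (length(ids)) ids[[1]] else NULL)
}
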
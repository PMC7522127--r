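# Build small DICOM files byte-by-byte (explicit VR little endian) so the
# reader can be exercised without binary fixtures in the repository.

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0x20))
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), u32le(length(value_raw)), value_raw)
  } else {
    c(hdr, u16le(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))

# wrap a serialised dataset into a single sequence item
dcm_sequence <- function(group, elem, item_raw) {
  item <- c(u16le(0xFFFE), u16le(0xE000), u32le(length(item_raw)), item_raw)
  dcm_element(group, elem, "SQ", item)
}

# Write one single-frame 16-bit DICOM file. pixels: (rows, cols) matrix of
# stored values (pre-rescale).
write_test_dicom <- function(path, pixels, instance = 1, patient_id = "P001",
                             slope = 1, intercept = 0,
                             weight_kg = 70, dose_bq = 3.5e8,
                             inj_time = "100000", acq_time = "100000",
                             half_life = 6586.2,
                             pixel_spacing = c(4, 4), thickness = 4,
                             include_weight = TRUE) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  stored <- as.integer(round(t(pixels)))          # row-major
  px_raw <- writeBin(stored, raw(), size = 2, endian = "little")

  meta <- c(
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  rph_item <- c(
    dcm_str(0x0018, 0x1072, "TM", inj_time),
    dcm_str(0x0018, 0x1074, "DS", format(dose_bq)),
    dcm_str(0x0018, 0x1075, "DS", format(half_life)))
  body <- c(
    dcm_str(0x0008, 0x0032, "TM", acq_time),
    dcm_str(0x0010, 0x0020, "LO", patient_id),
    if (include_weight) dcm_str(0x0010, 0x1030, "DS", format(weight_kg)),
    dcm_str(0x0018, 0x0050, "DS", format(thickness)),
    dcm_sequence(0x0054, 0x0016, rph_item),
    dcm_str(0x0020, 0x0013, "IS", format(instance)),
    dcm_element(0x0028, 0x0010, "US", u16le(rows)),
    dcm_element(0x0028, 0x0011, "US", u16le(cols)),
    dcm_str(0x0028, 0x0030, "DS",
            paste(format(pixel_spacing), collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", u16le(16)),
    dcm_element(0x0028, 0x0103, "US", u16le(0)),
    dcm_str(0x0028, 0x1052, "DS", format(intercept)),
    dcm_str(0x0028, 0x1053, "DS", format(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
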
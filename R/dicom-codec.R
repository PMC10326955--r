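# Minimal DICOM part-10 encoder/decoder, explicit VR little endian
# (transfer syntax 1.2.840.10008.1.2.1). Covers exactly the element set the
# synthetic instance generator and the download validator need: string VRs,
# US, and OB/OW pixel data. Long-form length encoding is used for OB/OW/UN,
# short form elsewhere; values are padded to even length as the standard
# requires (UI with NUL, text with space).

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"
SKIFF_IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.10.1437.1"

uint_le <- function(x, n_bytes) {
  x <- as.numeric(x)
  out <- raw(n_bytes)
  for (i in seq_len(n_bytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

le_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

pad_even <- function(bytes, pad) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

# One data element: group/element as integers, VR string, value raw vector.
encode_element <- function(group, element, vr, value) {
  if (is.character(value)) value <- charToRaw(value)
  value <- pad_even(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  long_form <- vr %in% c("OB", "OW", "UN", "SQ", "UT")
  c(
    uint_le(group, 2), uint_le(element, 2), charToRaw(vr),
    if (long_form) c(raw(2), uint_le(length(value), 4))
    else uint_le(length(value), 2),
    value
  )
}

#' Encode a minimal DICOM instance
#'
#' Serializes a flat set of common attributes into a valid DICOM part-10
#' stream (128-byte preamble, `DICM` magic, file meta group, explicit VR
#' little endian dataset). Only the attributes needed to describe a
#' single-frame 8-bit grayscale image are supported; this is the format the
#' synthetic DICOMweb store serves and the downloader writes to disk.
#'
#' @param sop_instance_uid,study_uid,series_uid DICOM UIDs (dot-separated
#'   numeric components).
#' @param patient_id,patient_name Patient identification strings.
#' @param modality DICOM modality code (default `"CT"`).
#' @param instance_number Integer position of the instance in its series.
#' @param rows,cols Image dimensions; `pixel_data` must hold `rows * cols`
#'   bytes (one byte per pixel, MONOCHROME2).
#' @param pixel_data Raw vector of pixel bytes; defaults to a zero image.
#' @return A raw vector holding the complete part-10 stream.
#' @seealso [dicom_decode()]
#' @export
dicom_encode <- function(sop_instance_uid, study_uid, series_uid,
                         patient_id = "ANON", patient_name = "ANON",
                         modality = "CT", instance_number = 1L,
                         rows = 8L, cols = 8L,
                         pixel_data = raw(rows * cols)) {
  stopifnot(length(pixel_data) == rows * cols)
  meta_body <- c(
    encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    encode_element(0x0002, 0x0002, "UI", DICOM_SOP_CT_IMAGE),
    encode_element(0x0002, 0x0003, "UI", sop_instance_uid),
    encode_element(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
    encode_element(0x0002, 0x0012, "UI", SKIFF_IMPLEMENTATION_UID)
  )
  dataset <- c(
    encode_element(0x0008, 0x0016, "UI", DICOM_SOP_CT_IMAGE),
    encode_element(0x0008, 0x0018, "UI", sop_instance_uid),
    encode_element(0x0008, 0x0060, "CS", modality),
    encode_element(0x0010, 0x0010, "PN", patient_name),
    encode_element(0x0010, 0x0020, "LO", patient_id),
    encode_element(0x0020, 0x000D, "UI", study_uid),
    encode_element(0x0020, 0x000E, "UI", series_uid),
    encode_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    encode_element(0x0028, 0x0002, "US", uint_le(1, 2)),
    encode_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    encode_element(0x0028, 0x0010, "US", uint_le(rows, 2)),
    encode_element(0x0028, 0x0011, "US", uint_le(cols, 2)),
    encode_element(0x0028, 0x0100, "US", uint_le(8, 2)),
    encode_element(0x0028, 0x0101, "US", uint_le(8, 2)),
    encode_element(0x0028, 0x0102, "US", uint_le(7, 2)),
    encode_element(0x0028, 0x0103, "US", uint_le(0, 2)),
    encode_element(0x7FE0, 0x0010, "OB", pixel_data)
  )
  c(
    raw(128), charToRaw("DICM"),
    encode_element(0x0002, 0x0000, "UL", uint_le(length(meta_body), 4)),
    meta_body, dataset
  )
}

#' Decode a DICOM part-10 stream
#'
#' Parses the subset written by [dicom_encode()] (explicit VR little endian)
#' into a named list of attribute values. Used to validate files after
#' download and in round-trip tests; not a general DICOM reader.
#'
#' @param bytes Raw vector holding a part-10 stream.
#' @return Named list keyed by `"(gggg,eeee)"` tag strings; string VRs are
#'   decoded to character, US to integer, OB/OW left raw.
#' @export
dicom_decode <- function(bytes) {
  if (length(bytes) < 132 ||
      !identical(bytes[129:132], charToRaw("DICM"))) {
    stop_domain("not a DICOM part-10 stream (missing DICM magic)")
  }
  pos <- 133L
  out <- list()
  string_vrs <- c("UI", "CS", "PN", "LO", "SH", "IS", "DS", "DA", "TM", "AE")
  while (pos + 7 <= length(bytes)) {
    group <- le_uint(bytes[pos:(pos + 1)])
    element <- le_uint(bytes[(pos + 2):(pos + 3)])
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
      len <- le_uint(bytes[(pos + 8):(pos + 11)])
      pos <- pos + 12L
    } else {
      len <- le_uint(bytes[(pos + 6):(pos + 7)])
      pos <- pos + 8L
    }
    value <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    tag <- sprintf("(%04X,%04X)", group, element)
    out[[tag]] <- if (vr %in% string_vrs) {
      sub(" +$", "", rawToChar(value[value != as.raw(0)]))
    } else if (vr == "US") {
      as.integer(le_uint(value))
    } else if (vr == "UL") {
      le_uint(value)
    } else {
      value
    }
  }
  out
}

# Convenience accessors for the tags the package cares about.
dicom_tag <- function(parsed, name) {
  tags <- c(
    sop_instance_uid = "(0008,0018)", study_uid = "(0020,000D)",
    series_uid = "(0020,000E)", modality = "(0008,0060)",
    patient_id = "(0010,0020)", rows = "(0028,0010)", cols = "(0028,0011)",
    instance_number = "(0020,0013)", pixel_data = "(7FE0,0010)"
  )
  parsed[[tags[[name]]]]
}
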
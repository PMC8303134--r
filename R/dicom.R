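## Minimal DICOM support: explicit-VR little-endian single-frame grayscale
## objects (the secondary-capture shape hip ultrasound exports take after
## anonymising export). A writer builds synthetic files for testing the
## conversion path; the reader handles what the writer emits plus standard
## explicit-VR files with uncompressed 8/16-bit MONOCHROME pixel data.

.dcm_explicit_le <- "1.2.840.10008.1.2.1"
.dcm_sc_class <- "1.2.840.10008.5.1.4.1.1.7"

## patient-identifying attributes stripped during conversion
.dcm_phi_tags <- c("PatientName", "PatientID", "PatientBirthDate",
                   "PatientSex", "PatientAge", "ReferringPhysicianName",
                   "InstitutionName", "AccessionNumber", "StudyDate",
                   "OperatorsName")

.dcm_dictionary <- data.frame(
  group = c(0x0008, 0x0008, 0x0008, 0x0008, 0x0008, 0x0010, 0x0010, 0x0010,
            0x0010, 0x0010, 0x0008, 0x0008, 0x0008, 0x0028, 0x0028, 0x0028,
            0x0028, 0x0028, 0x0028, 0x0028, 0x0028, 0x7fe0),
  element = c(0x0016, 0x0018, 0x0020, 0x0060, 0x0090, 0x0010, 0x0020, 0x0030,
              0x0040, 0x1010, 0x0070, 0x0080, 0x1070, 0x0002, 0x0004, 0x0010,
              0x0011, 0x0100, 0x0101, 0x0102, 0x0103, 0x0010),
  vr = c("UI", "UI", "DA", "CS", "PN", "PN", "LO", "DA", "CS", "AS", "LO",
         "LO", "PN", "US", "CS", "US", "US", "US", "US", "US", "US", "OB"),
  name = c("SOPClassUID", "SOPInstanceUID", "StudyDate", "Modality",
           "ReferringPhysicianName", "PatientName", "PatientID",
           "PatientBirthDate", "PatientSex", "PatientAge", "Manufacturer",
           "InstitutionName", "OperatorsName", "SamplesPerPixel",
           "PhotometricInterpretation", "Rows", "Columns", "BitsAllocated",
           "BitsStored", "HighBit", "PixelRepresentation", "PixelData"),
  stringsAsFactors = FALSE
)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcm_element <- function(group, element, vr, value) {
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    body <- value
    c(head, as.raw(c(0, 0)), .u32(length(body)), body)
  } else if (vr == "US") {
    body <- .u16(value)
    c(head, .u16(length(body)), body)
  } else if (vr == "UL") {
    body <- .u32(value)
    c(head, .u16(length(body)), body)
  } else {
    body <- charToRaw(as.character(value))
    if (length(body) %% 2 == 1) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      body <- c(body, pad)
    }
    c(head, .u16(length(body)), body)
  }
}

#' Write a synthetic single-frame grayscale DICOM file
#'
#' Explicit VR little endian, MONOCHROME2, 8 bits per pixel. Intended for
#' building test inputs for [convert_dicom()]; the demographic arguments
#' exist so the anonymisation contract can be exercised.
#'
#' @param image integer matrix, values 0-255 (rows = y).
#' @param path output file.
#' @param patient_name,patient_id,birth_date,sex,institution identifying
#'   attributes embedded in the file.
#' @param sop_instance_uid instance UID recorded in the object.
#' @export
write_dicom <- function(image, path, patient_name = "Anon^Infant",
                        patient_id = "000000", birth_date = "20260101",
                        sex = "O", institution = "None",
                        sop_instance_uid = "1.2.826.0.1.3680043.9999.1") {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 255))
  px <- as.raw(as.integer(t(image)))  # row-major pixel order
  meta <- c(
    .dcm_element(0x0002, 0x0002, "UI", .dcm_sc_class),
    .dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    .dcm_element(0x0002, 0x0010, "UI", .dcm_explicit_le)
  )
  body <- c(
    .dcm_element(0x0008, 0x0016, "UI", .dcm_sc_class),
    .dcm_element(0x0008, 0x0018, "UI", sop_instance_uid),
    .dcm_element(0x0008, 0x0060, "CS", "US"),
    .dcm_element(0x0008, 0x0080, "LO", institution),
    .dcm_element(0x0010, 0x0010, "PN", patient_name),
    .dcm_element(0x0010, 0x0020, "LO", patient_id),
    .dcm_element(0x0010, 0x0030, "DA", birth_date),
    .dcm_element(0x0010, 0x0040, "CS", sex),
    .dcm_element(0x0028, 0x0002, "US", 1),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0010, "US", nrow(image)),
    .dcm_element(0x0028, 0x0011, "US", ncol(image)),
    .dcm_element(0x0028, 0x0100, "US", 8),
    .dcm_element(0x0028, 0x0101, "US", 8),
    .dcm_element(0x0028, 0x0102, "US", 7),
    .dcm_element(0x0028, 0x0103, "US", 0),
    .dcm_element(0x7fe0, 0x0010, "OB", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(.dcm_element(0x0002, 0x0000, "UL", length(meta)), meta, body),
           con)
  invisible(path)
}

#' Read a DICOM file (explicit VR little endian, uncompressed grayscale)
#'
#' @param path DICOM file.
#' @return list with `meta` (named list of textual/numeric attributes) and
#'   `image` (integer matrix, `NULL` when the object carries no pixel data).
#' @export
read_dicom <- function(path) {
  buf <- readBin(path, raw(), file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM") {
    stop("read_dicom: not a DICOM file (missing DICM magic)", call. = FALSE)
  }
  pos <- 133L
  meta <- list()
  pixel <- NULL
  rd16 <- function(at) {
    readBin(buf[at:(at + 1)], "integer", size = 2, endian = "little",
            signed = FALSE)
  }
  rd32 <- function(at) {
    readBin(buf[at:(at + 3)], "integer", size = 4, endian = "little")
  }
  while (pos + 7 <= length(buf)) {
    group <- rd16(pos); element <- rd16(pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd32(pos + 8)
      val_at <- pos + 12L
    } else {
      len <- rd16(pos + 6)
      val_at <- pos + 8L
    }
    value <- if (len > 0) buf[val_at:(val_at + len - 1)] else raw(0)
    hit <- .dcm_dictionary[.dcm_dictionary$group == group &
                             .dcm_dictionary$element == element, ]
    if (nrow(hit) == 1) {
      nm <- hit$name
      if (nm == "PixelData") {
        pixel <- value
      } else if (hit$vr == "US") {
        meta[[nm]] <- readBin(value, "integer", size = 2, endian = "little",
                              signed = FALSE)
      } else {
        v <- value[value != as.raw(0)]  # drop UI nul padding
        meta[[nm]] <- trimws(rawToChar(v), which = "right")
      }
    }
    pos <- val_at + len
  }
  image <- NULL
  if (!is.null(pixel)) {
    rows <- meta$Rows; cols <- meta$Columns
    if (is.null(rows) || is.null(cols)) {
      stop("read_dicom: pixel data without Rows/Columns", call. = FALSE)
    }
    bits <- meta$BitsAllocated %||% 8
    vals <- if (bits <= 8) {
      as.integer(pixel)
    } else {
      readBin(pixel, "integer", n = rows * cols, size = 2, endian = "little",
              signed = FALSE)
    }
    image <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  }
  list(meta = meta, image = image)
}

#' Convert a DICOM file to an anonymised grayscale PNG with metadata sidecar
#'
#' Pixel data is window-levelled to 256 gray levels (8-bit sources pass
#' through unchanged; wider sources are min-max scaled) and written as PNG.
#' The sidecar (YAML) carries the technical attributes with every
#' patient-identifying attribute removed.
#'
#' @param dicom_path input DICOM file.
#' @param png_path output PNG file.
#' @param sidecar_path output YAML sidecar (default: `png_path` with a
#'   `.yaml` extension).
#' @return the PNG path, invisibly.
#' @export
convert_dicom <- function(dicom_path, png_path,
                          sidecar_path = paste0(
                            tools::file_path_sans_ext(png_path), ".yaml")) {
  d <- read_dicom(dicom_path)
  if (is.null(d$image)) {
    stop("convert_dicom: DICOM object carries no pixel data", call. = FALSE)
  }
  img <- d$image
  if ((d$meta$BitsAllocated %||% 8) > 8 || max(img) > 255) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) {
      round(255 * (img - rng[1]) / (rng[2] - rng[1]))
    } else {
      img * 0L
    }
  }
  write_gray_png(img, png_path)
  meta <- d$meta[setdiff(names(d$meta), .dcm_phi_tags)]
  yaml::write_yaml(meta, sidecar_path)
  invisible(png_path)
}
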
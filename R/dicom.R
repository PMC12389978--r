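# Minimal single-frame grayscale DICOM support (explicit/implicit VR little
# endian).  Covers exactly the tag set a monochrome secondary-capture image
# needs; everything else is skipped on read and never written.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"

pack_u16 <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(x %% 256L, (x %/% 256L) %% 256L))
}

pack_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# Even-length string payload, padded per VR convention (space for text
# VRs, NUL for UIDs).
raw_to_string <- function(b) {
  trimws(rawToChar(b[b != as.raw(0)]))
}

pad_string <- function(s, pad = as.raw(0x20)) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

# One explicit-VR little-endian data element.
dicom_element <- function(group, element, vr, payload) {
  stopifnot(is.raw(payload))
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  header <- c(pack_u16(group), pack_u16(element), charToRaw(vr))
  if (long_vr) {
    c(header, as.raw(c(0, 0)), pack_u32(length(payload)), payload)
  } else {
    if (length(payload) > 65535) stop("payload too long for short VR", call. = FALSE)
    c(header, pack_u16(length(payload)), payload)
  }
}

#' Write a minimal single-frame grayscale DICOM file
#'
#' Quantizes an image in \[0, 1\] to `bits` unsigned integer levels and writes
#' it as an explicit-VR little-endian secondary-capture DICOM with the minimal
#' tag set needed for pixel decoding. Intended for generating test fixtures
#' that round-trip through [read_dicom()].
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param path Output file path.
#' @param bits Bit depth of the stored pixels, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_dicom_fixture <- function(img, path, bits = 16) {
  assert_image(img)
  if (min(img) < 0 || max(img) > 1) {
    stop("`img` must lie in [0, 1] before quantization", call. = FALSE)
  }
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  maxval <- 2^bits - 1
  q <- round_half_away(img * maxval)          # row-major pixel order on disk
  pix <- as.integer(as.vector(t(q)))
  payload <- if (bits == 8L) {
    pr <- as.raw(pix)
    if (length(pr) %% 2L == 1L) pr <- c(pr, as.raw(0)) else pr
  } else {
    pack_u16(pix)
  }

  meta_body <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_element(0x0002, 0x0002, "UI", pad_string(UID_SC_SOP_CLASS, as.raw(0))),
    dicom_element(0x0002, 0x0003, "UI", pad_string("1.2.826.0.1.3680043.8.498.1", as.raw(0))),
    dicom_element(0x0002, 0x0010, "UI", pad_string(UID_EXPLICIT_LE, as.raw(0))),
    dicom_element(0x0002, 0x0012, "UI", pad_string("1.2.826.0.1.3680043.8.498.2", as.raw(0)))
  )
  dataset <- c(
    dicom_element(0x0008, 0x0016, "UI", pad_string(UID_SC_SOP_CLASS, as.raw(0))),
    dicom_element(0x0008, 0x0018, "UI", pad_string("1.2.826.0.1.3680043.8.498.1", as.raw(0))),
    dicom_element(0x0028, 0x0002, "US", pack_u16(1L)),
    dicom_element(0x0028, 0x0004, "CS", pad_string("MONOCHROME2")),
    dicom_element(0x0028, 0x0010, "US", pack_u16(nrow(img))),
    dicom_element(0x0028, 0x0011, "US", pack_u16(ncol(img))),
    dicom_element(0x0028, 0x0100, "US", pack_u16(bits)),
    dicom_element(0x0028, 0x0101, "US", pack_u16(bits)),
    dicom_element(0x0028, 0x0102, "US", pack_u16(bits - 1L)),
    dicom_element(0x0028, 0x0103, "US", pack_u16(0L)),
    dicom_element(0x7FE0, 0x0010, "OW", payload)
  )
  out <- c(
    raw(128), charToRaw("DICM"),
    dicom_element(0x0002, 0x0000, "UL", pack_u32(length(meta_body))),
    meta_body, dataset
  )
  writeBin(out, path)
  invisible(path)
}

#' Read a single-frame grayscale DICOM image
#'
#' Parses an explicit- or implicit-VR little-endian DICOM file, decodes its
#' pixel data, applies the rescale slope/intercept when present, inverts
#' MONOCHROME1 images, and min-max normalizes the result to \[0, 1\].
#' Multi-frame and color (samples-per-pixel > 1) files are rejected.
#'
#' @param path Path to the DICOM file.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 132 || !identical(buf[129:132], charToRaw("DICM"))) {
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  }
  u16 <- function(i) readBin(buf[i:(i + 1)], "integer", size = 2, signed = FALSE,
                             endian = "little")
  u32 <- function(i) readBin(buf[i:(i + 3)], "integer", size = 4, endian = "little")

  tags <- list()
  pixel <- NULL
  transfer_syntax <- UID_EXPLICIT_LE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  while (pos + 7L <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2L)
    explicit <- group == 0x0002 || transfer_syntax == UID_EXPLICIT_LE
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); body <- pos + 12L
      } else {
        len <- u16(pos + 6L); body <- pos + 8L
      }
    } else {
      len <- u32(pos + 4L); body <- pos + 8L
    }
    if (len < 0 || body + len - 1L > length(buf) + 1L) {
      stop("corrupt DICOM element at offset ", pos, call. = FALSE)
    }
    payload <- if (len > 0) buf[body:(body + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    if (key == "7FE0,0010") {
      pixel <- payload
    } else if (group %in% c(0x0002, 0x0008, 0x0028)) {
      tags[[key]] <- payload
      if (key == "0002,0010") {
        transfer_syntax <- raw_to_string(payload)
      }
    }
    pos <- body + len
  }
  if (!transfer_syntax %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
    stop("unsupported transfer syntax: ", transfer_syntax, call. = FALSE)
  }

  tag_u16 <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    readBin(tags[[key]][1:2], "integer", size = 2, signed = FALSE, endian = "little")
  }
  tag_str <- function(key, default = "") {
    if (is.null(tags[[key]])) return(default)
    raw_to_string(tags[[key]])
  }

  samples <- tag_u16("0028,0002", 1L)
  if (samples != 1L) stop("color image (samples per pixel = ", samples,
                          "): only grayscale is supported", call. = FALSE)
  nframes <- suppressWarnings(as.integer(tag_str("0028,0008", "1")))
  if (!is.na(nframes) && nframes > 1L) {
    stop("multi-frame DICOM (", nframes, " frames) is not supported", call. = FALSE)
  }
  rows <- tag_u16("0028,0010"); cols <- tag_u16("0028,0011")
  bits <- tag_u16("0028,0100", 16L)
  signed <- identical(tag_u16("0028,0103", 0L), 1L)
  if (is.null(rows) || is.null(cols)) stop("missing image dimensions", call. = FALSE)
  if (is.null(pixel)) stop("no pixel data in DICOM file", call. = FALSE)
  if (!bits %in% c(8L, 16L)) stop("unsupported bits allocated: ", bits, call. = FALSE)

  n <- rows * cols
  vals <- if (bits == 8L) {
    v <- as.integer(pixel[seq_len(n)])
    if (signed) ifelse(v > 127L, v - 256L, v) else v
  } else {
    readBin(pixel, "integer", n = n, size = 2, signed = signed, endian = "little")
  }
  if (bits == 16L && !signed) vals <- ifelse(vals < 0L, vals + 65536L, vals)
  vals <- as.numeric(vals)

  slope <- suppressWarnings(as.numeric(tag_str("0028,1053", "1")))
  intercept <- suppressWarnings(as.numeric(tag_str("0028,1052", "0")))
  if (!is.na(slope) && !is.na(intercept) && (slope != 1 || intercept != 0)) {
    vals <- vals * slope + intercept
  }

  img <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  if (tag_str("0028,0004", "MONOCHROME2") == "MONOCHROME1") img <- -img
  normalize_minmax(img)
}
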
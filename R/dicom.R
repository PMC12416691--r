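# Minimal DICOM file support: Explicit VR Little Endian, single-frame
# 16-bit grayscale Secondary Capture, MONOCHROME1/2. Covers exactly what
# phantom submissions need (PhotometricInterpretation, BitsStored, Rows,
# Columns, PixelData); unknown tags are skipped on read and corrupt or
# missing photometric tags degrade to "unknown" for the border heuristic.

.ts_explicit_le <- "1.2.840.10008.1.2.1"
.sop_secondary_capture <- "1.2.840.10008.5.1.4.1.1.7"
.impl_uid <- "1.2.826.0.1.3680043.10.1462.1"

#' @keywords internal
dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")

#' @keywords internal
dcm_element <- function(group, element, vr, value) {
  # value: raw vector already encoded; pads to even length
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  if (length(value) %% 2 == 1) value <- c(value, as.raw(0))
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    c(head, dcm_uint16(length(value)), value)
  }
}

#' Write a raw phantom image as a DICOM file
#'
#' @param img a [raw_image()] (values must fit the stored bit depth)
#' @param path output file path
#' @param instance_uid SOP instance UID (a fresh one is derived from the
#'   content hash when NULL)
#' @return `path`, invisibly
#' @export
write_dicom <- function(img, path, instance_uid = NULL) {
  if (!inherits(img, "raw_image")) stop("img must be a raw_image")
  px <- img$pixels
  if (max(px) > 65535) stop("pixel values exceed 16-bit range")
  if (is.null(instance_uid)) {
    h <- sum(as.numeric(px) * seq_along(px)) %% 1e9
    instance_uid <- sprintf("%s.%.0f.%d.%d", .impl_uid, h, nrow(px), ncol(px))
  }
  photometric <- toupper(img$photometric)
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("photometric must be monochrome1 or monochrome2 for writing")
  meta <- c(
    dcm_element(2L, 1L, "OB", as.raw(c(0, 1))),
    dcm_element(2L, 2L, "UI", .sop_secondary_capture),
    dcm_element(2L, 3L, "UI", instance_uid),
    dcm_element(2L, 16L, "UI", .ts_explicit_le),
    dcm_element(2L, 18L, "UI", .impl_uid))
  meta <- c(dcm_element(2L, 0L, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little")), meta)
  bits_stored <- as.integer(img$bit_depth)
  body <- c(
    dcm_element(8L, 22L, "UI", .sop_secondary_capture),          # 0008,0016
    dcm_element(8L, 24L, "UI", instance_uid),                    # 0008,0018
    dcm_element(40L, 2L, "US", dcm_uint16(1L)),                  # samples/px
    dcm_element(40L, 4L, "CS", photometric),
    dcm_element(40L, 16L, "US", dcm_uint16(nrow(px))),           # rows
    dcm_element(40L, 17L, "US", dcm_uint16(ncol(px))),           # columns
    dcm_element(40L, 256L, "US", dcm_uint16(16L)),               # allocated
    dcm_element(40L, 257L, "US", dcm_uint16(bits_stored)),
    dcm_element(40L, 258L, "US", dcm_uint16(bits_stored - 1L)),  # high bit
    dcm_element(40L, 259L, "US", dcm_uint16(0L)),                # unsigned
    dcm_element(32736L, 16L, "OW", dcm_uint16(as.vector(t(px)))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Read a DICOM file written in Explicit VR Little Endian
#'
#' Parses the subset of tags the pipeline needs. A missing or unrecognized
#' PhotometricInterpretation yields `photometric = "unknown"`, which
#' [to_monochrome2()] resolves heuristically.
#'
#' @param path DICOM file path
#' @return a [raw_image()]
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 160 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  u16 <- function(at) sum(as.integer(bytes[at:(at + 1)]) * c(1L, 256L))
  u32 <- function(at) sum(as.numeric(bytes[at:(at + 3)]) * c(1, 256, 65536, 16777216))
  tags <- list()
  n <- length(bytes)
  while (pos + 7 <= n) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8); data_at <- pos + 12
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- u16(pos + 6); data_at <- pos + 8
    } else stop("unsupported (implicit VR?) element at byte ", pos)
    if (len > n - data_at + 1) stop("truncated DICOM element")
    key <- sprintf("%04x,%04x", group, element)
    tags[[key]] <- list(vr = vr, at = data_at, len = len)
    pos <- data_at + len
  }
  getstr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(bytes[t$at:(t$at + t$len - 1)]))
  }
  getu16 <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    u16(t$at)
  }
  rows <- getu16("0028,0010"); cols <- getu16("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns")
  bits <- getu16("0028,0101")
  if (is.null(bits)) bits <- 16L
  ph <- getstr("0028,0004")
  photometric <- if (is.null(ph)) "unknown"
  else if (ph == "MONOCHROME1") "monochrome1"
  else if (ph == "MONOCHROME2") "monochrome2"
  else "unknown"
  t <- tags[["7fe0,0010"]]
  if (is.null(t)) stop("missing PixelData")
  vals <- readBin(bytes[t$at:(t$at + t$len - 1)], integer(),
                  n = t$len / 2, size = 2, signed = FALSE,
                  endian = "little")
  px <- matrix(vals, rows, cols, byrow = TRUE)
  raw_image(px, photometric, as.integer(bits))
}
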
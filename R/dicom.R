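# Minimal single-frame DICOM support: a reader for uncompressed
# little-endian CT slices (explicit or implicit VR) and a small writer used
# to produce test fixtures. Not a general DICOM implementation.

.u16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))
.u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

.EXPLICIT_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                   "IS", "LO", "LT", "OB", "OF", "OW", "PN", "SH", "SL",
                   "SQ", "SS", "ST", "TM", "UI", "UL", "UN", "US", "UT")
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one data element starting at offset `pos` (1-based) of `bytes`.
# Returns list(group, elem, vr, value_raw, next_pos).
.dicomElement <- function(bytes, pos, explicit) {
  group <- .u16(bytes[pos:(pos + 1L)])
  elem <- .u16(bytes[(pos + 2L):(pos + 3L)])
  pos <- pos + 4L
  vr <- NA_character_
  if (explicit) {
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    if (!vr %in% .EXPLICIT_VRS)
      stop(sprintf("unknown VR '%s' at offset %d", vr, pos))
    if (vr %in% .LONG_VRS) {
      len <- .u32(bytes[(pos + 4L):(pos + 7L)])
      pos <- pos + 8L
    } else {
      len <- .u16(bytes[(pos + 2L):(pos + 3L)])
      pos <- pos + 4L
    }
  } else {
    len <- .u32(bytes[pos:(pos + 3L)])
    pos <- pos + 4L
  }
  if (len == 4294967295)
    stop("undefined-length DICOM elements are not supported")
  if (pos + len - 1L > length(bytes))
    stop("truncated DICOM element")
  value <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
  list(group = group, elem = elem, vr = vr, value = value,
       next_pos = pos + as.integer(len))
}

.dicomString <- function(raw) {
  s <- rawToChar(raw[raw != as.raw(0)])
  trimws(s)
}

#' Read a single-frame CT DICOM slice
#'
#' Parses an uncompressed little-endian DICOM file (explicit or implicit
#' VR, with or without the 128-byte preamble) and returns the slice with
#' pixel values rescaled to Hounsfield units:
#' \code{HU = stored * RescaleSlope + RescaleIntercept}. The rescale is
#' affine and exact for integer stored values. Files missing the rescale
#' tags, multi-frame files, and compressed transfer syntaxes are rejected
#' with an explicit error; there is no silent default.
#'
#' @param path path to a DICOM file.
#' @return A \linkS4class{CTSlice} with \code{source = "dicom"}.
#' @seealso \code{\link{writeDicomSlice}} for the fixture writer.
#' @export
readDicomSlice <- function(path) {
  if (!file.exists(path)) stop("cannot read DICOM file: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  explicit <- TRUE
  ts <- NULL
  if (length(bytes) >= 132L &&
      identical(rawToChar(bytes[129:132]), "DICM")) {
    pos <- 133L
    # file meta group (0002) is always explicit little-endian
    repeat {
      if (pos + 7L > length(bytes)) break
      if (.u16(bytes[pos:(pos + 1L)]) != 2L) break
      el <- .dicomElement(bytes, pos, explicit = TRUE)
      if (el$elem == 0x0010) ts <- .dicomString(el$value)
      pos <- el$next_pos
    }
    if (!is.null(ts)) {
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts == "1.2.840.10008.1.2.1") explicit <- TRUE
      else stop("unsupported transfer syntax: ", ts,
                " (only uncompressed little-endian is supported)")
    }
  } else {
    # no preamble: sniff explicit VR from the first element
    if (length(bytes) < 8L) stop("not a parseable DICOM file: ", path)
    explicit <- rawToChar(bytes[(pos + 4L):(pos + 5L)]) %in% .EXPLICIT_VRS
  }

  tags <- list()
  key <- function(g, e) sprintf("%04X,%04X", g, e)
  while (pos + 7L <= length(bytes)) {
    el <- .dicomElement(bytes, pos, explicit)
    tags[[key(el$group, el$elem)]] <- el
    pos <- el$next_pos
  }

  need <- function(k, name) {
    if (is.null(tags[[k]]))
      stop(sprintf("DICOM file lacks required tag (%s) %s", k, name))
    tags[[k]]
  }
  nFrames <- tags[["0028,0008"]]
  if (!is.null(nFrames) && as.integer(.dicomString(nFrames$value)) > 1L)
    stop("multi-frame DICOM files are not supported (one slice per file)")

  rows <- .u16(need("0028,0010", "Rows")$value[1:2])
  cols <- .u16(need("0028,0011", "Columns")$value[1:2])
  bits <- .u16(need("0028,0100", "BitsAllocated")$value[1:2])
  signed <- .u16(need("0028,0103", "PixelRepresentation")$value[1:2]) == 1L
  slope <- as.numeric(.dicomString(need("0028,1053", "RescaleSlope")$value))
  intercept <- as.numeric(.dicomString(need("0028,1052", "RescaleIntercept")$value))
  pdata <- need("7FE0,0010", "PixelData")$value

  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)
  nbytes <- bits %/% 8L
  if (length(pdata) < rows * cols * nbytes)
    stop("PixelData shorter than Rows*Columns")
  stored <- readBin(pdata, "integer", n = rows * cols, size = nbytes,
                    signed = if (nbytes == 1L) FALSE else signed,
                    endian = "little")
  if (nbytes == 2L && !signed) stored <- ifelse(stored < 0, stored + 65536, stored)
  hu <- stored * slope + intercept
  # DICOM pixel data is row-major, first row first
  px <- matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)

  pid <- if (!is.null(tags[["0010,0020"]])) .dicomString(tags[["0010,0020"]]$value) else "unknown"
  sid <- if (!is.null(tags[["0008,0018"]])) .dicomString(tags[["0008,0018"]]$value)
         else if (!is.null(tags[["0020,0013"]])) .dicomString(tags[["0020,0013"]]$value)
         else "unknown"
  CTSlice(px, patientID = pid, sliceID = sid, source = "dicom")
}

.padEven <- function(raw, pad = as.raw(0)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

.emitExplicit <- function(group, elem, vr, value) {
  value <- .padEven(value, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  hdr <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                  size = 2, endian = "little")
  if (vr %in% .LONG_VRS) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value), raw(), size = 2, endian = "little"), value)
  }
}

#' Write a CT slice as a minimal DICOM file (test fixtures)
#'
#' Emits an explicit-VR little-endian single-frame CT dataset with 16-bit
#' signed pixels, \code{RescaleSlope = 1} and
#' \code{RescaleIntercept = -1024} (stored = HU + 1024). Intended for
#' building test fixtures and round-trip checks, not for clinical use.
#'
#' @param slice a \linkS4class{CTSlice}; HU values are rounded to integers.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDicomSlice <- function(slice, path) {
  stopifnot(is(slice, "CTSlice"))
  intercept <- -1024; slope <- 1
  stored <- as.integer(round((round(slice@pixels) - intercept) / slope))
  if (any(stored < -32768 | stored > 32767))
    stop("HU values out of range for 16-bit storage")
  rows <- nrow(slice@pixels); cols <- ncol(slice@pixels)
  # pixel data is row-major
  pdata <- writeBin(as.vector(t(matrix(stored, rows, cols))),
                    raw(), size = 2, endian = "little")

  str_ <- function(s) charToRaw(as.character(s))
  us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  sopClass <- "1.2.840.10008.5.1.4.1.1.2"  # CT Image Storage
  sopInst <- paste0("1.2.826.0.1.3680043.9999.", abs(sum(stored)) %% 100000, ".",
                    rows, ".", cols)
  meta <- c(
    .emitExplicit(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .emitExplicit(0x0002, 0x0002, "UI", str_(sopClass)),
    .emitExplicit(0x0002, 0x0003, "UI", str_(sopInst)),
    .emitExplicit(0x0002, 0x0010, "UI", str_("1.2.840.10008.1.2.1")),
    .emitExplicit(0x0002, 0x0012, "UI", str_("1.2.826.0.1.3680043.9999.1"))
  )
  metaLen <- .emitExplicit(0x0002, 0x0000, "UL",
                           writeBin(length(meta), raw(), size = 4, endian = "little"))
  body <- c(
    .emitExplicit(0x0008, 0x0016, "UI", str_(sopClass)),
    .emitExplicit(0x0008, 0x0018, "UI", str_(slice@sliceID)),
    .emitExplicit(0x0008, 0x0060, "CS", str_("CT")),
    .emitExplicit(0x0010, 0x0020, "LO", str_(slice@patientID)),
    .emitExplicit(0x0028, 0x0002, "US", us(1)),
    .emitExplicit(0x0028, 0x0004, "CS", str_("MONOCHROME2")),
    .emitExplicit(0x0028, 0x0010, "US", us(rows)),
    .emitExplicit(0x0028, 0x0011, "US", us(cols)),
    .emitExplicit(0x0028, 0x0100, "US", us(16)),
    .emitExplicit(0x0028, 0x0101, "US", us(16)),
    .emitExplicit(0x0028, 0x0102, "US", us(15)),
    .emitExplicit(0x0028, 0x0103, "US", us(1)),
    .emitExplicit(0x0028, 0x1052, "DS", str_(intercept)),
    .emitExplicit(0x0028, 0x1053, "DS", str_(slope)),
    .emitExplicit(0x7FE0, 0x0010, "OW", pdata)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), metaLen, meta, body), con)
  invisible(path)
}
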
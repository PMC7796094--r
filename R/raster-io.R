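# Mask rasters: foreground (lung) = 255, background = 0.
# BMP is written as uncompressed 8-bit grayscale with a 256-entry gray
# palette (the classic mask dialect); PNG is the lossless alternative via
# the png package.

.writeBMP8 <- function(m255, path) {
  h <- nrow(m255); w <- ncol(m255)
  rowBytes <- ((w + 3L) %/% 4L) * 4L
  imgSize <- rowBytes * h
  offset <- 14L + 40L + 256L * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  # file header
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + imgSize), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(offset), con, size = 4, endian = "little")
  # info header
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")  # bottom-up
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")              # BI_RGB
  writeBin(as.integer(imgSize), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 256L, 0L), con, size = 4, endian = "little")
  # gray palette BGRA
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  pal[seq(4, 1024, by = 4)] <- as.raw(0)
  writeBin(pal, con)
  # pixel rows, bottom-up, padded to 4 bytes
  pad <- raw(rowBytes - w)
  for (r in h:1) writeBin(c(as.raw(m255[r, ]), pad), con)
  invisible(path)
}

.readBMP8 <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(bytes[1:2]) != "BM") stop("not a BMP file: ", path)
  offset <- .u32(bytes[11:14])
  hdrSize <- .u32(bytes[15:18])
  if (hdrSize < 40) stop("unsupported BMP header")
  w <- .u32(bytes[19:22])
  hRaw <- .u32(bytes[23:26])
  topDown <- hRaw > 2^31
  h <- if (topDown) 2^32 - hRaw else hRaw
  bpp <- .u16(bytes[29:30])
  comp <- .u32(bytes[31:34])
  if (bpp != 8L || comp != 0L)
    stop("only uncompressed 8-bit BMP is supported")
  palOff <- 14L + hdrSize
  nPal <- .u32(bytes[47:50]); if (nPal == 0) nPal <- 256
  pal <- as.integer(bytes[palOff + seq_len(nPal * 4)])
  gray <- pal[seq(1, nPal * 4, by = 4)]  # blue channel of BGRA gray ramp
  rowBytes <- ((w + 3L) %/% 4L) * 4L
  m <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    r <- if (topDown) i else h - i + 1L
    start <- offset + (i - 1L) * rowBytes
    idx <- as.integer(bytes[start + seq_len(w)])
    m[r, ] <- gray[idx + 1L]
  }
  m
}

#' Write a binary mask as a BMP or PNG raster
#'
#' Foreground (lung) pixels are written as 255, background as 0; reading
#' the file back with \code{\link{readMask}} reproduces the mask exactly.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output path.
#' @param format \code{"bmp"} (uncompressed 8-bit grayscale) or
#'   \code{"png"}.
#' @return \code{path}, invisibly.
#' @examples
#' p <- tempfile(fileext = ".png")
#' m <- BinaryMask(matrix(c(0, 1, 1, 0), 2, 2))
#' writeMask(m, p, "png")
#' identical(readMask(p)@.Data, m@.Data)
#' @export
writeMask <- function(mask, path, format = c("bmp", "png")) {
  stopifnot(is(mask, "BinaryMask"))
  format <- match.arg(format)
  m255 <- mask@.Data * 255L
  if (format == "bmp") {
    .writeBMP8(m255, path)
  } else {
    png::writePNG(m255 / 255, path)
  }
  invisible(path)
}

#' Read a binary mask raster
#'
#' Accepts BMP or PNG files written by \code{\link{writeMask}} (or any
#' two-valued 0/255 grayscale raster); pixels above 127 become foreground.
#'
#' @param path path to a \code{.bmp} or \code{.png} file.
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    im <- png::readPNG(path)
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    round(im * 255)
  } else {
    .readBMP8(path)
  }
  BinaryMask(m > 127)
}
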
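#' CTSlice: a 2-D CT slice in Hounsfield units
#'
#' Container for one HU-calibrated CT slice with identity metadata. Pixel
#' values are expected to lie in a plausible post-rescale range
#' [-2000, 4000] HU.
#'
#' @slot pixels numeric matrix of HU values (rows x columns).
#' @slot patientID,sliceID opaque identifiers.
#' @slot source either \code{"dicom"} or \code{"phantom"}.
#' @export
setClass("CTSlice",
  representation(pixels = "matrix", patientID = "character",
                 sliceID = "character", source = "character"))

setValidity("CTSlice", function(object) {
  p <- object@pixels
  if (nrow(p) < 1L || ncol(p) < 1L)
    return("pixel grid must have positive dimensions")
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    return("pixels must be finite numeric HU values")
  if (any(p < -2000) || any(p > 4000))
    return("HU values outside plausible range [-2000, 4000]")
  if (length(object@source) != 1L || !object@source %in% c("dicom", "phantom"))
    return("source must be 'dicom' or 'phantom'")
  TRUE
})

#' Construct a CTSlice
#'
#' @param pixels numeric matrix of HU values.
#' @param patientID,sliceID identifier strings.
#' @param source provenance, \code{"dicom"} or \code{"phantom"}.
#' @return A \linkS4class{CTSlice}.
#' @examples
#' s <- CTSlice(matrix(-1000, 8, 8), source = "phantom")
#' dim(s)
#' @export
CTSlice <- function(pixels, patientID = "unknown", sliceID = "unknown",
                    source = c("phantom", "dicom")) {
  source <- match.arg(source)
  new("CTSlice", pixels = pixels, patientID = as.character(patientID),
      sliceID = as.character(sliceID), source = source)
}

#' @describeIn CTSlice slice dimensions (rows, columns).
#' @param x a \code{CTSlice}.
#' @export
setMethod("dim", "CTSlice", function(x) dim(x@pixels))

#' Pixel grid of a CTSlice
#' @param x a \linkS4class{CTSlice}.
#' @return The HU matrix.
#' @export
huPixels <- function(x) {
  stopifnot(is(x, "CTSlice"))
  x@pixels
}

setMethod("show", "CTSlice", function(object) {
  cat(sprintf("CTSlice %dx%d [%s] patient=%s slice=%s HU range [%.0f, %.0f]\n",
              nrow(object@pixels), ncol(object@pixels), object@source,
              object@patientID, object@sliceID,
              min(object@pixels), max(object@pixels)))
})

#' BinaryMask: a 0/1 image mask
#'
#' An integer matrix restricted to values {0, 1}; foreground (lung) is 1.
#' Behaves like a matrix in arithmetic and subsetting.
#'
#' @export
setClass("BinaryMask", contains = "matrix")

setValidity("BinaryMask", function(object) {
  if (nrow(object) < 1L || ncol(object) < 1L)
    return("mask must have positive dimensions")
  v <- object@.Data
  if (anyNA(v) || !all(v == 0L | v == 1L))
    return("mask values must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryMask
#' @param m matrix of 0/1 values (numeric or integer, or logical).
#' @return A \linkS4class{BinaryMask}.
#' @examples
#' BinaryMask(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
BinaryMask <- function(m) {
  if (is.logical(m)) m[] <- as.integer(m)
  storage.mode(m) <- "integer"
  new("BinaryMask", m)
}

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %dx%d, %d foreground pixel(s)\n",
              nrow(object), ncol(object), sum(object@.Data)))
})

#' LabelMap: connected-component labels
#'
#' Integer matrix where 0 is background and positive values 1..n identify
#' maximal connected foreground components.
#'
#' @slot nLabels number of distinct positive labels.
#' @export
setClass("LabelMap", contains = "matrix",
         representation(nLabels = "integer"))

setValidity("LabelMap", function(object) {
  v <- object@.Data
  if (anyNA(v) || any(v < 0L)) return("labels must be non-negative")
  n <- object@nLabels
  pos <- sort(unique(v[v > 0L]))
  if (length(pos) != n || (n > 0L && !identical(pos, seq_len(n))))
    return("positive labels must be exactly 1..nLabels")
  TRUE
})

#' Number of labelled components
#' @param x a \linkS4class{LabelMap}.
#' @return Integer count of positive labels.
#' @export
nLabels <- function(x) {
  stopifnot(is(x, "LabelMap"))
  x@nLabels
}

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap %dx%d, %d component(s)\n",
              nrow(object), ncol(object), object@nLabels))
})

#' StructuringElement: a disk footprint for binary morphology
#'
#' The footprint is the discrete Euclidean disk
#' \{(dx, dy): dx^2 + dy^2 <= r^2\}, symmetric about its centre.
#'
#' @slot footprint 0/1 matrix of odd side 2r+1.
#' @slot kind footprint family; only \code{"disk"}.
#' @slot radius positive integer radius in pixels.
#' @export
setClass("StructuringElement",
  representation(footprint = "matrix", kind = "character",
                 radius = "integer"))

setValidity("StructuringElement", function(object) {
  r <- object@radius
  if (length(r) != 1L || is.na(r) || r < 1L) return("radius must be >= 1")
  fp <- object@footprint
  if (!all(dim(fp) == 2L * r + 1L)) return("footprint side must be 2r+1")
  off <- expand.grid(dy = -r:r, dx = -r:r)
  want <- matrix(as.integer(off$dx^2 + off$dy^2 <= r^2), 2L * r + 1L)
  if (!all(fp == want)) return("footprint must be the Euclidean <= r^2 disk")
  if (!identical(object@kind, "disk")) return("kind must be 'disk'")
  TRUE
})

#' Disk structuring element
#'
#' @param radius positive integer radius in pixels.
#' @return A \linkS4class{StructuringElement} whose footprint is the
#'   discrete Euclidean disk of the given radius.
#' @examples
#' diskElement(2)
#' @export
diskElement <- function(radius) {
  r <- as.integer(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  fp <- matrix(as.integer(off$dx^2 + off$dy^2 <= r^2), 2L * r + 1L)
  new("StructuringElement", footprint = fp, kind = "disk", radius = r)
}

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement disk r=%d (%d offsets)\n",
              object@radius, sum(object@footprint)))
})

# offsets (dr, dc) of a structuring element relative to its centre
.selemOffsets <- function(selem) {
  r <- selem@radius
  idx <- which(selem@footprint == 1L, arr.ind = TRUE)
  list(dr = as.integer(idx[, 1L] - r - 1L), dc = as.integer(idx[, 2L] - r - 1L))
}

#' ThreeChannelImage: engineered network input
#'
#' H x W x 3 stack in [0, 1]: channel 1 = normalized original image,
#' channel 2 = Canny edge map (0/1), channel 3 = dilated binary (0/1).
#'
#' @slot channels numeric array of dimension (H, W, 3).
#' @slot engineered TRUE for the engineered stack (edge/dilation channels
#'   are then required to be two-valued); FALSE for the default-channel
#'   replication used as an ablation arm.
#' @export
setClass("ThreeChannelImage",
         representation(channels = "array", engineered = "logical"))

setValidity("ThreeChannelImage", function(object) {
  ch <- object@channels
  d <- dim(ch)
  if (length(d) != 3L || d[3L] != 3L) return("channels must be H x W x 3")
  if (anyNA(ch) || any(ch < 0) || any(ch > 1)) return("values must be in [0, 1]")
  if (isTRUE(object@engineered)) {
    for (k in 2:3) {
      v <- ch[, , k]
      if (!all(v == 0 | v == 1))
        return(sprintf("channel %d must be two-valued {0, 1}", k))
    }
  }
  TRUE
})

setMethod("dim", "ThreeChannelImage", function(x) dim(x@channels))

#' Channel stack of a ThreeChannelImage
#' @param x a \linkS4class{ThreeChannelImage}.
#' @return The (H, W, 3) array.
#' @export
imageChannels <- function(x) {
  stopifnot(is(x, "ThreeChannelImage"))
  x@channels
}

setMethod("show", "ThreeChannelImage", function(object) {
  d <- dim(object@channels)
  cat(sprintf("ThreeChannelImage %dx%dx3 (%d edge px, %d dilated-white px)\n",
              d[1L], d[2L], sum(object@channels[, , 2L]),
              sum(object@channels[, , 3L])))
})

#' DatasetSplit: reproducible train/validation/test partition
#'
#' @slot trainIDs,valIDs,testIDs disjoint identifier vectors.
#' @slot seed integer driving the permutation.
#' @slot fractions three non-negative reals summing to 1.
#' @export
setClass("DatasetSplit",
  representation(trainIDs = "character", valIDs = "character",
                 testIDs = "character", seed = "integer",
                 fractions = "numeric"))

setValidity("DatasetSplit", function(object) {
  all3 <- c(object@trainIDs, object@valIDs, object@testIDs)
  if (anyDuplicated(all3)) return("partitions must be pairwise disjoint")
  if (length(object@fractions) != 3L || any(object@fractions < 0) ||
      abs(sum(object@fractions) - 1) > 1e-9)
    return("fractions must be three non-negative reals summing to 1")
  TRUE
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit train=%d val=%d test=%d (seed %d)\n",
              length(object@trainIDs), length(object@valIDs),
              length(object@testIDs), object@seed))
})

#' Identifier lists of a DatasetSplit
#' @param x a \linkS4class{DatasetSplit}.
#' @return Named list with elements \code{train}, \code{val}, \code{test}.
#' @export
splitIDs <- function(x) {
  stopifnot(is(x, "DatasetSplit"))
  list(train = x@trainIDs, val = x@valIDs, test = x@testIDs)
}
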
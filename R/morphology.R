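#' Threshold a CT slice into a binary lung-candidate mask
#'
#' A pixel is foreground (1) iff its attenuation is strictly below the
#' threshold; -604 HU is the standard lung-parenchyma cut between aerated
#' lung (~ -800 HU) and soft tissue (~ +40 HU). The inequality is strict,
#' so a pixel exactly at the threshold is background.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param thresholdHU threshold in HU (default -604).
#' @return A \linkS4class{BinaryMask}; 1 where HU < threshold.
#' @examples
#' s <- CTSlice(matrix(c(-1000, 0, -604, -605), 2, 2))
#' binarizeHU(s)
#' @export
binarizeHU <- function(slice, thresholdHU = -604) {
  stopifnot(is(slice, "CTSlice"))
  BinaryMask(slice@pixels < thresholdHU)
}

.asIntMat <- function(mask) {
  m <- if (is(mask, "BinaryMask")) mask@.Data else mask
  storage.mode(m) <- "integer"
  m
}

#' Remove foreground components touching the image border
#'
#' Every connected foreground component containing at least one border
#' pixel is deleted; interior components are untouched. In a thresholded
#' CT slice this removes the air surrounding the body, which always
#' reaches the frame.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param connectivity 4 or 8 (default 8).
#' @return A \linkS4class{BinaryMask}, a subset of the input.
#' @export
clearBorder <- function(mask, connectivity = 8) {
  stopifnot(is(mask, "BinaryMask"), connectivity %in% c(4, 8))
  lab <- cpp_label(.asIntMat(mask), as.integer(connectivity))
  H <- nrow(lab); W <- ncol(lab)
  border <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  border <- border[border > 0L]
  out <- mask@.Data
  out[lab %in% border] <- 0L
  BinaryMask(out)
}

#' Label connected foreground components
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param connectivity 4 or 8 (default 8).
#' @return A \linkS4class{LabelMap}; labels 1..n in scan order, 0 background.
#' @examples
#' m <- BinaryMask(diag(2))
#' nLabels(labelComponents(m, 8))  # diagonal pair: one 8-connected component
#' nLabels(labelComponents(m, 4))  # two 4-connected components
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is(mask, "BinaryMask"), connectivity %in% c(4, 8))
  lab <- cpp_label(.asIntMat(mask), as.integer(connectivity))
  n <- attr(lab, "n_labels")
  attr(lab, "n_labels") <- NULL
  new("LabelMap", lab, nLabels = as.integer(n))
}

#' Keep the k largest components
#'
#' Retains the \code{k} components of largest pixel area (all of them when
#' fewer exist); with the default \code{k = 2} this selects the two lungs.
#' Area ties are broken toward the smaller label id, which is deterministic
#' because labelling is scan-ordered.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param k number of components to keep (default 2).
#' @return A \linkS4class{BinaryMask}.
#' @export
keepLargestK <- function(labelmap, k = 2) {
  stopifnot(is(labelmap, "LabelMap"), k >= 1)
  v <- labelmap@.Data
  if (labelmap@nLabels == 0L) return(BinaryMask(v))
  areas <- tabulate(v[v > 0L], nbins = labelmap@nLabels)
  keep <- order(-areas, seq_along(areas))[seq_len(min(k, length(areas)))]
  BinaryMask(matrix(as.integer(v %in% keep), nrow(v), ncol(v)))
}

#' Binary erosion
#'
#' A pixel survives iff the structuring-element footprint translated to it
#' lies entirely inside the foreground; out-of-frame positions count as
#' background. Anti-extensive: the output is a subset of the input.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param selem a \linkS4class{StructuringElement}.
#' @return A \linkS4class{BinaryMask}.
#' @export
maskErode <- function(mask, selem) {
  stopifnot(is(mask, "BinaryMask"), is(selem, "StructuringElement"))
  off <- .selemOffsets(selem)
  BinaryMask(cpp_erode(.asIntMat(mask), off$dr, off$dc))
}

#' Binary dilation
#'
#' Minkowski sum: the union of the mask translated by every offset of the
#' structuring element. Extensive: the input is a subset of the output.
#'
#' @inheritParams maskErode
#' @return A \linkS4class{BinaryMask}.
#' @export
maskDilate <- function(mask, selem) {
  stopifnot(is(mask, "BinaryMask"), is(selem, "StructuringElement"))
  off <- .selemOffsets(selem)
  BinaryMask(cpp_dilate(.asIntMat(mask), off$dr, off$dc))
}

#' Binary closing
#'
#' Dilation followed by erosion with the same element; fills concavities
#' and slits narrower than the disk, which is what re-attaches
#' juxtapleural nodules carved out by thresholding. Extensive and
#' idempotent.
#'
#' @inheritParams maskErode
#' @return A \linkS4class{BinaryMask}.
#' @details Dilation and erosion are composed on a canvas padded by the
#'   disk radius, so the dilated shape may extend past the frame before
#'   being eroded back (the infinite-plane set definition, cropped to the
#'   frame); without the padding, closing would not be extensive for
#'   foreground near the border.
#' @export
maskClose <- function(mask, selem) {
  stopifnot(is(mask, "BinaryMask"), is(selem, "StructuringElement"))
  r <- selem@radius
  m <- .asIntMat(mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2L * r, W + 2L * r)
  pad[r + seq_len(H), r + seq_len(W)] <- m
  off <- .selemOffsets(selem)
  closed <- cpp_erode(cpp_dilate(pad, off$dr, off$dc), off$dr, off$dc)
  BinaryMask(closed[r + seq_len(H), r + seq_len(W)])
}

#' Fill enclosed holes
#'
#' Background components not 4-connected to the image border are flipped to
#' foreground; in a lung mask these are vessel shadows and thresholding
#' breaches inside the lung fields. Extensive and idempotent.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return A \linkS4class{BinaryMask}.
#' @export
fillHoles <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- .asIntMat(mask)
  reach <- cpp_background_from_border(m)
  out <- m
  out[!reach & m == 0L] <- 1L
  BinaryMask(out)
}

#' Default parameters of the ground-truth extraction pipeline
#'
#' @return Named list: \code{thresholdHU} (-604), \code{keepK} (2),
#'   \code{erodeRadius} (2), \code{closeRadius} (10), \code{connectivity} (8).
#' @export
maskPipelineParams <- function() {
  list(thresholdHU = -604, keepK = 2, erodeRadius = 2, closeRadius = 10,
       connectivity = 8)
}

#' Extract a lung mask from a CT slice (seven-step pipeline)
#'
#' Sequential composition of the semi-automatic ground-truth extraction:
#' (1) threshold at -604 HU, (2) clear border-connected blobs, (3) label
#' connected components, (4) keep the two largest (the lungs),
#' (5) erode with a disk of radius 2, (6) close with a disk of radius 10
#' (recovers wall-attached nodules), (7) fill enclosed holes (vessels).
#' Deterministic; a slice with no surviving foreground yields an empty
#' mask flagged for manual review rather than an error.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param params parameter list as from \code{\link{maskPipelineParams}}.
#' @return A \linkS4class{BinaryMask} with attribute \code{needsReview}
#'   (TRUE when the mask came out empty).
#' @examples
#' pm <- generatePhantom(PhantomSpec(noiseSD = 0, seed = 3))
#' m <- extractLungMask(pm$slice)
#' diceCoef(m, pm$mask) > 0.95
#' @export
extractLungMask <- function(slice, params = maskPipelineParams()) {
  stopifnot(is(slice, "CTSlice"))
  p <- modifyList(maskPipelineParams(), params)
  m <- binarizeHU(slice, p$thresholdHU)
  m <- clearBorder(m, p$connectivity)
  lab <- labelComponents(m, p$connectivity)
  m <- keepLargestK(lab, p$keepK)
  m <- maskErode(m, diskElement(p$erodeRadius))
  m <- maskClose(m, diskElement(p$closeRadius))
  m <- fillHoles(m)
  empty <- sum(m@.Data) == 0L
  if (empty)
    warning("extracted mask is empty; flagged for manual review")
  attr(m, "needsReview") <- empty
  m
}
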
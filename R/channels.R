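# Engineering of the three network input channels: normalized original,
# Canny edge map, dilated binary image.

#' Binarize a slice for channel engineering (lung = black)
#'
#' Channel-engineering polarity: lung-candidate pixels (HU below the
#' threshold) become 0 (black), everything else 1 (white) — the pixelwise
#' complement of \code{\link{binarizeHU}} at the same threshold.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param thresholdHU threshold in HU (default -604).
#' @return A \linkS4class{BinaryMask} with white = non-lung.
#' @export
binarizeForChannels <- function(slice, thresholdHU = -604) {
  stopifnot(is(slice, "CTSlice"))
  BinaryMask(1L - binarizeHU(slice, thresholdHU)@.Data)
}

#' Dilate the white foreground of the channel binary
#'
#' Grows the white (non-lung) regions, which removes small black noise
#' specks inside the body and tightens the white rim around the lungs; the
#' black lung area can only shrink or stay equal.
#'
#' @param binary a \linkS4class{BinaryMask} from
#'   \code{\link{binarizeForChannels}}.
#' @param selem a \linkS4class{StructuringElement} (default disk r = 2).
#' @return A \linkS4class{BinaryMask}.
#' @export
dilationChannel <- function(binary, selem = diskElement(2)) {
  maskDilate(binary, selem)
}

# separable convolution with edge replication
.convSepReplicate <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  # horizontal pass
  out <- matrix(0, H, W)
  for (d in -r:r) {
    cols <- pmin(pmax(seq_len(W) + d, 1L), W)
    out <- out + k[d + r + 1L] * img[, cols, drop = FALSE]
  }
  img <- out
  out <- matrix(0, H, W)
  for (d in -r:r) {
    rows <- pmin(pmax(seq_len(H) + d, 1L), H)
    out <- out + k[d + r + 1L] * img[rows, , drop = FALSE]
  }
  out
}

.shiftReplicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  m[pmin(pmax(seq_len(H) + dr, 1L), H), pmin(pmax(seq_len(W) + dc, 1L), W)]
}

#' Canny edge detection
#'
#' Standard Canny: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and double-threshold
#' hysteresis (weak edge pixels survive only when 8-connected to a strong
#' one). The smoothing and threshold parameters default to \code{sigma = 2} with
#' hysteresis thresholds at the 70th/90th percentiles of the non-zero
#' gradient magnitudes.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param low,high hysteresis thresholds on gradient magnitude; \code{NULL}
#'   selects the percentile defaults. Must satisfy \code{0 <= low <= high}.
#' @return A \linkS4class{BinaryMask} of edge pixels.
#' @examples
#' flat <- CTSlice(matrix(0, 16, 16))
#' sum(cannyEdges(flat))  # constant image: no edges
#' @export
cannyEdges <- function(slice, sigma = 2, low = NULL, high = NULL) {
  stopifnot(is(slice, "CTSlice"), sigma > 0)
  if (!is.null(low) && !is.null(high) && (low > high || low < 0))
    stop("hysteresis thresholds must satisfy 0 <= low <= high")
  img <- slice@pixels
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  sm <- .convSepReplicate(img, k)

  # Sobel gradients: gx along columns, gy along rows
  gx <- (.shiftReplicate(sm, -1, 1) + 2 * .shiftReplicate(sm, 0, 1) +
           .shiftReplicate(sm, 1, 1)) -
        (.shiftReplicate(sm, -1, -1) + 2 * .shiftReplicate(sm, 0, -1) +
           .shiftReplicate(sm, 1, -1))
  gy <- (.shiftReplicate(sm, 1, -1) + 2 * .shiftReplicate(sm, 1, 0) +
           .shiftReplicate(sm, 1, 1)) -
        (.shiftReplicate(sm, -1, -1) + 2 * .shiftReplicate(sm, -1, 0) +
           .shiftReplicate(sm, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(BinaryMask(matrix(0L, nrow(img), ncol(img))))

  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  n1 <- matrix(0, nrow(img), ncol(img)); n2 <- n1
  b0 <- (ang < 22.5) | (ang >= 157.5)          # horizontal gradient
  b45 <- ang >= 22.5 & ang < 67.5
  b90 <- ang >= 67.5 & ang < 112.5             # vertical gradient
  b135 <- ang >= 112.5 & ang < 157.5
  pick <- function(dr, dc) .shiftReplicate(mag, dr, dc)
  n1[b0] <- pick(0, 1)[b0];    n2[b0] <- pick(0, -1)[b0]
  n1[b45] <- pick(1, 1)[b45];  n2[b45] <- pick(-1, -1)[b45]
  n1[b90] <- pick(1, 0)[b90];  n2[b90] <- pick(-1, 0)[b90]
  n1[b135] <- pick(-1, 1)[b135]; n2[b135] <- pick(1, -1)[b135]
  nms <- mag >= n1 & mag >= n2 & mag > 0

  if (is.null(high)) high <- stats::quantile(mag[mag > 0], 0.90, names = FALSE)
  if (is.null(low)) low <- min(stats::quantile(mag[mag > 0], 0.70, names = FALSE), high)
  if (low > high) stop("hysteresis thresholds must satisfy 0 <= low <= high")
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  BinaryMask(cpp_hysteresis(strong, weak))
}

#' Default channel-engineering parameters
#'
#' @return Named list: HU threshold for the binary channel (-604), the
#'   channel-0 normalization window in HU (\code{c(-1000, 400)}, a standard
#'   lung window), Canny \code{sigma}/\code{low}/\code{high}, and the
#'   dilation radius for channel 3.
#' @export
channelParams <- function() {
  list(thresholdHU = -604, window = c(-1000, 400), sigma = 2,
       low = NULL, high = NULL, dilateRadius = 2)
}

#' Assemble the three engineered input channels
#'
#' Channel 1 is the original image min-max normalized over a clipping
#' window; channel 2 the Canny edge map; channel 3 the dilated binary
#' image. With \code{defaultChannels = TRUE} the original normalized image
#' is replicated into all three channels instead — the default-channel
#' ablation arm, run through the identical downstream pipeline.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param params list as from \code{\link{channelParams}}.
#' @param defaultChannels replicate the original image in all channels.
#' @return A \linkS4class{ThreeChannelImage}.
#' @examples
#' pm <- generatePhantom(PhantomSpec(height = 64, width = 64))
#' x <- assembleChannels(pm$slice)
#' dim(x)
#' @export
assembleChannels <- function(slice, params = channelParams(),
                             defaultChannels = FALSE) {
  stopifnot(is(slice, "CTSlice"))
  p <- modifyList(channelParams(), params)
  w <- p$window
  if (w[2L] <= w[1L]) {
    warning("degenerate normalization window; channel 0 set to uniform 0")
    orig <- matrix(0, nrow(slice@pixels), ncol(slice@pixels))
  } else {
    orig <- (pmin(pmax(slice@pixels, w[1L]), w[2L]) - w[1L]) / (w[2L] - w[1L])
  }
  H <- nrow(orig); W <- ncol(orig)
  if (defaultChannels) {
    ch <- array(c(orig, orig, orig), dim = c(H, W, 3L))
    return(new("ThreeChannelImage", channels = ch, engineered = FALSE))
  }
  edges <- cannyEdges(slice, sigma = p$sigma, low = p$low, high = p$high)
  dil <- dilationChannel(binarizeForChannels(slice, p$thresholdHU),
                         diskElement(p$dilateRadius))
  ch <- array(c(orig, as.numeric(edges@.Data), as.numeric(dil@.Data)),
              dim = c(H, W, 3L))
  new("ThreeChannelImage", channels = ch, engineered = TRUE)
}
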
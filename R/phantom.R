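#' PhantomSpec: parameters of the synthetic lung phantom
#'
#' Describes a 2-D chest phantom: an air background (~ -1000 HU), a
#' soft-tissue body ellipse, two dark lung ellipses well below the -604 HU
#' parenchyma threshold, bright intra-lung vessels, and an optional
#' wall-attached (juxtapleural) nodule whose HU lies above the threshold.
#' The parameter set is valid only if the phantom is separable by thresholding
#' (lung HU < -604 < body and nodule HU) and both lungs stay strictly
#' inside the body ellipse, which stays strictly inside the frame.
#'
#' @slot height,width frame size in pixels.
#' @slot backgroundHU,bodyHU,lungHU,vesselHU,noduleHU tissue attenuations (HU).
#' @slot nVessels number of intra-lung vessel disks.
#' @slot attachNodule whether to place a wall-attached nodule.
#' @slot noduleRadius nodule radius in pixels.
#' @slot noiseSD additive Gaussian noise standard deviation (HU).
#' @slot seed integer seed; equal specs generate bit-identical phantoms.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
                 backgroundHU = "numeric", bodyHU = "numeric",
                 lungHU = "numeric", vesselHU = "numeric",
                 noduleHU = "numeric", nVessels = "integer",
                 attachNodule = "logical", noduleRadius = "numeric",
                 noiseSD = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@height < 32L || object@width < 32L)
    return("frame must be at least 32x32")
  if (!(object@lungHU < -604))
    return("lungHU must be below the -604 HU parenchyma threshold")
  if (!(object@noduleHU > -604))
    return("noduleHU must be above the -604 HU parenchyma threshold")
  if (!(object@bodyHU > -604))
    return("bodyHU must be above the -604 HU parenchyma threshold")
  if (object@noiseSD < 0) return("noiseSD must be non-negative")
  if (object@nVessels < 0L) return("nVessels must be non-negative")
  if (object@noduleRadius <= 0) return("noduleRadius must be positive")
  g <- .phantomGeometry(object@height, object@width)
  if (!g$ok) return(g$why)
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults encode typical chest CT attenuations: air -1000 HU, soft tissue
#' +40 HU, aerated lung -800 HU, blood vessels 0 HU, nodule +20 HU, and
#' 20 HU Gaussian noise (an order of magnitude below the 196 HU gap between
#' lung and the -604 HU threshold).
#'
#' @param height,width frame size in pixels (default 256).
#' @param backgroundHU,bodyHU,lungHU,vesselHU,noduleHU tissue HU values.
#' @param nVessels vessel disks per lung pair (default 6).
#' @param attachNodule place a wall-attached nodule (default FALSE).
#' @param noduleRadius nodule radius in pixels (default 6).
#' @param noiseSD Gaussian HU noise sd (default 20).
#' @param seed integer seed (default 1).
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' spec <- PhantomSpec(noiseSD = 0, nVessels = 0)
#' pm <- generatePhantom(spec)
#' dim(pm$slice)
#' @export
PhantomSpec <- function(height = 256L, width = 256L, backgroundHU = -1000,
                        bodyHU = 40, lungHU = -800, vesselHU = 0,
                        noduleHU = 20, nVessels = 6L, attachNodule = FALSE,
                        noduleRadius = 6, noiseSD = 20, seed = 1L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      backgroundHU = backgroundHU, bodyHU = bodyHU, lungHU = lungHU,
      vesselHU = vesselHU, noduleHU = noduleHU, nVessels = as.integer(nVessels),
      attachNodule = attachNodule, noduleRadius = noduleRadius,
      noiseSD = noiseSD, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec %dx%d lung=%g HU body=%g HU noise sd=%g ",
                     "vessels=%d nodule=%s seed=%d\n"),
              object@height, object@width, object@lungHU, object@bodyHU,
              object@noiseSD, object@nVessels,
              if (object@attachNodule) sprintf("r=%g", object@noduleRadius)
              else "none", object@seed))
})

# Canonical (unjittered) ellipse geometry, all in pixel units.
# Returns centres (row, col) and semi-axes (a = row, b = col) plus a
# validity check that lungs sit strictly inside the body, and the body
# strictly inside the frame with margin.
.phantomGeometry <- function(H, W, jitterShift = c(0, 0, 0, 0),
                             jitterScale = c(1, 1, 1, 1)) {
  body <- list(cr = H / 2, cc = W / 2, a = 0.40 * H, b = 0.44 * W)
  lungL <- list(cr = H / 2 + jitterShift[1L], cc = W / 2 - 0.18 * W + jitterShift[2L],
                a = 0.26 * H * jitterScale[1L], b = 0.15 * W * jitterScale[2L])
  lungR <- list(cr = H / 2 + jitterShift[3L], cc = W / 2 + 0.18 * W + jitterShift[4L],
                a = 0.26 * H * jitterScale[3L], b = 0.15 * W * jitterScale[4L])
  margin <- max(2, round(0.015 * min(H, W)))
  okFrame <- (body$cr - body$a > margin) && (body$cr + body$a < H - margin) &&
    (body$cc - body$b > margin) && (body$cc + body$b < W - margin)
  inside <- function(l) {
    # bounding-box check with a safety gap against the body ellipse
    gap <- 3
    pts <- rbind(c(l$cr - l$a, l$cc), c(l$cr + l$a, l$cc),
                 c(l$cr, l$cc - l$b), c(l$cr, l$cc + l$b))
    all(((pts[, 1L] - body$cr) / (body$a - gap))^2 +
        ((pts[, 2L] - body$cc) / (body$b - gap))^2 < 1)
  }
  ok <- okFrame && inside(lungL) && inside(lungR)
  why <- if (!okFrame) "body ellipse does not fit strictly inside the frame"
         else if (!ok) "lung ellipse not strictly inside the body ellipse"
         else ""
  list(body = body, lungL = lungL, lungR = lungR, ok = ok, why = why)
}

.ellipseMask <- function(H, W, e) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((r - e$cr) / e$a)^2 + ((c - e$cc) / e$b)^2 <= 1
}

.diskMask <- function(H, W, cr, cc, rad) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  (r - cr)^2 + (c - cc)^2 <= rad^2
}

#' Generate a lung phantom with known ground truth
#'
#' Renders the phantom described by \code{spec} and returns both the HU
#' slice and its exact ground-truth lung mask (filled lung ellipses plus
#' the attached-nodule disk; vessel pixels are interior and therefore part
#' of the ground truth). Equal specs give bit-identical output.
#'
#' The nodule, when present, is placed tangent to the lateral lung wall
#' from the inside (a juxtapleural lesion): its HU is above the parenchyma
#' threshold, so naive thresholding carves it out of the lung field and
#' only the closing step of the extraction pipeline can recover it.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param .jitter internal: list of geometry perturbations used by
#'   \code{\link{generateCohort}}.
#' @return List with elements \code{slice} (\linkS4class{CTSlice}),
#'   \code{mask} (\linkS4class{BinaryMask} ground truth) and
#'   \code{nodule} (logical matrix of nodule pixels, all FALSE when
#'   \code{attachNodule} is off).
#' @examples
#' pm <- generatePhantom(PhantomSpec(noiseSD = 0, nVessels = 0, seed = 7))
#' sum(huPixels(pm$slice)[pm$mask == 1] != -800)  # noiseless lung field
#' @export
generatePhantom <- function(spec, .jitter = NULL) {
  validObject(spec)
  H <- spec@height; W <- spec@width
  if (is.null(.jitter)) {
    g <- .phantomGeometry(H, W)
  } else {
    g <- .phantomGeometry(H, W, .jitter$shift, .jitter$scale)
    if (!g$ok) g <- .phantomGeometry(H, W)  # fall back to canonical geometry
  }
  set.seed(spec@seed)
  img <- matrix(spec@backgroundHU, H, W)
  body <- .ellipseMask(H, W, g$body)
  img[body] <- spec@bodyHU
  lungs <- .ellipseMask(H, W, g$lungL) | .ellipseMask(H, W, g$lungR)
  img[lungs] <- spec@lungHU

  # vessels: small bright disks strictly interior to the lung fields
  if (spec@nVessels > 0L) {
    eroded <- .ellipseMask(H, W, modifyList(g$lungL, list(a = g$lungL$a - 4, b = g$lungL$b - 4))) |
      .ellipseMask(H, W, modifyList(g$lungR, list(a = g$lungR$a - 4, b = g$lungR$b - 4)))
    cand <- which(eroded)
    pick <- cand[ceiling(runif(spec@nVessels) * length(cand))]
    for (p in pick) {
      rr <- (p - 1L) %% H + 1L; cc <- (p - 1L) %/% H + 1L
      vr <- 1 + 2 * runif(1)
      v <- .diskMask(H, W, rr, cc, vr) & lungs
      img[v] <- spec@vesselHU
    }
  }

  nodule <- matrix(FALSE, H, W)
  if (spec@attachNodule) {
    # Juxtapleural nodule: centred radius+3 px inside the lateral lung wall,
    # so the disk sits against the wall within the morphological working
    # band (erode radius 2 opens its thresholding bite to the wall, and only
    # the closing step can recover it).
    e <- g$lungR
    theta <- runif(1, -0.5, 0.5)  # angle around the lateral wall
    bx <- e$cc + (e$b) * cos(theta)
    by <- e$cr + (e$a) * sin(theta)
    # unit inward normal of the axis-aligned ellipse at (by, bx)
    nr <- (by - e$cr) / e$a^2; nc <- (bx - e$cc) / e$b^2
    nn <- sqrt(nr^2 + nc^2)
    depth <- spec@noduleRadius + 4
    cr <- by - depth * nr / nn; cc <- bx - depth * nc / nn
    nodule <- .diskMask(H, W, cr, cc, spec@noduleRadius)
    img[nodule] <- spec@noduleHU
  }

  if (spec@noiseSD > 0) img <- img + matrix(rnorm(H * W, 0, spec@noiseSD), H, W)
  img <- pmin(pmax(img, -2000), 4000)

  truth <- lungs | nodule
  list(slice = CTSlice(img, patientID = "phantom",
                       sliceID = sprintf("seed%d", spec@seed),
                       source = "phantom"),
       mask = BinaryMask(truth), nodule = nodule)
}

# Deterministic per-sample seed: identity for the first sample (so a
# degenerate cohort equals generatePhantom(spec)), large prime stride after.
.deriveSeed <- function(seed, idx) {
  as.integer((as.numeric(seed) + (idx - 1) * 100003) %% 2147483647)
}

#' Generate a cohort of jittered phantoms
#'
#' Draws \code{n} phantoms whose lung-ellipse centres/axes and nodule
#' placement are jittered per sample; per-sample seeds are derived
#' deterministically from \code{spec@seed} and the sample index, so cohorts
#' are reproducible and order-independent.
#'
#' @param n number of phantoms (>= 1).
#' @param spec base \linkS4class{PhantomSpec}.
#' @param jitter relative jitter amplitude in [0, 1]; 0 reproduces
#'   \code{generatePhantom(spec)} exactly.
#' @return List of \code{n} phantom lists as from \code{\link{generatePhantom}}.
#' @examples
#' coh <- generateCohort(3, PhantomSpec(height = 64, width = 64), jitter = 0.2)
#' length(coh)
#' @export
generateCohort <- function(n, spec, jitter = 0.2) {
  stopifnot(n >= 1, jitter >= 0, jitter <= 1)
  validObject(spec)
  lapply(seq_len(n), function(i) {
    si <- .deriveSeed(spec@seed, i)
    sp <- spec
    sp@seed <- si
    jit <- NULL
    if (jitter > 0) {
      set.seed(.deriveSeed(si, 2L))
      H <- spec@height
      jit <- list(shift = runif(4, -1, 1) * jitter * 0.04 * H,
                  scale = 1 + runif(4, -1, 1) * jitter * 0.15)
    }
    generatePhantom(sp, .jitter = jit)
  })
}
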
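# Training loop (Adam) and prediction for the segmentation network.

.asInputArray <- function(x) {
  if (is(x, "ThreeChannelImage")) x@channels
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("network input must be a ThreeChannelImage or (H, W, 3) array")
}

.asTargetMatrix <- function(y) {
  if (is(y, "BinaryMask")) {
    m <- y@.Data
    storage.mode(m) <- "double"
    m
  } else if (is.matrix(y)) y
  else stop("target must be a BinaryMask or matrix")
}

# loss value and gradient w.r.t. the pre-sigmoid logits
.lossGrad <- function(prob, truth, loss) {
  n <- length(truth)
  p <- pmin(pmax(prob[, , 1L], 1e-7), 1 - 1e-7)
  out <- list(bce = NA_real_, dice = NA_real_)
  dL_dz <- matrix(0, nrow(truth), ncol(truth))
  if (loss %in% c("bce", "bce_dice")) {
    out$bce <- -mean(truth * log(p) + (1 - truth) * log(1 - p))
    dL_dz <- dL_dz + (p - truth) / n
  }
  if (loss %in% c("dice", "bce_dice")) {
    s <- 1
    num <- 2 * sum(p * truth) + s
    den <- sum(p) + sum(truth) + s
    out$dice <- 1 - num / den
    dL_dp <- -(2 * truth * den - num) / den^2
    dL_dz <- dL_dz + dL_dp * p * (1 - p)
  }
  value <- sum(unlist(out), na.rm = TRUE)
  dlogits <- array(dL_dz, dim = c(nrow(truth), ncol(truth), 1L))
  list(value = value, dlogits = dlogits)
}

#' Train a segmentation model
#'
#' Gradient-based minimization of the configured loss with Adam, fully
#' seeded (initial shuffling order and every stochastic choice derive from
#' \code{tc@seed}). Per-epoch training loss/accuracy and validation
#' loss/accuracy/Dice are recorded. Training aborts with a diagnostic on a
#' non-finite loss. When \code{tc@earlyStopDice} is set, training stops at
#' the first epoch whose validation Dice reaches it.
#'
#' @param model a \linkS4class{SegmentationModel} from \code{\link{buildModel}}.
#' @param trainSet,valSet lists of \code{list(x = , y = )} pairs; \code{x} a
#'   \linkS4class{ThreeChannelImage} (or (H, W, 3) array), \code{y} a
#'   \linkS4class{BinaryMask}. \code{valSet} may be empty.
#' @param tc a \linkS4class{TrainConfig}.
#' @return List with the trained \code{model} and \code{history}, a
#'   data.frame with one row per completed epoch.
#' @export
trainModel <- function(model, trainSet, valSet = list(), tc = trainConfig()) {
  stopifnot(is(model, "SegmentationModel"), is(tc, "TrainConfig"))
  validObject(tc)
  if (length(trainSet) == 0L) stop("training set is empty")
  cfg <- model@config
  xs <- lapply(trainSet, function(s) .asInputArray(s$x))
  ys <- lapply(trainSet, function(s) .asTargetMatrix(s$y))
  hw <- cfg@inputSize
  for (x in xs)
    if (!all(dim(x)[1:2] == hw)) stop("training image size mismatch")

  P <- model@params
  S <- as.environment(model@state)
  mAdam <- lapply(P, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  vAdam <- mAdam
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  step <- 0L
  set.seed(tc@seed)
  n <- length(xs)
  history <- NULL

  for (epoch in seq_len(tc@epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; epochAcc <- 0
    batches <- split(ord, ceiling(seq_along(ord) / tc@batchSize))
    for (batch in batches) {
      G <- new.env(parent = emptyenv())
      bl <- 0
      for (i in batch) {
        fw <- .netForward(P, S, cfg, xs[[i]], training = TRUE, keep = TRUE)
        lg <- .lossGrad(fw$prob, ys[[i]], tc@loss)
        if (!is.finite(lg$value))
          stop(sprintf("non-finite loss (%.3g) at epoch %d; aborting",
                       lg$value, epoch))
        bl <- bl + lg$value
        epochAcc <- epochAcc + mean((fw$prob[, , 1L] >= tc@predThreshold) ==
                                      (ys[[i]] == 1))
        .netBackward(lg$dlogits, fw$K, P, cfg, G)
      }
      epochLoss <- epochLoss + bl
      step <- step + 1L
      scale <- 1 / length(batch)
      b1t <- 1 - beta1^step; b2t <- 1 - beta2^step
      for (nm in names(P)) {
        g <- G[[nm]]
        if (is.null(g)) next
        g <- g * scale
        mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g
        vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g * g
        P[[nm]] <- P[[nm]] - tc@learningRate * (mAdam[[nm]] / b1t) /
          (sqrt(vAdam[[nm]] / b2t) + epsA)
      }
    }
    row <- data.frame(epoch = epoch, trainLoss = epochLoss / n,
                      trainAcc = epochAcc / n, valLoss = NA_real_,
                      valAcc = NA_real_, valDice = NA_real_)
    if (length(valSet)) {
      vl <- 0; va <- 0; vd <- 0
      for (s in valSet) {
        xv <- .asInputArray(s$x); yv <- .asTargetMatrix(s$y)
        fw <- .netForward(P, S, cfg, xv, training = FALSE, keep = FALSE)
        vl <- vl + .lossGrad(fw$prob, yv, tc@loss)$value
        pm <- fw$prob[, , 1L] >= tc@predThreshold
        va <- va + mean(pm == (yv == 1))
        vd <- vd + diceCoef(BinaryMask(pm), BinaryMask(yv == 1))
      }
      row$valLoss <- vl / length(valSet)
      row$valAcc <- va / length(valSet)
      row$valDice <- vd / length(valSet)
    }
    history <- rbind(history, row)
    if (!is.na(tc@earlyStopDice) && !is.na(row$valDice) &&
        row$valDice >= tc@earlyStopDice) break
  }
  out <- model
  out@params <- P
  out@state <- as.list(S)
  list(model = out, history = history)
}

#' Predict a probability map and mask for one image
#'
#' Runs the forward pass in inference mode; the binary mask is
#' \code{probability >= threshold}.
#'
#' @param model a \linkS4class{SegmentationModel}.
#' @param image a \linkS4class{ThreeChannelImage} or (H, W, 3) array of the
#'   configured input size.
#' @param threshold probability cut in (0, 1), default 0.5.
#' @return List with \code{prob} (H x W matrix in (0, 1)) and \code{mask}
#'   (\linkS4class{BinaryMask}).
#' @export
predictModel <- function(model, image, threshold = 0.5) {
  stopifnot(is(model, "SegmentationModel"))
  x <- .asInputArray(image)
  if (!all(dim(x)[1:2] == model@config@inputSize))
    stop("image size does not match the configured input size")
  S <- as.environment(model@state)
  fw <- .netForward(model@params, S, model@config, x,
                    training = FALSE, keep = FALSE)
  prob <- fw$prob[, , 1L]
  list(prob = prob, mask = BinaryMask(prob >= threshold))
}

#' @describeIn predictModel standard \code{predict} method.
#' @param object a \linkS4class{SegmentationModel}.
#' @param ... passed to \code{predictModel} (\code{image}, \code{threshold}).
#' @export
setMethod("predict", "SegmentationModel", function(object, ...) {
  predictModel(object, ...)
})
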
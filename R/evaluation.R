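# Pixel-level evaluation: confusion counts, accuracy/precision/recall/F1,
# Dice overlap, and pooled ROC/AUC. Positive class = lung = 1.

#' Pixelwise confusion counts
#'
#' @param pred,truth \linkS4class{BinaryMask}s of equal dimensions;
#'   positive class is lung (1).
#' @return Named numeric vector \code{c(TP, FP, TN, FN)} summing to the
#'   pixel count.
#' @examples
#' a <- BinaryMask(matrix(1, 3, 3))
#' confusionCounts(a, a)  # TP = 9
#' @export
confusionCounts <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth dimensions differ")
  p <- pred@.Data == 1L; t <- truth@.Data == 1L
  c(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 PR / (P + R). Any 0/0 case yields \code{NA} (an explicit
#' undefined marker), never an error.
#'
#' @param counts named vector as from \code{\link{confusionCounts}}.
#' @return Named numeric vector \code{c(accuracy, precision, recall, f1)}.
#' @examples
#' pixelMetrics(c(TP = 2, FP = 2, TN = 10, FN = 2))
#' @export
pixelMetrics <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  acc <- sdiv(TP + TN, TP + TN + FP + FN)
  pr <- sdiv(TP, TP + FP)
  re <- sdiv(TP, TP + FN)
  f1 <- if (is.na(pr) || is.na(re) || pr + re == 0) NA_real_
        else 2 * pr * re / (pr + re)
  c(accuracy = acc, precision = pr, recall = re, f1 = f1)
}

#' Dice similarity coefficient
#'
#' \code{2 |E intersect Q| / (|E| + |Q|)} over foreground pixels; equals F1
#' for the same positive class. Two empty masks agree perfectly: Dice = 1.
#'
#' @param pred,truth \linkS4class{BinaryMask}s of equal dimensions.
#' @return Dice in [0, 1]; symmetric in its arguments.
#' @examples
#' m <- BinaryMask(matrix(c(1, 1, 0, 0), 2, 2))
#' diceCoef(m, m)
#' @export
diceCoef <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth dimensions differ")
  e <- sum(pred@.Data); q <- sum(truth@.Data)
  if (e + q == 0) return(1)
  2 * sum(pred@.Data * truth@.Data) / (e + q)
}

#' Pooled ROC curve and AUC
#'
#' Pools all pixels of all image pairs, sweeps the true/false positive
#' rates over every distinct probability threshold, and integrates by the
#' trapezoidal rule. A pool containing a single class yields \code{NA}.
#'
#' @param probs list of probability matrices (or a single matrix).
#' @param truths list of \linkS4class{BinaryMask}s (or one mask/matrix).
#' @return List with \code{curve} (data.frame of threshold, fpr, tpr) and
#'   \code{auc}.
#' @examples
#' p <- matrix(c(.9, .8, .7, .4, .3, .2), 2, 3)
#' y <- BinaryMask(matrix(c(1, 1, 0, 1, 0, 0), 2, 3))
#' rocAuc(p, y)$auc  # 8/9
#' @export
rocAuc <- function(probs, truths) {
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(probs) == length(truths))
  sc <- unlist(lapply(probs, as.numeric))
  lab <- unlist(lapply(seq_along(truths), function(i) {
    y <- truths[[i]]
    y <- if (is(y, "BinaryMask")) y@.Data else y
    if (!all(dim(y) == dim(probs[[i]]))) stop("paired dimensions differ")
    as.numeric(y)
  }))
  nP <- sum(lab == 1); nN <- sum(lab == 0)
  if (nP == 0 || nN == 0)
    return(list(curve = NULL, auc = NA_real_))
  o <- order(sc, decreasing = TRUE)
  sc <- sc[o]; lab <- lab[o]
  cumTP <- cumsum(lab == 1)
  cumFP <- cumsum(lab == 0)
  last <- c(diff(sc) != 0, TRUE)  # last index of each distinct score
  tpr <- c(0, cumTP[last] / nP)
  fpr <- c(0, cumFP[last] / nN)
  thr <- c(Inf, sc[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' EvalReport: dataset-level segmentation evaluation
#'
#' @slot TP,FP,TN,FN pooled pixel confusion counts.
#' @slot accuracy,precision,recall,f1,dice,auc metrics in [0, 1]
#'   (NA marks an undefined 0/0 case).
#' @slot nImages number of image pairs evaluated.
#' @export
setClass("EvalReport",
  representation(TP = "numeric", FP = "numeric", TN = "numeric",
                 FN = "numeric", accuracy = "numeric", precision = "numeric",
                 recall = "numeric", f1 = "numeric", dice = "numeric",
                 auc = "numeric", nImages = "integer"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(paste0("EvalReport over %d image(s):\n",
                     "  TP=%g FP=%g TN=%g FN=%g\n",
                     "  accuracy=%.4f precision=%.4f recall=%.4f ",
                     "f1=%.4f dice=%.4f auc=%s\n"),
              object@nImages, object@TP, object@FP, object@TN, object@FN,
              object@accuracy, object@precision, object@recall, object@f1,
              object@dice,
              if (is.na(object@auc)) "NA" else sprintf("%.4f", object@auc)))
})

#' Evaluate predicted masks against ground truth
#'
#' Confusion counts and Dice are pooled over all pixels of all pairs
#' (a single dataset-level confusion matrix); AUC uses the pooled pixels of
#' \code{probs} when given. \code{perImage = TRUE} additionally returns a
#' per-image metric table.
#'
#' @param preds list of predicted \linkS4class{BinaryMask}s.
#' @param truths list of ground-truth \linkS4class{BinaryMask}s.
#' @param probs optional list of probability matrices for ROC/AUC.
#' @param perImage also compute a per-image data.frame.
#' @return An \linkS4class{EvalReport}; with \code{perImage}, a list of the
#'   report and the table.
#' @export
evaluateMasks <- function(preds, truths, probs = NULL, perImage = FALSE) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(preds) == length(truths))
  cc <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  inter <- 0; szE <- 0; szQ <- 0
  tab <- NULL
  for (i in seq_along(preds)) {
    ci <- confusionCounts(preds[[i]], truths[[i]])
    cc <- cc + ci
    inter <- inter + sum(preds[[i]]@.Data * truths[[i]]@.Data)
    szE <- szE + sum(preds[[i]]@.Data); szQ <- szQ + sum(truths[[i]]@.Data)
    if (perImage) {
      mi <- pixelMetrics(ci)
      tab <- rbind(tab, data.frame(image = i, t(mi),
                                   dice = diceCoef(preds[[i]], truths[[i]])))
    }
  }
  m <- pixelMetrics(cc)
  dice <- if (szE + szQ == 0) 1 else 2 * inter / (szE + szQ)
  auc <- if (is.null(probs)) NA_real_ else rocAuc(probs, truths)$auc
  rep <- new("EvalReport", TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]],
             FN = cc[["FN"]], accuracy = m[["accuracy"]],
             precision = m[["precision"]], recall = m[["recall"]],
             f1 = m[["f1"]], dice = dice, auc = auc,
             nImages = length(preds))
  if (perImage) list(report = rep, perImage = tab) else rep
}
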
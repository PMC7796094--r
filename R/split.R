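#' Split identifiers into train/validation/test partitions
#'
#' Identifiers are permuted by a seeded RNG and cut into three groups of
#' sizes \code{round(n * f)} for the validation and test fractions, with
#' the remainder assigned to training. With 1714 identifiers and fractions
#' (0.70, 0.15, 0.15) this yields the 1200/257/257 partition used for the
#' LIDC-derived dataset. Equal \code{(ids, fractions, seed)} reproduce the
#' identical split.
#'
#' @param ids non-empty character (or coercible) identifier vector.
#' @param fractions three non-negative reals summing to 1 (within 1e-9);
#'   default \code{c(0.70, 0.15, 0.15)}.
#' @param seed integer seed.
#' @return A \linkS4class{DatasetSplit}.
#' @examples
#' sp <- splitDataset(sprintf("img%04d", 1:1714), seed = 42)
#' lengths(splitIDs(sp))  # 1200, 257, 257
#' @export
splitDataset <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("id list must be non-empty")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative reals summing to 1")
  n <- length(ids)
  nVal <- round(n * fractions[2L])
  nTest <- round(n * fractions[3L])
  nTrain <- n - nVal - nTest  # remainder goes to training
  set.seed(as.integer(seed))
  perm <- sample(ids, n)
  new("DatasetSplit",
      trainIDs = perm[seq_len(nTrain)],
      valIDs = perm[nTrain + seq_len(nVal)],
      testIDs = perm[nTrain + nVal + seq_len(nTest)],
      seed = as.integer(seed), fractions = as.numeric(fractions))
}
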
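# Res BCDU-Net: U-shaped segmentation network with a ResNet-34 encoder,
# densely connected bottleneck and bidirectional ConvLSTM skip fusion.
# Forward and backward passes are written out explicitly; see the methods
# vignette for the layer plan.

#' NetworkConfig: architecture hyper-parameters
#'
#' @slot inputSize (H, W), both divisible by 32 (the encoder halves the
#'   resolution five times).
#' @slot inChannels number of input channels (3).
#' @slot encoder encoder family; only \code{"resnet34"}.
#' @slot encoderPretrained load externally supplied encoder weights.
#' @slot baseFilters width of the first stage; the reference network is 64.
#' @slot channelSchedule per-stage widths, doubling:
#'   \code{baseFilters * c(1, 2, 4, 8)}.
#' @slot bottleneckBlocks number of bottleneck conv blocks (3).
#' @slot bottleneckDense number of dense (concatenation) connections (2).
#' @slot useBConvLSTM fuse skips with bidirectional ConvLSTM (ablation flag).
#' @slot useDenseBottleneck densely connect the bottleneck (ablation flag).
#' @slot bconvlstmKernel odd ConvLSTM kernel size (3).
#' @slot outActivation output nonlinearity; only \code{"sigmoid"}.
#' @export
setClass("NetworkConfig",
  representation(inputSize = "integer", inChannels = "integer",
                 encoder = "character", encoderPretrained = "logical",
                 baseFilters = "integer", channelSchedule = "integer",
                 bottleneckBlocks = "integer", bottleneckDense = "integer",
                 useBConvLSTM = "logical", useDenseBottleneck = "logical",
                 bconvlstmKernel = "integer", outActivation = "character"))

setValidity("NetworkConfig", function(object) {
  hw <- object@inputSize
  if (length(hw) != 2L || any(hw %% 32L != 0L))
    return("input height and width must be divisible by 32")
  cs <- object@channelSchedule
  if (length(cs) != 4L || !all(cs[-1L] == 2L * cs[-4L]))
    return("channelSchedule must double at each stage")
  if (cs[1L] != object@baseFilters)
    return("channelSchedule must start at baseFilters")
  if (object@inChannels != 3L) return("inChannels must be 3")
  if (object@encoder != "resnet34") return("encoder must be 'resnet34'")
  if (object@bconvlstmKernel %% 2L != 1L || object@bconvlstmKernel < 1L)
    return("bconvlstmKernel must be an odd positive integer")
  if (object@outActivation != "sigmoid") return("outActivation must be 'sigmoid'")
  TRUE
})

#' Construct a NetworkConfig
#'
#' @param inputSize integer (H, W), both divisible by 32; default
#'   \code{c(256, 256)}.
#' @param baseFilters first-stage width (default 64, giving the
#'   64-128-256-512 schedule; smaller values give a proportionally
#'   narrower desk-scale network).
#' @param useBConvLSTM,useDenseBottleneck ablation flags (default TRUE);
#'   when off, skip fusion degrades to plain concatenation and the
#'   bottleneck to plain stacked convolutions.
#' @param encoderPretrained load encoder weights from a file at build time.
#' @param bconvlstmKernel ConvLSTM kernel size (odd, default 3).
#' @return A \linkS4class{NetworkConfig}.
#' @export
networkConfig <- function(inputSize = c(256L, 256L), baseFilters = 64L,
                          useBConvLSTM = TRUE, useDenseBottleneck = TRUE,
                          encoderPretrained = FALSE, bconvlstmKernel = 3L) {
  new("NetworkConfig", inputSize = as.integer(inputSize), inChannels = 3L,
      encoder = "resnet34", encoderPretrained = encoderPretrained,
      baseFilters = as.integer(baseFilters),
      channelSchedule = as.integer(baseFilters * c(1L, 2L, 4L, 8L)),
      bottleneckBlocks = 3L, bottleneckDense = 2L,
      useBConvLSTM = useBConvLSTM, useDenseBottleneck = useDenseBottleneck,
      bconvlstmKernel = as.integer(bconvlstmKernel), outActivation = "sigmoid")
}

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(paste0("NetworkConfig %dx%dx3, resnet34 encoder (%s), ",
                     "schedule %s, BConvLSTM=%s denseBottleneck=%s\n"),
              object@inputSize[1L], object@inputSize[2L],
              if (object@encoderPretrained) "pretrained" else "random init",
              paste(object@channelSchedule, collapse = "-"),
              object@useBConvLSTM, object@useDenseBottleneck))
})

#' TrainConfig: optimisation hyper-parameters
#'
#' @slot epochs,batchSize positive integers (full-scale training uses 50
#'   epochs at batch size 32).
#' @slot loss \code{"bce"}, \code{"dice"} or \code{"bce_dice"}.
#' @slot learningRate Adam step size.
#' @slot seed seed fixing initialization and shuffling.
#' @slot predThreshold probability cut for mask prediction, in (0, 1).
#' @slot earlyStopDice stop once validation Dice reaches this value
#'   (NA disables early stopping).
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer", loss = "character",
                 learningRate = "numeric", seed = "integer",
                 predThreshold = "numeric", earlyStopDice = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L || object@batchSize < 1L)
    return("epochs and batchSize must be positive")
  if (!object@loss %in% c("bce", "dice", "bce_dice"))
    return("loss must be bce, dice or bce_dice")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@predThreshold <= 0 || object@predThreshold >= 1)
    return("predThreshold must be in (0, 1)")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param epochs number of passes over the training set (default 50).
#' @param batchSize gradient-averaging batch size (default 32).
#' @param loss \code{"bce"} (default), \code{"dice"} or \code{"bce_dice"}.
#' @param learningRate Adam step size (default 1e-4).
#' @param seed integer seed (default 1).
#' @param predThreshold probability cut for masks (default 0.5).
#' @param earlyStopDice stop when validation Dice reaches this (default NA).
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 32L, loss = "bce",
                        learningRate = 1e-4, seed = 1L, predThreshold = 0.5,
                        earlyStopDice = NA_real_) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), loss = loss,
      learningRate = learningRate, seed = as.integer(seed),
      predThreshold = predThreshold, earlyStopDice = earlyStopDice)
}

#' SegmentationModel: a trained (or freshly initialized) network
#'
#' @slot config the \linkS4class{NetworkConfig}.
#' @slot params named list of parameter arrays.
#' @slot state named list of normalization running moments.
#' @slot nParameters total scalar parameter count.
#' @slot seed seed used at initialization.
#' @export
setClass("SegmentationModel",
  representation(config = "NetworkConfig", params = "list", state = "list",
                 nParameters = "numeric", seed = "integer"))

setMethod("show", "SegmentationModel", function(object) {
  cat(sprintf("SegmentationModel (%s) %s parameters, input %dx%dx3\n",
              object@config@encoder,
              format(object@nParameters, big.mark = ","),
              object@config@inputSize[1L], object@config@inputSize[2L]))
})

#' Parameter count of a model
#' @param model a \linkS4class{SegmentationModel}.
#' @return Total number of scalar parameters.
#' @export
nParameters <- function(model) {
  stopifnot(is(model, "SegmentationModel"))
  model@nParameters
}

# ---- parameter construction -------------------------------------------------

.mkConvBN <- function(P, S, nm, kh, kw, cin, cout) {
  P[[paste0(nm, ".W")]] <- .heInit(kh, kw, cin, cout)
  P[[paste0(nm, ".b")]] <- numeric(cout)
  P[[paste0(nm, ".gamma")]] <- rep(1, cout)
  P[[paste0(nm, ".beta")]] <- numeric(cout)
  S[[paste0(nm, ".mean")]] <- numeric(cout)
  S[[paste0(nm, ".var")]] <- rep(1, cout)
  list(P = P, S = S)
}

.mkConv <- function(P, nm, kh, kw, cin, cout) {
  P[[paste0(nm, ".W")]] <- .heInit(kh, kw, cin, cout)
  P[[paste0(nm, ".b")]] <- numeric(cout)
  P
}

.mkLSTM <- function(P, nm, k, C) {
  # gate conv maps [x, h] (2C channels) to the (i, f, o, g) gate stack (4C);
  # forget-gate bias starts at 1
  for (dir in c("fw", "bw")) {
    P[[paste0(nm, ".", dir, ".W")]] <- .heInit(k, k, 2L * C, 4L * C)
    b <- numeric(4L * C)
    b[C + seq_len(C)] <- 1
    P[[paste0(nm, ".", dir, ".b")]] <- b
  }
  P
}

.RESNET34_BLOCKS <- c(3L, 4L, 6L, 3L)

.buildParams <- function(cfg) {
  C <- cfg@channelSchedule
  lk <- cfg@bconvlstmKernel
  P <- list(); S <- list()
  add <- function(nm, kh, kw, cin, cout) {
    r <- .mkConvBN(P, S, nm, kh, kw, cin, cout)
    P <<- r$P; S <<- r$S
  }
  add("stem", 7L, 7L, cfg@inChannels, C[1L])
  for (s in 1:4) {
    cin <- if (s == 1L) C[1L] else C[s - 1L]
    for (b in seq_len(.RESNET34_BLOCKS[s])) {
      nm <- sprintf("enc%d.blk%d", s, b)
      bcin <- if (b == 1L) cin else C[s]
      add(paste0(nm, ".c1"), 3L, 3L, bcin, C[s])
      add(paste0(nm, ".c2"), 3L, 3L, C[s], C[s])
      if (b == 1L && s > 1L) add(paste0(nm, ".down"), 1L, 1L, bcin, C[s])
    }
  }
  cin4 <- C[4L]
  for (i in seq_len(cfg@bottleneckBlocks)) {
    bcin <- if (cfg@useDenseBottleneck) (i - 1L) * C[4L] + cin4 else C[4L]
    add(sprintf("bot.b%d", i), 3L, 3L, bcin, C[4L])
  }
  # deepest fusion at equal resolution with the 512-channel tap
  if (cfg@useBConvLSTM) P <- .mkLSTM(P, "fuse0.lstm", lk, C[4L])
  add("fuse0.c1", 3L, 3L, 2L * C[4L], C[4L])
  add("fuse0.c2", 3L, 3L, C[4L], C[4L])
  for (l in 3:1) {
    nm <- sprintf("dec%d", l)
    add(paste0(nm, ".up"), 3L, 3L, C[l + 1L], C[l])
    if (cfg@useBConvLSTM) P <- .mkLSTM(P, paste0(nm, ".lstm"), lk, C[l])
    add(paste0(nm, ".c1"), 3L, 3L, 2L * C[l], C[l])
    add(paste0(nm, ".c2"), 3L, 3L, C[l], C[l])
  }
  # stem-level skip: plain concatenation
  add("decS.up", 3L, 3L, C[1L], C[1L])
  add("decS.c1", 3L, 3L, 2L * C[1L], C[1L])
  add("decS.c2", 3L, 3L, C[1L], C[1L])
  add("head.up", 3L, 3L, C[1L], C[1L])
  P <- .mkConv(P, "head.out", 1L, 1L, C[1L], 1L)
  list(P = P, S = S)
}

#' Build a segmentation model
#'
#' Initializes all parameters (seeded He-normal; normalization scales 1,
#' offsets 0, ConvLSTM forget-gate bias 1). The encoder is the ResNet-34
#' stage plan (3/4/6/3 basic blocks with identity shortcuts, 1x1
#' projection at stage transitions); the bottleneck has 3 convolutional
#' blocks with 2 dense (concatenation) connections; the decoder performs 5
#' up-samplings with BConvLSTM fusion at the four tapped skip levels and
#' plain concatenation at the stem level. Pre-trained encoder weights are
#' load-only: \code{encoderPretrained = TRUE} requires an explicit weight
#' file and never downloads anything.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param seed integer seed for initialization.
#' @param pretrainedWeights path to an RDS file holding a named list of
#'   encoder parameter arrays; required iff \code{config@encoderPretrained}.
#' @return A \linkS4class{SegmentationModel}.
#' @examples
#' m <- buildModel(networkConfig(c(64, 64), baseFilters = 8), seed = 1)
#' nParameters(m) > 0
#' @export
buildModel <- function(config, seed = 1L, pretrainedWeights = NULL) {
  validObject(config)
  if (config@encoderPretrained && is.null(pretrainedWeights))
    stop("encoderPretrained = TRUE requires a pretrainedWeights file; ",
         "weights are never downloaded")
  set.seed(as.integer(seed))
  ps <- .buildParams(config)
  if (!is.null(pretrainedWeights)) {
    w <- readRDS(pretrainedWeights)
    bad <- setdiff(names(w), names(ps$P))
    if (length(bad)) stop("unknown parameter names in weight file: ",
                          paste(head(bad, 3), collapse = ", "))
    for (nm in names(w)) {
      if (!all(dim(ps$P[[nm]]) == dim(w[[nm]]) | is.null(dim(ps$P[[nm]]))))
        stop("shape mismatch for pretrained parameter ", nm)
      ps$P[[nm]] <- w[[nm]]
    }
  }
  new("SegmentationModel", config = config, params = ps$P, state = ps$S,
      nParameters = sum(vapply(ps$P, length, 1L)), seed = as.integer(seed))
}

# ---- composite layers -------------------------------------------------------

# conv + norm + ReLU
.cbrF <- function(x, P, S, nm, stride, training, keep, relu = TRUE) {
  cv <- .convF(x, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]],
               stride = stride, keep = keep)
  bn <- .bnF(cv$y, P[[paste0(nm, ".gamma")]], P[[paste0(nm, ".beta")]],
             training, S[[paste0(nm, ".mean")]], S[[paste0(nm, ".var")]],
             keep = keep)
  if (training) {
    S[[paste0(nm, ".mean")]] <- bn$rmean
    S[[paste0(nm, ".var")]] <- bn$rvar
  }
  if (relu) {
    rl <- .reluF(bn$y, keep)
    list(y = rl$y, cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache))
  } else {
    list(y = bn$y, cache = list(cv = cv$cache, bn = bn$cache, rl = NULL))
  }
}

.cbrB <- function(dy, cache, G, nm) {
  if (!is.null(cache$rl)) dy <- .reluB(dy, cache$rl)
  bb <- .bnB(dy, cache$bn)
  .gAdd(G, paste0(nm, ".gamma"), bb$dgamma)
  .gAdd(G, paste0(nm, ".beta"), bb$dbeta)
  cb <- .convB(bb$dx, cache$cv)
  .gAdd(G, paste0(nm, ".W"), cb$dW)
  .gAdd(G, paste0(nm, ".b"), cb$db)
  cb$dx
}

# ResNet basic block with identity (or projected) shortcut
.resF <- function(x, P, S, nm, stride, down, training, keep) {
  c1 <- .cbrF(x, P, S, paste0(nm, ".c1"), stride, training, keep)
  c2 <- .cbrF(c1$y, P, S, paste0(nm, ".c2"), 1L, training, keep, relu = FALSE)
  if (down) {
    sc <- .cbrF(x, P, S, paste0(nm, ".down"), stride, training, keep,
                relu = FALSE)
    scy <- sc$y; scCache <- sc$cache
  } else {
    scy <- x; scCache <- NULL
  }
  s <- c2$y + scy
  rl <- .reluF(s, keep)
  list(y = rl$y, cache = list(c1 = c1$cache, c2 = c2$cache, sc = scCache,
                              rl = rl$cache, down = down))
}

.resB <- function(dy, cache, G, nm) {
  ds <- .reluB(dy, cache$rl)
  dx2 <- .cbrB(ds, cache$c2, G, paste0(nm, ".c2"))
  dx1 <- .cbrB(dx2, cache$c1, G, paste0(nm, ".c1"))
  dsc <- if (cache$down) .cbrB(ds, cache$sc, G, paste0(nm, ".down")) else ds
  dx1 + dsc
}

# one ConvLSTM direction over the length-2 sequence (x1, x2)
.lstmDirF <- function(x1, x2, Wg, bg, keep = FALSE) {
  C <- dim(x1)[3L]
  z0 <- array(0, dim = dim(x1))
  cv1 <- .convF(.concatC(x1, z0), Wg, bg, 1L, keep = keep)
  g1 <- .lstmGates(cv1$y, C)
  c1 <- g1$i * g1$g
  t1 <- tanh(c1)
  h1 <- g1$o * t1
  cv2 <- .convF(.concatC(x2, h1), Wg, bg, 1L, keep = keep)
  g2 <- .lstmGates(cv2$y, C)
  c2 <- g2$f * c1 + g2$i * g2$g
  t2 <- tanh(c2)
  h2 <- g2$o * t2
  list(h = h2,
       cache = if (keep) list(cv1 = cv1$cache, cv2 = cv2$cache, g1 = g1,
                              g2 = g2, c1 = c1, t1 = t1, t2 = t2, C = C)
               else NULL)
}

.lstmGates <- function(z, C) {
  list(i = .sigmoid(z[, , seq_len(C), drop = FALSE]),
       f = .sigmoid(z[, , C + seq_len(C), drop = FALSE]),
       o = .sigmoid(z[, , 2L * C + seq_len(C), drop = FALSE]),
       g = tanh(z[, , 3L * C + seq_len(C), drop = FALSE]))
}

.lstmDirB <- function(dh2, cache) {
  C <- cache$C
  g1 <- cache$g1; g2 <- cache$g2
  do2 <- dh2 * cache$t2
  dc2 <- dh2 * g2$o * (1 - cache$t2^2)
  di2 <- dc2 * g2$g
  df2 <- dc2 * cache$c1
  dg2 <- dc2 * g2$i
  dc1 <- dc2 * g2$f
  dz2 <- array(c(di2 * g2$i * (1 - g2$i), df2 * g2$f * (1 - g2$f),
                 do2 * g2$o * (1 - g2$o), dg2 * (1 - g2$g^2)),
               dim = c(dim(dh2)[1:2], 4L * C))
  cb2 <- .convB(dz2, cache$cv2)
  sp2 <- .splitC(cb2$dx, C)
  dx2 <- sp2[[1L]]; dh1 <- sp2[[2L]]
  do1 <- dh1 * cache$t1
  dc1 <- dc1 + dh1 * g1$o * (1 - cache$t1^2)
  di1 <- dc1 * g1$g
  dg1 <- dc1 * g1$i
  dz1 <- array(c(di1 * g1$i * (1 - g1$i), array(0, dim = dim(di1)),
                 do1 * g1$o * (1 - g1$o), dg1 * (1 - g1$g^2)),
               dim = c(dim(dh2)[1:2], 4L * C))
  cb1 <- .convB(dz1, cache$cv1)
  dx1 <- .splitC(cb1$dx, C)[[1L]]
  list(dx1 = dx1, dx2 = dx2, dW = cb1$dW + cb2$dW, db = cb1$db + cb2$db)
}

#' Bidirectional ConvLSTM fusion of two same-shape feature maps
#'
#' The encoder and decoder maps form a length-2 sequence. One ConvLSTM
#' (parameter set \code{fw}) processes it as (encoder, decoder), a second
#' independent ConvLSTM (\code{bw}) processes the reversed order; the two
#' final hidden states are concatenated along channels. With zero inputs
#' and zero parameters the output is exactly zero.
#'
#' @param encoderMap,decoderMap (H, W, C) arrays of equal shape.
#' @param weightsFw,weightsBw gate kernels of shape (k, k, 2C, 4C); gate
#'   order along the output channels is input, forget, output, candidate.
#' @param biasFw,biasBw gate biases of length 4C.
#' @return An (H, W, 2C) array: forward then backward hidden state.
#' @examples
#' a <- array(0, c(4, 4, 2)); W0 <- array(0, c(3, 3, 4, 8))
#' range(bconvlstmFuse(a, a, W0, numeric(8), W0, numeric(8)))
#' @export
bconvlstmFuse <- function(encoderMap, decoderMap, weightsFw, biasFw,
                          weightsBw, biasBw) {
  if (!all(dim(encoderMap) == dim(decoderMap)))
    stop("encoder and decoder maps must share spatial size and channels")
  C <- dim(encoderMap)[3L]
  kd <- dim(weightsFw)
  if (kd[3L] != 2L * C || kd[4L] != 4L * C)
    stop("gate kernel must have shape (k, k, 2C, 4C)")
  hf <- .lstmDirF(encoderMap, decoderMap, weightsFw, biasFw)$h
  hb <- .lstmDirF(decoderMap, encoderMap, weightsBw, biasBw)$h
  .concatC(hf, hb)
}

# skip fusion + two conv blocks
.fuseF <- function(skip, d, P, S, nm, useLSTM, training, keep) {
  if (useLSTM) {
    fw <- .lstmDirF(skip, d, P[[paste0(nm, ".lstm.fw.W")]],
                    P[[paste0(nm, ".lstm.fw.b")]], keep = keep)
    bw <- .lstmDirF(d, skip, P[[paste0(nm, ".lstm.bw.W")]],
                    P[[paste0(nm, ".lstm.bw.b")]], keep = keep)
    f <- .concatC(fw$h, bw$h)
    fcache <- list(fw = fw$cache, bw = bw$cache)
  } else {
    f <- .concatC(skip, d)
    fcache <- list(C = dim(skip)[3L])
  }
  c1 <- .cbrF(f, P, S, paste0(nm, ".c1"), 1L, training, keep)
  c2 <- .cbrF(c1$y, P, S, paste0(nm, ".c2"), 1L, training, keep)
  list(y = c2$y, cache = list(f = fcache, c1 = c1$cache, c2 = c2$cache,
                              useLSTM = useLSTM))
}

.fuseB <- function(dy, cache, G, nm) {
  d2 <- .cbrB(dy, cache$c2, G, paste0(nm, ".c2"))
  df <- .cbrB(d2, cache$c1, G, paste0(nm, ".c1"))
  if (cache$useLSTM) {
    C <- dim(df)[3L] %/% 2L
    sp <- .splitC(df, C)
    bf <- .lstmDirB(sp[[1L]], cache$f$fw)
    bb <- .lstmDirB(sp[[2L]], cache$f$bw)
    .gAdd(G, paste0(nm, ".lstm.fw.W"), bf$dW)
    .gAdd(G, paste0(nm, ".lstm.fw.b"), bf$db)
    .gAdd(G, paste0(nm, ".lstm.bw.W"), bb$dW)
    .gAdd(G, paste0(nm, ".lstm.bw.b"), bb$db)
    list(dskip = bf$dx1 + bb$dx2, dd = bf$dx2 + bb$dx1)
  } else {
    sp <- .splitC(df, cache$f$C)
    list(dskip = sp[[1L]], dd = sp[[2L]])
  }
}

# ---- full network -----------------------------------------------------------

.netForward <- function(P, S, cfg, x, training = FALSE, keep = FALSE) {
  K <- list()
  stem <- .cbrF(x, P, S, "stem", 2L, training, keep); K$stem <- stem$cache
  d <- dim(stem$y)
  mp <- cpp_maxpool(stem$y, d[1L], d[2L], d[3L], 3L, 2L, 1L)
  K$mp <- list(argmax = mp$argmax, d = d)
  h <- mp$out
  taps <- list()
  for (s in 1:4) {
    for (b in seq_len(.RESNET34_BLOCKS[s])) {
      nm <- sprintf("enc%d.blk%d", s, b)
      stride <- if (b == 1L && s > 1L) 2L else 1L
      down <- b == 1L && s > 1L
      r <- .resF(h, P, S, nm, stride, down, training, keep)
      K[[nm]] <- r$cache
      h <- r$y
    }
    taps[[s]] <- h
  }
  # bottleneck
  bin <- h
  outs <- list()
  for (i in seq_len(cfg@bottleneckBlocks)) {
    xi <- if (cfg@useDenseBottleneck) {
      Reduce(.concatC, c(list(bin), outs))
    } else {
      if (i == 1L) bin else outs[[i - 1L]]
    }
    bi <- .cbrF(xi, P, S, sprintf("bot.b%d", i), 1L, training, keep)
    K[[sprintf("bot.b%d", i)]] <- bi$cache
    outs[[i]] <- bi$y
  }
  h <- outs[[cfg@bottleneckBlocks]]
  # decoder
  f0 <- .fuseF(taps[[4L]], h, P, S, "fuse0", cfg@useBConvLSTM, training, keep)
  K$fuse0 <- f0$cache
  h <- f0$y
  for (l in 3:1) {
    nm <- sprintf("dec%d", l)
    u <- .upsample2F(h)
    up <- .cbrF(u, P, S, paste0(nm, ".up"), 1L, training, keep)
    K[[paste0(nm, ".up")]] <- up$cache
    fl <- .fuseF(taps[[l]], up$y, P, S, nm, cfg@useBConvLSTM, training, keep)
    K[[nm]] <- fl$cache
    h <- fl$y
  }
  u <- .upsample2F(h)
  upS <- .cbrF(u, P, S, "decS.up", 1L, training, keep); K$decS.up <- upS$cache
  fS <- .fuseF(stem$y, upS$y, P, S, "decS", FALSE, training, keep)
  K$decS <- fS$cache
  u <- .upsample2F(fS$y)
  hu <- .cbrF(u, P, S, "head.up", 1L, training, keep); K$head.up <- hu$cache
  ho <- .convF(hu$y, P[["head.out.W"]], P[["head.out.b"]], 1L, keep = keep)
  K$head.out <- ho$cache
  logits <- ho$y
  prob <- .sigmoid(logits)
  list(prob = prob, logits = logits, K = if (keep) K else NULL, S = S)
}

# dlogits: gradient of the loss w.r.t. the pre-sigmoid output
.netBackward <- function(dlogits, K, P, cfg, G) {
  dh <- .convB(dlogits, K$head.out)
  .gAdd(G, "head.out.W", dh$dW); .gAdd(G, "head.out.b", dh$db)
  dy <- .cbrB(dh$dx, K$head.up, G, "head.up")
  dy <- .upsample2B(dy)
  fS <- .fuseB(dy, K$decS, G, "decS")
  dstem2 <- fS$dskip
  dy <- .cbrB(fS$dd, K$decS.up, G, "decS.up")
  dy <- .upsample2B(dy)
  dtaps <- vector("list", 4L)
  for (l in 1:3) {
    nm <- sprintf("dec%d", l)
    fl <- .fuseB(dy, K[[nm]], G, nm)
    dtaps[[l]] <- fl$dskip
    du <- .cbrB(fl$dd, K[[paste0(nm, ".up")]], G, paste0(nm, ".up"))
    dy <- .upsample2B(du)
  }
  f0 <- .fuseB(dy, K$fuse0, G, "fuse0")
  dtaps[[4L]] <- f0$dskip
  dy <- f0$dd
  # bottleneck (reverse)
  nb <- cfg@bottleneckBlocks
  douts <- vector("list", nb)
  douts[[nb]] <- dy
  dbin <- NULL
  for (i in nb:1) {
    nm <- sprintf("bot.b%d", i)
    dxi <- .cbrB(douts[[i]], K[[nm]], G, nm)
    if (cfg@useDenseBottleneck) {
      # input of block i was concat(bin, out1, ..., out_{i-1})
      Cb <- dim(dxi)[3L] %/% i  # all concat members have C4 channels
      parts <- lapply(seq_len(i), function(j)
        dxi[, , (j - 1L) * Cb + seq_len(Cb), drop = FALSE])
      dbin <- if (is.null(dbin)) parts[[1L]] else dbin + parts[[1L]]
      for (j in seq_len(i - 1L))
        douts[[j]] <- if (is.null(douts[[j]])) parts[[j + 1L]]
                      else douts[[j]] + parts[[j + 1L]]
    } else {
      if (i == 1L) dbin <- if (is.null(dbin)) dxi else dbin + dxi
      else douts[[i - 1L]] <- if (is.null(douts[[i - 1L]])) dxi
                              else douts[[i - 1L]] + dxi
    }
  }
  dy <- dbin + dtaps[[4L]]
  # encoder (reverse)
  for (s in 4:1) {
    if (s < 4L) dy <- dy + dtaps[[s]]
    for (b in rev(seq_len(.RESNET34_BLOCKS[s]))) {
      nm <- sprintf("enc%d.blk%d", s, b)
      dy <- .resB(dy, K[[nm]], G, nm)
    }
  }
  dstem <- cpp_maxpool_bwd(dy, K$mp$argmax, K$mp$d[1L], K$mp$d[2L], K$mp$d[3L])
  dstem <- dstem + dstem2
  invisible(.cbrB(dstem, K$stem, G, "stem"))
}

#' Encoder feature taps
#'
#' Runs the stem and the four ResNet-34 stages in inference mode and
#' returns the four tapped skip feature maps; their channel widths follow
#' the doubling schedule (64, 128, 256, 512 at full width).
#'
#' @param model a \linkS4class{SegmentationModel}.
#' @param image a \linkS4class{ThreeChannelImage} or (H, W, 3) array.
#' @return List of four (H/4..H/32, W/4..W/32, C) arrays, shallowest first.
#' @export
encoderFeatures <- function(model, image) {
  stopifnot(is(model, "SegmentationModel"))
  x <- .asInputArray(image)
  P <- model@params
  S <- as.environment(model@state)
  stem <- .cbrF(x, P, S, "stem", 2L, FALSE, FALSE)
  d <- dim(stem$y)
  h <- cpp_maxpool(stem$y, d[1L], d[2L], d[3L], 3L, 2L, 1L)$out
  taps <- vector("list", 4L)
  for (s in 1:4) {
    for (b in seq_len(.RESNET34_BLOCKS[s])) {
      nm <- sprintf("enc%d.blk%d", s, b)
      stride <- if (b == 1L && s > 1L) 2L else 1L
      h <- .resF(h, P, S, nm, stride, b == 1L && s > 1L, FALSE, FALSE)$y
    }
    taps[[s]] <- h
  }
  taps
}
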
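# Independent brute-force oracles used across the suite. These implement
# the set definitions and recurrences directly (plain R loops), never the
# package's code paths.

randomMask <- function(h, w, p = 0.4) {
  BinaryMask(matrix(rbinom(h * w, 1, p), h, w))
}

diskOffsets <- function(r) {
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off[off$dr^2 + off$dc^2 <= r^2, ]
}

# erosion by set definition: pixel kept iff every offset lands on foreground
oracleErode <- function(m, r) {
  off <- diskOffsets(r)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (m[i, j] == 0) next
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      ni <- i + off$dr[k]; nj <- j + off$dc[k]
      if (ni < 1 || ni > H || nj < 1 || nj > W || m[ni, nj] == 0) {
        ok <- FALSE; break
      }
    }
    if (ok) out[i, j] <- 1L
  }
  out
}

# dilation by set definition: union of translates
oracleDilate <- function(m, r) {
  off <- diskOffsets(r)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (m[i, j] == 0) next
    for (k in seq_len(nrow(off))) {
      ni <- i + off$dr[k]; nj <- j + off$dc[k]
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W) out[ni, nj] <- 1L
    }
  }
  out
}

# closing on the infinite plane, cropped: pad by r before composing
oracleClose <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2 * r, W + 2 * r)
  pad[r + seq_len(H), r + seq_len(W)] <- m
  oracleErode(oracleDilate(pad, r), r)[r + seq_len(H), r + seq_len(W)]
}

neighborOffsets <- function(connectivity) {
  if (connectivity == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
}

# iterative flood fill over a predicate matrix from seed indices
oracleFlood <- function(inset, seeds, connectivity) {
  H <- nrow(inset); W <- ncol(inset)
  reach <- matrix(FALSE, H, W)
  reach[seeds] <- inset[seeds]
  nb <- neighborOffsets(connectivity)
  repeat {
    changed <- FALSE
    idx <- which(reach, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      for (t in seq_len(nrow(nb))) {
        ni <- idx[k, 1] + nb[t, 1]; nj <- idx[k, 2] + nb[t, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            inset[ni, nj] && !reach[ni, nj]) {
          reach[ni, nj] <- TRUE; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  reach
}

borderIndex <- function(H, W) {
  rbind(cbind(1, seq_len(W)), cbind(H, seq_len(W)),
        cbind(seq_len(H), 1), cbind(seq_len(H), W))
}

oracleClearBorder <- function(m, connectivity = 8) {
  reach <- oracleFlood(m == 1, borderIndex(nrow(m), ncol(m)), connectivity)
  out <- m
  out[reach] <- 0L
  out
}

oracleFillHoles <- function(m) {
  reach <- oracleFlood(m == 0, borderIndex(nrow(m), ncol(m)), 4)
  out <- m
  out[m == 0 & !reach] <- 1L
  out
}

# count components by repeated flood fill
oracleComponentCount <- function(m, connectivity) {
  left <- m == 1
  n <- 0L
  while (any(left)) {
    seed <- which(left, arr.ind = TRUE)[1, , drop = FALSE]
    comp <- oracleFlood(left, seed, connectivity)
    left <- left & !comp
    n <- n + 1L
  }
  n
}

# AUC as the Mann-Whitney pairwise concordance statistic
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# ---- ConvLSTM recurrence oracle --------------------------------------------

bind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

# direct same-padded convolution by quadruple loop (small inputs only)
oracleConv <- function(x, W, b) {
  d <- dim(x); kd <- dim(W)
  pad <- (kd[1] - 1) / 2
  out <- array(0, dim = c(d[1], d[2], kd[4]))
  for (co in seq_len(kd[4])) {
    acc <- matrix(b[co], d[1], d[2])
    for (ci in seq_len(d[3])) for (u in seq_len(kd[1])) for (v in seq_len(kd[2])) {
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        ri <- i + u - 1 - pad; cj <- j + v - 1 - pad
        if (ri >= 1 && ri <= d[1] && cj >= 1 && cj <= d[2])
          acc[i, j] <- acc[i, j] + x[ri, cj, ci] * W[u, v, ci, co]
      }
    }
    out[, , co] <- acc
  }
  out
}

# hand-unrolled two-step ConvLSTM direction (gate order i, f, o, g)
oracleLSTMDir <- function(x1, x2, W, b) {
  C <- dim(x1)[3]
  sig <- function(z) 1 / (1 + exp(-z))
  gates <- function(z) list(i = sig(z[, , 1:C, drop = FALSE]),
                            f = sig(z[, , C + 1:C, drop = FALSE]),
                            o = sig(z[, , 2 * C + 1:C, drop = FALSE]),
                            g = tanh(z[, , 3 * C + 1:C, drop = FALSE]))
  g1 <- gates(oracleConv(bind3(x1, array(0, dim(x1))), W, b))
  c1 <- g1$i * g1$g
  h1 <- g1$o * tanh(c1)
  g2 <- gates(oracleConv(bind3(x2, h1), W, b))
  c2 <- g2$f * c1 + g2$i * g2$g
  g2$o * tanh(c2)
}

# small phantom training pairs for network tests
phantomPairs <- function(n, seed, size = 64, jitter = 0.3) {
  spec <- PhantomSpec(height = size, width = size, nVessels = 2,
                      attachNodule = TRUE, noduleRadius = 3, seed = seed)
  coh <- generateCohort(n, spec, jitter = jitter)
  lapply(coh, function(p) list(x = assembleChannels(p$slice), y = p$mask))
}

# canonical scan-order labelling by repeated flood fill
oracleLabel <- function(m, connectivity) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  n <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (m[i, j] == 1 && lab[i, j] == 0L) {
      n <- n + 1L
      comp <- oracleFlood(m == 1, cbind(i, j), connectivity)
      lab[comp] <- n
    }
  }
  lab
}
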
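# Numerical primitives for the segmentation network. Feature maps are
# (H, W, C) arrays; convolutions run as im2col (C++) + BLAS GEMM. Every
# forward op has a matching hand-written backward.

.convF <- function(x, Wt, b, stride = 1L, pad = NULL, keep = FALSE) {
  d <- dim(x); kd <- dim(Wt)
  if (is.null(pad)) pad <- (kd[1L] - 1L) %/% 2L
  cols <- cpp_im2col(x, d[1L], d[2L], d[3L], kd[1L], kd[2L],
                     as.integer(stride), as.integer(pad))
  Wmat <- matrix(Wt, kd[1L] * kd[2L] * kd[3L], kd[4L])
  y <- crossprod(cols, Wmat)
  y <- y + rep(b, each = nrow(y))
  Ho <- (d[1L] + 2L * pad - kd[1L]) %/% stride + 1L
  Wo <- (d[2L] + 2L * pad - kd[2L]) %/% stride + 1L
  dim(y) <- c(Ho, Wo, kd[4L])
  cache <- if (keep) list(cols = cols, dimx = d, kd = kd,
                          stride = as.integer(stride), pad = as.integer(pad),
                          Wmat = Wmat) else NULL
  list(y = y, cache = cache)
}

.convB <- function(dy, cache) {
  kd <- cache$kd
  dyMat <- matrix(dy, ncol = kd[4L])
  dW <- cache$cols %*% dyMat
  dim(dW) <- kd
  db <- colSums(dyMat)
  dcols <- tcrossprod(cache$Wmat, dyMat)
  dx <- cpp_col2im(dcols, cache$dimx[1L], cache$dimx[2L], cache$dimx[3L],
                   kd[1L], kd[2L], cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

# Normalization over the spatial dimensions of each channel (per-sample
# statistics) with running moments for inference.
.bnF <- function(x, gamma, beta, training, rmean, rvar,
                 momentum = 0.9, eps = 1e-5, keep = FALSE) {
  d <- dim(x); N <- d[1L] * d[2L]; C <- d[3L]
  xm <- matrix(x, N, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    rmean2 <- momentum * rmean + (1 - momentum) * mu
    rvar2 <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean; v <- rvar
    rmean2 <- rmean; rvar2 <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = N)) * rep(invstd, each = N)
  y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  dim(y) <- d
  cache <- if (keep) list(xhat = xhat, invstd = invstd, gamma = gamma,
                          d = d) else NULL
  list(y = y, cache = cache, rmean = rmean2, rvar = rvar2)
}

.bnB <- function(dy, cache) {
  d <- cache$d; N <- d[1L] * d[2L]
  dyM <- matrix(dy, N, d[3L])
  dgamma <- colSums(dyM * cache$xhat)
  dbeta <- colSums(dyM)
  dxhat <- dyM * rep(cache$gamma, each = N)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(s1 / N, each = N) -
           cache$xhat * rep(s2 / N, each = N)) * rep(cache$invstd, each = N)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.reluF <- function(x, keep = FALSE) {
  y <- x; y[y < 0] <- 0
  list(y = y, cache = if (keep) (x > 0) else NULL)
}

.reluB <- function(dy, cache) dy * cache

.sigmoid <- function(x) 1 / (1 + exp(-x))

.upsample2F <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , drop = FALSE]
}

.upsample2B <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1L], by = 2L); co <- seq(1L, d[2L], by = 2L)
  dy[ro, co, , drop = FALSE] + dy[ro + 1L, co, , drop = FALSE] +
    dy[ro, co + 1L, , drop = FALSE] + dy[ro + 1L, co + 1L, , drop = FALSE]
}

.concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:2] == db[1:2]))
  array(c(a, b), dim = c(da[1L], da[2L], da[3L] + db[3L]))
}

.splitC <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), drop = FALSE],
       x[, , c1 + seq_len(d[3L] - c1), drop = FALSE])
}

# gradient accumulation into an environment keyed by parameter name
.gAdd <- function(G, name, val) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

# seeded He-normal initialization for a conv kernel (kh, kw, Cin, Cout)
.heInit <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}
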
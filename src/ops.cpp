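#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature maps are R arrays dim (H, W, C), column-major.

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unfold an (H,W,C) array into a (kh*kw*C) x (Ho*Wo) matrix so that a
// convolution becomes a single GEMM.  Out-of-frame taps read as zero.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericMatrix cols(kh * kw * C, Ho * Wo);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int colidx = ho + Ho * wo;
      double *dst = pc + (R_xlen_t)colidx * nrow;
      for (int ch = 0; ch < C; ++ch) {
        const double *plane = px + (R_xlen_t)ch * H * W;
        for (int dw = 0; dw < kw; ++dw) {
          const int c = wo * stride + dw - pad;
          const int base = ch * kh * kw + dw * kh;
          if (c < 0 || c >= W) {
            for (int dh = 0; dh < kh; ++dh) dst[base + dh] = 0.0;
            continue;
          }
          const double *colsrc = plane + (R_xlen_t)c * H;
          for (int dh = 0; dh < kh; ++dh) {
            const int r = ho * stride + dh - pad;
            dst[base + dh] = (r < 0 || r >= H) ? 0.0 : colsrc[r];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add columns back onto an (H,W,C) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericVector x((R_xlen_t)H * W * C);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int nrow = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int colidx = ho + Ho * wo;
      const double *src = pc + (R_xlen_t)colidx * nrow;
      for (int ch = 0; ch < C; ++ch) {
        double *plane = px + (R_xlen_t)ch * H * W;
        for (int dw = 0; dw < kw; ++dw) {
          const int c = wo * stride + dw - pad;
          if (c < 0 || c >= W) continue;
          const int base = ch * kh * kw + dw * kh;
          double *colds = plane + (R_xlen_t)c * H;
          for (int dh = 0; dh < kh; ++dh) {
            const int r = ho * stride + dh - pad;
            if (r >= 0 && r < H) colds[r] += src[base + dh];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Max pooling with argmax bookkeeping (1-based linear indices into the
// input array) so the backward pass is a scatter.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C,
                 int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector out((R_xlen_t)Ho * Wo * C);
  IntegerVector arg((R_xlen_t)Ho * Wo * C);
  const double *px = x.begin();
  for (int ch = 0; ch < C; ++ch) {
    const double *plane = px + (R_xlen_t)ch * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int dw = 0; dw < k; ++dw) {
          const int c = wo * stride + dw - pad;
          if (c < 0 || c >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int r = ho * stride + dh - pad;
            if (r < 0 || r >= H) continue;
            const double v = plane[r + (R_xlen_t)c * H];
            if (v > best) { best = v; besti = r + c * H + ch * H * W; }
          }
        }
        const R_xlen_t oi = ho + (R_xlen_t)Ho * wo + (R_xlen_t)Ho * Wo * ch;
        out[oi] = (besti < 0) ? 0.0 : best;
        arg[oi] = besti + 1;  // 0 marks an all-padding window
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                              int H, int W, int C) {
  NumericVector dx((R_xlen_t)H * W * C);
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    const int a = argmax[i];
    if (a > 0) dx[a - 1] += dy[i];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Connected-component labelling of a 0/1 matrix by breadth-first search.
// Labels are 1..n in order of first encounter in column-major scan.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(r + c * H);
      while (!q.empty()) {
        const int cur = q.front(); q.pop();
        const int cr = cur % H, cc = cur / H;
        for (int t = 0; t < nn; ++t) {
          const int nr = cr + dr8[t], nc = cc + dc8[t];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            q.push(nr + nc * H);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Background pixels reachable from the image border (4-connectivity).
// The complement over background is the set of holes.
// [[Rcpp::export]]
LogicalMatrix cpp_background_from_border(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix reach(H, W);
  std::queue<int> q;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if ((r == 0 || r == H - 1 || c == 0 || c == W - 1) &&
          mask(r, c) == 0 && !reach(r, c)) {
        reach(r, c) = true;
        q.push(r + c * H);
        while (!q.empty()) {
          const int cur = q.front(); q.pop();
          const int cr = cur % H, cc = cur / H;
          for (int t = 0; t < 4; ++t) {
            const int nr = cr + dr[t], nc = cc + dc[t];
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) == 0 && !reach(nr, nc)) {
              reach(nr, nc) = true;
              q.push(nr + nc * H);
            }
          }
        }
      }
    }
  }
  return reach;
}

// Binary erosion: pixel survives iff every footprint offset lands on
// foreground; out-of-frame counts as background.
// [[Rcpp::export]]
IntegerMatrix cpp_erode(IntegerMatrix mask, IntegerVector dr, IntegerVector dc) {
  const int H = mask.nrow(), W = mask.ncol(), K = dr.size();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      bool all = true;
      for (int t = 0; t < K; ++t) {
        const int nr = r + dr[t], nc = c + dc[t];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W || mask(nr, nc) == 0) {
          all = false; break;
        }
      }
      if (all) out(r, c) = 1;
    }
  }
  return out;
}

// Binary dilation: union of the mask translated by every footprint offset.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate(IntegerMatrix mask, IntegerVector dr, IntegerVector dc) {
  const int H = mask.nrow(), W = mask.ncol(), K = dr.size();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      for (int t = 0; t < K; ++t) {
        const int nr = r + dr[t], nc = c + dc[t];
        if (nr >= 0 && nr < H && nc >= 0 && nc < W) out(nr, nc) = 1;
      }
    }
  }
  return out;
}

// Hysteresis: keep weak-edge pixels 8-connected to a strong pixel.
// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(LogicalMatrix strong, LogicalMatrix weak) {
  const int H = strong.nrow(), W = strong.ncol();
  LogicalMatrix keep(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  std::queue<int> q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (strong(r, c)) { keep(r, c) = true; q.push(r + c * H); }
  while (!q.empty()) {
    const int cur = q.front(); q.pop();
    const int cr = cur % H, cc = cur / H;
    for (int t = 0; t < 8; ++t) {
      const int nr = cr + dr8[t], nc = cc + dc8[t];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (weak(nr, nc) && !keep(nr, nc)) {
        keep(nr, nc) = true;
        q.push(nr + nc * H);
      }
    }
  }
  return keep;
}
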
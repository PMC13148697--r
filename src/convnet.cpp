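// Small two-headed convolutional network: batched forward/backward passes.
//
// All convolutions are 3x3, stride 2, zero padding 1 (strided downsampling),
// followed by ReLU; the trunk ends in global average pooling, a ReLU
// embedding layer, and two linear heads (multi-class diagnosis softmax,
// single-logit prognosis sigmoid).  Activations for a whole batch are kept
// as C x (H*W*B) matrices so every convolution is a single GEMM against an
// im2col matrix, and all trunk arithmetic runs in single precision — the
// two together are what make CPU training of the benchmark feasible.  The
// R boundary stays double precision; parameters and gradients are converted
// per call (they are tiny relative to the GEMM work).
//
// Layout convention: within one image, pixel (row i, col j) maps to flat
// index j*H + i (column-major, matching R arrays); image b occupies columns
// [b*H*W, (b+1)*H*W).

#include <RcppArmadillo.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pin the BLAS to one thread so training trajectories are bit-identical
// regardless of the host's core count (summation order in threaded GEMM is
// not deterministic across thread counts). No-op when the loaded BLAS does
// not expose the OpenBLAS entry point.
// [[Rcpp::export]]
bool blas_single_thread_cpp() {
#ifndef _WIN32
  void* self = dlopen(nullptr, RTLD_NOW | RTLD_GLOBAL);
  if (self != nullptr) {
    using setter_t = void (*)(int);
    auto f = reinterpret_cast<setter_t>(dlsym(self, "openblas_set_num_threads"));
    if (f != nullptr) {
      f(1);
      return true;
    }
  }
#endif
  return false;
}

static const float LOG_EPS = 1e-7f;

static arma::fmat as_fmat(SEXP m) {
  return arma::conv_to<arma::fmat>::from(as<arma::mat>(m));
}

static arma::fvec as_fvec(SEXP v) {
  return arma::conv_to<arma::fvec>::from(as<arma::vec>(v));
}

// im2col for a 3x3/stride-2/pad-1 convolution over a batched activation
// matrix.  Output: (9*C) x (Ho*Wo*B); kernel offset k = ky*3+kx contributes
// rows [k*C, (k+1)*C).
static arma::fmat im2col3(const arma::fmat& act, const int H, const int W,
                          const int B, int& Ho, int& Wo) {
  const int C = act.n_rows;
  Ho = (H + 1) / 2;
  Wo = (W + 1) / 2;
  arma::fmat out(9 * C, (arma::uword)Ho * Wo * B, arma::fill::zeros);
  const float* ap = act.memptr();
  float* op = out.memptr();
  const arma::uword arows = C, orows = 9 * (arma::uword)C;
  for (int b = 0; b < B; ++b) {
    const arma::uword ib = (arma::uword)b * H * W;
    const arma::uword ob = (arma::uword)b * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const arma::uword oc = ob + (arma::uword)ox * Ho + oy;
        float* ocol = op + oc * orows;
        for (int kx = 0; kx < 3; ++kx) {
          const int ix = 2 * ox + kx - 1;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = 2 * oy + ky - 1;
            if (iy < 0 || iy >= H) continue;
            const int k = ky * 3 + kx;
            std::memcpy(ocol + (arma::uword)k * C,
                        ap + (ib + (arma::uword)ix * H + iy) * arows,
                        sizeof(float) * C);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back to input pixels.
static arma::fmat col2im3(const arma::fmat& cols, const int C, const int H,
                          const int W, const int B) {
  const int Ho = (H + 1) / 2;
  const int Wo = (W + 1) / 2;
  arma::fmat act(C, (arma::uword)H * W * B, arma::fill::zeros);
  const float* cp = cols.memptr();
  float* ap = act.memptr();
  const arma::uword crows = 9 * (arma::uword)C;
  for (int b = 0; b < B; ++b) {
    const arma::uword ib = (arma::uword)b * H * W;
    const arma::uword ob = (arma::uword)b * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const arma::uword oc = ob + (arma::uword)ox * Ho + oy;
        const float* ccol = cp + oc * crows;
        for (int kx = 0; kx < 3; ++kx) {
          const int ix = 2 * ox + kx - 1;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = 2 * oy + ky - 1;
            if (iy < 0 || iy >= H) continue;
            const int k = ky * 3 + kx;
            float* acol = ap + (ib + (arma::uword)ix * H + iy) * (arma::uword)C;
            const float* s = ccol + (arma::uword)k * C;
            for (int c = 0; c < C; ++c) acol[c] += s[c];
          }
        }
      }
    }
  }
  return act;
}

// One batched pass. x: H x W x B array of pixel intensities; ydiag: 0-based
// grade or NA_INTEGER; yprog: 0/1 or NA_REAL; cw: per-class diagnosis loss
// weights (length = n classes).  Losses are means over the labelled members
// of the batch for each head; gradients match.  When want_grads is FALSE
// only probabilities and losses are returned.
// [[Rcpp::export]]
List cnn_batch_cpp(const arma::cube& x, const List& params,
                   const IntegerVector& ydiag, const NumericVector& yprog,
                   const arma::vec& cw_in, const bool want_grads) {
  const int H0 = x.n_rows, W0 = x.n_cols, B = x.n_slices;
  const List conv_w_in = params["conv_w"];
  const List conv_b_in = params["conv_b"];
  const int L = conv_w_in.size();
  std::vector<arma::fmat> conv_w(L);
  std::vector<arma::fvec> conv_b(L);
  for (int l = 0; l < L; ++l) {
    conv_w[l] = as_fmat(conv_w_in[l]);
    conv_b[l] = as_fvec(conv_b_in[l]);
  }
  const arma::fmat emb_w = as_fmat(params["emb_w"]);
  const arma::fvec emb_b = as_fvec(params["emb_b"]);
  const arma::fmat diag_w = as_fmat(params["diag_w"]);
  const arma::fvec diag_b = as_fvec(params["diag_b"]);
  const arma::fmat prog_w = as_fmat(params["prog_w"]);
  const arma::fvec prog_b = as_fvec(params["prog_b"]);
  const arma::fvec cw = arma::conv_to<arma::fvec>::from(cw_in);
  const int G = diag_w.n_rows;

  // trunk forward
  arma::fmat cur = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(x.memptr()), 1,
                (arma::uword)H0 * W0 * B, false));
  std::vector<arma::fmat> cols(L), zs(L);
  std::vector<int> Hs(L + 1), Ws(L + 1);
  Hs[0] = H0; Ws[0] = W0;
  for (int l = 0; l < L; ++l) {
    int Ho, Wo;
    cols[l] = im2col3(cur, Hs[l], Ws[l], B, Ho, Wo);
    zs[l] = conv_w[l] * cols[l];
    zs[l].each_col() += conv_b[l];
    cur = arma::clamp(zs[l], 0.0f, arma::datum::inf);
    Hs[l + 1] = Ho; Ws[l + 1] = Wo;
  }
  const int Clast = cur.n_rows;
  const arma::uword npix = (arma::uword)Hs[L] * Ws[L];

  arma::fmat g(Clast, B);
  for (int b = 0; b < B; ++b)
    g.col(b) = arma::mean(cur.cols((arma::uword)b * npix,
                                   (arma::uword)(b + 1) * npix - 1), 1);
  arma::fmat ze = emb_w * g;
  ze.each_col() += emb_b;
  arma::fmat e = arma::clamp(ze, 0.0f, arma::datum::inf);

  arma::fmat ld = diag_w * e;  // G x B
  ld.each_col() += diag_b;
  arma::fmat P(G, B);
  for (int b = 0; b < B; ++b) {
    arma::fvec c = ld.col(b);
    c -= c.max();
    arma::fvec ec = arma::exp(c);
    P.col(b) = ec / arma::accu(ec);
  }
  arma::frowvec lp = prog_w * e + prog_b(0);  // 1 x B
  arma::frowvec pp = 1.0f / (1.0f + arma::exp(-lp));

  // losses
  int nd = 0, np = 0;
  double loss_d = 0.0, loss_p = 0.0;
  for (int b = 0; b < B; ++b) {
    if (ydiag[b] != NA_INTEGER) {
      ++nd;
      loss_d += -cw(ydiag[b]) * std::log(std::max(P(ydiag[b], b), LOG_EPS));
    }
    if (!NumericVector::is_na(yprog[b])) {
      ++np;
      const float p = std::min(std::max(pp(b), LOG_EPS), 1.0f - LOG_EPS);
      loss_p += -(yprog[b] * std::log(p) + (1.0 - yprog[b]) * std::log(1.0 - p));
    }
  }
  if (nd > 0) loss_d /= nd;
  if (np > 0) loss_p /= np;

  List out = List::create(
      _["prob_diag"] = wrap(arma::conv_to<arma::mat>::from(P.t())),
      _["prob_prog"] = wrap(arma::conv_to<arma::vec>::from(arma::fvec(pp.t()))),
      _["loss_diag"] = nd > 0 ? loss_d : NA_REAL,
      _["loss_prog"] = np > 0 ? loss_p : NA_REAL,
      _["n_diag"] = nd, _["n_prog"] = np);
  if (!want_grads) return out;

  // head gradients (already averaged over labelled members)
  arma::fmat dld(G, B, arma::fill::zeros);
  arma::frowvec dlp(B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    if (nd > 0 && ydiag[b] != NA_INTEGER) {
      arma::fvec d = P.col(b);
      d(ydiag[b]) -= 1.0f;
      dld.col(b) = cw(ydiag[b]) * d / (float)nd;
    }
    if (np > 0 && !NumericVector::is_na(yprog[b]))
      dlp(b) = (pp(b) - (float)yprog[b]) / (float)np;
  }

  arma::fmat g_diag_w = dld * e.t();
  arma::fvec g_diag_b = arma::sum(dld, 1);
  arma::fmat g_prog_w = dlp * e.t();
  arma::fvec g_prog_b(1);
  g_prog_b(0) = arma::accu(dlp);

  arma::fmat de = diag_w.t() * dld + prog_w.t() * dlp;
  arma::fmat dze = de % (ze > 0);
  arma::fmat g_emb_w = dze * g.t();
  arma::fvec g_emb_b = arma::sum(dze, 1);
  arma::fmat dg = emb_w.t() * dze;  // Clast x B

  arma::fmat dcur(Clast, cur.n_cols);
  for (int b = 0; b < B; ++b)
    dcur.cols((arma::uword)b * npix, (arma::uword)(b + 1) * npix - 1) =
        arma::repmat(dg.col(b) / (float)npix, 1, npix);

  List g_conv_w(L), g_conv_b(L);
  for (int l = L - 1; l >= 0; --l) {
    arma::fmat dz = dcur % (zs[l] > 0);
    g_conv_w[l] = wrap(arma::conv_to<arma::mat>::from(dz * cols[l].t()));
    g_conv_b[l] = wrap(arma::conv_to<arma::vec>::from(arma::fvec(arma::sum(dz, 1))));
    if (l > 0) {
      arma::fmat dcols = conv_w[l].t() * dz;
      dcur = col2im3(dcols, zs[l - 1].n_rows, Hs[l], Ws[l], B);
    }
  }

  out["grads"] = List::create(
      _["conv_w"] = g_conv_w, _["conv_b"] = g_conv_b,
      _["emb_w"] = wrap(arma::conv_to<arma::mat>::from(g_emb_w)),
      _["emb_b"] = wrap(arma::conv_to<arma::vec>::from(g_emb_b)),
      _["diag_w"] = wrap(arma::conv_to<arma::mat>::from(g_diag_w)),
      _["diag_b"] = wrap(arma::conv_to<arma::vec>::from(g_diag_b)),
      _["prog_w"] = wrap(arma::conv_to<arma::mat>::from(g_prog_w)),
      _["prog_b"] = wrap(arma::conv_to<arma::vec>::from(g_prog_b)));
  return out;
}

// Nearest-neighbour affine augmentation (flip, rotation about the centre,
// zoom, translation), one parameter set per image.  Out-of-bounds samples
// are zero.  Deterministic given its arguments; all randomness is drawn on
// the R side.
// [[Rcpp::export]]
arma::cube augment_batch_cpp(const arma::cube& x, const LogicalVector& flip,
                             const NumericVector& angle_deg,
                             const NumericVector& zoom,
                             const NumericVector& dx,
                             const NumericVector& dy) {
  const int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  arma::cube out(H, W, B, arma::fill::zeros);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int b = 0; b < B; ++b) {
    const double th = angle_deg[b] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double z = zoom[b];
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        // inverse map: destination -> source
        double u = (j - cx) / z, v = (i - cy) / z;
        double su = ct * u + st * v + cx + dx[b];
        double sv = -st * u + ct * v + cy + dy[b];
        if (flip[b]) su = (W - 1) - su;
        const int sj = (int)std::lround(su), si = (int)std::lround(sv);
        if (si >= 0 && si < H && sj >= 0 && sj < W) out(i, j, b) = x(si, sj, b);
      }
    }
  }
  return out;
}
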
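// Minimal CNN engine for the growth-stage classifier: five stride-1
// "same"-padded convolutions with ReLU, optional local response
// normalisation after layers 1-2, overlapping max pooling (window 3,
// stride 2) after layers 1, 2 and 5, then FC(1024) -> FC(256) -> softmax
// with inverted dropout on both hidden FC layers.
//
// Templated on the floating type: float for training speed on one CPU,
// double for the numerical gradient-check used in the tests. Weights,
// gradients and Adam state live on the R side in double; this engine keeps
// a working copy, accumulates gradients over a batch, and returns them.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::Mat;
using arma::Col;
using arma::umat;

static const int N_CONV = 5;

template <typename T>
struct Net {
  // architecture
  int H0, W0, C0;
  std::vector<int> ksz, chan;      // length 5
  std::vector<bool> pooled, lrn;   // length 5
  int pool_win, pool_stride;
  int lrn_n;
  T lrn_alpha, lrn_beta, lrn_k;
  std::vector<int> fc;             // hidden fc sizes, length 2
  int n_classes;
  T dropout;

  // derived spatial sizes: inH[i] x inW[i] is the input to conv i,
  // outH[i] x outW[i] its output after optional pooling
  std::vector<int> inH, inW, outH, outW;
  int feat_len;

  // parameters, gradient accumulators and Adam moments
  std::vector<Mat<T>> Wc, gWc, mWc, vWc;   // (k*k*Cin) x Cout
  std::vector<Col<T>> bc, gbc, mbc, vbc;
  std::vector<Mat<T>> Wf, gWf, mWf, vWf;   // 3 fc layers
  std::vector<Col<T>> bf, gbf, mbf, vbf;
  int adam_t = 0;

  // per-forward caches (training mode)
  std::vector<Mat<T>> Xin;         // input of conv i, (H*W) x Cin
  std::vector<Mat<T>> Cols;        // im2col of Xin (training mode)
  std::vector<Mat<T>> A;           // post-conv post-ReLU
  std::vector<Mat<T>> Dlrn;        // LRN denominators
  std::vector<umat> Pidx;          // pooling argmax (input row index)
  Col<T> f_c, a1_c, m1_c, h1_c, a2_c, m2_c, h2_c, probs_c;
  int label_c;

  std::mt19937 rng;

  explicit Net(List cfg) {
    IntegerVector inp = cfg["input"];
    H0 = inp[0]; W0 = inp[1]; C0 = inp[2];
    ksz = as<std::vector<int>>(cfg["kernels"]);
    chan = as<std::vector<int>>(cfg["channels"]);
    IntegerVector pl = cfg["pool_layers"], ll = cfg["lrn_layers"];
    pooled.assign(N_CONV, false);
    lrn.assign(N_CONV, false);
    for (int i = 0; i < pl.size(); ++i) pooled[pl[i] - 1] = true;
    for (int i = 0; i < ll.size(); ++i) lrn[ll[i] - 1] = true;
    pool_win = as<int>(cfg["pool_win"]);
    pool_stride = as<int>(cfg["pool_stride"]);
    lrn_n = as<int>(cfg["lrn_n"]);
    lrn_alpha = (T)as<double>(cfg["lrn_alpha"]);
    lrn_beta = (T)as<double>(cfg["lrn_beta"]);
    lrn_k = (T)as<double>(cfg["lrn_k"]);
    fc = as<std::vector<int>>(cfg["fc_sizes"]);
    n_classes = as<int>(cfg["n_classes"]);
    dropout = (T)as<double>(cfg["dropout"]);

    inH.resize(N_CONV); inW.resize(N_CONV);
    outH.resize(N_CONV); outW.resize(N_CONV);
    int h = H0, w = W0;
    for (int i = 0; i < N_CONV; ++i) {
      inH[i] = h; inW[i] = w;          // "same" conv keeps the size
      if (pooled[i]) {
        if (h < pool_win || w < pool_win)
          stop("spatial size underflow at pooling layer %d (%dx%d < window %d)",
               i + 1, h, w, pool_win);
        h = (h - pool_win) / pool_stride + 1;
        w = (w - pool_win) / pool_stride + 1;
      }
      outH[i] = h; outW[i] = w;
    }
    feat_len = h * w * chan[N_CONV - 1];

    Wc.resize(N_CONV); bc.resize(N_CONV);
    gWc.resize(N_CONV); gbc.resize(N_CONV);
    mWc.resize(N_CONV); vWc.resize(N_CONV);
    mbc.resize(N_CONV); vbc.resize(N_CONV);
    int cin = C0;
    for (int i = 0; i < N_CONV; ++i) {
      Wc[i].zeros(ksz[i] * ksz[i] * cin, chan[i]);
      bc[i].zeros(chan[i]);
      gWc[i].zeros(arma::size(Wc[i]));
      gbc[i].zeros(chan[i]);
      mWc[i].zeros(arma::size(Wc[i])); vWc[i].zeros(arma::size(Wc[i]));
      mbc[i].zeros(chan[i]); vbc[i].zeros(chan[i]);
      cin = chan[i];
    }
    std::vector<int> fdims = {feat_len, fc[0], fc[1], n_classes};
    Wf.resize(3); bf.resize(3); gWf.resize(3); gbf.resize(3);
    mWf.resize(3); vWf.resize(3); mbf.resize(3); vbf.resize(3);
    for (int i = 0; i < 3; ++i) {
      Wf[i].zeros(fdims[i + 1], fdims[i]);
      bf[i].zeros(fdims[i + 1]);
      gWf[i].zeros(arma::size(Wf[i]));
      gbf[i].zeros(fdims[i + 1]);
      mWf[i].zeros(arma::size(Wf[i])); vWf[i].zeros(arma::size(Wf[i]));
      mbf[i].zeros(fdims[i + 1]); vbf[i].zeros(fdims[i + 1]);
    }
    Xin.resize(N_CONV); Cols.resize(N_CONV); A.resize(N_CONV);
    Dlrn.resize(N_CONV); Pidx.resize(N_CONV);
  }

  // ---- primitives ------------------------------------------------------
  // Pixel index p = y + x*H (column-major, matching R arrays).
  // im2col column j = c*k*k + dx*k + dy, offsets dy,dx in 0..k-1 mapping
  // to spatial shifts -(k-1)/2 .. +(k-1)/2.
  static void im2col(const Mat<T>& x, int H, int W, int k, Mat<T>& cols) {
    const int C = x.n_cols, r = (k - 1) / 2;
    cols.zeros(H * W, k * k * C);
    for (int c = 0; c < C; ++c) {
      const T* src = x.colptr(c);
      for (int dx = 0; dx < k; ++dx) {
        const int sx = dx - r;
        for (int dy = 0; dy < k; ++dy) {
          const int sy = dy - r;
          T* dst = cols.colptr(c * k * k + dx * k + dy);
          const int y0 = std::max(0, -sy), y1 = std::min(H - 1, H - 1 - sy);
          const int x0 = std::max(0, -sx), x1 = std::min(W - 1, W - 1 - sx);
          if (y1 < y0) continue;
          const int len = y1 - y0 + 1;
          for (int xx = x0; xx <= x1; ++xx)
            std::memcpy(dst + (y0 + xx * H),
                        src + (y0 + sy + (xx + sx) * H),
                        len * sizeof(T));
        }
      }
    }
  }

  static void col2im(const Mat<T>& cols, int H, int W, int k, int C,
                     Mat<T>& x) {
    const int r = (k - 1) / 2;
    x.zeros(H * W, C);
    for (int c = 0; c < C; ++c) {
      T* dst = x.colptr(c);
      for (int dx = 0; dx < k; ++dx) {
        const int sx = dx - r;
        for (int dy = 0; dy < k; ++dy) {
          const int sy = dy - r;
          const T* src = cols.colptr(c * k * k + dx * k + dy);
          const int y0 = std::max(0, -sy), y1 = std::min(H - 1, H - 1 - sy);
          const int x0 = std::max(0, -sx), x1 = std::min(W - 1, W - 1 - sx);
          if (y1 < y0) continue;
          for (int xx = x0; xx <= x1; ++xx) {
            T* d = dst + (y0 + sy + (xx + sx) * H);
            const T* s = src + (y0 + xx * H);
            for (int i = 0; i <= y1 - y0; ++i) d[i] += s[i];
          }
        }
      }
    }
  }

  // d^(-beta); beta = 0.75 gets a sqrt-only fast path (pow is the
  // dominant scalar cost at feature-map scale)
  Mat<T> pow_nbeta(const Mat<T>& d) const {
    if (lrn_beta == (T)0.75) {
      Mat<T> s1 = arma::sqrt(d);
      return (T)1 / (s1 % arma::sqrt(s1));
    }
    return arma::pow(d, -lrn_beta);
  }

  // band matrix for LRN channel neighbourhoods
  Mat<T> lrn_band(int C) const {
    const int r = (lrn_n - 1) / 2;
    Mat<T> B(C, C, arma::fill::zeros);
    for (int i = 0; i < C; ++i)
      for (int j = std::max(0, i - r); j <= std::min(C - 1, i + r); ++j)
        B(j, i) = (T)1;
    return B;
  }

  void lrn_fwd(const Mat<T>& a, Mat<T>& d, Mat<T>& out) const {
    Mat<T> band = lrn_band(a.n_cols);
    d = lrn_k + (lrn_alpha / (T)lrn_n) * (arma::square(a) * band);
    out = a % pow_nbeta(d);
  }

  Mat<T> lrn_bwd(const Mat<T>& a, const Mat<T>& d, const Mat<T>& db) const {
    Mat<T> band = lrn_band(a.n_cols);
    Mat<T> dnb = pow_nbeta(d);                 // d^-beta
    Mat<T> t = db % a % (dnb / d);             // d^-(beta+1)
    return db % dnb -
           ((T)2 * lrn_alpha * lrn_beta / (T)lrn_n) * (a % (t * band));
  }

  void pool_fwd(const Mat<T>& x, int H, int W, Mat<T>& out, umat& idx) const {
    const int C = x.n_cols;
    const int H2 = (H - pool_win) / pool_stride + 1;
    const int W2 = (W - pool_win) / pool_stride + 1;
    out.set_size(H2 * W2, C);
    idx.set_size(H2 * W2, C);
    for (int c = 0; c < C; ++c) {
      const T* src = x.colptr(c);
      for (int ox = 0; ox < W2; ++ox) {
        for (int oy = 0; oy < H2; ++oy) {
          const int xx0 = ox * pool_stride, yy0 = oy * pool_stride;
          int best = yy0 + xx0 * H;
          T bv = src[best];
          for (int xx = xx0; xx < xx0 + pool_win; ++xx)
            for (int yy = yy0; yy < yy0 + pool_win; ++yy) {
              const int p = yy + xx * H;
              if (src[p] > bv) { bv = src[p]; best = p; }
            }
          out(oy + ox * H2, c) = bv;
          idx(oy + ox * H2, c) = best;
        }
      }
    }
  }

  Mat<T> pool_bwd(const Mat<T>& dout, const umat& idx, int HW) const {
    Mat<T> dx(HW, dout.n_cols, arma::fill::zeros);
    for (arma::uword c = 0; c < dout.n_cols; ++c)
      for (arma::uword i = 0; i < dout.n_rows; ++i)
        dx(idx(i, c), c) += dout(i, c);
    return dx;
  }

  // ---- forward ---------------------------------------------------------
  // Returns class probabilities; caches intermediates when training.
  Col<T> forward(const Mat<T>& x0, bool training, int seed) {
    Mat<T> x = x0, conv, d, pooled_out;
    umat idx;
    for (int i = 0; i < N_CONV; ++i) {
      if (training) Xin[i] = x;
      Mat<T>& cl = Cols[i];          // persistent buffer in both modes
      im2col(x, inH[i], inW[i], ksz[i], cl);
      conv = cl * Wc[i];
      conv.each_row() += bc[i].t();
      conv.transform([](T v) { return v > 0 ? v : (T)0; });  // ReLU
      if (training) A[i] = conv;
      if (lrn[i]) {
        Mat<T> b;
        lrn_fwd(conv, d, b);
        if (training) Dlrn[i] = d;
        conv = b;
      }
      if (pooled[i]) {
        pool_fwd(conv, inH[i], inW[i], pooled_out, idx);
        if (training) Pidx[i] = idx;
        x = pooled_out;
      } else {
        x = conv;
      }
    }
    Col<T> f = arma::vectorise(x);
    Col<T> z1 = Wf[0] * f + bf[0];
    Col<T> a1 = arma::clamp(z1, (T)0, std::numeric_limits<T>::max());
    Col<T> m1, m2;
    const T keep = (T)1 - dropout;
    if (training && dropout > 0) {
      rng.seed((unsigned)seed);
      std::uniform_real_distribution<double> unif(0.0, 1.0);
      m1.set_size(a1.n_elem);
      for (arma::uword i = 0; i < m1.n_elem; ++i)
        m1[i] = unif(rng) < keep ? (T)1 / keep : (T)0;
    } else {
      m1.ones(a1.n_elem);
    }
    Col<T> h1 = a1 % m1;
    Col<T> z2 = Wf[1] * h1 + bf[1];
    Col<T> a2 = arma::clamp(z2, (T)0, std::numeric_limits<T>::max());
    if (training && dropout > 0) {
      std::uniform_real_distribution<double> unif(0.0, 1.0);
      m2.set_size(a2.n_elem);
      for (arma::uword i = 0; i < m2.n_elem; ++i)
        m2[i] = unif(rng) < keep ? (T)1 / keep : (T)0;
    } else {
      m2.ones(a2.n_elem);
    }
    Col<T> h2 = a2 % m2;
    Col<T> z3 = Wf[2] * h2 + bf[2];
    z3 -= z3.max();                       // stable softmax
    Col<T> ez = arma::exp(z3);
    Col<T> probs = ez / arma::accu(ez);
    if (training) {
      f_c = f; a1_c = a1; m1_c = m1; h1_c = h1;
      a2_c = a2; m2_c = m2; h2_c = h2; probs_c = probs;
    }
    return probs;
  }

  // ---- backward (accumulates gradients) --------------------------------
  void backward(int label) {
    Col<T> dz3 = probs_c;
    dz3[label] -= (T)1;
    gWf[2] += dz3 * h2_c.t();
    gbf[2] += dz3;
    Col<T> dh2 = Wf[2].t() * dz3;
    Col<T> dz2 = dh2 % m2_c;
    dz2.elem(arma::find(a2_c <= (T)0)).zeros();
    gWf[1] += dz2 * h1_c.t();
    gbf[1] += dz2;
    Col<T> dh1 = Wf[1].t() * dz2;
    Col<T> dz1 = dh1 % m1_c;
    dz1.elem(arma::find(a1_c <= (T)0)).zeros();
    gWf[0] += dz1 * f_c.t();
    gbf[0] += dz1;
    Col<T> df = Wf[0].t() * dz1;
    Mat<T> dx(df.memptr(), outH[N_CONV - 1] * outW[N_CONV - 1],
              chan[N_CONV - 1]);
    Mat<T> dconv;
    for (int i = N_CONV - 1; i >= 0; --i) {
      if (pooled[i])
        dconv = pool_bwd(dx, Pidx[i], inH[i] * inW[i]);
      else
        dconv = dx;
      if (lrn[i]) dconv = lrn_bwd(A[i], Dlrn[i], dconv);
      {                                               // ReLU mask
        const T* a = A[i].memptr();
        T* g = dconv.memptr();
        const arma::uword n = dconv.n_elem;
        for (arma::uword p = 0; p < n; ++p)
          if (a[p] <= (T)0) g[p] = (T)0;
      }
      gWc[i] += Cols[i].t() * dconv;
      gbc[i] += arma::sum(dconv, 0).t();
      if (i > 0) {
        Mat<T> dcols = dconv * Wc[i].t();
        col2im(dcols, inH[i], inW[i], ksz[i], (int)Xin[i].n_cols, dx);
      }
    }
  }

  double train_step(const Mat<T>& x0, int label, int seed) {
    Col<T> probs = forward(x0, true, seed);
    double loss = -std::log(std::max((double)probs[label], 1e-12));
    label_c = label;
    backward(label);
    return loss;
  }

  // Fused in-place Adam update from the accumulated batch gradients.
  void adam_step(double lr, double b1, double b2, double eps, int batch_n) {
    ++adam_t;
    const double corr =
        std::sqrt(1 - std::pow(b2, adam_t)) / (1 - std::pow(b1, adam_t));
    auto upd = [&](T* w, T* g, T* m, T* v, arma::uword n) {
      const T bn = (T)1 / (T)batch_n;
      const T tb1 = (T)b1, tb2 = (T)b2;
      const T step = (T)(lr * corr), te = (T)eps;
      for (arma::uword i = 0; i < n; ++i) {
        const T gi = g[i] * bn;
        m[i] = tb1 * m[i] + (1 - tb1) * gi;
        v[i] = tb2 * v[i] + (1 - tb2) * gi * gi;
        w[i] -= step * m[i] / (std::sqrt(v[i]) + te);
      }
    };
    for (int i = 0; i < N_CONV; ++i) {
      upd(Wc[i].memptr(), gWc[i].memptr(), mWc[i].memptr(), vWc[i].memptr(),
          Wc[i].n_elem);
      upd(bc[i].memptr(), gbc[i].memptr(), mbc[i].memptr(), vbc[i].memptr(),
          bc[i].n_elem);
    }
    for (int i = 0; i < 3; ++i) {
      upd(Wf[i].memptr(), gWf[i].memptr(), mWf[i].memptr(), vWf[i].memptr(),
          Wf[i].n_elem);
      upd(bf[i].memptr(), gbf[i].memptr(), mbf[i].memptr(), vbf[i].memptr(),
          bf[i].n_elem);
    }
  }

  void zero_grads() {
    for (int i = 0; i < N_CONV; ++i) { gWc[i].zeros(); gbc[i].zeros(); }
    for (int i = 0; i < 3; ++i) { gWf[i].zeros(); gbf[i].zeros(); }
  }
};

// ---- R interface ---------------------------------------------------------

// Accepts integer or double image arrays (0..255) and rescales to 0..1,
// so crops stored as compact integer arrays cross the boundary copy-free.
template <typename T>
static Mat<T> as_pixmat(SEXP img, int H, int W, int C) {
  Mat<T> x(H * W, C);
  const T s = (T)(1.0 / 255.0);
  const int n = H * W * C;
  if (TYPEOF(img) == INTSXP) {
    const int* p = INTEGER(img);
    T* q = x.memptr();
    for (int i = 0; i < n; ++i) q[i] = s * (T)p[i];
  } else {
    const double* p = REAL(img);
    T* q = x.memptr();
    for (int i = 0; i < n; ++i) q[i] = s * (T)p[i];
  }
  return x;
}

template <typename T>
static List weights_out(const Net<T>& net, bool grads) {
  List out;
  char nm[32];
  for (int i = 0; i < N_CONV; ++i) {
    snprintf(nm, sizeof nm, "conv%d_W", i + 1);
    out[nm] = wrap(arma::conv_to<arma::mat>::from(grads ? net.gWc[i] : net.Wc[i]));
    snprintf(nm, sizeof nm, "conv%d_b", i + 1);
    out[nm] = wrap(arma::conv_to<arma::vec>::from(grads ? net.gbc[i] : net.bc[i]));
  }
  const char* fnames[3] = {"fc1", "fc2", "out"};
  for (int i = 0; i < 3; ++i) {
    snprintf(nm, sizeof nm, "%s_W", fnames[i]);
    out[nm] = wrap(arma::conv_to<arma::mat>::from(grads ? net.gWf[i] : net.Wf[i]));
    snprintf(nm, sizeof nm, "%s_b", fnames[i]);
    out[nm] = wrap(arma::conv_to<arma::vec>::from(grads ? net.gbf[i] : net.bf[i]));
  }
  return out;
}

template <typename T>
static void weights_in(Net<T>& net, List w) {
  char nm[32];
  for (int i = 0; i < N_CONV; ++i) {
    snprintf(nm, sizeof nm, "conv%d_W", i + 1);
    net.Wc[i] = arma::conv_to<Mat<T>>::from(as<arma::mat>(w[nm]));
    snprintf(nm, sizeof nm, "conv%d_b", i + 1);
    net.bc[i] = arma::conv_to<Col<T>>::from(as<arma::vec>(w[nm]));
  }
  const char* fnames[3] = {"fc1", "fc2", "out"};
  for (int i = 0; i < 3; ++i) {
    snprintf(nm, sizeof nm, "%s_W", fnames[i]);
    net.Wf[i] = arma::conv_to<Mat<T>>::from(as<arma::mat>(w[nm]));
    snprintf(nm, sizeof nm, "%s_b", fnames[i]);
    net.bf[i] = arma::conv_to<Col<T>>::from(as<arma::vec>(w[nm]));
  }
}

#define DISPATCH(expr_f, expr_d)                         \
  if (precision == "float") {                            \
    XPtr<Net<float>> net(ptr); expr_f;                   \
  } else {                                               \
    XPtr<Net<double>> net(ptr); expr_d;                  \
  }

// [[Rcpp::export]]
SEXP cpp_net_create(List config, std::string precision) {
  if (precision == "float")
    return XPtr<Net<float>>(new Net<float>(config));
  return XPtr<Net<double>>(new Net<double>(config));
}

// [[Rcpp::export]]
void cpp_net_set_weights(SEXP ptr, std::string precision, List w) {
  DISPATCH(weights_in(*net, w), weights_in(*net, w))
}

// [[Rcpp::export]]
List cpp_net_get_weights(SEXP ptr, std::string precision) {
  DISPATCH(return weights_out(*net, false), return weights_out(*net, false))
}

// [[Rcpp::export]]
List cpp_net_get_grads(SEXP ptr, std::string precision) {
  DISPATCH(return weights_out(*net, true), return weights_out(*net, true))
}

// [[Rcpp::export]]
void cpp_net_zero_grads(SEXP ptr, std::string precision) {
  DISPATCH(net->zero_grads(), net->zero_grads())
}

// [[Rcpp::export]]
double cpp_net_train_step(SEXP ptr, std::string precision, SEXP img,
                          IntegerVector dims, int label, int seed) {
  DISPATCH(
    return net->train_step(as_pixmat<float>(img, dims[0], dims[1], dims[2]),
                           label, seed),
    return net->train_step(as_pixmat<double>(img, dims[0], dims[1], dims[2]),
                           label, seed))
}

// [[Rcpp::export]]
NumericVector cpp_net_predict(SEXP ptr, std::string precision,
                              SEXP img, IntegerVector dims) {
  DISPATCH(
    return wrap(arma::conv_to<arma::vec>::from(
        net->forward(as_pixmat<float>(img, dims[0], dims[1], dims[2]),
                     false, 0))),
    return wrap(arma::conv_to<arma::vec>::from(
        net->forward(as_pixmat<double>(img, dims[0], dims[1], dims[2]),
                     false, 0))))
}

// [[Rcpp::export]]
void cpp_net_adam_step(SEXP ptr, std::string precision, double lr,
                       double beta1, double beta2, double eps, int batch_n) {
  DISPATCH(net->adam_step(lr, beta1, beta2, eps, batch_n),
           net->adam_step(lr, beta1, beta2, eps, batch_n))
}

// [[Rcpp::export]]
List cpp_net_dims(SEXP ptr, std::string precision) {
  DISPATCH(
    return List::create(_["feat_len"] = net->feat_len,
                        _["outH"] = wrap(net->outH),
                        _["outW"] = wrap(net->outW)),
    return List::create(_["feat_len"] = net->feat_len,
                        _["outH"] = wrap(net->outH),
                        _["outW"] = wrap(net->outW)))
}
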
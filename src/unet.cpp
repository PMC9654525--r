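// Compact U-net (encoder/decoder with skip connections) for per-pixel
// nucleus classification. Double precision, single threaded, fully
// deterministic for a fixed seed. Convolutions are 3x3 (pad 1) via im2col;
// the head is a 1x1 convolution; training is Adam on softmax cross-entropy
// with an ignore class (label 0).

#include <RcppArmadillo.h>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Subnormal activations/gradients in decayed channels can slow x86 floating
// point by two orders of magnitude; flush them to zero for the numeric core.
struct FlushDenormals {
#if defined(__SSE2__)
  unsigned int ftz, daz;
  FlushDenormals() : ftz(_MM_GET_FLUSH_ZERO_MODE()),
                     daz(_MM_GET_DENORMALS_ZERO_MODE()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};
using arma::cube;
using arma::mat;
using arma::vec;

struct Conv {
  mat W;   // (cout x cin*ksize*ksize)
  vec b;   // cout
  int k;   // kernel size: 3 or 1
};

struct Grad {
  mat dW;
  vec db;
};

// ---- basic ops --------------------------------------------------------------

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(C * 9, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          const double* src = s.colptr(js);
          double* dst = out.memptr() + (size_t)r + (size_t)(j * H) * out.n_rows;
          for (int i = 0; i < H; ++i) {
            const int is = i + dy;
            if (is < 0 || is >= H) continue;
            dst[(size_t)i * out.n_rows] = src[is];
          }
        }
      }
    }
  }
  return out;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& s = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          double* dst = s.colptr(js);
          const double* src = cols.memptr() + (size_t)r +
            (size_t)(j * H) * cols.n_rows;
          for (int i = 0; i < H; ++i) {
            const int is = i + dy;
            if (is < 0 || is >= H) continue;
            dst[is] += src[(size_t)i * cols.n_rows];
          }
        }
      }
    }
  }
  return x;
}

static mat flatten_channels(const cube& x) {
  const int HW = x.n_rows * x.n_cols, C = x.n_slices;
  mat out(C, HW);
  for (int c = 0; c < C; ++c)
    out.row(c) = arma::vectorise(x.slice(c)).t();
  return out;
}

static cube unflatten_channels(const mat& m, int H, int W) {
  cube x(H, W, m.n_rows);
  for (arma::uword c = 0; c < m.n_rows; ++c)
    x.slice(c) = arma::reshape(m.row(c).t(), H, W);
  return x;
}

// forward conv; returns pre-activation cube, stores im2col matrix if tape
static cube conv_forward(const Conv& cv, const cube& x, mat* cols_out) {
  const int H = x.n_rows, W = x.n_cols;
  mat cols = (cv.k == 3) ? im2col3(x) : flatten_channels(x);
  mat y = cv.W * cols;
  y.each_col() += cv.b;
  if (cols_out) *cols_out = std::move(cols);
  return unflatten_channels(y, H, W);
}

// backward conv: given dY (cube), stored cols, input dims -> dX, accumulate grads
static cube conv_backward(const Conv& cv, const mat& cols, const cube& dy,
                          int Hin, int Win, int Cin, Grad& g) {
  mat dY = flatten_channels(dy);
  g.dW += dY * cols.t();
  g.db += arma::sum(dY, 1);
  mat dcols = cv.W.t() * dY;
  if (cv.k == 3) return col2im3(dcols, Hin, Win, Cin);
  return unflatten_channels(dcols, Hin, Win);
}

static void relu_inplace(cube& x) { x.transform([](double v) { return v > 0 ? v : 0.0; }); }

static cube maxpool2(const cube& x, arma::ucube& argmax) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  argmax.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -1e300; int bi = 0;
        for (int d = 0; d < 4; ++d) {
          const int ii = 2 * i + (d & 1), jj = 2 * j + (d >> 1);
          const double v = x(ii, jj, c);
          if (v > best) { best = v; bi = d; }
        }
        y(i, j, c) = best;
        argmax(i, j, c) = bi;
      }
  return y;
}

static cube maxpool2_backward(const cube& dy, const arma::ucube& argmax) {
  const int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube dx(2 * H, 2 * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const int d = argmax(i, j, c);
        dx(2 * i + (d & 1), 2 * j + (d >> 1), c) = dy(i, j, c);
      }
  return dx;
}

static cube upsample2(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

static cube upsample2_backward(const cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
          dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

static cube concat_channels(const cube& a, const cube& b) {
  cube y(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  y.slices(0, a.n_slices - 1) = a;
  y.slices(a.n_slices, y.n_slices - 1) = b;
  return y;
}

// ---- network ----------------------------------------------------------------

struct Net {
  int in_ch, K, base, depth;
  std::vector<Conv> layers;
};

static int n_layers(int depth) { return 5 * depth + 3; }

static Net net_from_list(const List& weights) {
  List meta = weights.attr("meta");
  Net net;
  net.in_ch = as<int>(meta["in_ch"]);
  net.K = as<int>(meta["n_classes"]);
  net.base = as<int>(meta["base"]);
  net.depth = as<int>(meta["depth"]);
  List lw = weights["layers"];
  for (int i = 0; i < lw.size(); ++i) {
    List li = lw[i];
    Conv cv;
    cv.W = as<mat>(li["W"]);
    cv.b = as<vec>(li["b"]);
    cv.k = as<int>(li["k"]);
    net.layers.push_back(cv);
  }
  return net;
}

static List net_to_list(const Net& net) {
  List lw(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i)
    lw[i] = List::create(_["W"] = net.layers[i].W, _["b"] = net.layers[i].b,
                         _["k"] = net.layers[i].k);
  List out = List::create(_["layers"] = lw);
  out.attr("meta") = List::create(_["in_ch"] = net.in_ch,
                                  _["n_classes"] = net.K,
                                  _["base"] = net.base,
                                  _["depth"] = net.depth);
  out.attr("class") = "unet_weights";
  return out;
}

// tape of one forward pass
struct Tape {
  std::vector<mat> cols;        // im2col per conv layer
  std::vector<cube> pre;        // pre-activation outputs per conv layer
  std::vector<arma::uvec> in_dims; // input dims per conv layer (H, W, C)
  std::vector<arma::ucube> pool_argmax;
  std::vector<cube> skips;      // post-activation encoder outputs
  cube logits;
};

static cube net_forward(const Net& net, const cube& x0, Tape* tape) {
  const int D = net.depth;
  cube x = x0;
  int li = 0;
  std::vector<cube> skips;
  Tape dummy;
  Tape& T = tape ? *tape : dummy;
  T.cols.resize(net.layers.size());
  T.pre.resize(net.layers.size());
  T.in_dims.resize(net.layers.size());
  T.pool_argmax.resize(D);

  auto run_conv = [&](cube& inp, bool relu) {
    T.in_dims[li] = arma::uvec({inp.n_rows, inp.n_cols, inp.n_slices});
    cube y = conv_forward(net.layers[li], inp, tape ? &T.cols[li] : nullptr);
    if (tape) T.pre[li] = y;
    if (relu) relu_inplace(y);
    ++li;
    return y;
  };

  for (int l = 0; l < D; ++l) {
    x = run_conv(x, true);
    x = run_conv(x, true);
    skips.push_back(x);
    arma::ucube am;
    x = maxpool2(x, am);
    if (tape) T.pool_argmax[l] = am;
  }
  x = run_conv(x, true);
  x = run_conv(x, true);
  for (int l = D - 1; l >= 0; --l) {
    x = upsample2(x);
    x = run_conv(x, true);
    x = concat_channels(skips[l], x);
    x = run_conv(x, true);
    x = run_conv(x, true);
  }
  cube logits = run_conv(x, false);
  if (tape) { T.skips = skips; T.logits = logits; }
  return logits;
}

static cube softmax_cube(const cube& logits) {
  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  cube p(H, W, K);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double mx = -1e300;
      for (int k = 0; k < K; ++k) mx = std::max(mx, logits(i, j, k));
      double s = 0;
      for (int k = 0; k < K; ++k) { const double e = std::exp(logits(i, j, k) - mx); p(i, j, k) = e; s += e; }
      for (int k = 0; k < K; ++k) p(i, j, k) /= s;
    }
  return p;
}

// cross entropy with ignore label 0; fills dlogits if requested
static double ce_loss(const cube& logits, const arma::imat& labels,
                      cube* dlogits) {
  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  cube p = softmax_cube(logits);
  double loss = 0;
  int n = 0;
  if (dlogits) dlogits->zeros(H, W, K);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int lb = labels(i, j);
      if (lb <= 0 || lb > K) continue;
      loss -= std::log(std::max(p(i, j, lb - 1), 1e-300));
      ++n;
    }
  if (n == 0) return 0.0;
  if (dlogits) {
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const int lb = labels(i, j);
        if (lb <= 0 || lb > K) continue;
        for (int k = 0; k < K; ++k)
          (*dlogits)(i, j, k) = (p(i, j, k) - (k == lb - 1 ? 1.0 : 0.0)) / n;
      }
  }
  return loss / n;
}

static void net_backward(const Net& net, const Tape& T, const cube& dlogits,
                         std::vector<Grad>& grads) {
  const int D = net.depth;
  int li = net.layers.size() - 1;
  auto back_conv = [&](const cube& dy_in, bool relu) {
    cube dy = dy_in;
    if (relu) {
      const cube& pre = T.pre[li];
      for (arma::uword q = 0; q < dy.n_elem; ++q)
        if (pre(q) <= 0) dy(q) = 0;
    }
    const arma::uvec& dmn = T.in_dims[li];
    cube dx = conv_backward(net.layers[li], T.cols[li], dy,
                            dmn(0), dmn(1), dmn(2), grads[li]);
    --li;
    return dx;
  };

  std::vector<cube> skip_grads(D);
  cube dx = back_conv(dlogits, false);  // head
  for (int l = 0; l < D; ++l) {
    dx = back_conv(dx, true);
    dx = back_conv(dx, true);
    // split concat: first slices belong to skip, rest to the upsampled path
    const int cs = T.skips[l].n_slices;
    cube d_skip = dx.slices(0, cs - 1);
    cube d_up = dx.slices(cs, dx.n_slices - 1);
    skip_grads[l] = d_skip;
    dx = back_conv(d_up, true);
    dx = upsample2_backward(dx);
  }
  dx = back_conv(dx, true);
  dx = back_conv(dx, true);
  for (int l = D - 1; l >= 0; --l) {
    dx = maxpool2_backward(dx, T.pool_argmax[l]);
    dx += skip_grads[l];
    dx = back_conv(dx, true);
    dx = back_conv(dx, true);
  }
}

// ---- augmentation -----------------------------------------------------------

static mat rot90mat(const mat& a) { return arma::flipud(a.t()); }

static cube aug_cube(const cube& x, int k, bool flip) {
  std::vector<mat> slices(x.n_slices);
  for (int c = 0; c < (int)x.n_slices; ++c) {
    mat s = x.slice(c);
    for (int r = 0; r < k; ++r) s = rot90mat(s);
    if (flip) s = arma::fliplr(s);
    slices[c] = std::move(s);
  }
  cube y(slices[0].n_rows, slices[0].n_cols, x.n_slices);
  for (int c = 0; c < (int)x.n_slices; ++c) y.slice(c) = slices[c];
  return y;
}

static arma::imat aug_labels(const arma::imat& x, int k, bool flip) {
  arma::imat s = x;
  for (int r = 0; r < k; ++r) s = arma::flipud(s.t());
  if (flip) s = arma::fliplr(s);
  return s;
}

// ---- exported functions -----------------------------------------------------

// [[Rcpp::export]]
List cpp_unet_init(int in_ch, int n_classes, int base, int depth, int seed) {
  std::mt19937 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  Net net; net.in_ch = in_ch; net.K = n_classes; net.base = base; net.depth = depth;
  auto add = [&](int cin, int cout, int k) {
    Conv cv; cv.k = k;
    const int fan = cin * k * k;
    cv.W.set_size(cout, fan);
    const double sdv = std::sqrt(2.0 / fan);
    for (arma::uword q = 0; q < cv.W.n_elem; ++q) cv.W(q) = sdv * nd(rng);
    cv.b = vec(cout, arma::fill::zeros);
    net.layers.push_back(cv);
  };
  int cin = in_ch;
  std::vector<int> ch(depth + 1);
  for (int l = 0; l <= depth; ++l) ch[l] = base << l;
  for (int l = 0; l < depth; ++l) { add(cin, ch[l], 3); add(ch[l], ch[l], 3); cin = ch[l]; }
  add(ch[depth - 1], ch[depth], 3); add(ch[depth], ch[depth], 3);
  for (int l = depth - 1; l >= 0; --l) {
    add(ch[l + 1], ch[l], 3);       // after upsample
    add(2 * ch[l], ch[l], 3);       // after concat
    add(ch[l], ch[l], 3);
  }
  add(base, n_classes, 1);          // head
  return net_to_list(net);
}

// [[Rcpp::export]]
List cpp_unet_train(List weights, List images, List labels,
                    int iterations, double lr, int batch_size,
                    bool augment, int seed, int checkpoint_every,
                    Nullable<List> val_images = R_NilValue,
                    Nullable<List> val_labels = R_NilValue) {
  FlushDenormals ftz_guard;
  Net net = net_from_list(weights);
  const int N = images.size();
  if (N == 0) stop("empty training dataset");
  std::vector<cube> X(N);
  std::vector<arma::imat> Y(N);
  for (int i = 0; i < N; ++i) {
    X[i] = as<cube>(images[i]);
    Y[i] = as<arma::imat>(labels[i]);
  }
  std::vector<cube> Xv; std::vector<arma::imat> Yv;
  if (val_images.isNotNull()) {
    List vi(val_images), vl(val_labels);
    for (int i = 0; i < vi.size(); ++i) {
      Xv.push_back(as<cube>(vi[i]));
      Yv.push_back(as<arma::imat>(vl[i]));
    }
  }
  std::mt19937 rng(seed);
  std::uniform_int_distribution<int> pick(0, N - 1);
  std::uniform_int_distribution<int> rot(0, 3);
  std::uniform_int_distribution<int> coin(0, 1);

  const size_t L = net.layers.size();
  std::vector<mat> mW(L), vW(L);
  std::vector<vec> mb(L), vb(L);
  for (size_t i = 0; i < L; ++i) {
    mW[i].zeros(arma::size(net.layers[i].W)); vW[i] = mW[i];
    mb[i].zeros(net.layers[i].b.n_elem); vb[i] = mb[i];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  NumericVector loss_log(iterations);
  double best_acc = -1.0;
  List best_weights = net_to_list(net);
  int best_iter = 0;

  auto eval_acc = [&](const std::vector<cube>& Xs,
                      const std::vector<arma::imat>& Ys) {
    long ok = 0, tot = 0;
    for (size_t s = 0; s < Xs.size(); ++s) {
      cube logits = net_forward(net, Xs[s], nullptr);
      for (arma::uword j = 0; j < logits.n_cols; ++j)
        for (arma::uword i = 0; i < logits.n_rows; ++i) {
          const int lb = Ys[s](i, j);
          if (lb <= 0) continue;
          int am = 0; double bv = logits(i, j, 0);
          for (int k = 1; k < net.K; ++k)
            if (logits(i, j, k) > bv) { bv = logits(i, j, k); am = k; }
          if (am + 1 == lb) ++ok;
          ++tot;
        }
    }
    return tot ? (double)ok / tot : 0.0;
  };

  for (int it = 0; it < iterations; ++it) {
    std::vector<Grad> grads(L);
    for (size_t i = 0; i < L; ++i) {
      grads[i].dW.zeros(arma::size(net.layers[i].W));
      grads[i].db.zeros(net.layers[i].b.n_elem);
    }
    double lsum = 0;
    const int B = std::min(batch_size, N);
    for (int b = 0; b < B; ++b) {
      const int s = pick(rng);
      cube x = X[s]; arma::imat y = Y[s];
      if (augment) {
        const int k = rot(rng); const bool fl = coin(rng);
        if (k || fl) { x = aug_cube(x, k, fl); y = aug_labels(y, k, fl); }
      }
      Tape tape;
      cube logits = net_forward(net, x, &tape);
      cube dlogits;
      const double l = ce_loss(logits, y, &dlogits);
      if (!std::isfinite(l)) stop("NaN/Inf loss at iteration %d", it + 1);
      lsum += l;
      net_backward(net, tape, dlogits, grads);
    }
    loss_log[it] = lsum / B;
    const double t = it + 1;
    const double corr = std::sqrt(1 - std::pow(b2, t)) / (1 - std::pow(b1, t));
    for (size_t i = 0; i < L; ++i) {
      mat gW = grads[i].dW / B;
      vec gb = grads[i].db / B;
      mW[i] = b1 * mW[i] + (1 - b1) * gW;
      vW[i] = b2 * vW[i] + (1 - b2) * arma::square(gW);
      mb[i] = b1 * mb[i] + (1 - b1) * gb;
      vb[i] = b2 * vb[i] + (1 - b2) * arma::square(gb);
      net.layers[i].W -= lr * corr * mW[i] / (arma::sqrt(vW[i]) + eps);
      net.layers[i].b -= lr * corr * mb[i] / (arma::sqrt(vb[i]) + eps);
    }
    if (checkpoint_every > 0 &&
        ((it + 1) % checkpoint_every == 0 || it + 1 == iterations)) {
      const double acc = Xv.empty() ? eval_acc(X, Y) : eval_acc(Xv, Yv);
      if (acc > best_acc) {
        best_acc = acc; best_weights = net_to_list(net); best_iter = it + 1;
      }
    }
  }
  if (checkpoint_every <= 0) {
    best_weights = net_to_list(net);
    best_acc = eval_acc(X, Y);
    best_iter = iterations;
  }
  return List::create(_["weights"] = best_weights,
                      _["final_weights"] = net_to_list(net),
                      _["loss"] = loss_log,
                      _["best_accuracy"] = best_acc,
                      _["best_iteration"] = best_iter);
}

// [[Rcpp::export]]
NumericVector cpp_unet_predict(List weights, NumericVector image) {
  FlushDenormals ftz_guard;
  Net net = net_from_list(weights);
  IntegerVector dm = image.attr("dim");
  cube x(image.begin(), dm[0], dm[1], dm[2]);
  cube p = softmax_cube(net_forward(net, x, nullptr));
  NumericVector out(p.begin(), p.end());
  out.attr("dim") = IntegerVector::create(p.n_rows, p.n_cols, p.n_slices);
  return out;
}

// [[Rcpp::export]]
double cpp_unet_loss(List weights, NumericVector image, IntegerMatrix labels) {
  FlushDenormals ftz_guard;
  Net net = net_from_list(weights);
  IntegerVector dm = image.attr("dim");
  cube x(image.begin(), dm[0], dm[1], dm[2]);
  arma::imat y(labels.rows(), labels.cols());
  for (int j = 0; j < labels.cols(); ++j)
    for (int i = 0; i < labels.rows(); ++i)
      y(i, j) = labels(i, j);
  cube logits = net_forward(net, x, nullptr);
  return ce_loss(logits, y, nullptr);
}
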
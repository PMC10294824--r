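// Compact VGG-style CNN for spectrogram maps: stacks of 3x3 same-padded
// convolutions with ReLU, 2x2 max pooling, fully-connected layers and a
// softmax head, trained with mini-batch Adam on cross-entropy.
// Layout conventions: images are column-major (H, W, C) cubes; a conv
// layer's weights are a (9*Cin x Cout) matrix acting on im2col rows;
// FC weights are (in x out). All state lives in R lists so models can
// be saved, inspected and re-initialised from the R side.

#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

// The training loop allocates and frees MB-sized im2col buffers for
// every sample; keeping such blocks on the heap freelist (instead of
// round-tripping through mmap and its zero-fill) saves a large share
// of the per-sample cost on glibc systems.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 64 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 64 * 1024 * 1024);
    done = true;
  }
#endif
}

using namespace Rcpp;

struct ConvLayer { arma::mat W; arma::vec b; };
struct FcLayer   { arma::mat W; arma::vec b; };

struct Net {
  std::vector<ConvLayer> conv;
  std::vector<FcLayer> fc;
  std::vector<int> pool_after;   // 1-based conv indices followed by a pool
  int input_size;
};

static Net net_from_r(const List& params, const List& arch) {
  Net net;
  List convs = params["conv"], fcs = params["fc"];
  for (int i = 0; i < convs.size(); ++i) {
    List li = convs[i];
    net.conv.push_back({as<arma::mat>(li["W"]), as<arma::vec>(li["b"])});
  }
  for (int i = 0; i < fcs.size(); ++i) {
    List li = fcs[i];
    net.fc.push_back({as<arma::mat>(li["W"]), as<arma::vec>(li["b"])});
  }
  IntegerVector pa = arch["pool_after"];
  net.pool_after = std::vector<int>(pa.begin(), pa.end());
  net.input_size = as<int>(arch["input_size"]);
  return net;
}

static List net_to_r(const Net& net) {
  List convs(net.conv.size()), fcs(net.fc.size());
  for (size_t i = 0; i < net.conv.size(); ++i)
    convs[i] = List::create(
      _["W"] = net.conv[i].W,
      _["b"] = NumericVector(net.conv[i].b.begin(), net.conv[i].b.end()));
  for (size_t i = 0; i < net.fc.size(); ++i)
    fcs[i] = List::create(
      _["W"] = net.fc[i].W,
      _["b"] = NumericVector(net.fc[i].b.begin(), net.fc[i].b.end()));
  return List::create(_["conv"] = convs, _["fc"] = fcs);
}

// 3x3 im2col with zero padding 1: (H*W) x (9*C); columns written in
// place, one contiguous image-column stripe at a time
static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * (size_t)W, 9 * (size_t)C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice(c).memptr();
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int col = c * 9 + (ky + 1) * 3 + (kx + 1);
        const int r0 = std::max(0, -ky), r1 = std::min(H, H - ky);
        double* o = out.colptr(col);
        for (int j = 0; j < W; ++j) {
          double* oj = o + (size_t)j * H;
          const int js = j + kx;
          if (js < 0 || js >= W) {
            std::fill(oj, oj + H, 0.0);
            continue;
          }
          const double* sj = xs + (size_t)js * H + ky;
          if (r0 > 0) std::fill(oj, oj + r0, 0.0);
          std::copy(sj + r0, sj + r1, oj + r0);
          if (r1 < H) std::fill(oj + r1, oj + H, 0.0);
        }
      }
    }
  }
  return out;
}

// adjoint of im2col3: scatter column gradients back onto the image
static void col2im3(const arma::mat& dcols, arma::cube& dx) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    double* xs = dx.slice(c).memptr();
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int col = c * 9 + (ky + 1) * 3 + (kx + 1);
        const int r0 = std::max(0, -ky), r1 = std::min(H, H - ky);
        const double* o = dcols.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int js = j + kx;
          if (js < 0 || js >= W) continue;
          const double* oj = o + (size_t)j * H;
          double* sj = xs + (size_t)js * H + ky;
          for (int i = r0; i < r1; ++i) sj[i] += oj[i];
        }
      }
    }
  }
}

static arma::cube maxpool2(const arma::cube& x, arma::uvec& argmax) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  argmax.set_size((size_t)Ho * Wo * C);
  size_t t = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i, ++t) {
        double best = -arma::datum::inf;
        size_t bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bidx = (size_t)ii + (size_t)jj * H + (size_t)c * H * W;
            }
          }
        out(i, j, c) = best;
        argmax(t) = bidx;
      }
  return out;
}

struct SampleCache {
  std::vector<arma::mat> cols;      // im2col input per conv layer
  std::vector<arma::mat> relu_out;  // post-ReLU conv output (HW x C)
  std::vector<bool> pooled;         // pool applied after conv i?
  std::vector<arma::uvec> pool_idx;
  std::vector<int> in_h;            // spatial size entering conv i
  std::vector<arma::vec> fc_in;     // input to fc layer j
  std::vector<arma::vec> fc_act;    // post-activation fc output
};

static arma::vec softmax(const arma::vec& z) {
  arma::vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

static arma::vec forward_sample(const Net& net, const arma::mat& img,
                                SampleCache* cache) {
  arma::cube x(img.n_rows, img.n_cols, 1);
  x.slice(0) = img;
  int hw = net.input_size;
  for (size_t i = 0; i < net.conv.size(); ++i) {
    arma::mat cols = im2col3(x);
    arma::mat pre = cols * net.conv[i].W;
    pre.each_row() += net.conv[i].b.t();
    pre.transform([](double v) { return v > 0 ? v : 0.0; });
    const int cout = net.conv[i].W.n_cols;
    arma::cube out(pre.memptr(), hw, hw, cout);
    bool pool = std::find(net.pool_after.begin(), net.pool_after.end(),
                          (int)i + 1) != net.pool_after.end();
    arma::uvec pidx;
    if (cache) {
      cache->cols.push_back(std::move(cols));
      cache->relu_out.push_back(pre);
      cache->in_h.push_back(hw);
      cache->pooled.push_back(pool);
    }
    if (pool) {
      out = maxpool2(out, pidx);
      hw /= 2;
    }
    if (cache) cache->pool_idx.push_back(pidx);
    x = std::move(out);
  }
  arma::vec v = arma::vectorise(x);
  for (size_t j = 0; j < net.fc.size(); ++j) {
    if (cache) cache->fc_in.push_back(v);
    arma::vec z = net.fc[j].W.t() * v + net.fc[j].b;
    if (j + 1 < net.fc.size())
      z.transform([](double a) { return a > 0 ? a : 0.0; });
    if (cache) cache->fc_act.push_back(z);
    v = std::move(z);
  }
  return softmax(v);
}

struct Grads {
  std::vector<arma::mat> convW;
  std::vector<arma::vec> convb;
  std::vector<arma::mat> fcW;
  std::vector<arma::vec> fcb;
  void init(const Net& net) {
    for (auto& l : net.conv) {
      convW.push_back(arma::mat(l.W.n_rows, l.W.n_cols, arma::fill::zeros));
      convb.push_back(arma::vec(l.b.n_elem, arma::fill::zeros));
    }
    for (auto& l : net.fc) {
      fcW.push_back(arma::mat(l.W.n_rows, l.W.n_cols, arma::fill::zeros));
      fcb.push_back(arma::vec(l.b.n_elem, arma::fill::zeros));
    }
  }
  void zero() {
    for (auto& g : convW) g.zeros();
    for (auto& g : convb) g.zeros();
    for (auto& g : fcW) g.zeros();
    for (auto& g : fcb) g.zeros();
  }
};

// accumulate gradients for one sample; returns its loss
static double backward_sample(const Net& net, const arma::mat& img, int y,
                              Grads& g, int& correct) {
  SampleCache cache;
  arma::vec p = forward_sample(net, img, &cache);
  if ((int)p.index_max() == y) ++correct;
  const double loss = -std::log(std::max(p(y), 1e-300));

  arma::vec dz = p;
  dz(y) -= 1.0;
  for (int j = (int)net.fc.size() - 1; j >= 0; --j) {
    g.fcW[j] += cache.fc_in[j] * dz.t();
    g.fcb[j] += dz;
    arma::vec dv = net.fc[j].W * dz;
    if (j > 0) {
      dv %= arma::conv_to<arma::vec>::from(cache.fc_act[j - 1] > 0);
      dz = std::move(dv);
    } else {
      // gradient w.r.t. the flattened last conv output
      dz = std::move(dv);
    }
  }

  for (int i = (int)net.conv.size() - 1; i >= 0; --i) {
    const int hw = cache.in_h[i];
    const int cout = net.conv[i].W.n_cols;
    arma::mat dout;
    if (cache.pooled[i]) {
      const int ho = hw / 2;
      arma::vec dflat((size_t)hw * hw * cout, arma::fill::zeros);
      const arma::uvec& idx = cache.pool_idx[i];
      for (size_t t = 0; t < idx.n_elem; ++t) dflat(idx(t)) += dz(t);
      dout = arma::mat(dflat.memptr(), (size_t)hw * hw, cout);
      (void)ho;
    } else {
      dout = arma::mat(dz.memptr(), (size_t)hw * hw, cout);
    }
    arma::mat dpre = std::move(dout);
    {
      const arma::mat& ro = cache.relu_out[i];
      double* d = dpre.memptr();
      const double* r = ro.memptr();
      const size_t n_el = ro.n_elem;
      for (size_t t = 0; t < n_el; ++t)
        if (r[t] <= 0) d[t] = 0.0;
    }
    g.convW[i] += cache.cols[i].t() * dpre;
    g.convb[i] += arma::sum(dpre, 0).t();
    if (i > 0) {
      arma::mat dcols = dpre * net.conv[i].W.t();
      const int cin = net.conv[i].W.n_rows / 9;
      arma::cube dx(hw, hw, cin);
      col2im3(dcols, dx);
      dz = arma::vectorise(dx);
    }
  }
  return loss;
}

struct AdamState {
  std::vector<arma::mat> m, v;
  int t = 0;
  void init_like(const std::vector<arma::mat>& shapes) {
    for (auto& s : shapes) {
      m.push_back(arma::mat(s.n_rows, s.n_cols, arma::fill::zeros));
      v.push_back(arma::mat(s.n_rows, s.n_cols, arma::fill::zeros));
    }
  }
};

static void adam_step(arma::mat& w, const arma::mat& grad, arma::mat& m,
                      arma::mat& v, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * grad;
  v = b2 * v + (1 - b2) * arma::square(grad);
  w -= lr * (m / (1 - std::pow(b1, t))) /
       (arma::sqrt(v / (1 - std::pow(b2, t))) + eps);
}

static void eval_set(const Net& net, const arma::cube& X,
                     const arma::ivec& y, double& loss, double& acc) {
  const int n = X.n_slices;
  if (n == 0) { loss = NA_REAL; acc = NA_REAL; return; }
  double l = 0; int correct = 0;
  for (int i = 0; i < n; ++i) {
    arma::vec p = forward_sample(net, X.slice(i), nullptr);
    l += -std::log(std::max(p(y(i)), 1e-300));
    if ((int)p.index_max() == y(i)) ++correct;
  }
  loss = l / n;
  acc = (double)correct / n;
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::cube& X, const arma::ivec& y, List params,
                   List arch, double lr, int epochs, int batch_size,
                   int seed, const arma::cube& Xval,
                   const arma::ivec& yval) {
  tune_allocator();
  Net net = net_from_r(params, arch);
  const int n = X.n_slices;
  if ((int)y.n_elem != n) stop("cnn_train_cpp: label/sample count mismatch");
  batch_size = std::max(1, std::min(batch_size, n));

  Grads g;
  g.init(net);
  // Adam moments: conv W, conv b (as column mats), fc W, fc b
  AdamState st;
  std::vector<arma::mat> shapes;
  for (auto& l : net.conv) { shapes.push_back(l.W); shapes.push_back(arma::mat(l.b)); }
  for (auto& l : net.fc) { shapes.push_back(l.W); shapes.push_back(arma::mat(l.b)); }
  st.init_like(shapes);

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  arma::vec tr_loss(epochs), tr_acc(epochs), va_loss(epochs), va_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; int ep_correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop_i = std::min(n, start + batch_size);
      const int bs = stop_i - start;
      g.zero();
      for (int k = start; k < stop_i; ++k) {
        const int i = order[k];
        ep_loss += backward_sample(net, X.slice(i), y(i), g, ep_correct);
      }
      const double scale = 1.0 / bs;
      ++st.t;
      size_t s = 0;
      for (size_t i = 0; i < net.conv.size(); ++i) {
        arma::mat gw = g.convW[i] * scale;
        adam_step(net.conv[i].W, gw, st.m[s], st.v[s], lr, st.t); ++s;
        arma::mat gb = arma::mat(g.convb[i]) * scale;
        arma::mat bmat(net.conv[i].b);
        adam_step(bmat, gb, st.m[s], st.v[s], lr, st.t); ++s;
        net.conv[i].b = bmat.col(0);
      }
      for (size_t i = 0; i < net.fc.size(); ++i) {
        arma::mat gw = g.fcW[i] * scale;
        adam_step(net.fc[i].W, gw, st.m[s], st.v[s], lr, st.t); ++s;
        arma::mat gb = arma::mat(g.fcb[i]) * scale;
        arma::mat bmat(net.fc[i].b);
        adam_step(bmat, gb, st.m[s], st.v[s], lr, st.t); ++s;
        net.fc[i].b = bmat.col(0);
      }
    }
    if (!std::isfinite(ep_loss))
      stop("cnn_train_cpp: non-finite training loss at epoch %d", ep + 1);
    // running training metrics (accumulated batch by batch within the epoch)
    tr_loss(ep) = ep_loss / n;
    tr_acc(ep) = (double)ep_correct / n;
    double vl, va;
    eval_set(net, Xval, yval, vl, va);
    va_loss(ep) = vl;
    va_acc(ep) = va;
  }

  return List::create(
    _["params"] = net_to_r(net),
    _["train_loss"] = tr_loss, _["train_acc"] = tr_acc,
    _["val_loss"] = va_loss, _["val_acc"] = va_acc);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::cube& X, List params, List arch) {
  tune_allocator();
  Net net = net_from_r(params, arch);
  const int n = X.n_slices;
  arma::mat probs(n, 2);
  for (int i = 0; i < n; ++i)
    probs.row(i) = forward_sample(net, X.slice(i), nullptr).t();
  return probs;
}
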
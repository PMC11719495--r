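// Minimal depthwise-CNN engine: valid-padding stride-1 convolutions
// (standard and depthwise, multiplier 1), stride-p max pooling, flatten,
// inverted dropout, dense layers, sigmoid head with binary cross-entropy,
// Adam / RMSprop optimizers. Convolutions run as im2col + GEMM; training
// processes one image at a time within a batch and accumulates gradients.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::cube;
using arma::mat;
using arma::uvec;
using arma::vec;

enum LayerKind { CONV = 1, DEPTHWISE = 2, MAXPOOL = 3, FLATTEN = 4,
                 DROPOUT = 5, DENSE = 6 };
enum Act { NONE = 0, RELU = 1, SIGMOID = 2 };

struct Net {
  std::vector<int> kind, kk, nout, act;
  std::vector<double> rate;
  std::vector<mat> W;
  std::vector<vec> b;
  int nl;
};

static Net parse_net(const Rcpp::IntegerVector& kind, const Rcpp::IntegerVector& kk,
                     const Rcpp::IntegerVector& nout, const Rcpp::IntegerVector& act,
                     const Rcpp::NumericVector& rate, const Rcpp::List& weights) {
  Net net;
  net.nl = kind.size();
  for (int l = 0; l < net.nl; ++l) {
    net.kind.push_back(kind[l]);
    net.kk.push_back(kk[l]);
    net.nout.push_back(nout[l]);
    net.act.push_back(act[l]);
    net.rate.push_back(rate[l]);
    if (weights.size() > l && !Rf_isNull(weights[l])) {
      Rcpp::List wl = weights[l];
      net.W.push_back(Rcpp::as<mat>(wl["W"]));
      net.b.push_back(Rcpp::as<vec>(wl["b"]));
    } else {
      net.W.push_back(mat());
      net.b.push_back(vec());
    }
  }
  return net;
}

// patch rows ordered channel-major: r = c*k*k + kj*k + ki
static mat im2col_all(const cube& A, int k) {
  const int H = A.n_rows, Wd = A.n_cols, C = A.n_slices;
  const int Ho = H - k + 1, Wo = Wd - k + 1;
  if (Ho < 1 || Wo < 1) Rcpp::stop("kernel larger than input");
  mat cols(k * k * C, static_cast<size_t>(Ho) * Wo);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j)
          for (int i = 0; i < Ho; ++i)
            cols(r, static_cast<size_t>(j) * Ho + i) = A(i + ki, j + kj, c);
      }
  return cols;
}

static void col2im_add(cube& dA, const mat& dcols, int k) {
  const int H = dA.n_rows, Wd = dA.n_cols, C = dA.n_slices;
  const int Ho = H - k + 1, Wo = Wd - k + 1;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j)
          for (int i = 0; i < Ho; ++i)
            dA(i + ki, j + kj, c) += dcols(r, static_cast<size_t>(j) * Ho + i);
      }
}

static cube mat_to_cube(const mat& Zt, int Ho, int Wo, int C) {
  cube out(Ho, Wo, C);
  std::memcpy(out.memptr(), Zt.memptr(), sizeof(double) * Zt.n_elem);
  return out;
}

struct Cache {
  std::vector<cube> outc;
  std::vector<vec> outv;
  std::vector<mat> cols;
  std::vector<uvec> amax;
  std::vector<vec> dmask;
  explicit Cache(int nl) : outc(nl), outv(nl), cols(nl), amax(nl), dmask(nl) {}
};

static void relu_inplace(mat& Z) {
  Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

// forward one image; returns final activation (sigmoid probability for the
// standard binary head). `training` enables dropout.
static double forward_one(const cube& img, const Net& net, bool training,
                          std::mt19937& rng, Cache& cc) {
  const cube* cur = &img;
  vec curv;
  bool vec_stage = false;
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (int l = 0; l < net.nl; ++l) {
    switch (net.kind[l]) {
    case CONV: {
      const int k = net.kk[l];
      const int Ho = cur->n_rows - k + 1, Wo = cur->n_cols - k + 1;
      cc.cols[l] = im2col_all(*cur, k);
      if (net.W[l].n_rows != cc.cols[l].n_rows)
        Rcpp::stop("conv weight shape mismatch at layer %d", l + 1);
      mat Z = net.W[l].t() * cc.cols[l];
      Z.each_col() += net.b[l];
      if (net.act[l] == RELU) relu_inplace(Z);
      mat Zt = Z.t();
      cc.outc[l] = mat_to_cube(Zt, Ho, Wo, Z.n_rows);
      cur = &cc.outc[l];
      break;
    }
    case DEPTHWISE: {
      const int k = net.kk[l];
      const int C = cur->n_slices;
      const int Ho = cur->n_rows - k + 1, Wo = cur->n_cols - k + 1;
      cc.cols[l] = im2col_all(*cur, k);
      if (net.W[l].n_rows != static_cast<arma::uword>(k * k) ||
          net.W[l].n_cols != static_cast<arma::uword>(C))
        Rcpp::stop("depthwise weight shape mismatch at layer %d", l + 1);
      mat Z(C, static_cast<size_t>(Ho) * Wo);
      for (int c = 0; c < C; ++c) {
        Z.row(c) = net.W[l].col(c).t() *
                   cc.cols[l].rows(c * k * k, (c + 1) * k * k - 1);
        Z.row(c) += net.b[l](c);
      }
      if (net.act[l] == RELU) relu_inplace(Z);
      mat Zt = Z.t();
      cc.outc[l] = mat_to_cube(Zt, Ho, Wo, C);
      cur = &cc.outc[l];
      break;
    }
    case MAXPOOL: {
      const int p = net.kk[l];
      const int H = cur->n_rows, Wd = cur->n_cols, C = cur->n_slices;
      const int Ho = H / p, Wo = Wd / p;
      if (Ho < 1 || Wo < 1) Rcpp::stop("pool window larger than input");
      cube out(Ho, Wo, C);
      uvec am(static_cast<size_t>(Ho) * Wo * C);
      size_t t = 0;
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < Wo; ++j)
          for (int i = 0; i < Ho; ++i) {
            double best = -arma::datum::inf;
            size_t bidx = 0;
            for (int dj = 0; dj < p; ++dj)
              for (int di = 0; di < p; ++di) {
                const int ii = i * p + di, jj = j * p + dj;
                const double v = (*cur)(ii, jj, c);
                if (v > best) {
                  best = v;
                  bidx = static_cast<size_t>(ii) +
                         static_cast<size_t>(H) * (jj + static_cast<size_t>(Wd) * c);
                }
              }
            out(i, j, c) = best;
            am[t++] = bidx;
          }
      cc.outc[l] = out;
      cc.amax[l] = am;
      cur = &cc.outc[l];
      break;
    }
    case FLATTEN: {
      curv = arma::vectorise(*cur);
      cc.outv[l] = curv;
      vec_stage = true;
      break;
    }
    case DROPOUT: {
      if (!vec_stage) Rcpp::stop("dropout before flatten is not supported");
      if (training && net.rate[l] > 0) {
        vec mask(curv.n_elem);
        const double keep = 1.0 - net.rate[l];
        for (arma::uword i = 0; i < mask.n_elem; ++i)
          mask[i] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        curv %= mask;
        cc.dmask[l] = mask;
      }
      cc.outv[l] = curv;
      break;
    }
    case DENSE: {
      if (!vec_stage) Rcpp::stop("dense before flatten is not supported");
      if (net.W[l].n_rows != curv.n_elem)
        Rcpp::stop("dense weight shape mismatch at layer %d", l + 1);
      vec z = net.W[l].t() * curv + net.b[l];
      if (net.act[l] == RELU) z.transform([](double v) { return v > 0.0 ? v : 0.0; });
      if (net.act[l] == SIGMOID) z.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
      curv = z;
      cc.outv[l] = curv;
      break;
    }
    default:
      Rcpp::stop("unknown layer kind");
    }
  }
  if (curv.n_elem != 1) Rcpp::stop("network must end in a single output unit");
  return curv[0];
}

struct Grads {
  std::vector<mat> W;
  std::vector<vec> b;
  explicit Grads(const Net& net) {
    for (int l = 0; l < net.nl; ++l) {
      W.push_back(mat(net.W[l].n_rows, net.W[l].n_cols, arma::fill::zeros));
      b.push_back(vec(net.b[l].n_elem, arma::fill::zeros));
    }
  }
  void zero() {
    for (size_t l = 0; l < W.size(); ++l) { W[l].zeros(); b[l].zeros(); }
  }
};

// backprop one image; dlogit = dL/dz at the sigmoid head (= p - y for BCE)
static void backward_one(const cube& img, const Net& net, const Cache& cc,
                         double dlogit, Grads& g) {
  const int nl = net.nl;
  vec dv;
  cube dc;
  bool vec_stage = true;

  // head: dense + sigmoid (validated by the R layer specs)
  {
    const int l = nl - 1;
    vec dz(1);
    dz[0] = dlogit;
    const vec& in = cc.outv[l - 1];
    g.W[l] += in * dz.t();
    g.b[l] += dz;
    dv = net.W[l] * dz;
  }

  for (int l = nl - 2; l >= 0; --l) {
    switch (net.kind[l]) {
    case DENSE: {
      vec dz = dv;
      if (net.act[l] == RELU)
        for (arma::uword i = 0; i < dz.n_elem; ++i)
          if (cc.outv[l][i] <= 0) dz[i] = 0;
      const vec& in = cc.outv[l - 1];
      g.W[l] += in * dz.t();
      g.b[l] += dz;
      dv = net.W[l] * dz;
      break;
    }
    case DROPOUT: {
      if (cc.dmask[l].n_elem) dv %= cc.dmask[l];
      break;
    }
    case FLATTEN: {
      const cube& in = (l == 0) ? img : cc.outc[l - 1];
      dc = cube(in.n_rows, in.n_cols, in.n_slices);
      std::memcpy(dc.memptr(), dv.memptr(), sizeof(double) * dv.n_elem);
      vec_stage = false;
      break;
    }
    case MAXPOOL: {
      const cube& in = (l == 0) ? img : cc.outc[l - 1];
      cube dprev(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
      const uvec& am = cc.amax[l];
      const double* src = dc.memptr();
      double* dst = dprev.memptr();
      for (arma::uword t = 0; t < am.n_elem; ++t) dst[am[t]] += src[t];
      dc = dprev;
      break;
    }
    case CONV: {
      const int k = net.kk[l];
      const cube& out = cc.outc[l];
      const int Cout = out.n_slices;
      const size_t HW = static_cast<size_t>(out.n_rows) * out.n_cols;
      mat dZt(dc.memptr(), HW, Cout); // copies
      if (net.act[l] == RELU) {
        const double* o = out.memptr();
        double* d = dZt.memptr();
        for (size_t i = 0; i < HW * Cout; ++i)
          if (o[i] <= 0) d[i] = 0;
      }
      mat dZ = dZt.t();
      g.W[l] += cc.cols[l] * dZ.t();
      g.b[l] += arma::sum(dZ, 1);
      if (l > 0) {
        mat dcols = net.W[l] * dZ;
        const cube& in = cc.outc[l - 1];
        cube dprev(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
        col2im_add(dprev, dcols, k);
        dc = dprev;
      }
      break;
    }
    case DEPTHWISE: {
      const int k = net.kk[l];
      const cube& out = cc.outc[l];
      const int C = out.n_slices;
      const size_t HW = static_cast<size_t>(out.n_rows) * out.n_cols;
      mat dZt(dc.memptr(), HW, C);
      if (net.act[l] == RELU) {
        const double* o = out.memptr();
        double* d = dZt.memptr();
        for (size_t i = 0; i < HW * C; ++i)
          if (o[i] <= 0) d[i] = 0;
      }
      mat dcols(k * k * C, HW, arma::fill::none);
      for (int c = 0; c < C; ++c) {
        const mat cols_c = cc.cols[l].rows(c * k * k, (c + 1) * k * k - 1);
        g.W[l].col(c) += cols_c * dZt.col(c);
        g.b[l](c) += arma::accu(dZt.col(c));
        dcols.rows(c * k * k, (c + 1) * k * k - 1) =
          net.W[l].col(c) * dZt.col(c).t();
      }
      if (l > 0) {
        const cube& in = cc.outc[l - 1];
        cube dprev(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
        col2im_add(dprev, dcols, k);
        dc = dprev;
      }
      break;
    }
    default:
      Rcpp::stop("unknown layer kind in backward pass");
    }
  }
  (void)vec_stage;
}

static double bce(double p, double y) {
  const double eps = 1e-12;
  p = std::min(std::max(p, eps), 1.0 - eps);
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

struct Optimizer {
  int type; // 1 = adam, 2 = rmsprop
  double lr, beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-7;
  long t = 0;
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  Optimizer(const Net& net, int type_, double lr_) : type(type_), lr(lr_) {
    for (int l = 0; l < net.nl; ++l) {
      mW.push_back(mat(net.W[l].n_rows, net.W[l].n_cols, arma::fill::zeros));
      vW.push_back(mat(net.W[l].n_rows, net.W[l].n_cols, arma::fill::zeros));
      mb.push_back(vec(net.b[l].n_elem, arma::fill::zeros));
      vb.push_back(vec(net.b[l].n_elem, arma::fill::zeros));
    }
  }
  void step(Net& net, const Grads& g) {
    ++t;
    for (int l = 0; l < net.nl; ++l) {
      if (net.W[l].n_elem == 0) continue;
      if (type == 1) {
        mW[l] = beta1 * mW[l] + (1 - beta1) * g.W[l];
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(g.W[l]);
        mb[l] = beta1 * mb[l] + (1 - beta1) * g.b[l];
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(g.b[l]);
        const double c1 = 1 - std::pow(beta1, t), c2 = 1 - std::pow(beta2, t);
        net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      } else {
        vW[l] = rho * vW[l] + (1 - rho) * arma::square(g.W[l]);
        vb[l] = rho * vb[l] + (1 - rho) * arma::square(g.b[l]);
        net.W[l] -= lr * g.W[l] / (arma::sqrt(vW[l]) + eps);
        net.b[l] -= lr * g.b[l] / (arma::sqrt(vb[l]) + eps);
      }
    }
  }
};

static std::vector<cube> image_views(const Rcpp::NumericVector& X) {
  Rcpp::IntegerVector dim = X.attr("dim");
  if (dim.size() != 4) Rcpp::stop("images must be an H x W x C x N array");
  const int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  std::vector<cube> out;
  out.reserve(N);
  const size_t stride = static_cast<size_t>(H) * W * C;
  double* ptr = const_cast<double*>(&X[0]);
  for (int n = 0; n < N; ++n)
    out.emplace_back(ptr + n * stride, H, W, C, false, true);
  return out;
}

// [[Rcpp::export]]
Rcpp::List dcnn_train_cpp(Rcpp::NumericVector X, Rcpp::NumericVector y,
                          Rcpp::NumericVector Xval, Rcpp::NumericVector yval,
                          Rcpp::IntegerVector kind, Rcpp::IntegerVector kk,
                          Rcpp::IntegerVector nout, Rcpp::IntegerVector act,
                          Rcpp::NumericVector rate, Rcpp::List weights,
                          int epochs, int batch_size, double lr,
                          int optimizer, int seed, double threshold) {
  Net net = parse_net(kind, kk, nout, act, rate, weights);
  std::vector<cube> imgs = image_views(X);
  std::vector<cube> vimgs;
  const bool has_val = yval.size() > 0;
  if (has_val) vimgs = image_views(Xval);
  const int N = imgs.size();
  if (N == 0) Rcpp::stop("empty training set");
  if (y.size() != N) Rcpp::stop("label count does not match image count");

  std::mt19937 rng(static_cast<unsigned>(seed));
  Grads grads(net);
  Optimizer opt(net, optimizer, lr);
  mat history(epochs, 4, arma::fill::zeros);
  std::vector<size_t> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0;
    int correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int stop = std::min(start + batch_size, N);
      const int bn = stop - start;
      grads.zero();
      double gscale = 1.0 / bn;
      for (int i = start; i < stop; ++i) {
        Cache cc(net.nl);
        const double p = forward_one(imgs[idx[i]], net, true, rng, cc);
        const double yi = y[idx[i]];
        loss_sum += bce(p, yi);
        correct += ((p >= threshold) == (yi > 0.5));
        backward_one(imgs[idx[i]], net, cc, gscale * (p - yi), grads);
      }
      opt.step(net, grads);
      Rcpp::checkUserInterrupt();
    }
    history(ep, 0) = loss_sum / N;
    history(ep, 1) = static_cast<double>(correct) / N;
    if (has_val) {
      double vloss = 0;
      int vcorrect = 0;
      for (size_t i = 0; i < vimgs.size(); ++i) {
        Cache cc(net.nl);
        const double p = forward_one(vimgs[i], net, false, rng, cc);
        vloss += bce(p, yval[i]);
        vcorrect += ((p >= threshold) == (yval[i] > 0.5));
      }
      history(ep, 2) = vloss / vimgs.size();
      history(ep, 3) = static_cast<double>(vcorrect) / vimgs.size();
    }
  }

  Rcpp::List wout(net.nl);
  for (int l = 0; l < net.nl; ++l) {
    if (net.W[l].n_elem)
      wout[l] = Rcpp::List::create(Rcpp::Named("W") = net.W[l],
                                   Rcpp::Named("b") = net.b[l]);
  }
  return Rcpp::List::create(Rcpp::Named("weights") = wout,
                            Rcpp::Named("history") = history);
}

// Mean BCE loss and its analytic gradients over a batch, dropout off.
// Exposed for finite-difference verification of the backward pass.
// [[Rcpp::export]]
Rcpp::List dcnn_grad_cpp(Rcpp::NumericVector X, Rcpp::NumericVector y,
                         Rcpp::IntegerVector kind, Rcpp::IntegerVector kk,
                         Rcpp::IntegerVector nout, Rcpp::IntegerVector act,
                         Rcpp::NumericVector rate, Rcpp::List weights) {
  Net net = parse_net(kind, kk, nout, act, rate, weights);
  std::vector<cube> imgs = image_views(X);
  const int N = imgs.size();
  std::mt19937 rng(0);
  Grads grads(net);
  double loss = 0;
  for (int i = 0; i < N; ++i) {
    Cache cc(net.nl);
    const double p = forward_one(imgs[i], net, false, rng, cc);
    loss += bce(p, y[i]);
    backward_one(imgs[i], net, cc, (p - y[i]) / N, grads);
  }
  Rcpp::List gout(net.nl);
  for (int l = 0; l < net.nl; ++l)
    if (net.W[l].n_elem)
      gout[l] = Rcpp::List::create(Rcpp::Named("W") = grads.W[l],
                                   Rcpp::Named("b") = grads.b[l]);
  return Rcpp::List::create(Rcpp::Named("loss") = loss / N,
                            Rcpp::Named("grads") = gout);
}

// [[Rcpp::export]]
arma::vec dcnn_predict_cpp(Rcpp::NumericVector X,
                           Rcpp::IntegerVector kind, Rcpp::IntegerVector kk,
                           Rcpp::IntegerVector nout, Rcpp::IntegerVector act,
                           Rcpp::NumericVector rate, Rcpp::List weights) {
  Net net = parse_net(kind, kk, nout, act, rate, weights);
  std::vector<cube> imgs = image_views(X);
  std::mt19937 rng(0); // unused: inference has no stochastic layers
  vec out(imgs.size());
  for (size_t i = 0; i < imgs.size(); ++i) {
    Cache cc(net.nl);
    out[i] = forward_one(imgs[i], net, false, rng, cc);
  }
  return out;
}

// Runs the real layer operations on a zero image, synthesizing
// zero-filled weights of whatever size each operation requires from the
// actual tensor flowing through it. Reports per-layer output shapes and
// required weight dimensions -- the engine-side oracle for the analytic
// shape/parameter propagation.
// [[Rcpp::export]]
Rcpp::List dcnn_probe_cpp(int H, int W, int C,
                          Rcpp::IntegerVector kind, Rcpp::IntegerVector kk,
                          Rcpp::IntegerVector nout, Rcpp::IntegerVector act,
                          Rcpp::NumericVector rate) {
  Net net;
  net.nl = kind.size();
  for (int l = 0; l < net.nl; ++l) {
    net.kind.push_back(kind[l]);
    net.kk.push_back(kk[l]);
    net.nout.push_back(nout[l]);
    net.act.push_back(act[l]);
    net.rate.push_back(rate[l]);
    net.W.push_back(mat());
    net.b.push_back(vec());
  }
  cube img(H, W, C, arma::fill::zeros);
  // first pass: size the weights layer by layer from the live tensor dims
  {
    int h = H, w = W, c = C;
    long flat = -1;
    for (int l = 0; l < net.nl; ++l) {
      switch (net.kind[l]) {
      case CONV: {
        const int k = net.kk[l];
        if (h < k || w < k) Rcpp::stop("kernel larger than input at layer %d", l + 1);
        net.W[l] = mat(k * k * c, net.nout[l], arma::fill::zeros);
        net.b[l] = vec(net.nout[l], arma::fill::zeros);
        h = h - k + 1; w = w - k + 1; c = net.nout[l];
        break;
      }
      case DEPTHWISE: {
        const int k = net.kk[l];
        if (h < k || w < k) Rcpp::stop("kernel larger than input at layer %d", l + 1);
        net.W[l] = mat(k * k, c, arma::fill::zeros);
        net.b[l] = vec(c, arma::fill::zeros);
        h = h - k + 1; w = w - k + 1;
        break;
      }
      case MAXPOOL:
        h /= net.kk[l]; w /= net.kk[l];
        if (h < 1 || w < 1) Rcpp::stop("pool window larger than input at layer %d", l + 1);
        break;
      case FLATTEN:
        flat = static_cast<long>(h) * w * c;
        break;
      case DROPOUT:
        break;
      case DENSE:
        if (flat < 0) Rcpp::stop("dense before flatten at layer %d", l + 1);
        net.W[l] = mat(flat, net.nout[l], arma::fill::zeros);
        net.b[l] = vec(net.nout[l], arma::fill::zeros);
        flat = net.nout[l];
        break;
      }
    }
  }
  // second pass: execute the real ops and record observed output shapes
  Cache cc(net.nl);
  std::mt19937 rng(0);
  forward_one(img, net, false, rng, cc);
  Rcpp::List shapes(net.nl), wdims(net.nl);
  for (int l = 0; l < net.nl; ++l) {
    if (cc.outc[l].n_elem)
      shapes[l] = Rcpp::IntegerVector::create(cc.outc[l].n_rows, cc.outc[l].n_cols,
                                              cc.outc[l].n_slices);
    else if (cc.outv[l].n_elem)
      shapes[l] = Rcpp::IntegerVector::create(cc.outv[l].n_elem);
    else // inference-mode dropout leaves no cache; shape is pass-through
      shapes[l] = shapes[l - 1];
    if (net.W[l].n_elem)
      wdims[l] = Rcpp::IntegerVector::create(net.W[l].n_rows, net.W[l].n_cols,
                                             net.b[l].n_elem);
  }
  return Rcpp::List::create(Rcpp::Named("shapes") = shapes,
                            Rcpp::Named("weight_dims") = wdims);
}
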
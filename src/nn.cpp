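// 1-D convolutional network engine: forward, backprop, Adam.
// Data layout: cube (channels, length, batch); conv works on an im2col
// matrix (in_channels * kernel, out_len * batch) so the inner products run
// through BLAS gemm.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

enum OpKind { OP_INPUT, OP_CONV, OP_POOL, OP_LRELU, OP_ADD, OP_DROPOUT,
              OP_FLATTEN, OP_DENSE };

struct Node {
  OpKind op;
  int kernel = 0, stride = 1, dilation = 1, filters = 0, in_channels = 0;
  double slope = 0.0, rate = 0.0;
  std::vector<int> inputs;

  // trainable parameters (conv/dense)
  mat W; vec b;
  mat gW; vec gb;
  mat mW, vW; vec mb, vb;

  // forward caches
  cube out, grad;
  mat cols;                 // conv im2col cache
  std::vector<int> colmap;  // conv input index per (tap row-block, out col)
  umat argmax;              // pool
  cube mask;                // lrelu/dropout
  int cached_in_len = 0;
  int pad_left = 0, out_len = 0;
};

struct Network {
  std::vector<Node> nodes;
  std::mt19937_64 rng;

  void init_params(uint64_t seed) {
    rng.seed(seed);
    for (auto &nd : nodes) {
      if (nd.op == OP_CONV) {
        int fan_in = nd.in_channels * nd.kernel;
        double s = std::sqrt(1.0 / fan_in);
        std::uniform_real_distribution<double> U(-s, s);
        nd.W.set_size(nd.filters, fan_in);
        for (uword i = 0; i < nd.W.n_elem; ++i) nd.W(i) = U(rng);
        nd.b.zeros(nd.filters);
      } else if (nd.op == OP_DENSE) {
        double s = std::sqrt(1.0 / nd.in_channels);
        std::uniform_real_distribution<double> U(-s, s);
        nd.W.set_size(nd.filters, nd.in_channels);
        for (uword i = 0; i < nd.W.n_elem; ++i) nd.W(i) = U(rng);
        nd.b.zeros(nd.filters);
      }
      if (nd.op == OP_CONV || nd.op == OP_DENSE) {
        nd.mW.zeros(size(nd.W)); nd.vW.zeros(size(nd.W));
        nd.mb.zeros(nd.b.n_elem); nd.vb.zeros(nd.b.n_elem);
      }
    }
  }

  size_t n_params() const {
    size_t n = 0;
    for (auto &nd : nodes)
      if (nd.op == OP_CONV || nd.op == OP_DENSE)
        n += nd.W.n_elem + nd.b.n_elem;
    return n;
  }

  void conv_forward(Node &nd, const cube &x, bool store) {
    const int cin = x.n_rows, L = x.n_cols, B = x.n_slices;
    const int k = nd.kernel, d = nd.dilation, s = nd.stride;
    const int keff = (k - 1) * d + 1;
    const int out_len = (L + s - 1) / s;
    const int pad_total = std::max(0, (out_len - 1) * s + keff - L);
    nd.pad_left = pad_total / 2;
    nd.out_len = out_len;
    nd.cached_in_len = L;
    nd.cols.zeros(cin * k, (size_t)out_len * B);
    nd.colmap.assign((size_t)k * out_len, -1);
    for (int t = 0; t < out_len; ++t)
      for (int j = 0; j < k; ++j) {
        int in = t * s - nd.pad_left + j * d;
        if (in >= 0 && in < L) nd.colmap[(size_t)t * k + j] = in;
      }
    for (int bb = 0; bb < B; ++bb) {
      const mat &xs = x.slice(bb);
      for (int t = 0; t < out_len; ++t) {
        double *colp = nd.cols.colptr((size_t)bb * out_len + t);
        for (int j = 0; j < k; ++j) {
          int in = nd.colmap[(size_t)t * k + j];
          if (in >= 0)
            std::memcpy(colp + (size_t)j * cin, xs.colptr(in),
                        sizeof(double) * cin);
        }
      }
    }
    mat Y = nd.W * nd.cols;           // filters x (out_len*B)
    Y.each_col() += nd.b;
    nd.out.set_size(nd.filters, out_len, B);
    for (int bb = 0; bb < B; ++bb)
      nd.out.slice(bb) = Y.cols((size_t)bb * out_len,
                                (size_t)(bb + 1) * out_len - 1);
    if (!store) nd.cols.reset();   // backward never runs in inference
  }

  cube conv_backward(Node &nd, const cube &dy) {
    const int cin = nd.in_channels, k = nd.kernel;
    const int B = dy.n_slices, out_len = nd.out_len, L = nd.cached_in_len;
    mat dY(nd.filters, (size_t)out_len * B);
    for (int bb = 0; bb < B; ++bb)
      dY.cols((size_t)bb * out_len, (size_t)(bb + 1) * out_len - 1) =
        dy.slice(bb);
    nd.gW += dY * nd.cols.t();
    nd.gb += sum(dY, 1);
    mat dcols = nd.W.t() * dY;        // (cin*k) x (out_len*B)
    cube dx(cin, L, B, fill::zeros);
    for (int bb = 0; bb < B; ++bb) {
      mat &dxs = dx.slice(bb);
      for (int t = 0; t < out_len; ++t) {
        const double *colp = dcols.colptr((size_t)bb * out_len + t);
        for (int j = 0; j < k; ++j) {
          int in = nd.colmap[(size_t)t * k + j];
          if (in >= 0) {
            double *dst = dxs.colptr(in);
            const double *src = colp + (size_t)j * cin;
            for (int c = 0; c < cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
    return dx;
  }

  void forward(const cube &x, bool training, bool store) {
    for (auto &nd : nodes) {
      switch (nd.op) {
      case OP_INPUT:
        nd.out = x;
        break;
      case OP_CONV:
        conv_forward(nd, nodes[nd.inputs[0]].out, store);
        break;
      case OP_POOL: {
        const cube &in = nodes[nd.inputs[0]].out;
        const int C = in.n_rows, L = in.n_cols, B = in.n_slices;
        const int sz = nd.kernel, st = nd.stride;
        if (L < sz) Rcpp::stop("pool input length %d < pool size %d", L, sz);
        const int out_len = (L - sz) / st + 1;
        nd.out.set_size(C, out_len, B);
        nd.argmax.set_size(C, (size_t)out_len * B);
        for (int bb = 0; bb < B; ++bb) {
          const mat &xs = in.slice(bb);
          for (int t = 0; t < out_len; ++t)
            for (int c = 0; c < C; ++c) {
              int best = t * st; double bv = xs(c, best);
              for (int j = 1; j < sz; ++j)
                if (xs(c, t * st + j) > bv) { bv = xs(c, t * st + j);
                                              best = t * st + j; }
              nd.out(c, t, bb) = bv;
              nd.argmax(c, (size_t)bb * out_len + t) = best;
            }
        }
        break;
      }
      case OP_LRELU: {
        const cube &in = nodes[nd.inputs[0]].out;
        nd.mask.set_size(size(in));
        nd.out.set_size(size(in));
        for (uword i = 0; i < in.n_elem; ++i) {
          double g = in(i) >= 0 ? 1.0 : nd.slope;
          nd.mask(i) = g;
          nd.out(i) = g * in(i);
        }
        break;
      }
      case OP_ADD: {
        nd.out = nodes[nd.inputs[0]].out;
        for (size_t i = 1; i < nd.inputs.size(); ++i)
          nd.out += nodes[nd.inputs[i]].out;
        break;
      }
      case OP_DROPOUT: {
        const cube &in = nodes[nd.inputs[0]].out;
        if (training && nd.rate > 0) {
          std::uniform_real_distribution<double> U(0.0, 1.0);
          nd.mask.set_size(size(in));
          double keep = 1.0 - nd.rate;
          for (uword i = 0; i < in.n_elem; ++i)
            nd.mask(i) = (U(rng) < keep) ? 1.0 / keep : 0.0;
          nd.out = in % nd.mask;
        } else {
          nd.mask.reset();
          nd.out = in;
        }
        break;
      }
      case OP_FLATTEN: {
        const cube &in = nodes[nd.inputs[0]].out;
        const int B = in.n_slices, n = in.n_rows * in.n_cols;
        nd.out.set_size(n, 1, B);
        for (int bb = 0; bb < B; ++bb)
          nd.out.slice(bb) = reshape(in.slice(bb), n, 1);
        break;
      }
      case OP_DENSE: {
        const cube &in = nodes[nd.inputs[0]].out;
        const int B = in.n_slices;
        mat X(nd.in_channels, B);
        for (int bb = 0; bb < B; ++bb) X.col(bb) = in.slice(bb).col(0);
        mat Y = nd.W * X;
        Y.each_col() += nd.b;
        nd.out.set_size(nd.filters, 1, B);
        for (int bb = 0; bb < B; ++bb) nd.out.slice(bb) = Y.col(bb);
        break;
      }
      }
    }
  }

  // dLogits: (n_classes, batch) gradient at the output node.
  void backward(const mat &dlogits) {
    for (auto &nd : nodes) nd.grad.reset();
    Node &outn = nodes.back();
    outn.grad.set_size(outn.out.n_rows, 1, outn.out.n_slices);
    for (uword bb = 0; bb < outn.out.n_slices; ++bb)
      outn.grad.slice(bb) = dlogits.col(bb);
    for (int i = (int)nodes.size() - 1; i >= 0; --i) {
      Node &nd = nodes[i];
      if (nd.grad.is_empty()) continue;
      auto accum = [&](int src, const cube &g) {
        Node &sn = nodes[src];
        if (sn.grad.is_empty()) sn.grad = g; else sn.grad += g;
      };
      switch (nd.op) {
      case OP_INPUT: break;
      case OP_CONV:
        accum(nd.inputs[0], conv_backward(nd, nd.grad));
        break;
      case OP_POOL: {
        const cube &in = nodes[nd.inputs[0]].out;
        cube dx(in.n_rows, in.n_cols, in.n_slices, fill::zeros);
        const int C = in.n_rows, out_len = nd.out.n_cols, B = in.n_slices;
        for (int bb = 0; bb < B; ++bb)
          for (int t = 0; t < out_len; ++t)
            for (int c = 0; c < C; ++c)
              dx(c, nd.argmax(c, (size_t)bb * out_len + t), bb) +=
                nd.grad(c, t, bb);
        accum(nd.inputs[0], dx);
        break;
      }
      case OP_LRELU:
        accum(nd.inputs[0], nd.grad % nd.mask);
        break;
      case OP_ADD:
        for (int src : nd.inputs) accum(src, nd.grad);
        break;
      case OP_DROPOUT:
        accum(nd.inputs[0],
              nd.mask.is_empty() ? nd.grad : cube(nd.grad % nd.mask));
        break;
      case OP_FLATTEN: {
        const cube &in = nodes[nd.inputs[0]].out;
        cube dx(in.n_rows, in.n_cols, in.n_slices);
        for (uword bb = 0; bb < in.n_slices; ++bb)
          dx.slice(bb) = reshape(nd.grad.slice(bb), in.n_rows, in.n_cols);
        accum(nd.inputs[0], dx);
        break;
      }
      case OP_DENSE: {
        const cube &in = nodes[nd.inputs[0]].out;
        const int B = in.n_slices;
        mat X(nd.in_channels, B), dY(nd.filters, B);
        for (int bb = 0; bb < B; ++bb) {
          X.col(bb) = in.slice(bb).col(0);
          dY.col(bb) = nd.grad.slice(bb).col(0);
        }
        nd.gW += dY * X.t();
        nd.gb += sum(dY, 1);
        mat dX = nd.W.t() * dY;
        cube dx(nd.in_channels, 1, B);
        for (int bb = 0; bb < B; ++bb) dx.slice(bb) = dX.col(bb);
        accum(nd.inputs[0], dx);
        break;
      }
      }
    }
  }

  // Drop every per-batch buffer; keeps idle network handles small.
  void release_caches() {
    for (auto &nd : nodes) {
      nd.out.reset(); nd.grad.reset(); nd.cols.reset();
      nd.mask.reset(); nd.argmax.reset();
      nd.colmap.clear(); nd.colmap.shrink_to_fit();
    }
  }

  void zero_grads() {
    for (auto &nd : nodes)
      if (nd.op == OP_CONV || nd.op == OP_DENSE) {
        nd.gW.zeros(size(nd.W));
        nd.gb.zeros(nd.b.n_elem);
      }
  }

  void adam_step(double lr, double beta1, double beta2, double eps,
                 long step) {
    double c1 = 1.0 - std::pow(beta1, (double)step);
    double c2 = 1.0 - std::pow(beta2, (double)step);
    for (auto &nd : nodes) {
      if (nd.op != OP_CONV && nd.op != OP_DENSE) continue;
      nd.mW = beta1 * nd.mW + (1 - beta1) * nd.gW;
      nd.vW = beta2 * nd.vW + (1 - beta2) * square(nd.gW);
      nd.W -= lr * (nd.mW / c1) / (sqrt(nd.vW / c2) + eps);
      nd.mb = beta1 * nd.mb + (1 - beta1) * nd.gb;
      nd.vb = beta2 * nd.vb + (1 - beta2) * square(nd.gb);
      nd.b -= lr * (nd.mb / c1) / (sqrt(nd.vb / c2) + eps);
    }
  }

  mat softmax_probs() {
    Node &outn = nodes.back();
    const int K = outn.out.n_rows, B = outn.out.n_slices;
    mat P(K, B);
    for (int bb = 0; bb < B; ++bb) {
      vec z = outn.out.slice(bb).col(0);
      z -= z.max();
      vec e = exp(z);
      P.col(bb) = e / accu(e);
    }
    return P;
  }
};

static OpKind parse_op(const std::string &s) {
  if (s == "input") return OP_INPUT;
  if (s == "conv") return OP_CONV;
  if (s == "pool") return OP_POOL;
  if (s == "lrelu") return OP_LRELU;
  if (s == "add" || s == "merge") return OP_ADD;
  if (s == "dropout") return OP_DROPOUT;
  if (s == "flatten") return OP_FLATTEN;
  if (s == "dense") return OP_DENSE;
  Rcpp::stop("Unknown layer op '%s'", s);
}

// [[Rcpp::export]]
SEXP nn_build(Rcpp::List nodes, int seed) {
  Network *net = new Network();
  for (R_xlen_t i = 0; i < nodes.size(); ++i) {
    Rcpp::List sp = nodes[i];
    Node nd;
    nd.op = parse_op(Rcpp::as<std::string>(sp["op"]));
    nd.kernel = Rcpp::as<int>(sp["kernel"]);
    nd.stride = Rcpp::as<int>(sp["stride"]);
    nd.dilation = Rcpp::as<int>(sp["dilation"]);
    nd.filters = Rcpp::as<int>(sp["filters"]);
    nd.in_channels = Rcpp::as<int>(sp["in_channels"]);
    nd.slope = Rcpp::as<double>(sp["slope"]);
    nd.rate = Rcpp::as<double>(sp["rate"]);
    nd.inputs = Rcpp::as<std::vector<int>>(sp["inputs"]);
    net->nodes.push_back(nd);
  }
  net->init_params((uint64_t)seed + 0x9e3779b97f4a7c15ULL);
  Rcpp::XPtr<Network> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double nn_nparams(SEXP net_) {
  Rcpp::XPtr<Network> net(net_);
  return (double)net->n_params();
}

// [[Rcpp::export]]
arma::vec nn_params_get(SEXP net_) {
  Rcpp::XPtr<Network> net(net_);
  vec out((uword)net->n_params());
  uword at = 0;
  for (auto &nd : net->nodes)
    if (nd.op == OP_CONV || nd.op == OP_DENSE) {
      out.subvec(at, at + nd.W.n_elem - 1) = vectorise(nd.W);
      at += nd.W.n_elem;
      out.subvec(at, at + nd.b.n_elem - 1) = nd.b;
      at += nd.b.n_elem;
    }
  return out;
}

// [[Rcpp::export]]
void nn_params_set(SEXP net_, const arma::vec &theta) {
  Rcpp::XPtr<Network> net(net_);
  if (theta.n_elem != net->n_params())
    Rcpp::stop("Parameter vector has wrong length.");
  uword at = 0;
  for (auto &nd : net->nodes)
    if (nd.op == OP_CONV || nd.op == OP_DENSE) {
      nd.W = reshape(theta.subvec(at, at + nd.W.n_elem - 1),
                     nd.W.n_rows, nd.W.n_cols);
      at += nd.W.n_elem;
      nd.b = theta.subvec(at, at + nd.b.n_elem - 1);
      at += nd.b.n_elem;
    }
}

// [[Rcpp::export]]
arma::mat nn_predict(SEXP net_, const arma::cube &x) {
  Rcpp::XPtr<Network> net(net_);
  net->forward(x, false, false);
  arma::mat P = net->softmax_probs().t();   // batch x classes
  net->release_caches();
  return P;
}

static double batch_loss(const mat &P, const std::vector<int> &y,
                         const uvec &idx) {
  double loss = 0;
  for (uword i = 0; i < idx.n_elem; ++i)
    loss += -std::log(std::max(P(y[idx(i)], i), 1e-12));
  return loss;
}

// [[Rcpp::export]]
Rcpp::List nn_eval_loss(SEXP net_, const arma::cube &x,
                        const std::vector<int> &y, int batch_size) {
  Rcpp::XPtr<Network> net(net_);
  const int n = x.n_slices;
  double loss = 0; int correct = 0;
  for (int s = 0; s < n; s += batch_size) {
    int e = std::min(n, s + batch_size);
    cube xb = x.slices(s, e - 1);
    net->forward(xb, false, false);
    mat P = net->softmax_probs();
    for (int i = 0; i < e - s; ++i) {
      loss += -std::log(std::max(P(y[s + i], i), 1e-12));
      if ((int)P.col(i).index_max() == y[s + i]) ++correct;
    }
  }
  net->release_caches();
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("acc") = (double)correct / n);
}

// One full loss + gradient evaluation with dropout disabled; used by the
// finite-difference gradient checks.
// [[Rcpp::export]]
Rcpp::List nn_loss_grads(SEXP net_, const arma::cube &x,
                         const std::vector<int> &y) {
  Rcpp::XPtr<Network> net(net_);
  const int n = x.n_slices;
  net->zero_grads();
  net->forward(x, false, true);
  mat P = net->softmax_probs();
  double loss = 0;
  mat dlogits = P;
  for (int i = 0; i < n; ++i) {
    loss += -std::log(std::max(P(y[i], i), 1e-12));
    dlogits(y[i], i) -= 1.0;
  }
  dlogits /= n;
  net->backward(dlogits);
  vec g((uword)net->n_params());
  uword at = 0;
  for (auto &nd : net->nodes)
    if (nd.op == OP_CONV || nd.op == OP_DENSE) {
      g.subvec(at, at + nd.gW.n_elem - 1) = vectorise(nd.gW);
      at += nd.gW.n_elem;
      g.subvec(at, at + nd.gb.n_elem - 1) = nd.gb;
      at += nd.gb.n_elem;
    }
  net->release_caches();
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grads") = g);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_train(SEXP net_, const arma::cube &x,
                             const std::vector<int> &y,
                             const arma::cube &xval,
                             const std::vector<int> &yval,
                             int epochs, int batch_size, double lr,
                             int seed) {
  Rcpp::XPtr<Network> net(net_);
  const int n = x.n_slices;
  if (n == 0) Rcpp::stop("Empty training set.");
  net->rng.seed((uint64_t)seed * 0x2545F4914F6CDD1DULL + 1);
  Rcpp::NumericMatrix hist(epochs, 4);
  colnames(hist) = Rcpp::CharacterVector::create(
    "train_loss", "train_acc", "val_loss", "val_acc");
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), net->rng);
    double ep_loss = 0; int ep_correct = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(n, s + batch_size);
      int bs = e - s;
      cube xb(x.n_rows, x.n_cols, bs);
      std::vector<int> yb(bs);
      for (int i = 0; i < bs; ++i) {
        xb.slice(i) = x.slice(order[s + i]);
        yb[i] = y[order[s + i]];
      }
      net->zero_grads();
      net->forward(xb, true, true);
      mat P = net->softmax_probs();
      mat dlogits = P;
      for (int i = 0; i < bs; ++i) {
        ep_loss += -std::log(std::max(P(yb[i], i), 1e-12));
        if ((int)P.col(i).index_max() == yb[i]) ++ep_correct;
        dlogits(yb[i], i) -= 1.0;
      }
      if (!std::isfinite(ep_loss))
        Rcpp::stop("NaN/Inf loss at epoch %d; reduce the learning rate.",
                   ep + 1);
      dlogits /= bs;
      net->backward(dlogits);
      ++step;
      if (lr > 0) net->adam_step(lr, 0.9, 0.999, 1e-8, step);
    }
    hist(ep, 0) = ep_loss / n;
    hist(ep, 1) = (double)ep_correct / n;
    if (xval.n_slices > 0) {
      Rcpp::List ev = nn_eval_loss(net_, xval, yval,
                                   std::max(batch_size, 64));
      hist(ep, 2) = Rcpp::as<double>(ev["loss"]);
      hist(ep, 3) = Rcpp::as<double>(ev["acc"]);
    } else {
      hist(ep, 2) = NA_REAL;
      hist(ep, 3) = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  net->release_caches();
  return hist;
}
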
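// 1D convolutional network for spectrum classification.
//
// Architecture: repeated [valid conv (stride 1) -> leaky ReLU -> non-overlapping
// max pool] blocks followed by a fully connected classifier head, trained with
// softmax cross-entropy and AdamW (decoupled weight decay).
//
// Convolutions are evaluated as one GEMM per layer over an im2col matrix that
// stacks all samples of a chunk side by side; pooling exploits that p
// consecutive columns of the conv output are contiguous in column-major
// storage, so the regrouping is a plain memcpy. Gradients are exact (verified
// against finite differences in the test suite).

#include <RcppArmadillo.h>

// The engine runs in single precision: the skinny conv GEMMs are memory-
// bandwidth-bound, and float halves the traffic. Parameters cross the R
// boundary as doubles and are converted once per call.
#include <cstring>
#include <random>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvGeom {
  int c_in, c_out, k, p;     // channels, kernel, pool width
  int L_in, L_conv, L_pool;  // lengths entering, after conv, after pool
};

struct Arch {
  std::vector<ConvGeom> conv;
  std::vector<int> hidden;
  int n_input = 0, n_classes = 0, n_flat = 0;
  double slope = 0.01;
};

Arch parse_arch(const Rcpp::List& a) {
  Arch arch;
  arch.n_input = Rcpp::as<int>(a["n_input"]);
  arch.n_classes = Rcpp::as<int>(a["n_classes"]);
  arch.slope = Rcpp::as<double>(a["slope"]);
  std::vector<int> kernel = Rcpp::as<std::vector<int>>(a["kernel"]);
  std::vector<int> pool = Rcpp::as<std::vector<int>>(a["pool"]);
  std::vector<int> channels = Rcpp::as<std::vector<int>>(a["channels"]);
  arch.hidden = Rcpp::as<std::vector<int>>(a["hidden"]);
  int L = arch.n_input, c_in = 1;
  for (size_t l = 0; l < kernel.size(); ++l) {
    ConvGeom g;
    g.c_in = c_in;
    g.c_out = channels[l];
    g.k = kernel[l];
    g.p = pool[l];
    g.L_in = L;
    g.L_conv = L - g.k + 1;
    if (g.L_conv < 1)
      Rcpp::stop("architecture error: length %d too short for kernel %d in conv layer %d",
                 L, g.k, (int)l + 1);
    g.L_pool = g.L_conv / g.p;
    if (g.L_pool < 1)
      Rcpp::stop("architecture error: length %d too short for pool %d in conv layer %d",
                 g.L_conv, g.p, (int)l + 1);
    L = g.L_pool;
    c_in = g.c_out;
    arch.conv.push_back(g);
  }
  arch.n_flat = L * c_in;
  return arch;
}

struct Params {
  std::vector<fmat> W;  // conv layers first (c_out x c_in*k), then dense (out x in)
  std::vector<fvec> b;
};

Params parse_params(const Rcpp::List& plist, const Arch& arch) {
  Params par;
  size_t n_layers = arch.conv.size() + arch.hidden.size() + 1;
  if ((size_t)plist.size() != 2 * n_layers)
    Rcpp::stop("parameter list has %d elements, expected %d", plist.size(), 2 * n_layers);
  for (size_t i = 0; i < n_layers; ++i) {
    par.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(plist[2 * i])));
    par.b.push_back(conv_to<fvec>::from(Rcpp::as<vec>(plist[2 * i + 1])));
  }
  return par;
}

Rcpp::List params_to_list(const Params& par, const Rcpp::List& tmpl) {
  Rcpp::List out(tmpl.size());
  out.names() = tmpl.names();
  for (size_t i = 0; i < par.W.size(); ++i) {
    out[2 * i] = Rcpp::wrap(conv_to<mat>::from(par.W[i]));
    out[2 * i + 1] = Rcpp::wrap(conv_to<vec>::from(par.b[i]));
  }
  return out;
}

// leaky ReLU in place; writes the derivative into grad (same shape)
void leaky_inplace(fmat& Z, fmat& grad, double slope) {
  grad.set_size(Z.n_rows, Z.n_cols);
  float* z = Z.memptr();
  float* g = grad.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (z[i] > 0) {
      g[i] = 1.0;
    } else {
      g[i] = slope;
      z[i] *= slope;
    }
  }
}

struct Cache {
  std::vector<fmat> K;      // im2col matrices, (c_in*k) x (L_conv*B)
  std::vector<fmat> actg;   // conv activation derivative, c_out x (L_conv*B)
  std::vector<umat> Jmax;  // winning pool offset in 0..p-1, c_out x (L_pool*B)
  std::vector<fmat> Hin;    // dense layer inputs: flatten, then hidden activations
  std::vector<fmat> dactg;  // dense activation derivative (dropout scaling folded in)
  fmat logits;              // n_classes x B
};

// im2col: sample segments of A (c x L_in each) become segments of K
// (c*k x L_conv each); row block j holds the input shifted by j taps.
void im2col_fill(const fmat& A, fmat& K, const ConvGeom& g, int B) {
  for (int s = 0; s < B; ++s)
    for (int j = 0; j < g.k; ++j)
      K.submat(j * g.c_in, (size_t)s * g.L_conv,
               (j + 1) * g.c_in - 1, (size_t)s * g.L_conv + g.L_conv - 1) =
          A.cols((size_t)s * g.L_in + j, (size_t)s * g.L_in + j + g.L_conv - 1);
}

// Forward pass over one chunk. X rows are samples. When `train` is false no
// dropout is applied and only the logits are produced.
Cache forward_chunk(const Params& par, const Arch& arch,
                    const fmat& X, bool train, double dropout, std::mt19937* rng) {
  const int B = X.n_rows;
  Cache c;
  fmat A(1, (size_t)arch.n_input * B);
  for (int s = 0; s < B; ++s)
    A.cols((size_t)s * arch.n_input, (size_t)(s + 1) * arch.n_input - 1) = X.row(s);

  for (size_t l = 0; l < arch.conv.size(); ++l) {
    const ConvGeom& g = arch.conv[l];
    fmat K(g.c_in * g.k, (size_t)g.L_conv * B);
    im2col_fill(A, K, g, B);
    fmat Z = par.W[l] * K;
    Z.each_col() += par.b[l];
    fmat grad;
    leaky_inplace(Z, grad, arch.slope);

    // regroup: p consecutive conv columns are one pool window; in col-major
    // storage the cropped segment (c x L_pool*p) IS the (c*p x L_pool) block
    const int c_out = g.c_out, p = g.p, Lp = g.L_pool;
    fmat R(c_out * p, (size_t)Lp * B);
    for (int s = 0; s < B; ++s)
      std::memcpy(R.colptr((size_t)s * Lp), Z.colptr((size_t)s * g.L_conv),
                  sizeof(float) * (size_t)c_out * Lp * p);
    fmat P(c_out, (size_t)Lp * B);
    umat J(c_out, (size_t)Lp * B);
    const float* r = R.memptr();
    float* pp = P.memptr();
    uword* jj = J.memptr();
    const uword ncol = P.n_cols;
    for (uword col = 0; col < ncol; ++col) {
      const float* rc = r + col * (size_t)(c_out * p);
      for (int row = 0; row < c_out; ++row) {
        float best = rc[row];
        uword bj = 0;
        for (int j = 1; j < p; ++j) {
          float v = rc[j * c_out + row];
          if (v > best) { best = v; bj = j; }  // ties: earliest window position
        }
        pp[col * c_out + row] = best;
        jj[col * c_out + row] = bj;
      }
    }
    if (train) {
      c.K.push_back(std::move(K));
      c.actg.push_back(std::move(grad));
      c.Jmax.push_back(std::move(J));
    }
    A = std::move(P);
  }

  // flatten: sample segments are contiguous, so columns of F are memcpys
  fmat F(arch.n_flat, B);
  for (int s = 0; s < B; ++s)
    std::memcpy(F.colptr(s), A.colptr((size_t)s * arch.conv.back().L_pool),
                sizeof(float) * arch.n_flat);

  size_t nconv = arch.conv.size();
  fmat H = std::move(F);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (size_t l = 0; l < arch.hidden.size(); ++l) {
    if (train) c.Hin.push_back(H);
    fmat Z = par.W[nconv + l] * H;
    Z.each_col() += par.b[nconv + l];
    fmat grad;
    leaky_inplace(Z, grad, arch.slope);
    if (train && dropout > 0.0) {
      const double keep = 1.0 - dropout;
      float* z = Z.memptr();
      float* g = grad.memptr();
      for (uword i = 0; i < Z.n_elem; ++i) {
        if (unif(*rng) < keep) {  // inverted dropout
          z[i] /= keep;
          g[i] /= keep;
        } else {
          z[i] = 0.0;
          g[i] = 0.0;
        }
      }
    }
    if (train) c.dactg.push_back(std::move(grad));
    H = std::move(Z);
  }
  if (train) c.Hin.push_back(H);
  c.logits = par.W.back() * H;
  c.logits.each_col() += par.b.back();
  return c;
}

// softmax cross-entropy; returns summed loss, writes dlogits = softmax - onehot
double ce_loss(const fmat& logits, const ivec& y, fmat& dlogits) {
  fmat P = logits;
  P.each_row() -= max(P, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  double loss = 0.0;
  dlogits = P;
  for (uword s = 0; s < y.n_elem; ++s) {
    loss -= std::log(std::max((double)P(y[s], s), 1e-300));
    dlogits(y[s], s) -= 1.0;
  }
  return loss;
}

// Backward pass for one chunk; gradients of the summed loss accumulate into gW/gb.
void backward_chunk(const Params& par, const Arch& arch,
                    Cache& c, const fmat& dlogits,
                    std::vector<fmat>& gW, std::vector<fvec>& gb) {
  const size_t nconv = arch.conv.size(), nh = arch.hidden.size();
  const int B = dlogits.n_cols;

  fmat dZ = dlogits;
  for (int l = (int)nh; l >= 0; --l) {
    gW[nconv + l] += dZ * c.Hin[l].t();
    gb[nconv + l] += sum(dZ, 1);
    dZ = par.W[nconv + l].t() * dZ;
    if (l > 0) dZ %= c.dactg[l - 1];
  }

  // un-flatten: gradient w.r.t. the last pooled map, c_out x (L_pool*B)
  const ConvGeom& last = arch.conv.back();
  fmat dP(last.c_out, (size_t)last.L_pool * B);
  for (int s = 0; s < B; ++s)
    std::memcpy(dP.colptr((size_t)s * last.L_pool), dZ.colptr(s),
                sizeof(float) * arch.n_flat);

  for (int l = (int)nconv - 1; l >= 0; --l) {
    const ConvGeom& g = arch.conv[l];
    const int c_out = g.c_out, p = g.p, Lp = g.L_pool;
    // pool backward: place each pooled gradient at its winning offset
    fmat R(c_out * p, (size_t)Lp * B, fill::zeros);
    {
      const float* dp = dP.memptr();
      const uword* jj = c.Jmax[l].memptr();
      float* r = R.memptr();
      const uword ncol = dP.n_cols;
      for (uword col = 0; col < ncol; ++col)
        for (int row = 0; row < c_out; ++row)
          r[col * (size_t)(c_out * p) + jj[col * c_out + row] * c_out + row] =
              dp[col * c_out + row];
    }
    fmat dZc(c_out, (size_t)g.L_conv * B, fill::zeros);  // cropped tail stays zero
    for (int s = 0; s < B; ++s)
      std::memcpy(dZc.colptr((size_t)s * g.L_conv), R.colptr((size_t)s * Lp),
                  sizeof(float) * (size_t)c_out * Lp * p);
    dZc %= c.actg[l];
    gW[l] += dZc * c.K[l].t();
    gb[l] += sum(dZc, 1);
    if (l > 0) {
      fmat dK = par.W[l].t() * dZc;
      fmat dA(g.c_in, (size_t)g.L_in * B, fill::zeros);
      for (int s = 0; s < B; ++s)
        for (int j = 0; j < g.k; ++j)
          dA.cols((size_t)s * g.L_in + j, (size_t)s * g.L_in + j + g.L_conv - 1) +=
              dK.submat(j * g.c_in, (size_t)s * g.L_conv,
                        (j + 1) * g.c_in - 1, (size_t)s * g.L_conv + g.L_conv - 1);
      dP = std::move(dA);  // L_in of layer l equals L_pool of layer l-1
    }
  }
}

uvec predict_labels(const fmat& logits) {
  uvec out(logits.n_cols);
  for (uword s = 0; s < logits.n_cols; ++s)
    out[s] = logits.col(s).index_max();  // ties: lowest class index wins
  return out;
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Params& p) {
    for (const fmat& W : p.W) {
      mW.push_back(zeros<fmat>(W.n_rows, W.n_cols));
      vW.push_back(zeros<fmat>(W.n_rows, W.n_cols));
    }
    for (const fvec& b : p.b) {
      mb.push_back(zeros<fvec>(b.n_elem));
      vb.push_back(zeros<fvec>(b.n_elem));
    }
  }
  // single fused pass per tensor: no expression-template temporaries
  void update_one(float* p, const float* g, float* m, float* v, uword n,
                  double lr, double wd, double c1, double c2) {
    for (uword i = 0; i < n; ++i) {
      m[i] = b1 * m[i] + (1 - b1) * g[i];
      v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
      double mhat = m[i] / c1, vhat = v[i] / c2;
      p[i] -= lr * wd * p[i] + lr * mhat / (std::sqrt(vhat) + eps);
    }
  }

  // AdamW: decay applied directly to the weights (decoupled), not to biases
  void step(Params& p, const std::vector<fmat>& gW, const std::vector<fvec>& gb,
            double lr, double wd) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t), c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < p.W.size(); ++i) {
      update_one(p.W[i].memptr(), gW[i].memptr(), mW[i].memptr(), vW[i].memptr(),
                 p.W[i].n_elem, lr, wd, c1, c2);
      update_one(p.b[i].memptr(), gb[i].memptr(), mb[i].memptr(), vb[i].memptr(),
                 p.b[i].n_elem, lr, 0.0, c1, c2);
    }
  }
};

// mean loss + accuracy + gradient over an index set, chunked
double run_epoch_grads(const Params& par, const Arch& arch, const fmat& X, const ivec& y,
                       const uvec& rows, int chunk, double dropout, std::mt19937& rng,
                       std::vector<fmat>& gW, std::vector<fvec>& gb, double& acc) {
  const size_t N = rows.n_elem;
  double loss = 0.0;
  size_t correct = 0;
  for (size_t start = 0; start < N; start += chunk) {
    size_t end = std::min(N, start + (size_t)chunk);
    uvec sel = rows.subvec(start, end - 1);
    fmat Xc = X.rows(sel);
    ivec yc(end - start);
    for (size_t i = 0; i < end - start; ++i) yc[i] = y[sel[i]];
    Cache c = forward_chunk(par, arch, Xc, true, dropout, &rng);
    fmat dlog;
    loss += ce_loss(c.logits, yc, dlog);
    uvec pred = predict_labels(c.logits);
    for (size_t i = 0; i < pred.n_elem; ++i)
      if ((sword)pred[i] == yc[i]) ++correct;
    dlog /= (double)N;  // gradient of the mean loss over the whole index set
    backward_chunk(par, arch, c, dlog, gW, gb);
  }
  acc = (double)correct / (double)N;
  return loss / (double)N;
}

double accuracy_of(const Params& par, const Arch& arch, const fmat& X, const ivec& y,
                   int chunk) {
  const size_t N = X.n_rows;
  size_t correct = 0;
  for (size_t start = 0; start < N; start += chunk) {
    size_t end = std::min(N, start + (size_t)chunk);
    fmat Xc = X.rows(start, end - 1);
    Cache c = forward_chunk(par, arch, Xc, false, 0.0, nullptr);
    uvec pred = predict_labels(c.logits);
    for (size_t i = 0; i < pred.n_elem; ++i)
      if ((sword)pred[i] == y[start + i]) ++correct;
  }
  return (double)correct / (double)N;
}

void zero_grads(const Params& par, std::vector<fmat>& gW, std::vector<fvec>& gb) {
  if (gW.empty()) {
    for (const fmat& W : par.W) gW.push_back(zeros<fmat>(W.n_rows, W.n_cols));
    for (const fvec& b : par.b) gb.push_back(zeros<fvec>(b.n_elem));
  } else {
    for (fmat& W : gW) W.zeros();
    for (fvec& b : gb) b.zeros();
  }
}

}  // namespace

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(Rcpp::List params, Rcpp::List arch_list, const arma::mat& X,
                          int chunk = 128) {
  Arch arch = parse_arch(arch_list);
  Params par = parse_params(params, arch);
  const fmat Xf = conv_to<fmat>::from(X);
  const size_t N = Xf.n_rows;
  fmat out((size_t)arch.n_classes, N);
  for (size_t start = 0; start < N; start += chunk) {
    size_t end = std::min(N, start + (size_t)chunk);
    fmat Xc = Xf.rows(start, end - 1);
    Cache c = forward_chunk(par, arch, Xc, false, 0.0, nullptr);
    out.cols(start, end - 1) = c.logits;
  }
  return conv_to<mat>::from(out.t());  // N x n_classes logits
}

// [[Rcpp::export]]
Rcpp::List cnn_loss_grad_cpp(Rcpp::List params, Rcpp::List arch_list,
                             const arma::mat& X, const arma::ivec& y) {
  Arch arch = parse_arch(arch_list);
  Params par = parse_params(params, arch);
  std::vector<fmat> gW;
  std::vector<fvec> gb;
  zero_grads(par, gW, gb);
  std::mt19937 rng(0);
  const fmat Xf = conv_to<fmat>::from(X);
  uvec rows = regspace<uvec>(0, Xf.n_rows - 1);
  double acc;
  double loss = run_epoch_grads(par, arch, Xf, y, rows, 128, 0.0, rng, gW, gb, acc);
  Rcpp::List grads(2 * gW.size());
  for (size_t i = 0; i < gW.size(); ++i) {
    grads[2 * i] = Rcpp::wrap(conv_to<mat>::from(gW[i]));
    grads[2 * i + 1] = Rcpp::wrap(conv_to<vec>::from(gb[i]));
  }
  grads.names() = Rcpp::as<Rcpp::CharacterVector>(params.names());
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("accuracy") = acc,
                            Rcpp::Named("gradients") = grads);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List params, Rcpp::List arch_list,
                         const arma::mat& Xtr, const arma::ivec& ytr,
                         const arma::mat& Xte, const arma::ivec& yte,
                         double lr, double weight_decay, double dropout,
                         int max_epochs, int eval_interval, int batch_size,
                         int chunk, unsigned int seed) {
  Arch arch = parse_arch(arch_list);
  Params par = parse_params(params, arch);
  Adam opt(par);
  std::mt19937 rng(seed);
  std::vector<fmat> gW;
  std::vector<fvec> gb;
  const fmat Xtrf = conv_to<fmat>::from(Xtr);
  const fmat Xtef = conv_to<fmat>::from(Xte);

  const size_t N = Xtrf.n_rows;
  bool full_batch = batch_size <= 0 || (size_t)batch_size >= N;
  std::vector<double> log_epoch, log_loss, log_tracc, log_teacc;

  Params best = par;  // parameters at the best test evaluation so far
  double best_acc = -1.0;
  uvec order = regspace<uvec>(0, N - 1);
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    double loss, tracc;
    if (full_batch) {
      zero_grads(par, gW, gb);
      loss = run_epoch_grads(par, arch, Xtrf, ytr, order, chunk, dropout, rng, gW, gb, tracc);
      opt.step(par, gW, gb, lr, weight_decay);
    } else {
      // mini-batch: one AdamW step per shuffled batch; epoch statistics are
      // sample-weighted averages of the pre-update batch statistics
      std::shuffle(order.begin(), order.end(), rng);
      double lsum = 0.0, asum = 0.0;
      for (size_t start = 0; start < N; start += batch_size) {
        size_t end = std::min(N, start + (size_t)batch_size);
        uvec sel = order.subvec(start, end - 1);
        zero_grads(par, gW, gb);
        double bacc;
        double bl = run_epoch_grads(par, arch, Xtrf, ytr, sel, chunk, dropout, rng, gW, gb, bacc);
        opt.step(par, gW, gb, lr, weight_decay);
        lsum += bl * (end - start);
        asum += bacc * (end - start);
      }
      loss = lsum / N;
      tracc = asum / N;
    }
    if (!std::isfinite(loss))
      Rcpp::stop("divergence error: non-finite training loss at epoch %d", epoch);
    if (epoch % eval_interval == 0 || epoch == max_epochs) {
      double teacc = accuracy_of(par, arch, Xtef, yte, chunk);
      if (teacc > best_acc) {  // strict: earliest best evaluation is kept
        best_acc = teacc;
        best = par;
      }
      log_epoch.push_back(epoch);
      log_loss.push_back(loss);
      log_tracc.push_back(tracc);
      log_teacc.push_back(teacc);
    }
    if (epoch % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("epoch") = log_epoch,
      Rcpp::Named("loss") = log_loss,
      Rcpp::Named("train_accuracy") = log_tracc,
      Rcpp::Named("test_accuracy") = log_teacc,
      Rcpp::Named("params") = params_to_list(par, params),
      Rcpp::Named("best_params") = params_to_list(best, params));
}
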
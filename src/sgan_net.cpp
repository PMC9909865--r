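// Hot path of the SGAN networks: forward and backward passes of the
// 1-d convolutional discriminator and the dense batch-norm generator,
// plus fused per-minibatch gradient computations so that intermediate
// activations never cross the R boundary.
// Layout conventions (match the R wrappers):
//  - activations are B x (L*C) matrices, position fastest within channel;
//  - conv kernels are (k*Cin) x Cout with row (off * Cin + ci);
//  - im2col patch matrices are (B*Lout) x (k*Cin), batch fastest;
//  - logits column 1 = benign, column 2 = oncogenic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat leaky_mask(const arma::mat& x, double slope) {
  arma::mat m(x.n_rows, x.n_cols);
  const double* src = x.memptr();
  double* dst = m.memptr();
  for (arma::uword i = 0; i < x.n_elem; ++i) dst[i] = src[i] > 0 ? 1.0 : slope;
  return m;
}

static arma::mat im2col1d(const arma::mat& X, int L, int Cin, int kernel,
                          int stride, int Lout) {
  const int B = X.n_rows;
  arma::mat col(B * Lout, kernel * Cin);
  for (int off = 0; off < kernel; ++off) {
    for (int ci = 0; ci < Cin; ++ci) {
      const int dst = off * Cin + ci;
      for (int l = 0; l < Lout; ++l) {
        std::memcpy(col.colptr(dst) + (size_t)l * B,
                    X.colptr(ci * L + l * stride + off), B * sizeof(double));
      }
    }
  }
  return col;
}

// ---- discriminator -------------------------------------------------------

struct DiscParams {
  std::vector<arma::mat> K;
  std::vector<arma::vec> b;
  arma::mat headW;
  arma::vec headb;
  int kernel, stride;
  double slope;
};

static DiscParams disc_unpack(List conv, const arma::mat& headW,
                              const arma::vec& headb, int kernel, int stride,
                              double slope) {
  DiscParams p;
  for (int i = 0; i < conv.size(); ++i) {
    List ly = conv[i];
    p.K.push_back(as<arma::mat>(ly["K"]));
    p.b.push_back(as<arma::vec>(ly["b"]));
  }
  p.headW = headW;
  p.headb = headb;
  p.kernel = kernel;
  p.stride = stride;
  p.slope = slope;
  return p;
}

struct DiscCache {
  std::vector<arma::mat> col, mask;
  std::vector<int> L, Cin, Lout;
  arma::mat features, logits;
};

static void disc_run(const DiscParams& p, const arma::mat& X, DiscCache& c) {
  const int B = X.n_rows;
  arma::mat A = X;
  int L = X.n_cols, Cin = 1;
  for (size_t i = 0; i < p.K.size(); ++i) {
    const int Cout = p.K[i].n_cols;
    const int Lout = (L - p.kernel) / p.stride + 1;
    arma::mat col = im2col1d(A, L, Cin, p.kernel, p.stride, Lout);
    arma::mat pre = col * p.K[i];
    for (int co = 0; co < Cout; ++co) pre.col(co) += p.b[i](co);
    arma::mat mask = leaky_mask(pre, p.slope);
    pre %= mask;                       // pre now holds the activation
    c.L.push_back(L);
    c.Cin.push_back(Cin);
    c.Lout.push_back(Lout);
    c.col.push_back(std::move(col));
    c.mask.push_back(std::move(mask));
    A = arma::reshape(pre, B, (size_t)Lout * Cout);
    L = Lout;
    Cin = Cout;
  }
  c.features = A;
  c.logits = A * p.headW;
  c.logits.col(0) += p.headb(0);
  c.logits.col(1) += p.headb(1);
}

struct DiscGrads {
  std::vector<arma::mat> gK;
  std::vector<arma::vec> gb;
  arma::mat gheadW;
  arma::vec gheadb;
  arma::mat dX;
  bool init = false;
};

// Backward through the discriminator; accumulates parameter gradients into
// `g` (when want_param_grads) and optionally returns the input gradient.
static void disc_back(const DiscParams& p, const DiscCache& c,
                      const arma::mat* dlogits, const arma::mat* dfeatures,
                      DiscGrads& g, bool need_input_grad,
                      bool want_param_grads = true) {
  const int B = c.features.n_rows;
  if (!g.init) {
    for (size_t i = 0; i < p.K.size(); ++i) {
      g.gK.push_back(arma::zeros<arma::mat>(p.K[i].n_rows, p.K[i].n_cols));
      g.gb.push_back(arma::zeros<arma::vec>(p.b[i].n_elem));
    }
    g.gheadW = arma::zeros<arma::mat>(p.headW.n_rows, p.headW.n_cols);
    g.gheadb = arma::zeros<arma::vec>(2);
    g.init = true;
  }
  arma::mat dA(B, c.features.n_cols, arma::fill::zeros);
  if (dfeatures) dA += *dfeatures;
  if (dlogits) {
    if (want_param_grads) {
      g.gheadW += c.features.t() * (*dlogits);
      g.gheadb += arma::sum(*dlogits, 0).t();
    }
    dA += (*dlogits) * p.headW.t();
  }
  for (int i = (int)p.K.size() - 1; i >= 0; --i) {
    const int Cout = p.K[i].n_cols;
    arma::mat dpre = arma::reshape(dA, (size_t)B * c.Lout[i], Cout);
    dpre %= c.mask[i];
    if (want_param_grads) {
      g.gK[i] += c.col[i].t() * dpre;
      g.gb[i] += arma::sum(dpre, 0).t();
    }
    if (i > 0 || need_input_grad) {
      arma::mat dcol = dpre * p.K[i].t();
      arma::mat dX(B, (size_t)c.L[i] * c.Cin[i], arma::fill::zeros);
      for (int off = 0; off < p.kernel; ++off) {
        for (int ci = 0; ci < c.Cin[i]; ++ci) {
          const int src = off * c.Cin[i] + ci;
          for (int l = 0; l < c.Lout[i]; ++l) {
            double* dst = dX.colptr(ci * c.L[i] + l * p.stride + off);
            const double* sp = dcol.colptr(src) + (size_t)l * B;
            for (int b2 = 0; b2 < B; ++b2) dst[b2] += sp[b2];
          }
        }
      }
      dA = std::move(dX);
    }
  }
  if (need_input_grad) g.dX = dA;
}

static List disc_grads_to_list(const DiscGrads& g) {
  List gconv(g.gK.size());
  for (size_t i = 0; i < g.gK.size(); ++i) {
    gconv[i] = List::create(_["K"] = g.gK[i], _["b"] = g.gb[i]);
  }
  return List::create(_["conv"] = gconv,
                      _["head"] = List::create(_["W"] = g.gheadW,
                                               _["b"] = g.gheadb));
}

// Row-wise stable log-sum-exp of (l1, l2) and (l1, l2, 0).
static void lse23(const arma::mat& logits, arma::vec& s2, arma::vec& s3) {
  const int n = logits.n_rows;
  s2.set_size(n);
  s3.set_size(n);
  for (int i = 0; i < n; ++i) {
    const double a = logits(i, 0), b = logits(i, 1);
    double m2 = std::max(a, b);
    s2(i) = m2 + std::log(std::exp(a - m2) + std::exp(b - m2));
    double m3 = std::max(m2, 0.0);
    s3(i) = m3 + std::log(std::exp(a - m3) + std::exp(b - m3) +
                          std::exp(-m3));
  }
}

// [[Rcpp::export]]
List disc_fwd_cpp(const arma::mat& X, List conv, const arma::mat& headW,
                  const arma::vec& headb, int kernel, int stride,
                  double slope, bool want_caches = true) {
  DiscParams p = disc_unpack(conv, headW, headb, kernel, stride, slope);
  DiscCache c;
  disc_run(p, X, c);
  if (!want_caches) {
    return List::create(_["logits"] = c.logits, _["features"] = c.features,
                        _["caches"] = R_NilValue);
  }
  List caches(p.K.size());
  for (size_t i = 0; i < p.K.size(); ++i) {
    caches[i] = List::create(_["col"] = c.col[i], _["mask"] = c.mask[i],
                             _["L"] = c.L[i], _["Cin"] = c.Cin[i],
                             _["Lout"] = c.Lout[i]);
  }
  return List::create(_["logits"] = c.logits, _["features"] = c.features,
                      _["caches"] = caches);
}

// [[Rcpp::export]]
List disc_bwd_cpp(List conv, const arma::mat& headW, List caches,
                  const arma::mat& features, const arma::mat& logits,
                  SEXP dlogits_, SEXP dfeatures_, int kernel, int stride,
                  double slope, bool need_input_grad) {
  DiscParams p = disc_unpack(conv, headW, arma::zeros<arma::vec>(2), kernel,
                             stride, slope);
  DiscCache c;
  for (int i = 0; i < caches.size(); ++i) {
    List cc = caches[i];
    c.col.push_back(as<arma::mat>(cc["col"]));
    c.mask.push_back(as<arma::mat>(cc["mask"]));
    c.L.push_back(as<int>(cc["L"]));
    c.Cin.push_back(as<int>(cc["Cin"]));
    c.Lout.push_back(as<int>(cc["Lout"]));
  }
  c.features = features;
  c.logits = logits;
  DiscGrads g;
  arma::mat dlog, dfeat;
  const arma::mat* dlp = nullptr;
  const arma::mat* dfp = nullptr;
  if (dlogits_ != R_NilValue) {
    dlog = as<arma::mat>(dlogits_);
    dlp = &dlog;
  }
  if (dfeatures_ != R_NilValue) {
    dfeat = as<arma::mat>(dfeatures_);
    dfp = &dfeat;
  }
  disc_back(p, c, dlp, dfp, g, need_input_grad);
  return List::create(_["grads"] = disc_grads_to_list(g),
                      _["dX"] = need_input_grad ? wrap(g.dX) : R_NilValue);
}

// Fused discriminator minibatch: supervised loss on the labeled batch plus
// unsupervised adversarial loss on real (unlabeled) and generated batches;
// returns both loss values and the summed parameter gradients.
// [[Rcpp::export]]
List disc_step_grads_cpp(const arma::mat& Xlab, const arma::ivec& y,
                         const arma::mat& Xunl, const arma::mat& Xfake,
                         List conv, const arma::mat& headW,
                         const arma::vec& headb, int kernel, int stride,
                         double slope) {
  DiscParams p = disc_unpack(conv, headW, headb, kernel, stride, slope);
  DiscGrads g;

  // supervised: -mean log softmax(y)
  DiscCache cl;
  disc_run(p, Xlab, cl);
  const int nl = Xlab.n_rows;
  arma::vec s2l, s3l;
  lse23(cl.logits, s2l, s3l);
  double sup = 0.0;
  arma::mat dlog_l(nl, 2);
  for (int i = 0; i < nl; ++i) {
    const int yi = y(i) - 1;
    sup += s2l(i) - cl.logits(i, yi);
    dlog_l(i, 0) = std::exp(cl.logits(i, 0) - s2l(i));
    dlog_l(i, 1) = std::exp(cl.logits(i, 1) - s2l(i));
    dlog_l(i, yi) -= 1.0;
  }
  sup /= nl;
  dlog_l /= nl;
  disc_back(p, cl, &dlog_l, nullptr, g, false);

  // unsupervised, real side: mean(lse3 - lse2)
  DiscCache cu;
  disc_run(p, Xunl, cu);
  const int nu = Xunl.n_rows;
  arma::vec s2u, s3u;
  lse23(cu.logits, s2u, s3u);
  double unsup = arma::mean(s3u - s2u);
  arma::mat dlog_u(nu, 2);
  for (int i = 0; i < nu; ++i) {
    for (int j = 0; j < 2; ++j) {
      dlog_u(i, j) = (std::exp(cu.logits(i, j) - s3u(i)) -
                      std::exp(cu.logits(i, j) - s2u(i))) / nu;
    }
  }
  disc_back(p, cu, &dlog_u, nullptr, g, false);

  // unsupervised, fake side: mean(lse3)
  DiscCache cf;
  disc_run(p, Xfake, cf);
  const int nf = Xfake.n_rows;
  arma::vec s2f, s3f;
  lse23(cf.logits, s2f, s3f);
  unsup += arma::mean(s3f);
  arma::mat dlog_f(nf, 2);
  for (int i = 0; i < nf; ++i) {
    for (int j = 0; j < 2; ++j) {
      dlog_f(i, j) = std::exp(cf.logits(i, j) - s3f(i)) / nf;
    }
  }
  disc_back(p, cf, &dlog_f, nullptr, g, false);

  return List::create(_["sup"] = sup, _["unsup"] = unsup,
                      _["grads"] = disc_grads_to_list(g));
}

// Fused supervised-only minibatch (baseline model).
// [[Rcpp::export]]
List disc_sup_grads_cpp(const arma::mat& Xlab, const arma::ivec& y,
                        List conv, const arma::mat& headW,
                        const arma::vec& headb, int kernel, int stride,
                        double slope) {
  DiscParams p = disc_unpack(conv, headW, headb, kernel, stride, slope);
  DiscGrads g;
  DiscCache cl;
  disc_run(p, Xlab, cl);
  const int nl = Xlab.n_rows;
  arma::vec s2l, s3l;
  lse23(cl.logits, s2l, s3l);
  double sup = 0.0;
  arma::mat dlog_l(nl, 2);
  for (int i = 0; i < nl; ++i) {
    const int yi = y(i) - 1;
    sup += s2l(i) - cl.logits(i, yi);
    dlog_l(i, 0) = std::exp(cl.logits(i, 0) - s2l(i));
    dlog_l(i, 1) = std::exp(cl.logits(i, 1) - s2l(i));
    dlog_l(i, yi) -= 1.0;
  }
  sup /= nl;
  dlog_l /= nl;
  disc_back(p, cl, &dlog_l, nullptr, g, false);
  return List::create(_["sup"] = sup,
                      _["grads"] = disc_grads_to_list(g));
}

// ---- generator -----------------------------------------------------------

static const double BN_EPS_CPP = 1e-5;
static const double BN_MOM_CPP = 0.1;

struct GenCache {
  std::vector<arma::mat> X, xhat, mlk, dmask;
  std::vector<arma::vec> inv_sd;
  std::vector<bool> has_mask;
  arma::mat H_last, t_out, out;
};

static List gen_run(List layers, List bn_state, const arma::mat& outW,
                    const arma::vec& outb, double slope, bool training,
                    double dropout, const arma::mat& Z, GenCache& c) {
  arma::mat H = Z;
  const int n = Z.n_rows;
  List bn_new(layers.size());
  for (int i = 0; i < layers.size(); ++i) {
    List ly = layers[i];
    arma::mat W = ly["W"];
    arma::vec b = ly["b"];
    arma::vec gamma = ly["gamma"];
    arma::vec beta = ly["beta"];
    List st = bn_state[i];
    arma::vec rmean = st["mean"];
    arma::vec rvar = st["var"];
    arma::mat lin = H * W;
    lin.each_row() += b.t();
    arma::mat xhat;
    arma::vec inv_sd;
    if (training) {
      arma::vec mu = arma::mean(lin, 0).t();
      arma::mat ctr = lin;
      ctr.each_row() -= mu.t();
      arma::vec v = arma::mean(ctr % ctr, 0).t();
      inv_sd = 1.0 / arma::sqrt(v + BN_EPS_CPP);
      xhat = ctr;
      xhat.each_row() %= inv_sd.t();
      if (n > 1) {
        rmean = (1 - BN_MOM_CPP) * rmean + BN_MOM_CPP * mu;
        rvar = (1 - BN_MOM_CPP) * rvar +
               BN_MOM_CPP * v * ((double)n / (n - 1));
      }
    } else {
      inv_sd = 1.0 / arma::sqrt(rvar + BN_EPS_CPP);
      xhat = lin;
      xhat.each_row() -= rmean.t();
      xhat.each_row() %= inv_sd.t();
    }
    bn_new[i] = List::create(_["mean"] = rmean, _["var"] = rvar);
    arma::mat bn = xhat;
    bn.each_row() %= gamma.t();
    bn.each_row() += beta.t();
    arma::mat mlk = leaky_mask(bn, slope);
    arma::mat act = bn % mlk;
    bool has_mask = training && dropout > 0;
    if (has_mask) {
      // inverted dropout, drawn from the R RNG stream (layer by layer)
      arma::mat dm(act.n_rows, act.n_cols);
      const double keep = 1.0 - dropout;
      double* dp = dm.memptr();
      for (arma::uword e = 0; e < dm.n_elem; ++e) {
        dp[e] = (unif_rand() >= dropout) ? 1.0 / keep : 0.0;
      }
      act %= dm;
      c.dmask.push_back(std::move(dm));
    } else {
      c.dmask.push_back(arma::mat());
    }
    c.has_mask.push_back(has_mask);
    c.X.push_back(H);
    c.xhat.push_back(std::move(xhat));
    c.inv_sd.push_back(inv_sd);
    c.mlk.push_back(std::move(mlk));
    H = act;
  }
  c.H_last = H;
  arma::mat lin_out = H * outW;
  lin_out.each_row() += outb.t();
  c.t_out = arma::tanh(lin_out);
  c.out = (c.t_out + 1.0) / 2.0;
  return bn_new;
}

static List gen_back(List layers, const arma::mat& outW, const GenCache& c,
                     const arma::mat& dOut) {
  arma::mat dt = dOut % (0.5 * (1.0 - c.t_out % c.t_out));
  arma::mat goutW = c.H_last.t() * dt;
  arma::vec goutb = arma::sum(dt, 0).t();
  arma::mat dH = dt * outW.t();
  List glayers(layers.size());
  for (int i = layers.size() - 1; i >= 0; --i) {
    List ly = layers[i];
    arma::mat W = ly["W"];
    arma::vec gamma = ly["gamma"];
    if (c.has_mask[i]) dH %= c.dmask[i];
    dH %= c.mlk[i];
    arma::vec dgamma = arma::sum(dH % c.xhat[i], 0).t();
    arma::vec dbeta = arma::sum(dH, 0).t();
    arma::mat dxhat = dH;
    dxhat.each_row() %= gamma.t();
    const double n = (double)dH.n_rows;
    arma::rowvec s1 = arma::sum(dxhat, 0);
    arma::rowvec s2 = arma::sum(dxhat % c.xhat[i], 0);
    arma::mat dlin = n * dxhat;
    dlin.each_row() -= s1;
    arma::mat x2 = c.xhat[i];
    x2.each_row() %= s2;
    dlin -= x2;
    dlin.each_row() %= (c.inv_sd[i] / n).t();
    glayers[i] = List::create(_["W"] = c.X[i].t() * dlin,
                              _["b"] = arma::sum(dlin, 0).t(),
                              _["gamma"] = dgamma, _["beta"] = dbeta);
    dH = dlin * W.t();
  }
  return List::create(_["layers"] = glayers,
                      _["out"] = List::create(_["W"] = goutW,
                                              _["b"] = goutb));
}

// [[Rcpp::export]]
List gen_fwd_cpp(const arma::mat& Z, List layers, List bn_state,
                 const arma::mat& outW, const arma::vec& outb, double slope,
                 bool training, double dropout) {
  GenCache c;
  List bn_new = gen_run(layers, bn_state, outW, outb, slope, training,
                        dropout, Z, c);
  List caches(layers.size());
  for (int i = 0; i < layers.size(); ++i) {
    caches[i] = List::create(
      _["X"] = c.X[i], _["xhat"] = c.xhat[i], _["inv_sd"] = c.inv_sd[i],
      _["mlk"] = c.mlk[i],
      _["dmask"] = c.has_mask[i] ? wrap(c.dmask[i]) : R_NilValue);
  }
  return List::create(_["out"] = c.out, _["bn_state"] = bn_new,
                      _["caches"] = caches, _["H_last"] = c.H_last,
                      _["t_out"] = c.t_out);
}

// [[Rcpp::export]]
List gen_bwd_cpp(List layers, const arma::mat& outW, List caches,
                 const arma::mat& H_last, const arma::mat& t_out,
                 const arma::mat& dOut) {
  GenCache c;
  for (int i = 0; i < caches.size(); ++i) {
    List cc = caches[i];
    c.X.push_back(as<arma::mat>(cc["X"]));
    c.xhat.push_back(as<arma::mat>(cc["xhat"]));
    c.inv_sd.push_back(as<arma::vec>(cc["inv_sd"]));
    c.mlk.push_back(as<arma::mat>(cc["mlk"]));
    SEXP dm_ = cc["dmask"];
    if (dm_ != R_NilValue) {
      c.dmask.push_back(as<arma::mat>(dm_));
      c.has_mask.push_back(true);
    } else {
      c.dmask.push_back(arma::mat());
      c.has_mask.push_back(false);
    }
  }
  c.H_last = H_last;
  c.t_out = t_out;
  return gen_back(layers, outW, c, dOut);
}

// Generate a batch without exporting caches (cheap path for the
// discriminator step's synthetic minibatch).
// [[Rcpp::export]]
List gen_sample_cpp(const arma::mat& Z, List layers, List bn_state,
                    const arma::mat& outW, const arma::vec& outb,
                    double slope, bool training, double dropout) {
  GenCache c;
  List bn_new = gen_run(layers, bn_state, outW, outb, slope, training,
                        dropout, Z, c);
  return List::create(_["out"] = c.out, _["bn_state"] = bn_new);
}

// Fused generator minibatch: generate from Z (training mode), run the
// discriminator on the generated and the real batch, form the
// feature-matching loss on the chosen feature source, and backpropagate
// through the discriminator (parameters frozen) into the generator.
// [[Rcpp::export]]
List gen_step_grads_cpp(const arma::mat& Z, List layers, List bn_state,
                        const arma::mat& outW, const arma::vec& outb,
                        double gslope, double dropout, const arma::mat& Xreal,
                        List conv, const arma::mat& headW,
                        const arma::vec& headb, int kernel, int stride,
                        double dslope, bool use_logits) {
  GenCache gc;
  List bn_new = gen_run(layers, bn_state, outW, outb, gslope, true, dropout,
                        Z, gc);
  DiscParams p = disc_unpack(conv, headW, headb, kernel, stride, dslope);
  DiscCache cr, cf;
  disc_run(p, Xreal, cr);
  disc_run(p, gc.out, cf);
  arma::rowvec diff;
  const int nf = gc.out.n_rows;
  DiscGrads g;
  if (use_logits) {
    diff = arma::mean(cr.logits, 0) - arma::mean(cf.logits, 0);
    arma::mat dlog = arma::repmat(-2.0 * diff / nf, nf, 1);
    disc_back(p, cf, &dlog, nullptr, g, true, false);
  } else {
    diff = arma::mean(cr.features, 0) - arma::mean(cf.features, 0);
    arma::mat dfeat = arma::repmat(-2.0 * diff / nf, nf, 1);
    disc_back(p, cf, nullptr, &dfeat, g, true, false);
  }
  const double loss = arma::dot(diff, diff);
  List ggrads = gen_back(layers, outW, gc, g.dX);
  return List::create(_["loss"] = loss, _["grads"] = ggrads,
                      _["bn_state"] = bn_new);
}
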
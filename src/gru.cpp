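// BiGRU classifier core: forward pass, backpropagation through time,
// and an Adam training loop. Kept in compiled code because training
// iterates over tens of thousands of variable-length sentences.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

const double PCLIP = 1e-7;

struct Cell {
  mat Wr, Ur, Wz, Uz, Wh, Uh;
  vec br, bz, bh;
};

Cell cellFromList(const List& l) {
  Cell c;
  c.Wr = as<mat>(l["Wr"]); c.Ur = as<mat>(l["Ur"]); c.br = as<vec>(l["br"]);
  c.Wz = as<mat>(l["Wz"]); c.Uz = as<mat>(l["Uz"]); c.bz = as<vec>(l["bz"]);
  c.Wh = as<mat>(l["Wh"]); c.Uh = as<mat>(l["Uh"]); c.bh = as<vec>(l["bh"]);
  return c;
}

List cellToList(const Cell& c) {
  return List::create(
    _["Wr"] = c.Wr, _["Ur"] = c.Ur, _["br"] = c.br,
    _["Wz"] = c.Wz, _["Uz"] = c.Uz, _["bz"] = c.bz,
    _["Wh"] = c.Wh, _["Uh"] = c.Uh, _["bh"] = c.bh);
}

Cell zerosLike(const Cell& c) {
  Cell g;
  g.Wr = arma::zeros<mat>(c.Wr.n_rows, c.Wr.n_cols);
  g.Ur = arma::zeros<mat>(c.Ur.n_rows, c.Ur.n_cols);
  g.br = arma::zeros<vec>(c.br.n_elem);
  g.Wz = arma::zeros<mat>(c.Wz.n_rows, c.Wz.n_cols);
  g.Uz = arma::zeros<mat>(c.Uz.n_rows, c.Uz.n_cols);
  g.bz = arma::zeros<vec>(c.bz.n_elem);
  g.Wh = arma::zeros<mat>(c.Wh.n_rows, c.Wh.n_cols);
  g.Uh = arma::zeros<mat>(c.Uh.n_rows, c.Uh.n_cols);
  g.bh = arma::zeros<vec>(c.bh.n_elem);
  return g;
}

inline vec sigmoidv(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Trajectories of one directional pass; H columns are h_0 .. h_T.
struct CellCache {
  mat R, Z, Hc, H;
};

// X is D x T (columns are time steps). Returns final hidden state.
// The input projections W* X for all time steps are computed as three
// matrix products; the recurrent part stays sequential.
vec cellForward(const Cell& c, const mat& X, CellCache* cache) {
  const uword T = X.n_cols, H = c.br.n_elem;
  vec h(H, arma::fill::zeros);
  mat Ar = c.Wr * X; Ar.each_col() += c.br;
  mat Az = c.Wz * X; Az.each_col() += c.bz;
  mat Ah = c.Wh * X; Ah.each_col() += c.bh;
  if (cache) {
    cache->R.set_size(H, T); cache->Z.set_size(H, T);
    cache->Hc.set_size(H, T); cache->H.set_size(H, T + 1);
    cache->H.col(0) = h;
  }
  vec r(H), z(H), hc(H), rh(H);
  for (uword t = 0; t < T; ++t) {
    r = Ar.unsafe_col(t) + c.Ur * h;
    r = 1.0 / (1.0 + arma::exp(-r));
    z = Az.unsafe_col(t) + c.Uz * h;
    z = 1.0 / (1.0 + arma::exp(-z));
    rh = r % h;
    hc = arma::tanh(Ah.unsafe_col(t) + c.Uh * rh);
    h = z % h + (1.0 - z) % hc;
    if (cache) {
      cache->R.col(t) = r; cache->Z.col(t) = z;
      cache->Hc.col(t) = hc; cache->H.col(t + 1) = h;
    }
  }
  return h;
}

// Backprop through time; gT is dL/dh_T. Accumulates into g; fills dX
// (D x T) with gradients w.r.t. the inputs when dX != nullptr. The
// per-step work is limited to three mat-vec products plus elementwise
// arithmetic; all weight-gradient accumulation is batched into matrix
// products over the whole sentence.
void cellBackward(const Cell& c, const mat& X, const CellCache& cc,
                  const vec& gT, Cell& g, mat* dX) {
  const uword T = X.n_cols, H = gT.n_elem;
  mat DAr(H, T), DAz(H, T), DAh(H, T);
  vec gh = gT, dar(H), daz(H), dah(H), drh(H);
  for (uword t = T; t-- > 0;) {
    const auto hprev = cc.H.unsafe_col(t);
    const auto r = cc.R.unsafe_col(t);
    const auto z = cc.Z.unsafe_col(t);
    const auto hc = cc.Hc.unsafe_col(t);
    daz = gh % (hprev - hc) % z % (1.0 - z);
    dah = gh % (1.0 - z) % (1.0 - hc % hc);
    drh = c.Uh.t() * dah;              // d wrt (r .* hprev)
    dar = drh % hprev % r % (1.0 - r);
    gh = gh % z + drh % r + c.Ur.t() * dar + c.Uz.t() * daz;
    DAr.col(t) = dar; DAz.col(t) = daz; DAh.col(t) = dah;
  }
  const mat Hprev = cc.H.cols(0, T - 1);
  g.Wr += DAr * X.t();
  g.Ur += DAr * Hprev.t();
  g.br += arma::sum(DAr, 1);
  g.Wz += DAz * X.t();
  g.Uz += DAz * Hprev.t();
  g.bz += arma::sum(DAz, 1);
  g.Wh += DAh * X.t();
  g.Uh += DAh * (cc.R % Hprev).t();
  g.bh += arma::sum(DAh, 1);
  if (dX) *dX = c.Wr.t() * DAr + c.Wz.t() * DAz + c.Wh.t() * DAh;
}

// Gather embedding columns for a sentence. Token ids are 1-based row
// indices into E (V x D); id 0 denotes out-of-vocabulary -> zero vector.
mat gatherX(const arma::ivec& tok, const mat& E) {
  const uword T = tok.n_elem, D = E.n_cols;
  mat X(D, T, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    int id = tok[t];
    if (id > 0) X.col(t) = E.row(id - 1).t();
  }
  return X;
}

struct Model {
  Cell fwd, bwd;
  vec hw;
  double hb;
};

// forward pass for one sentence; returns probability, fills caches
double modelForward(const Model& m, const mat& X,
                    CellCache* cf, CellCache* cb, vec* concat) {
  vec hf = cellForward(m.fwd, X, cf);
  mat Xr = arma::fliplr(X);
  vec hbk = cellForward(m.bwd, Xr, cb);
  vec u = arma::join_cols(hf, hbk);
  if (concat) *concat = u;
  double logit = arma::dot(m.hw, u) + m.hb;
  return 1.0 / (1.0 + std::exp(-logit));
}

double dataLoss(double p, int y) {
  double pc = std::min(1.0 - PCLIP, std::max(PCLIP, p));
  return -(y * std::log(pc) + (1 - y) * std::log(1.0 - pc));
}

struct Grads {
  Cell fwd, bwd;
  vec hw;
  double hb;
  mat gE;                 // dense, only touched rows meaningful
  std::vector<uword> touched;
};

void addExampleGrad(const Model& m, const arma::ivec& tok, const mat& E,
                    int y, const vec& dropMask, bool trainEmbed, Grads& g,
                    double& lossAcc) {
  mat X = gatherX(tok, E);
  CellCache cf, cb;
  vec u;
  vec hf = cellForward(m.fwd, X, &cf);
  mat Xr = arma::fliplr(X);
  vec hbk = cellForward(m.bwd, Xr, &cb);
  u = arma::join_cols(hf, hbk);
  vec ud = u % dropMask;
  double logit = arma::dot(m.hw, ud) + m.hb;
  double p = 1.0 / (1.0 + std::exp(-logit));
  lossAcc += dataLoss(p, y);
  double dlogit = p - static_cast<double>(y);
  g.hw += dlogit * ud;
  g.hb += dlogit;
  vec du = dlogit * (m.hw % dropMask);
  const uword H = hf.n_elem;
  vec gTf = du.subvec(0, H - 1);
  vec gTb = du.subvec(H, 2 * H - 1);
  if (trainEmbed) {
    mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
    mat dXr(X.n_rows, X.n_cols, arma::fill::zeros);
    cellBackward(m.fwd, X, cf, gTf, g.fwd, &dX);
    cellBackward(m.bwd, Xr, cb, gTb, g.bwd, &dXr);
    dX += arma::fliplr(dXr);
    for (uword t = 0; t < X.n_cols; ++t) {
      int id = tok[t];
      if (id > 0) {
        g.gE.row(id - 1) += dX.col(t).t();
        g.touched.push_back(id - 1);
      }
    }
  } else {
    cellBackward(m.fwd, X, cf, gTf, g.fwd, nullptr);
    cellBackward(m.bwd, Xr, cb, gTb, g.bwd, nullptr);
  }
}

// collect pointers to every element of the weight matrices that take
// part in the decay norm (all non-bias weights; plus E when trainable)
double decayNorm(const Model& m, const mat& E, bool trainEmbed) {
  double s = 0.0;
  s += arma::accu(arma::square(m.fwd.Wr)) + arma::accu(arma::square(m.fwd.Ur));
  s += arma::accu(arma::square(m.fwd.Wz)) + arma::accu(arma::square(m.fwd.Uz));
  s += arma::accu(arma::square(m.fwd.Wh)) + arma::accu(arma::square(m.fwd.Uh));
  s += arma::accu(arma::square(m.bwd.Wr)) + arma::accu(arma::square(m.bwd.Ur));
  s += arma::accu(arma::square(m.bwd.Wz)) + arma::accu(arma::square(m.bwd.Uz));
  s += arma::accu(arma::square(m.bwd.Wh)) + arma::accu(arma::square(m.bwd.Uh));
  s += arma::dot(m.hw, m.hw);
  if (trainEmbed) s += arma::accu(arma::square(E));
  return std::sqrt(s);
}

// decay_form: 0 = alpha * ||w||_2 (unsquared, as printed), 1 = alpha * ||w||_2^2
void addDecayGrad(const Model& m, const mat& E, bool trainEmbed,
                  double alpha, int decayForm, Grads& g, double& lossAcc) {
  if (alpha <= 0.0) return;
  double nrm = decayNorm(m, E, trainEmbed);
  double coef;
  if (decayForm == 0) {
    lossAcc += alpha * nrm;
    if (nrm < 1e-12) return;
    coef = alpha / nrm;
  } else {
    lossAcc += alpha * nrm * nrm;
    coef = 2.0 * alpha;
  }
  g.fwd.Wr += coef * m.fwd.Wr; g.fwd.Ur += coef * m.fwd.Ur;
  g.fwd.Wz += coef * m.fwd.Wz; g.fwd.Uz += coef * m.fwd.Uz;
  g.fwd.Wh += coef * m.fwd.Wh; g.fwd.Uh += coef * m.fwd.Uh;
  g.bwd.Wr += coef * m.bwd.Wr; g.bwd.Ur += coef * m.bwd.Ur;
  g.bwd.Wz += coef * m.bwd.Wz; g.bwd.Uz += coef * m.bwd.Uz;
  g.bwd.Wh += coef * m.bwd.Wh; g.bwd.Uh += coef * m.bwd.Uh;
  g.hw += coef * m.hw;
  if (trainEmbed) {
    g.gE += coef * E;
    g.touched.clear();
    for (uword i = 0; i < E.n_rows; ++i) g.touched.push_back(i);
  }
}

std::vector<arma::ivec> sentencesToIvec(const List& sentences) {
  std::vector<arma::ivec> out;
  out.reserve(sentences.size());
  for (R_xlen_t i = 0; i < sentences.size(); ++i)
    out.push_back(as<arma::ivec>(sentences[i]));
  return out;
}

} // namespace

// [[Rcpp::export]]
arma::vec cpp_gru_forward(const arma::mat& X, const List& cell) {
  Cell c = cellFromList(cell);
  return cellForward(c, X, nullptr);
}

// [[Rcpp::export]]
arma::mat cpp_gru_forward_trajectory(const arma::mat& X, const List& cell) {
  Cell c = cellFromList(cell);
  CellCache cc;
  cellForward(c, X, &cc);
  return cc.H; // H x (T+1), columns h_0..h_T
}

// [[Rcpp::export]]
arma::vec cpp_bigru_forward(const arma::mat& X, const List& fwd, const List& bwd) {
  Model m{cellFromList(fwd), cellFromList(bwd), vec(), 0.0};
  vec hf = cellForward(m.fwd, X, nullptr);
  mat Xr = arma::fliplr(X);
  vec hb = cellForward(m.bwd, Xr, nullptr);
  return arma::join_cols(hf, hb);
}

// [[Rcpp::export]]
NumericVector cpp_predict(const List& sentences, const arma::mat& E,
                          const List& fwd, const List& bwd,
                          const arma::vec& hw, double hb) {
  Model m{cellFromList(fwd), cellFromList(bwd), hw, hb};
  std::vector<arma::ivec> toks = sentencesToIvec(sentences);
  NumericVector out(toks.size());
  for (size_t i = 0; i < toks.size(); ++i) {
    mat X = gatherX(toks[i], E);
    out[i] = modelForward(m, X, nullptr, nullptr, nullptr);
  }
  return out;
}

// Loss and analytic gradients with dropout disabled (for gradient checks
// and as the building block the training loop mirrors).
// [[Rcpp::export]]
List cpp_loss_grad(const List& sentences, const IntegerVector& labels,
                   const arma::mat& E, const List& fwd, const List& bwd,
                   const arma::vec& hw, double hb, double alpha,
                   int decay_form, bool train_embed) {
  Model m{cellFromList(fwd), cellFromList(bwd), hw, hb};
  std::vector<arma::ivec> toks = sentencesToIvec(sentences);
  Grads g;
  g.fwd = zerosLike(m.fwd); g.bwd = zerosLike(m.bwd);
  g.hw = arma::zeros<vec>(hw.n_elem); g.hb = 0.0;
  if (train_embed) g.gE = arma::zeros<mat>(E.n_rows, E.n_cols);
  double loss = 0.0;
  vec mask = arma::ones<vec>(hw.n_elem);
  for (size_t i = 0; i < toks.size(); ++i)
    addExampleGrad(m, toks[i], E, labels[i], mask, train_embed, g, loss);
  addDecayGrad(m, E, train_embed, alpha, decay_form, g, loss);
  List out = List::create(
    _["loss"] = loss,
    _["fwd"] = cellToList(g.fwd), _["bwd"] = cellToList(g.bwd),
    _["hw"] = g.hw, _["hb"] = g.hb);
  if (train_embed) out["gE"] = g.gE;
  return out;
}

namespace {

struct AdamState {
  std::vector<mat> mM, mV;
  long t = 0;
};

void adamStep(std::vector<mat*>& params, std::vector<mat*>& grads,
              AdamState& st, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.t += 1;
  double c1 = 1.0 - std::pow(b1, st.t), c2 = 1.0 - std::pow(b2, st.t);
  for (size_t i = 0; i < params.size(); ++i) {
    mat& g = *grads[i];
    st.mM[i] = b1 * st.mM[i] + (1.0 - b1) * g;
    st.mV[i] = b2 * st.mV[i] + (1.0 - b2) * (g % g);
    *params[i] -= lr * (st.mM[i] / c1) / (arma::sqrt(st.mV[i] / c2) + eps);
  }
}

void collectParamPtrs(Cell& c, std::vector<mat*>& v) {
  v.push_back(&c.Wr); v.push_back(&c.Ur);
  v.push_back(&c.Wz); v.push_back(&c.Uz);
  v.push_back(&c.Wh); v.push_back(&c.Uh);
}
void collectBiasPtrs(Cell& c, std::vector<mat*>& v) {
  // arma::vec derives from arma::mat (one column), so the upcast is safe
  v.push_back(&c.br);
  v.push_back(&c.bz);
  v.push_back(&c.bh);
}

} // namespace

// Adam training loop. Sentences are integer token-id vectors (1-based,
// 0 = OOV). Returns trained weights, the (possibly updated) embedding
// matrix, and the per-epoch mean data loss.
// [[Rcpp::export]]
List cpp_train(const List& sentences, const IntegerVector& labels,
               arma::mat E, const List& fwd, const List& bwd,
               const arma::vec& hw0, double hb0,
               double lr, int epochs, int batch, double dropout,
               double alpha, int decay_form, bool train_embed, int seed,
               int lr_schedule) {
  Model m{cellFromList(fwd), cellFromList(bwd), hw0, hb0};
  std::vector<arma::ivec> toks = sentencesToIvec(sentences);
  const size_t n = toks.size();
  const uword H2 = m.hw.n_elem;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // parameter / gradient registries (biases are updated but excluded
  // from the decay norm inside addDecayGrad)
  Grads g;
  g.fwd = zerosLike(m.fwd); g.bwd = zerosLike(m.bwd);
  g.hw = arma::zeros<vec>(H2); g.hb = 0.0;
  if (train_embed) g.gE = arma::zeros<mat>(E.n_rows, E.n_cols);
  mat hwM(m.hw.n_elem, 1), hbM(1, 1); // head as matrices for the registry
  hwM.col(0) = m.hw; hbM(0, 0) = m.hb;
  mat ghwM(m.hw.n_elem, 1, arma::fill::zeros), ghbM(1, 1, arma::fill::zeros);

  std::vector<mat*> params, grads;
  collectParamPtrs(m.fwd, params); collectBiasPtrs(m.fwd, params);
  collectParamPtrs(m.bwd, params); collectBiasPtrs(m.bwd, params);
  collectParamPtrs(g.fwd, grads);  collectBiasPtrs(g.fwd, grads);
  collectParamPtrs(g.bwd, grads);  collectBiasPtrs(g.bwd, grads);
  params.push_back(&hwM); params.push_back(&hbM);
  grads.push_back(&ghwM); grads.push_back(&ghbM);
  if (train_embed) { params.push_back(&E); grads.push_back(&g.gE); }

  AdamState st;
  for (auto* p : params) {
    st.mM.push_back(arma::zeros<mat>(p->n_rows, p->n_cols));
    st.mV.push_back(arma::zeros<mat>(p->n_rows, p->n_cols));
  }

  std::vector<size_t> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = i;

  NumericVector epochLoss(epochs);
  const long nBatches = (n + batch - 1) / batch;
  const long totalSteps = std::max(1L, nBatches * (long)epochs);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epLoss = 0.0;
    for (size_t start = 0; start < n; start += batch) {
      // lr_schedule 0: constant; 1: one-cycle (linear warmup over the
      // first 20% of steps to lr, then linear decay to lr/20)
      double lrNow = lr;
      if (lr_schedule == 1) {
        double frac = (double)step / (double)totalSteps;
        if (frac < 0.2) lrNow = lr * (0.05 + 0.95 * frac / 0.2);
        else lrNow = lr * (1.0 - 0.95 * (frac - 0.2) / 0.8);
      }
      ++step;
      size_t stop = std::min(n, start + static_cast<size_t>(batch));
      // zero grads
      for (auto* gp : grads) gp->zeros();
      g.hw.zeros(); g.hb = 0.0;
      double loss = 0.0;
      for (size_t j = start; j < stop; ++j) {
        size_t idx = order[j];
        vec mask(H2);
        if (dropout > 0.0) {
          for (uword k = 0; k < H2; ++k)
            mask[k] = (unif(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
        } else {
          mask.ones();
        }
        addExampleGrad(m, toks[idx], E, labels[idx], mask, train_embed,
                       g, loss);
      }
      epLoss += loss;
      addDecayGrad(m, E, train_embed, alpha, decay_form, g, loss);
      ghwM.col(0) = g.hw; ghbM(0, 0) = g.hb;
      adamStep(params, grads, st, lrNow);
      m.hw = hwM.col(0); m.hb = hbM(0, 0);
      Rcpp::checkUserInterrupt();
    }
    epochLoss[ep] = epLoss / static_cast<double>(n);
  }

  return List::create(
    _["fwd"] = cellToList(m.fwd), _["bwd"] = cellToList(m.bwd),
    _["hw"] = m.hw, _["hb"] = m.hb, _["E"] = E,
    _["epoch_loss"] = epochLoss);
}
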
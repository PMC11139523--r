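// Core numerics: the explainable-autoencoder trainer (nonlinear encoder with
// batch normalization and softplus, linear non-negative decoder, Poisson
// negative log-likelihood + minimum-volume log-determinant penalty, Adam with
// early stopping) and a Jonker-Volgenant shortest-augmenting-path solver for
// the linear assignment problem used by consensus clustering and signature
// matching.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------------------------------------------------------------------------
// Linear assignment (min cost), cost is n x m with n <= m.
// Classic Hungarian/JV with dual potentials, O(n^2 m).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_lap")]]
Rcpp::IntegerVector cpp_lap(const arma::mat& cost) {
  const int n = cost.n_rows, m = cost.n_cols;
  if (n > m) Rcpp::stop("cost matrix must have nrow <= ncol");
  if (!cost.is_finite()) Rcpp::stop("cost matrix has non-finite entries");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  Rcpp::IntegerVector ans(n);
  for (int j = 1; j <= m; ++j) if (p[j] > 0) ans[p[j] - 1] = j; // 1-based cols
  return ans;
}

// ---------------------------------------------------------------------------
// Autoencoder
// ---------------------------------------------------------------------------

static inline mat softplus(const mat& x) {
  // numerically stable log(1 + exp(x))
  mat out = x;
  out.transform([](double v) {
    if (v > 30.0) return v;
    if (v < -30.0) return std::exp(v);
    return std::log1p(std::exp(v));
  });
  return out;
}

// softplus and its derivative (the logistic) from a single exp evaluation
static inline void softplus_sig(const mat& x, mat& sp, mat& sg) {
  sp.set_size(x.n_rows, x.n_cols);
  sg.set_size(x.n_rows, x.n_cols);
  const double* px = x.memptr();
  double* pp = sp.memptr();
  double* pg = sg.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) {
    double v = px[i];
    if (v > 30.0) { pp[i] = v; pg[i] = 1.0; }
    else if (v < -30.0) { double e = std::exp(v); pp[i] = e; pg[i] = e; }
    else { double e = std::exp(v); pp[i] = std::log1p(e); pg[i] = e / (1.0 + e); }
  }
}

static inline mat sigmoid(const mat& x) {
  mat out = x;
  out.transform([](double v) {
    if (v >= 0.0) { double e = std::exp(-v); return 1.0 / (1.0 + e); }
    double e = std::exp(v); return e / (1.0 + e);
  });
  return out;
}

struct Adam {
  mat m, v;
  void init(const mat& w) { m.zeros(w.n_rows, w.n_cols); v.zeros(w.n_rows, w.n_cols); }
  void step(mat& w, const mat& g, double lr, double t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * square(g);
    mat mh = m / (1.0 - std::pow(0.9, t));
    mat vh = v / (1.0 - std::pow(0.999, t));
    w -= lr * mh / (sqrt(vh) + 1e-8);
  }
};

struct XAEParams {
  std::vector<mat> W;      // 3 hidden dense layers
  std::vector<rowvec> b, gam, bet, rmean, rvar;
  mat W4; rowvec b4;       // latent dense layer
  mat Wd;                  // decoder 96 x k, >= 0
  double c;                // latent activation scale
};

static const double BN_EPS = 1e-3;
static const double BN_MOM = 0.9;

// forward pass in inference mode (running BN statistics)
static void forward_eval(const XAEParams& P, const mat& X, mat& Z, mat& Xhat) {
  mat A = X;
  for (size_t l = 0; l < P.W.size(); ++l) {
    mat Zl = A * P.W[l];
    Zl.each_row() += P.b[l];
    rowvec invstd = 1.0 / sqrt(P.rvar[l] + BN_EPS);
    Zl.each_row() -= P.rmean[l];
    Zl.each_row() %= invstd % P.gam[l];
    Zl.each_row() += P.bet[l];
    A = softplus(Zl);
  }
  mat Pre = A * P.W4;
  Pre.each_row() += P.b4;
  Z = P.c * softplus(Pre);
  Xhat = Z * P.Wd.t();
}

// set BN running statistics to the exact activation moments on X, so that
// inference-mode forward agrees with training-mode behaviour
static void recalibrate_bn(XAEParams& P, const mat& X) {
  mat A = X;
  for (size_t l = 0; l < P.W.size(); ++l) {
    mat Zl = A * P.W[l];
    Zl.each_row() += P.b[l];
    P.rmean[l] = mean(Zl, 0);
    P.rvar[l] = var(Zl, 1, 0);
    rowvec invstd = 1.0 / sqrt(P.rvar[l] + BN_EPS);
    Zl.each_row() -= P.rmean[l];
    Zl.each_row() %= invstd % P.gam[l];
    Zl.each_row() += P.bet[l];
    A = softplus(Zl);
  }
}

static double logdet_pen(const mat& Wd) {
  mat G = Wd.t() * Wd;
  G.diag() += 1.0;
  double val, sign;
  log_det(val, sign, G);
  return val;
}

static double eval_loss(const XAEParams& P, const mat& X, double eps,
                        double beta, double l1w, double l1a, bool frozen) {
  mat Z, Xhat;
  forward_eval(P, X, Z, Xhat);
  mat Xq = Xhat + eps; // xhat >= 0 by construction; eps keeps the log finite
  double nll = accu(-X % log(Xq) + Xhat);
  double pen = (!frozen && beta > 0) ? beta * logdet_pen(P.Wd) : 0.0;
  double l1 = l1w * accu(abs(P.W4)) + l1a * accu(Z) / X.n_rows;
  return nll / X.n_rows + pen + l1;
}

// [[Rcpp::export(name = ".cpp_xae_train")]]
Rcpp::List cpp_xae_train(const arma::mat& X, int k,
                         const arma::ivec& units,
                         double lr, int batch, int max_epochs, int patience,
                         double val_frac, double beta, double eps,
                         double l1w, double l1a, int seed,
                         Rcpp::Nullable<Rcpp::NumericMatrix> Wd0 = R_NilValue,
                         bool frozen = false) {
  const int N = X.n_rows, D = X.n_cols;
  if (units.n_elem != 3) Rcpp::stop("encoder must have exactly 3 hidden layers");
  if (k < 1) Rcpp::stop("latent dimension k must be >= 1");
  if (N < 2) Rcpp::stop("need at least 2 samples to train");

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto runif_mat = [&](int r, int c, double lo, double hi) {
    mat M(r, c);
    for (int j = 0; j < c; ++j) for (int i = 0; i < r; ++i)
      M(i, j) = lo + (hi - lo) * unif(rng);
    return M;
  };

  // ---- init ----
  XAEParams P;
  std::vector<int> widths = { D, (int)units[0], (int)units[1], (int)units[2] };
  for (int l = 0; l < 3; ++l) {
    double lim = std::sqrt(6.0 / (widths[l] + widths[l + 1]));
    P.W.push_back(runif_mat(widths[l], widths[l + 1], -lim, lim));
    P.b.push_back(rowvec(widths[l + 1], fill::zeros));
    P.gam.push_back(rowvec(widths[l + 1], fill::ones));
    P.bet.push_back(rowvec(widths[l + 1], fill::zeros));
    P.rmean.push_back(rowvec(widths[l + 1], fill::zeros));
    P.rvar.push_back(rowvec(widths[l + 1], fill::ones));
  }
  {
    double lim = std::sqrt(6.0 / (widths[3] + k));
    P.W4 = runif_mat(widths[3], k, -lim, lim);
    P.b4 = rowvec(k, fill::zeros);
  }
  // latent scale: initial exposures sum roughly to the mean mutation burden
  double nbar = mean(sum(X, 1));
  P.c = std::max(nbar, 1.0) / (k * std::log(2.0));
  if (Wd0.isNotNull()) {
    P.Wd = Rcpp::as<mat>(Wd0.get());
    if ((int)P.Wd.n_rows != D || (int)P.Wd.n_cols != k)
      Rcpp::stop("decoder init matrix has wrong shape");
    if (P.Wd.min() < 0) Rcpp::stop("decoder init matrix must be non-negative");
  } else {
    // seed decoder columns from random observed spectra (normalized rows of
    // X): starts the signatures on the data simplex at probability scale,
    // with run-to-run diversity from the row choice
    P.Wd.set_size(D, k);
    std::uniform_int_distribution<int> rowpick(0, N - 1);
    for (int j = 0; j < k; ++j) {
      rowvec r = X.row(rowpick(rng));
      double s = accu(r);
      if (s <= 0) r.ones();
      P.Wd.col(j) = (r / accu(r)).t();
    }
    P.Wd += runif_mat(D, k, 0.0, 0.1 / D); // break ties, avoid hard zeros
  }

  // ---- validation split ----
  std::vector<int> idx(N);
  std::iota(idx.begin(), idx.end(), 0);
  std::shuffle(idx.begin(), idx.end(), rng);
  int nval = (int)std::floor(val_frac * N);
  if (N - nval < 2) nval = 0;
  uvec val_idx(nval), tr_idx(N - nval);
  for (int i = 0; i < nval; ++i) val_idx[i] = idx[i];
  for (int i = nval; i < N; ++i) tr_idx[i - nval] = idx[i];
  mat Xtr = X.rows(tr_idx);
  mat Xval = nval > 0 ? X.rows(val_idx) : mat();
  const int ntr = Xtr.n_rows;
  if (batch > ntr) batch = ntr;
  if (batch < 2) batch = 2;

  // ---- Adam state ----
  std::vector<Adam> aW(3), ab(3), ag(3), abe(3);
  for (int l = 0; l < 3; ++l) {
    aW[l].init(P.W[l]); ab[l].init(mat(P.b[l])); ag[l].init(mat(P.gam[l])); abe[l].init(mat(P.bet[l]));
  }
  Adam aW4, ab4, aWd;
  aW4.init(P.W4); ab4.init(mat(P.b4)); aWd.init(P.Wd);

  auto adam_vec = [&](Adam& st, rowvec& w, const rowvec& g, double t) {
    mat wm(w), gm(g);
    st.step(wm, gm, lr, t);
    w = wm.row(0);
  };

  std::vector<int> reseed_count(k, 0);
  std::vector<double> hist_tr, hist_val;
  XAEParams best = P;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, tglob = 0, stopped = 0;

  std::vector<int> order(ntr);
  std::iota(order.begin(), order.end(), 0);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // cosine decay of the learning rate to a tenth of its initial value
    double lr_e = max_epochs > 1
      ? lr * (0.1 + 0.45 * (1.0 + std::cos(M_PI * (epoch - 1.0) / (max_epochs - 1.0))))
      : lr;
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < ntr; start += batch) {
      int end = std::min(start + batch, ntr);
      int B = end - start;
      if (B < 2) continue; // batch statistics undefined on a single row
      uvec bi(B);
      for (int i = 0; i < B; ++i) bi[i] = order[start + i];
      mat A0 = Xtr.rows(bi);

      // -- forward (training mode, batch statistics) --
      std::vector<mat> Acache(4), Zhat(3), Ycache(3), Ysig(3);
      std::vector<rowvec> invstd(3);
      Acache[0] = A0;
      for (int l = 0; l < 3; ++l) {
        mat Zl = Acache[l] * P.W[l];
        Zl.each_row() += P.b[l];
        rowvec mu = mean(Zl, 0);
        rowvec va = var(Zl, 1, 0); // population variance
        invstd[l] = 1.0 / sqrt(va + BN_EPS);
        P.rmean[l] = BN_MOM * P.rmean[l] + (1 - BN_MOM) * mu;
        P.rvar[l] = BN_MOM * P.rvar[l] + (1 - BN_MOM) * va;
        Zl.each_row() -= mu;
        Zl.each_row() %= invstd[l];
        Zhat[l] = Zl;
        mat Y = Zl;
        Y.each_row() %= P.gam[l];
        Y.each_row() += P.bet[l];
        Ycache[l] = Y;
        softplus_sig(Y, Acache[l + 1], Ysig[l]);
      }
      mat Pre = Acache[3] * P.W4;
      Pre.each_row() += P.b4;
      mat SPpre, SGpre;
      softplus_sig(Pre, SPpre, SGpre);
      mat Zlat = P.c * SPpre;
      mat Xhat = Zlat * P.Wd.t();
      mat Xq = Xhat + eps; // xhat >= 0 by construction

      // regularizers enter once per minibatch; the data term is summed over it
      double loss = accu(-A0 % log(Xq) + Xhat);
      mat Ginv;
      if (!frozen && beta > 0) {
        mat G = P.Wd.t() * P.Wd;
        G.diag() += 1.0;
        double val, sgn;
        log_det(val, sgn, G);
        loss += beta * val;
        Ginv = inv_sympd(G);
      }
      if (l1w > 0) loss += l1w * accu(abs(P.W4));
      if (l1a > 0) loss += l1a * accu(Zlat);
      ep_loss += loss / B;
      nb++;
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", epoch);

      // -- backward --
      tglob++;
      mat dXhat = 1.0 - A0 / Xq;               // d/dxhat of sum(-x log(xhat+eps) + xhat)
      mat dWd;
      if (!frozen) {
        dWd = dXhat.t() * Zlat;
        if (beta > 0) dWd += 2.0 * beta * P.Wd * Ginv;
      }
      mat dZlat = dXhat * P.Wd;
      if (l1a > 0) dZlat += l1a;
      mat dPre = dZlat % (P.c * SGpre);
      mat dW4 = Acache[3].t() * dPre;
      if (l1w > 0) dW4 += l1w * sign(P.W4);
      rowvec db4 = sum(dPre, 0);
      mat dA = dPre * P.W4.t();
      std::vector<mat> gW(3);
      std::vector<rowvec> gb(3), gg(3), gbe(3);
      for (int l = 2; l >= 0; --l) {
        mat dY = dA % Ysig[l];
        gg[l] = sum(dY % Zhat[l], 0);
        gbe[l] = sum(dY, 0);
        mat dZh = dY;
        dZh.each_row() %= P.gam[l];
        rowvec s1 = sum(dZh, 0);
        rowvec s2 = sum(dZh % Zhat[l], 0);
        mat dZ = dZh * B;
        dZ.each_row() -= s1;
        mat t2 = Zhat[l];
        t2.each_row() %= s2;
        dZ -= t2;
        dZ.each_row() %= invstd[l] / B;
        gW[l] = Acache[l].t() * dZ;
        gb[l] = sum(dZ, 0);
        dA = dZ * P.W[l].t();
      }

      // -- Adam updates --
      double t = (double)tglob;
      for (int l = 0; l < 3; ++l) {
        aW[l].step(P.W[l], gW[l], lr_e, t);
        adam_vec(ab[l], P.b[l], gb[l], t);
        adam_vec(ag[l], P.gam[l], gg[l], t);
        adam_vec(abe[l], P.bet[l], gbe[l], t);
      }
      aW4.step(P.W4, dW4, lr_e, t);
      adam_vec(ab4, P.b4, db4, t);
      if (!frozen) {
        aWd.step(P.Wd, dWd, lr_e, t);
        P.Wd = clamp(P.Wd, 0.0, datum::inf); // projection keeps W >= 0
      }
    }
    hist_tr.push_back(nb > 0 ? ep_loss / nb : datum::nan);

    recalibrate_bn(P, ntr > 1024 ? mat(Xtr.rows(0, 1023)) : Xtr);

    // -- resurrection of dead latent components --
    // a latent unit whose activation collapses to ~0 everywhere receives no
    // gradient on its signature column; while training still has time left,
    // re-seed such components (like restarting an empty k-means cluster)
    if (!frozen && k > 1 && epoch % 10 == 0 && epoch <= (7 * max_epochs) / 10) {
      mat XcalView = ntr > 1024 ? mat(Xtr.rows(0, 1023)) : mat();
      mat Zc, Xh;
      forward_eval(P, ntr > 1024 ? XcalView : Xtr, Zc, Xh);
      rowvec zbar = mean(Zc, 0);
      double zmax = zbar.max();
      std::uniform_int_distribution<int> rowpick(0, ntr - 1);
      // bounded rescues: a unit that collapses again after two re-seeds is
      // redundant for this dataset and is left alone
      std::vector<char> reseed(k, 0);
      for (int j = 0; j < k; ++j)
        if (zmax <= 0 || zbar[j] < 0.08 * zmax) reseed[j] = 1;
      // a column that near-duplicates another wastes a component; rescue the
      // less active copy
      mat Wn = normalise(P.Wd, 2, 0);
      mat CC = Wn.t() * Wn;
      for (int i2 = 0; i2 < k; ++i2)
        for (int j2 = i2 + 1; j2 < k; ++j2)
          if (CC(i2, j2) > 0.98) reseed[zbar[i2] < zbar[j2] ? i2 : j2] = 1;
      for (int j = 0; j < k; ++j) if (reseed_count[j] >= 2) reseed[j] = 0;
      // re-seed from the worst-reconstructed spectra: the residual points at
      // whatever mutational process the current components fail to explain
      uvec worst;
      {
        const mat& Xc = ntr > 1024 ? (const mat&)XcalView : Xtr;
        mat Xq2 = Xh + eps;
        vec rnll = sum(-Xc % log(Xq2) + Xh, 1) / clamp(sum(Xc, 1), 1.0, datum::inf);
        worst = sort_index(rnll, "descend");
      }
      int wpos = 0;
      for (int j = 0; j < k; ++j) {
        if (!reseed[j]) continue;
        reseed_count[j]++;
        wait = 0; // give the rescued component a full patience window
        double lim = std::sqrt(6.0 / (widths[3] + k));
        for (int u = 0; u < widths[3]; ++u)
          P.W4(u, j) = -lim + 2 * lim * unif(rng);
        P.b4[j] = 0.0;
        rowvec r = (ntr > 1024 ? (const mat&)XcalView : Xtr).row(worst[wpos++]);
        if (accu(r) <= 0) r.ones();
        P.Wd.col(j) = (r / accu(r)).t();
        aW4.m.col(j).zeros(); aW4.v.col(j).zeros();
        aWd.m.col(j).zeros(); aWd.v.col(j).zeros();
        ab4.m(0, j) = 0; ab4.v(0, j) = 0;
      }
    }

    // -- early stopping on held-out loss (training loss if no split) --
    double vloss = eval_loss(P, nval > 0 ? Xval : Xtr, eps, beta, l1w, l1a, frozen);
    hist_val.push_back(vloss);
    if (!std::isfinite(vloss))
      Rcpp::stop("training diverged: non-finite validation loss at epoch %d", epoch);
    if (vloss < best_val) {
      best_val = vloss;
      best = P;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      stopped = epoch;
      break;
    }
    if (epoch % 20 == 0) Rcpp::checkUserInterrupt();
  }
  if (max_epochs > 0 && best_epoch > 0) {
    P = best;
    recalibrate_bn(P, Xtr); // final statistics from the full training set
  } else best_epoch = 0;

  Rcpp::List layers(3);
  for (int l = 0; l < 3; ++l) {
    layers[l] = Rcpp::List::create(
      Rcpp::Named("W") = P.W[l], Rcpp::Named("b") = P.b[l],
      Rcpp::Named("gamma") = P.gam[l], Rcpp::Named("beta") = P.bet[l],
      Rcpp::Named("rmean") = P.rmean[l], Rcpp::Named("rvar") = P.rvar[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("layers") = layers,
    Rcpp::Named("W4") = P.W4, Rcpp::Named("b4") = P.b4,
    Rcpp::Named("Wd") = P.Wd, Rcpp::Named("c") = P.c,
    Rcpp::Named("k") = k, Rcpp::Named("units") = units,
    Rcpp::Named("history") = Rcpp::List::create(
      Rcpp::Named("train") = hist_tr, Rcpp::Named("val") = hist_val),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("stopped_epoch") = stopped,
    Rcpp::Named("best_val") = best_val);
}

static XAEParams params_from_list(const Rcpp::List& model) {
  XAEParams P;
  Rcpp::List layers = model["layers"];
  for (int l = 0; l < 3; ++l) {
    Rcpp::List L = layers[l];
    P.W.push_back(Rcpp::as<mat>(L["W"]));
    P.b.push_back(Rcpp::as<rowvec>(L["b"]));
    P.gam.push_back(Rcpp::as<rowvec>(L["gamma"]));
    P.bet.push_back(Rcpp::as<rowvec>(L["beta"]));
    P.rmean.push_back(Rcpp::as<rowvec>(L["rmean"]));
    P.rvar.push_back(Rcpp::as<rowvec>(L["rvar"]));
  }
  P.W4 = Rcpp::as<mat>(model["W4"]);
  P.b4 = Rcpp::as<rowvec>(model["b4"]);
  P.Wd = Rcpp::as<mat>(model["Wd"]);
  P.c = Rcpp::as<double>(model["c"]);
  return P;
}

// [[Rcpp::export(name = ".cpp_xae_forward")]]
Rcpp::List cpp_xae_forward(const Rcpp::List& model, const arma::mat& X) {
  XAEParams P = params_from_list(model);
  if ((int)X.n_cols != (int)P.W[0].n_rows)
    Rcpp::stop("input has %d channels, model expects %d", X.n_cols, P.W[0].n_rows);
  mat Z, Xhat;
  forward_eval(P, X, Z, Xhat);
  return Rcpp::List::create(Rcpp::Named("z") = Z, Rcpp::Named("xhat") = Xhat);
}
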
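// 1D CNN-LSTM backend: forward pass, backpropagation and Adam training for
// architectures built from conv1d (valid, stride 1, ReLU), non-overlapping
// max-pooling, LSTM (single-bias gates, order i,f,g,o) and a sigmoid dense
// output trained with per-unit binary cross-entropy.
//
// Activations flow as cubes (time x features x batch). Parameters live in
// one flat vector; per-layer layout (matching the R param_count formulas):
//   conv : W (s*C_in x r, window index fastest within a channel), b (r)
//   lstm : Wx (4U x F), Wh (4U x U), b (4U)
//   dense: W (K x U), b (K)

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

enum LayerType { CONV, POOL, LSTM, DENSE };

struct Layer {
  LayerType type;
  int r = 0, s = 0, d = 0, units = 0;
  bool return_seq = false;
  int L_in = 0, C_in = 0, L_out = 0, C_out = 0;
  uword off = 0, n_par = 0;
};

static std::vector<Layer> parse_arch(const Rcpp::List& arch) {
  Rcpp::IntegerVector shp = arch["input_shape"];
  int L = shp[0], C = shp[1];
  Rcpp::List layers = arch["layers"];
  std::vector<Layer> out;
  uword off = 0;
  for (int i = 0; i < layers.size(); ++i) {
    Rcpp::List ls = layers[i];
    std::string kind = Rcpp::as<std::string>(ls["kind"]);
    Layer ly;
    ly.L_in = L; ly.C_in = C; ly.off = off;
    if (kind == "conv") {
      ly.type = CONV;
      ly.r = Rcpp::as<int>(ls["r"]);
      ly.s = Rcpp::as<int>(ls["s"]);
      if (L < ly.s) Rcpp::stop("conv kernel exceeds input length");
      ly.L_out = L - ly.s + 1;
      ly.C_out = ly.r;
      ly.n_par = (uword)ly.s * C * ly.r + ly.r;
    } else if (kind == "pool") {
      ly.type = POOL;
      ly.d = Rcpp::as<int>(ls["d"]);
      if (L < ly.d) Rcpp::stop("pool window exceeds input length");
      ly.L_out = L / ly.d;
      ly.C_out = C;
      ly.n_par = 0;
    } else if (kind == "lstm") {
      ly.type = LSTM;
      ly.units = Rcpp::as<int>(ls["units"]);
      ly.return_seq = Rcpp::as<bool>(ls["return_seq"]);
      ly.L_out = ly.return_seq ? L : 1;
      ly.C_out = ly.units;
      ly.n_par = 4u * ((uword)ly.units * (C + ly.units) + ly.units);
    } else if (kind == "dense") {
      ly.type = DENSE;
      if (L != 1) Rcpp::stop("dense layer requires a length-1 sequence");
      ly.units = Rcpp::as<int>(ls["units"]);
      ly.L_out = 1;
      ly.C_out = ly.units;
      ly.n_par = (uword)ly.units * C + ly.units;
    } else {
      Rcpp::stop("unknown layer kind: %s", kind);
    }
    if (ly.L_out < 1) Rcpp::stop("layer yields empty output");
    off += ly.n_par;
    L = ly.L_out; C = ly.C_out;
    out.push_back(ly);
  }
  return out;
}

static uword total_params(const std::vector<Layer>& net) {
  return net.empty() ? 0 : net.back().off + net.back().n_par;
}

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// ---- caches for backprop -------------------------------------------------

struct Cache {
  // conv
  mat M;         // im2col, (L_out*B) x (s*C_in)
  mat relu_mask; // (L_out*B) x r
  // pool: absolute source row index per pooled element
  ucube argidx;  // K x C x B
  // lstm, per timestep
  std::vector<mat> x, gi, gf, gg, go, cs, tanhc, h_prev, c_prev;
  // dense
  mat H, P;      // input (U x B), sigmoid output (K x B)
};

// im2col with column order c*s + si so that a column-major R array
// (s x C x r) flattens to the matching weight matrix (s*C x r).
static mat im2col(const cube& A, int s, int Lo) {
  int C = A.n_cols, B = A.n_slices;
  mat M(Lo * B, s * C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int si = 0; si < s; ++si)
        M.col(c * s + si).subvec(b * Lo, b * Lo + Lo - 1) =
          A.slice(b).col(c).subvec(si, si + Lo - 1);
  return M;
}

static cube forward(const std::vector<Layer>& net, const vec& par,
                    const cube& X, std::vector<Cache>* caches) {
  cube A = X;
  for (size_t li = 0; li < net.size(); ++li) {
    const Layer& ly = net[li];
    int B = A.n_slices;
    Cache ch;
    if (ly.type == CONV) {
      const mat W(const_cast<double*>(par.memptr()) + ly.off,
                  (uword)ly.s * ly.C_in, ly.r, false, true);
      const vec bb(const_cast<double*>(par.memptr()) + ly.off +
                   (uword)ly.s * ly.C_in * ly.r, ly.r, false, true);
      mat M = im2col(A, ly.s, ly.L_out);
      mat Y = M * W;
      Y.each_row() += bb.t();
      mat mask = conv_to<mat>::from(Y > 0);
      Y %= mask;  // ReLU
      cube A2(ly.L_out, ly.r, B);
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < ly.r; ++j)
          A2.slice(b).col(j) = Y.col(j).subvec(b * ly.L_out,
                                               (b + 1) * ly.L_out - 1);
      if (caches) { ch.M = std::move(M); ch.relu_mask = std::move(mask); }
      A = std::move(A2);
    } else if (ly.type == POOL) {
      cube A2(ly.L_out, ly.C_in, B);
      ucube arg(ly.L_out, ly.C_in, B);
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < ly.C_in; ++c)
          for (int k = 0; k < ly.L_out; ++k) {
            uword best = k * ly.d;
            double bv = A(best, c, b);
            for (int j = 1; j < ly.d; ++j) {
              if (A(k * ly.d + j, c, b) > bv) {
                bv = A(k * ly.d + j, c, b);
                best = k * ly.d + j;
              }
            }
            A2(k, c, b) = bv;
            arg(k, c, b) = best;
          }
      if (caches) ch.argidx = std::move(arg);
      A = std::move(A2);
    } else if (ly.type == LSTM) {
      int U = ly.units, F = ly.C_in, T = ly.L_in;
      const mat Wx(const_cast<double*>(par.memptr()) + ly.off, 4 * U, F,
                   false, true);
      const mat Wh(const_cast<double*>(par.memptr()) + ly.off +
                   (uword)4 * U * F, 4 * U, U, false, true);
      const vec bb(const_cast<double*>(par.memptr()) + ly.off +
                   (uword)4 * U * F + (uword)4 * U * U, 4 * U, false, true);
      mat h(U, B, fill::zeros), c(U, B, fill::zeros);
      cube A2(ly.L_out, U, B);
      for (int t = 0; t < T; ++t) {
        mat xt(F, B);
        for (int b = 0; b < B; ++b)
          xt.col(b) = A.slice(b).row(t).t();
        mat Z = Wx * xt + Wh * h;
        Z.each_col() += bb;
        mat gi = sigmoid(Z.rows(0, U - 1));
        mat gf = sigmoid(Z.rows(U, 2 * U - 1));
        mat gg = tanh(Z.rows(2 * U, 3 * U - 1));
        mat go = sigmoid(Z.rows(3 * U, 4 * U - 1));
        if (caches) {
          ch.x.push_back(xt); ch.h_prev.push_back(h); ch.c_prev.push_back(c);
        }
        c = gf % c + gi % gg;
        mat tc = tanh(c);
        h = go % tc;
        if (caches) {
          ch.gi.push_back(gi); ch.gf.push_back(gf); ch.gg.push_back(gg);
          ch.go.push_back(go); ch.cs.push_back(c); ch.tanhc.push_back(tc);
        }
        if (ly.return_seq)
          for (int b = 0; b < B; ++b)
            A2.slice(b).row(t) = h.col(b).t();
      }
      if (!ly.return_seq)
        for (int b = 0; b < B; ++b)
          A2.slice(b).row(0) = h.col(b).t();
      A = std::move(A2);
    } else { // DENSE
      int U = ly.C_in, K = ly.units;
      const mat W(const_cast<double*>(par.memptr()) + ly.off, K, U,
                  false, true);
      const vec bb(const_cast<double*>(par.memptr()) + ly.off +
                   (uword)K * U, K, false, true);
      mat H(U, B);
      for (int b = 0; b < B; ++b)
        H.col(b) = A.slice(b).row(0).t();
      mat Z = W * H;
      Z.each_col() += bb;
      mat P = sigmoid(Z);
      if (caches) { ch.H = H; ch.P = P; }
      cube A2(1, K, B);
      for (int b = 0; b < B; ++b)
        A2.slice(b).row(0) = P.col(b).t();
      A = std::move(A2);
    }
    if (caches) caches->push_back(std::move(ch));
  }
  return A;
}

// Binary cross-entropy (summed over the K output units, averaged over the
// batch) and its gradient; Yt is K x B one-hot.
static double loss_and_grad(const std::vector<Layer>& net, const vec& par,
                            const cube& X, const mat& Yt, vec& grad,
                            int* correct = nullptr) {
  std::vector<Cache> caches;
  cube out = forward(net, par, X, &caches);
  int B = X.n_slices;
  const Layer& last = net.back();
  const mat& P = caches.back().P;
  mat Pc = clamp(P, 1e-12, 1.0 - 1e-12);
  double loss = -accu(Yt % log(Pc) + (1.0 - Yt) % log(1.0 - Pc)) / B;
  if (correct) {
    *correct = 0;
    for (int b = 0; b < B; ++b)
      if (P.col(b).index_max() == Yt.col(b).index_max()) ++(*correct);
  }

  grad.zeros(total_params(net));
  // dLoss/dlogits for sigmoid + BCE
  mat dZ = (P - Yt) / B;                     // K x B
  cube dA;                                    // gradient w.r.t. layer input
  // dense backward
  {
    const Layer& ly = last;
    int U = ly.C_in, K = ly.units;
    const mat W(const_cast<double*>(par.memptr()) + ly.off, K, U,
                false, true);
    mat dW = dZ * caches.back().H.t();
    vec db = sum(dZ, 1);
    std::copy(dW.memptr(), dW.memptr() + dW.n_elem,
              grad.memptr() + ly.off);
    std::copy(db.memptr(), db.memptr() + db.n_elem,
              grad.memptr() + ly.off + (uword)K * U);
    mat dH = W.t() * dZ;                     // U x B
    dA.set_size(1, U, B);
    for (int b = 0; b < B; ++b)
      dA.slice(b).row(0) = dH.col(b).t();
  }

  for (int li = (int)net.size() - 2; li >= 0; --li) {
    const Layer& ly = net[li];
    Cache& ch = caches[li];
    cube dIn(ly.L_in, ly.C_in, B, fill::zeros);
    if (ly.type == CONV) {
      // cube gradient -> matrix in im2col layout
      mat dY(ly.L_out * B, ly.r);
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < ly.r; ++j)
          dY.col(j).subvec(b * ly.L_out, (b + 1) * ly.L_out - 1) =
            dA.slice(b).col(j);
      dY %= ch.relu_mask;
      mat dW = ch.M.t() * dY;
      vec db = sum(dY, 0).t();
      std::copy(dW.memptr(), dW.memptr() + dW.n_elem,
                grad.memptr() + ly.off);
      std::copy(db.memptr(), db.memptr() + db.n_elem,
                grad.memptr() + ly.off + dW.n_elem);
      const mat W(const_cast<double*>(par.memptr()) + ly.off,
                  (uword)ly.s * ly.C_in, ly.r, false, true);
      mat dM = dY * W.t();                   // (L_out*B) x (s*C_in)
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < ly.C_in; ++c)
          for (int si = 0; si < ly.s; ++si)
            dIn.slice(b).col(c).subvec(si, si + ly.L_out - 1) +=
              dM.col(c * ly.s + si).subvec(b * ly.L_out,
                                           (b + 1) * ly.L_out - 1);
    } else if (ly.type == POOL) {
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < ly.C_in; ++c)
          for (int k = 0; k < ly.L_out; ++k)
            dIn(ch.argidx(k, c, b), c, b) += dA(k, c, b);
    } else { // LSTM
      int U = ly.units, F = ly.C_in, T = ly.L_in;
      const mat Wx(const_cast<double*>(par.memptr()) + ly.off, 4 * U, F,
                   false, true);
      const mat Wh(const_cast<double*>(par.memptr()) + ly.off +
                   (uword)4 * U * F, 4 * U, U, false, true);
      mat dWx(4 * U, F, fill::zeros), dWh(4 * U, U, fill::zeros);
      vec db(4 * U, fill::zeros);
      mat dh_next(U, B, fill::zeros), dc_next(U, B, fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        mat dh = dh_next;
        if (ly.return_seq) {
          for (int b = 0; b < B; ++b)
            dh.col(b) += dA.slice(b).row(t).t();
        } else if (t == T - 1) {
          for (int b = 0; b < B; ++b)
            dh.col(b) += dA.slice(b).row(0).t();
        }
        const mat &gi = ch.gi[t], &gf = ch.gf[t], &gg = ch.gg[t],
                  &go = ch.go[t], &tc = ch.tanhc[t];
        mat dgo = dh % tc;
        mat dct = dh % go % (1.0 - tc % tc) + dc_next;
        mat dgi = dct % gg;
        mat dgf = dct % ch.c_prev[t];
        mat dgg = dct % gi;
        mat dZ2(4 * U, B);
        dZ2.rows(0, U - 1)        = dgi % gi % (1.0 - gi);
        dZ2.rows(U, 2 * U - 1)    = dgf % gf % (1.0 - gf);
        dZ2.rows(2 * U, 3 * U - 1) = dgg % (1.0 - gg % gg);
        dZ2.rows(3 * U, 4 * U - 1) = dgo % go % (1.0 - go);
        dWx += dZ2 * ch.x[t].t();
        dWh += dZ2 * ch.h_prev[t].t();
        db += sum(dZ2, 1);
        mat dxt = Wx.t() * dZ2;              // F x B
        for (int b = 0; b < B; ++b)
          dIn.slice(b).row(t) += dxt.col(b).t();
        dh_next = Wh.t() * dZ2;
        dc_next = dct % gf;
      }
      std::copy(dWx.memptr(), dWx.memptr() + dWx.n_elem,
                grad.memptr() + ly.off);
      std::copy(dWh.memptr(), dWh.memptr() + dWh.n_elem,
                grad.memptr() + ly.off + dWx.n_elem);
      std::copy(db.memptr(), db.memptr() + db.n_elem,
                grad.memptr() + ly.off + dWx.n_elem + dWh.n_elem);
    }
    dA = std::move(dIn);
  }
  return loss;
}

// ---- exported interface --------------------------------------------------

// [[Rcpp::export]]
arma::vec cpp_init_params(Rcpp::List arch, int seed) {
  std::vector<Layer> net = parse_arch(arch);
  vec par(total_params(net), fill::zeros);
  std::mt19937 rng(seed);
  for (const Layer& ly : net) {
    if (ly.type == CONV) {
      uword nw = (uword)ly.s * ly.C_in * ly.r;
      double limit = std::sqrt(6.0 / (ly.s * ly.C_in + ly.r));
      std::uniform_real_distribution<double> unif(-limit, limit);
      for (uword i = 0; i < nw; ++i) par(ly.off + i) = unif(rng);
    } else if (ly.type == LSTM) {
      int U = ly.units, F = ly.C_in;
      double lx = std::sqrt(6.0 / (F + 4 * U));
      std::uniform_real_distribution<double> ux(-lx, lx);
      for (uword i = 0; i < (uword)4 * U * F; ++i)
        par(ly.off + i) = ux(rng);
      double lh = std::sqrt(6.0 / (U + 4 * U));
      std::uniform_real_distribution<double> uh(-lh, lh);
      for (uword i = 0; i < (uword)4 * U * U; ++i)
        par(ly.off + 4 * U * F + i) = uh(rng);
      // forget-gate bias = 1 (standard initialisation aid)
      for (int i = 0; i < U; ++i)
        par(ly.off + (uword)4 * U * F + (uword)4 * U * U + U + i) = 1.0;
    } else if (ly.type == DENSE) {
      uword nw = (uword)ly.units * ly.C_in;
      double limit = std::sqrt(6.0 / (ly.C_in + ly.units));
      std::uniform_real_distribution<double> unif(-limit, limit);
      for (uword i = 0; i < nw; ++i) par(ly.off + i) = unif(rng);
    }
  }
  return par;
}

// [[Rcpp::export]]
arma::mat cpp_forward(Rcpp::List arch, arma::vec params, arma::cube X) {
  std::vector<Layer> net = parse_arch(arch);
  if (params.n_elem != total_params(net))
    Rcpp::stop("parameter vector has wrong length");
  int B = X.n_slices;
  int K = net.back().C_out;
  mat out(B, K);
  int chunk = 256;
  for (int start = 0; start < B; start += chunk) {
    int end = std::min(start + chunk, B) - 1;
    cube Xi = X.slices(start, end);
    cube Oi = forward(net, params, Xi, nullptr);
    for (int b = 0; b <= end - start; ++b)
      out.row(start + b) = Oi.slice(b).row(0);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List arch, arma::vec params, arma::cube X,
                         arma::mat Yt) {
  std::vector<Layer> net = parse_arch(arch);
  vec grad;
  double loss = loss_and_grad(net, params, X, Yt.t(), grad);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

static double eval_split(const std::vector<Layer>& net, const vec& par,
                         const cube& X, const mat& YtT, double* acc) {
  int B = X.n_slices;
  double loss = 0.0;
  int correct = 0, chunk = 512;
  for (int start = 0; start < B; start += chunk) {
    int end = std::min(start + chunk, B) - 1;
    cube Xi = X.slices(start, end);
    cube Oi = forward(net, par, Xi, nullptr);
    for (int b = 0; b <= end - start; ++b) {
      rowvec p = Oi.slice(b).row(0);
      rowvec y = YtT.row(start + b);
      rowvec pc = clamp(p, 1e-12, 1.0 - 1e-12);
      loss += -accu(y % log(pc) + (1.0 - y) % log(1.0 - pc));
      if (p.index_max() == y.index_max()) ++correct;
    }
  }
  if (acc) *acc = (double)correct / B;
  return loss / B;
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List arch, arma::cube Xtr, arma::mat Ytr,
                     arma::cube Xval, arma::mat Yval, Rcpp::List cfg) {
  std::vector<Layer> net = parse_arch(arch);
  int batch = Rcpp::as<int>(cfg["batch_size"]);
  int epochs = Rcpp::as<int>(cfg["epochs"]);
  double lr = Rcpp::as<double>(cfg["learning_rate"]);
  int patience = Rcpp::as<int>(cfg["patience"]);
  int seed = Rcpp::as<int>(cfg["seed"]);
  bool verbose = Rcpp::as<bool>(cfg["verbose"]);

  int n = Xtr.n_slices;
  bool has_val = Xval.n_slices > 0;
  vec par = cpp_init_params(arch, seed);
  uword np = par.n_elem;
  vec m(np, fill::zeros), v(np, fill::zeros), grad(np, fill::zeros);
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::mt19937 rng(seed + 1);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  mat YtrT = Ytr.t();  // K x n
  vec best_par = par;
  double best_val = datum::inf;
  int bad = 0;
  Rcpp::NumericMatrix history(epochs, 5);
  int done = 0;
  bool diverged = false;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double tr_loss = 0.0;
    long nb = 0;
    int tr_correct = 0;
    for (int start = 0; start < n; start += batch) {
      int bs = std::min(batch, n - start);
      cube Xb(Xtr.n_rows, Xtr.n_cols, bs);
      mat Yb(Ytr.n_cols, bs);
      for (int b = 0; b < bs; ++b) {
        Xb.slice(b) = Xtr.slice(idx[start + b]);
        Yb.col(b) = YtrT.col(idx[start + b]);
      }
      int bc = 0;
      double loss = loss_and_grad(net, par, Xb, Yb, grad, &bc);
      if (!std::isfinite(loss)) { diverged = true; break; }
      tr_loss += loss; ++nb; tr_correct += bc;
      ++step;
      m = b1 * m + (1 - b1) * grad;
      v = b2 * v + (1 - b2) * square(grad);
      double a = lr * std::sqrt(1 - std::pow(b2, (double)step)) /
                 (1 - std::pow(b1, (double)step));
      par -= a * (m / (sqrt(v) + eps));
    }
    if (diverged) break;
    // training metrics accumulated from the mini-batch forward passes
    double tr_acc = (double)tr_correct / n;
    double val_loss = NA_REAL, val_acc = NA_REAL;
    if (has_val) {
      val_loss = eval_split(net, par, Xval, Yval, &val_acc);
      if (val_loss < best_val - 1e-6) {
        best_val = val_loss; best_par = par; bad = 0;
      } else if (++bad >= patience) {
        history(ep, 0) = ep + 1; history(ep, 1) = tr_loss / nb;
        history(ep, 2) = tr_acc; history(ep, 3) = val_loss;
        history(ep, 4) = val_acc;
        done = ep + 1;
        break;
      }
    } else {
      best_par = par;
    }
    history(ep, 0) = ep + 1;
    history(ep, 1) = tr_loss / nb;
    history(ep, 2) = tr_acc;
    history(ep, 3) = val_loss;
    history(ep, 4) = val_acc;
    done = ep + 1;
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " loss " << tr_loss / nb
                  << " acc " << tr_acc << " val_acc " << val_acc << "\n";
    Rcpp::checkUserInterrupt();
  }
  if (!has_val) best_par = par;
  return Rcpp::List::create(
    Rcpp::Named("params") = best_par,
    Rcpp::Named("history") = history(Rcpp::Range(0, std::max(done - 1, 0)),
                                     Rcpp::_),
    Rcpp::Named("epochs_run") = done,
    Rcpp::Named("diverged") = diverged);
}
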
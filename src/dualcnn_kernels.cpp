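// Compiled kernels for the dual-branch CNN.
// Activation layout is column-major: (time * channels) x batch between
// layers (time fastest within channel), (time * batch) x maps inside a
// layer.  Convolutions are im2col + GEMM; dropout draws use R's RNG so
// training is reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

static const double BN_EPS = 1e-5;

struct BranchParams {
  std::vector<mat> W;
  std::vector<rowvec> b, gamma, beta, run_mu, run_var;
};

struct BranchCache {
  std::vector<mat> Xcol, Ypre, xhat, keep;
  std::vector<arma::imat> amax;
  std::vector<rowvec> mu, vv;
};

static BranchParams unpack_branch(const List& Ws, const List& bs,
                                  const List& gammas, const List& betas,
                                  const List& run_mu, const List& run_var,
                                  bool use_bn) {
  BranchParams p;
  const int nL = Ws.size();
  for (int l = 0; l < nL; ++l) {
    p.W.push_back(as<mat>(Ws[l]));
    p.b.push_back(as<rowvec>(bs[l]));
    if (use_bn) {
      p.gamma.push_back(as<rowvec>(gammas[l]));
      p.beta.push_back(as<rowvec>(betas[l]));
      if (run_mu.size() > l && Rf_length(run_mu[l]) > 0) {
        p.run_mu.push_back(as<rowvec>(run_mu[l]));
        p.run_var.push_back(as<rowvec>(run_var[l]));
      }
    }
  }
  return p;
}

// geom row: t_in, c_in, k, t_out, pool, t_pool, maps
static mat forward_branch(const mat& A0, const BranchParams& P,
                          const IntegerMatrix& geom, bool training,
                          bool use_bn, bool dropout, double drop_rate,
                          bool keep_cache, BranchCache* C) {
  const int nL = geom.nrow();
  const int B = A0.n_cols;
  mat A = A0;
  for (int l = 0; l < nL; ++l) {
    const int t_in = geom(l, 0), c_in = geom(l, 1), k = geom(l, 2),
              t_out = geom(l, 3), pool = geom(l, 4), t_pool = geom(l, 5),
              maps = geom(l, 6);
    mat Xcol(t_out * B, k * c_in);
    for (int j = 0; j < c_in; ++j)
      for (int kk = 0; kk < k; ++kk)
        Xcol.col(j * k + kk) =
            arma::vectorise(A.rows(j * t_in + kk, j * t_in + kk + t_out - 1));
    mat Y = Xcol * P.W[l];
    if (use_bn) {
      rowvec mu, vv;
      if (training) {
        mu = arma::mean(Y, 0);
        vv = arma::mean(arma::square(Y), 0) - arma::square(mu);
      } else {
        mu = P.run_mu[l];
        vv = P.run_var[l];
      }
      rowvec isd = 1.0 / arma::sqrt(vv + BN_EPS);
      Y.each_row() -= mu;
      Y.each_row() %= isd;
      if (C) {
        C->mu.push_back(mu);
        C->vv.push_back(vv);
        if (keep_cache) C->xhat.push_back(Y);
      }
      Y.each_row() %= P.gamma[l];
      Y.each_row() += P.beta[l];
    } else if (C) {
      C->mu.push_back(rowvec());
      C->vv.push_back(rowvec());
      if (keep_cache) C->xhat.push_back(mat());
    }
    if (!use_bn) Y.each_row() += P.b[l];
    Y.transform([](double v) { return v > 0.0 ? v : 0.0; });  // ReLU
    mat M(t_pool * B, maps);
    arma::imat amax(t_pool * B, maps);
    for (int c = 0; c < maps; ++c) {
      const double* yc = Y.colptr(c);
      double* mc = M.colptr(c);
      arma::sword* ac = amax.colptr(c);
      for (int b = 0; b < B; ++b) {
        const double* yb = yc + (size_t)b * t_out;
        double* mb = mc + (size_t)b * t_pool;
        arma::sword* ab = ac + (size_t)b * t_pool;
        for (int tp = 0; tp < t_pool; ++tp) {
          const int base = tp * pool;
          double best = yb[base];
          int besti = 0;
          for (int i = 1; i < pool; ++i)
            if (yb[base + i] > best) { best = yb[base + i]; besti = i; }
          mb[tp] = best;
          ab[tp] = besti;
        }
      }
    }
    mat keep;
    if (dropout && drop_rate > 0) {
      keep.set_size(B, maps);
      const double scale = 1.0 / (1.0 - drop_rate);
      for (int c = 0; c < maps; ++c)
        for (int b = 0; b < B; ++b)
          keep(b, c) = (unif_rand() < drop_rate) ? 0.0 : scale;
      for (int c = 0; c < maps; ++c) {
        double* mc = M.colptr(c);
        for (int b = 0; b < B; ++b) {
          const double s = keep(b, c);
          double* mb = mc + (size_t)b * t_pool;
          for (int tp = 0; tp < t_pool; ++tp) mb[tp] *= s;
        }
      }
    }
    if (keep_cache && C) {
      C->Xcol.push_back(Xcol);
      C->Ypre.push_back(Y);
      C->amax.push_back(amax);
      C->keep.push_back(keep);
    }
    mat An(t_pool * maps, B);
    for (int c = 0; c < maps; ++c)
      An.rows(c * t_pool, c * t_pool + t_pool - 1) =
          arma::reshape(M.col(c), t_pool, B);
    A = An;
  }
  return A;
}

struct BranchGrads {
  std::vector<mat> dW;
  std::vector<rowvec> db, dgamma, dbeta;
};

static void backward_branch(const mat& dF, const BranchParams& P,
                            const BranchCache& C, const IntegerMatrix& geom,
                            bool use_bn, BranchGrads* G) {
  const int nL = geom.nrow();
  const int B = dF.n_cols;
  G->dW.assign(nL, mat());
  G->db.assign(nL, rowvec());
  G->dgamma.assign(nL, rowvec());
  G->dbeta.assign(nL, rowvec());
  mat dA = dF;
  for (int l = nL - 1; l >= 0; --l) {
    const int t_in = geom(l, 0), c_in = geom(l, 1), k = geom(l, 2),
              t_out = geom(l, 3), pool = geom(l, 4), t_pool = geom(l, 5),
              maps = geom(l, 6);
    mat dM(t_pool * B, maps);
    for (int c = 0; c < maps; ++c)
      dM.col(c) =
          arma::vectorise(dA.rows(c * t_pool, c * t_pool + t_pool - 1));
    const mat& keep = C.keep[l];
    if (keep.n_elem > 0) {
      for (int c = 0; c < maps; ++c) {
        double* mc = dM.colptr(c);
        for (int b = 0; b < B; ++b) {
          const double s = keep(b, c);
          double* mb = mc + (size_t)b * t_pool;
          for (int tp = 0; tp < t_pool; ++tp) mb[tp] *= s;
        }
      }
    }
    const arma::imat& amax = C.amax[l];
    const mat& Ypre = C.Ypre[l];
    mat dY(t_out * B, maps, arma::fill::zeros);
    for (int c = 0; c < maps; ++c) {
      const double* mc = dM.colptr(c);
      const arma::sword* ac = amax.colptr(c);
      const double* pc = Ypre.colptr(c);
      double* yc = dY.colptr(c);
      for (int b = 0; b < B; ++b)
        for (int tp = 0; tp < t_pool; ++tp) {
          const size_t src = tp + (size_t)b * t_pool;
          const size_t dst = (size_t)b * t_out + tp * pool + ac[src];
          if (pc[dst] > 0.0) yc[dst] = mc[src];  // ReLU mask fused
        }
    }
    if (use_bn) {
      const mat& Xhat = C.xhat[l];
      const double N = dY.n_rows;
      G->dgamma[l] = arma::sum(dY % Xhat, 0);
      G->dbeta[l] = arma::sum(dY, 0);
      dY.each_row() %= P.gamma[l];
      rowvec s1 = arma::sum(dY, 0) / N;
      rowvec s2 = arma::sum(dY % Xhat, 0) / N;
      dY.each_row() -= s1;
      dY -= Xhat.each_row() % s2;
      dY.each_row() %= 1.0 / arma::sqrt(C.vv[l] + BN_EPS);
      G->db[l] = rowvec(maps, arma::fill::zeros);
    } else {
      G->db[l] = arma::sum(dY, 0);
    }
    G->dW[l] = C.Xcol[l].t() * dY;
    if (l > 0) {
      mat dXcol = dY * P.W[l].t();
      mat dAprev(t_in * c_in, B, arma::fill::zeros);
      for (int j = 0; j < c_in; ++j)
        for (int kk = 0; kk < k; ++kk)
          dAprev.rows(j * t_in + kk, j * t_in + kk + t_out - 1) +=
              arma::reshape(dXcol.col(j * k + kk), t_out, B);
      dA = dAprev;
    }
  }
}

static List grads_to_list(const BranchGrads& G) {
  return List::create(_["dW"] = wrap(G.dW), _["db"] = wrap(G.db),
                      _["dgamma"] = wrap(G.dgamma),
                      _["dbeta"] = wrap(G.dbeta));
}

// Evaluation / BN-recalibration forward pass.  Returns the branch flatten
// features plus (when training = true) the per-layer batch statistics.
// [[Rcpp::export]]
List branch_forward_cpp(const arma::mat& A0, const List& Ws, const List& bs,
                        const List& gammas, const List& betas,
                        const List& run_mu, const List& run_var,
                        const IntegerMatrix& geom, bool training, bool use_bn,
                        bool dropout, double drop_rate) {
  BranchParams P = unpack_branch(Ws, bs, gammas, betas, run_mu, run_var, use_bn);
  BranchCache C;
  mat flat = forward_branch(A0, P, geom, training, use_bn, dropout, drop_rate,
                            false, &C);
  return List::create(_["flat"] = flat, _["mu"] = wrap(C.mu),
                      _["vv"] = wrap(C.vv));
}

// One full training-step gradient: both branches, difference layer, FC and
// softmax head, categorical cross-entropy.  `parL`/`parR` are per-branch
// lists (Ws, bs, gammas, betas); for shared weights pass the same list twice
// and set `shared` so the branch gradients are summed.
// [[Rcpp::export]]
List dualcnn_step_cpp(const arma::mat& XL, const arma::mat& XR,
                      const List& parL, const List& parR,
                      const arma::mat& W1, const arma::vec& b1,
                      const arma::mat& W2, const arma::vec& b2,
                      const IntegerMatrix& geom, bool use_bn, bool shared,
                      bool dropout, double drop_rate,
                      const IntegerVector& y_idx, int n_classes) {
  BranchParams PL = unpack_branch(parL["W"], parL["b"], parL["gamma"],
                                  parL["beta"], List(), List(), use_bn);
  BranchParams PR = unpack_branch(parR["W"], parR["b"], parR["gamma"],
                                  parR["beta"], List(), List(), use_bn);
  BranchCache CL, CR;
  mat FL = forward_branch(XL, PL, geom, true, use_bn, dropout, drop_rate,
                          true, &CL);
  mat FR = forward_branch(XR, PR, geom, true, use_bn, dropout, drop_rate,
                          true, &CR);
  const int B = XL.n_cols;
  mat D = FL - FR;
  mat H1 = W1.t() * D;
  H1.each_col() += b1;
  mat H = H1;
  H.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat logits = W2.t() * H;
  logits.each_col() += b2;
  rowvec mx = arma::max(logits, 0);
  logits.each_row() -= mx;
  mat el = arma::exp(logits);
  rowvec denom = arma::sum(el, 0);
  mat probs = el.each_row() / denom;
  double loss = 0.0;
  int correct = 0;
  for (int i = 0; i < B; ++i) {
    const int yi = y_idx[i] - 1;
    loss -= std::log(std::max(probs(yi, i), 1e-12));
    arma::uword am;
    probs.col(i).max(am);
    if ((int)am == yi) ++correct;
  }
  loss /= B;
  mat dlogits = probs;
  for (int i = 0; i < B; ++i) dlogits(y_idx[i] - 1, i) -= 1.0;
  dlogits /= B;
  mat dW2 = H * dlogits.t();
  arma::vec db2 = arma::sum(dlogits, 1);
  mat dH = W2 * dlogits;
  dH %= arma::conv_to<mat>::from(H1 > 0);
  mat dW1 = D * dH.t();
  arma::vec db1 = arma::sum(dH, 1);
  mat dD = W1 * dH;
  BranchGrads GL, GR;
  backward_branch(dD, PL, CL, geom, use_bn, &GL);
  backward_branch(-dD, PR, CR, geom, use_bn, &GR);
  if (shared) {
    for (size_t l = 0; l < GL.dW.size(); ++l) {
      GL.dW[l] += GR.dW[l];
      GL.db[l] += GR.db[l];
      if (use_bn) {
        GL.dgamma[l] += GR.dgamma[l];
        GL.dbeta[l] += GR.dbeta[l];
      }
    }
  }
  return List::create(
      _["loss"] = loss, _["acc"] = (double)correct / B, _["probs"] = probs,
      _["gradL"] = grads_to_list(GL),
      _["gradR"] = shared ? R_NilValue : (SEXP)grads_to_list(GR),
      _["dW1"] = dW1, _["db1"] = db1, _["dW2"] = dW2, _["db2"] = db2,
      _["muL"] = wrap(CL.mu), _["vvL"] = wrap(CL.vv),
      _["muR"] = wrap(CR.mu), _["vvR"] = wrap(CR.vv));
}
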
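// Diffusion-convolutional GRU sequence-to-sequence core.
//
// Forward pass and backpropagation-through-time are implemented here so the
// training loop in R stays at mini-batch granularity.  Graph filters are
// polynomials in the random-walk transition operator(s); powers are applied
// by iterated sparse mat-mats, never materialized.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::sp_mat;
using arma::vec;

namespace {

struct CellParams {
  mat Wr, Wu, Wc;   // (nsup*(F+Q)) x Q
  vec br, bu, bc;   // Q
};

struct CellGrads {
  mat Wr, Wu, Wc;
  vec br, bu, bc;
};

struct CellCache {
  mat Pru;   // stacked supports of [x, H]          N x nsup*(F+Q)
  mat Pc;    // stacked supports of [x, r .* H]     N x nsup*(F+Q)
  mat r, u, c, Hprev;
  int Fin;
};

// Stacked diffusion features: [C, S1 C, ..., S1^K C, S2 C, ..., S2^K C]
mat conv_stack(const mat& C, const std::vector<sp_mat>& S, int K) {
  const int Fin = C.n_cols;
  const int nsup = 1 + static_cast<int>(S.size()) * K;
  mat P(C.n_rows, nsup * Fin);
  P.cols(0, Fin - 1) = C;
  int off = Fin;
  for (const sp_mat& s : S) {
    mat Xk = C;
    for (int k = 0; k < K; ++k) {
      Xk = s * Xk;
      P.cols(off, off + Fin - 1) = Xk;
      off += Fin;
    }
  }
  return P;
}

// Adjoint of conv_stack: collapse gradient w.r.t. the stacked blocks back to
// a gradient w.r.t. C using the backward recurrence over transposed supports.
mat conv_stack_backward(const mat& dP, const std::vector<sp_mat>& S, int K,
                        int Fin) {
  mat dC = dP.cols(0, Fin - 1);
  int off = Fin;
  for (const sp_mat& s : S) {
    mat g(dP.n_rows, Fin, arma::fill::zeros);
    // blocks for this direction are at off .. off + K*Fin - 1
    for (int k = K - 1; k >= 0; --k) {
      g = s.t() * (dP.cols(off + k * Fin, off + (k + 1) * Fin - 1) + g);
    }
    dC += g;
    off += K * Fin;
  }
  return dC;
}

inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

mat cell_forward(const mat& X, const mat& Hprev, const CellParams& p,
                 const std::vector<sp_mat>& S, int K, CellCache* cache) {
  mat C = arma::join_rows(X, Hprev);
  mat Pru = conv_stack(C, S, K);
  mat r = sigmoid(Pru * p.Wr + arma::repmat(p.br.t(), X.n_rows, 1));
  mat u = sigmoid(Pru * p.Wu + arma::repmat(p.bu.t(), X.n_rows, 1));
  mat Cc = arma::join_rows(X, r % Hprev);
  mat Pc = conv_stack(Cc, S, K);
  mat c = arma::tanh(Pc * p.Wc + arma::repmat(p.bc.t(), X.n_rows, 1));
  mat Hnew = u % Hprev + (1.0 - u) % c;
  if (cache) {
    cache->Pru = Pru; cache->Pc = Pc;
    cache->r = r; cache->u = u; cache->c = c;
    cache->Hprev = Hprev; cache->Fin = X.n_cols;
  }
  return Hnew;
}

// Returns dX; writes dHprev in place; accumulates parameter grads.
mat cell_backward(const mat& dH, const CellCache& cc, const CellParams& p,
                  const std::vector<sp_mat>& S, int K, CellGrads& g,
                  mat& dHprev) {
  const int Fin = cc.Fin;
  mat du = dH % (cc.Hprev - cc.c);
  mat dc = dH % (1.0 - cc.u);
  dHprev = dH % cc.u;

  // candidate branch
  mat dc_pre = dc % (1.0 - cc.c % cc.c);
  g.Wc += cc.Pc.t() * dc_pre;
  g.bc += arma::sum(dc_pre, 0).t();
  mat dCc = conv_stack_backward(dc_pre * p.Wc.t(), S, K, Fin + cc.Hprev.n_cols);
  mat dX = dCc.cols(0, Fin - 1);
  mat dRH = dCc.cols(Fin, dCc.n_cols - 1);
  mat dr = dRH % cc.Hprev;
  dHprev += dRH % cc.r;

  // gate branches (share stacked features Pru)
  mat du_pre = du % cc.u % (1.0 - cc.u);
  mat dr_pre = dr % cc.r % (1.0 - cc.r);
  g.Wu += cc.Pru.t() * du_pre;
  g.bu += arma::sum(du_pre, 0).t();
  g.Wr += cc.Pru.t() * dr_pre;
  g.br += arma::sum(dr_pre, 0).t();
  mat dCru = conv_stack_backward(du_pre * p.Wu.t() + dr_pre * p.Wr.t(), S, K,
                                 Fin + cc.Hprev.n_cols);
  dX += dCru.cols(0, Fin - 1);
  dHprev += dCru.cols(Fin, dCru.n_cols - 1);
  return dX;
}

CellParams cell_from_list(const List& l) {
  CellParams p;
  p.Wr = as<mat>(l["Wr"]); p.Wu = as<mat>(l["Wu"]); p.Wc = as<mat>(l["Wc"]);
  p.br = as<vec>(l["br"]); p.bu = as<vec>(l["bu"]); p.bc = as<vec>(l["bc"]);
  return p;
}

std::vector<sp_mat> supports_from_list(const List& l) {
  std::vector<sp_mat> S;
  for (int i = 0; i < l.size(); ++i) S.push_back(as<sp_mat>(l[i]));
  return S;
}

struct Model {
  std::vector<CellParams> enc, dec;
  vec w;      // output projection Q -> 1, shared across nodes
  double b;
};

Model model_from_list(const List& params) {
  Model m;
  List enc = params["enc"], dec = params["dec"];
  for (int l = 0; l < enc.size(); ++l) m.enc.push_back(cell_from_list(enc[l]));
  for (int l = 0; l < dec.size(); ++l) m.dec.push_back(cell_from_list(dec[l]));
  m.w = as<vec>(params["w"]);
  m.b = as<double>(params["b"]);
  return m;
}

// Stack B copies of a support along the diagonal so a whole mini-batch runs
// as one graph with B disconnected components.
sp_mat block_diag(const sp_mat& s, int B) {
  if (B == 1) return s;
  const int N = s.n_rows;
  arma::umat loc(2, s.n_nonzero * B);
  arma::vec val(s.n_nonzero * B);
  arma::uword k = 0;
  for (int b = 0; b < B; ++b) {
    for (sp_mat::const_iterator it = s.begin(); it != s.end(); ++it) {
      loc(0, k) = it.row() + b * N;
      loc(1, k) = it.col() + b * N;
      val(k) = *it;
      ++k;
    }
  }
  return sp_mat(loc, val, N * (arma::uword)B, N * (arma::uword)B);
}

mat stack_batch(const List& batch) {
  mat first = as<mat>(batch[0]);
  mat out(first.n_rows * batch.size(), first.n_cols);
  out.rows(0, first.n_rows - 1) = first;
  for (int b = 1; b < batch.size(); ++b) {
    mat m = as<mat>(batch[b]);
    out.rows(b * first.n_rows, (b + 1) * first.n_rows - 1) = m;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
arma::mat dcgru_cell_forward_cpp(const arma::mat& X, const arma::mat& H,
                                 const List& cell, const List& supports,
                                 int K) {
  CellParams p = cell_from_list(cell);
  std::vector<sp_mat> S = supports_from_list(supports);
  return cell_forward(X, H, p, S, K, nullptr);
}

// [[Rcpp::export]]
List seq2seq_encode_cpp(const List& params, const List& supports, int K,
                        const arma::mat& x_seq) {
  Model m = model_from_list(params);
  std::vector<sp_mat> S = supports_from_list(supports);
  const int N = x_seq.n_rows, L = m.enc.size();
  const int Q = m.enc[0].br.n_elem;
  std::vector<mat> H(L, mat(N, Q, arma::fill::zeros));
  for (arma::uword t = 0; t < x_seq.n_cols; ++t) {
    mat X = x_seq.col(t);
    for (int l = 0; l < L; ++l) {
      H[l] = cell_forward(X, H[l], m.enc[l], S, K, nullptr);
      X = H[l];
    }
  }
  List out(L);
  for (int l = 0; l < L; ++l) out[l] = H[l];
  return out;
}

// [[Rcpp::export]]
arma::mat seq2seq_decode_cpp(const List& params, const List& supports, int K,
                             const List& init, int t_f,
                             Nullable<NumericMatrix> teacher,
                             const LogicalVector& use_teacher) {
  Model m = model_from_list(params);
  std::vector<sp_mat> S = supports_from_list(supports);
  const int L = m.dec.size();
  std::vector<mat> H(L);
  for (int l = 0; l < L; ++l) H[l] = as<mat>(init[l]);
  const int N = H[0].n_rows;
  mat teach;
  bool has_teach = teacher.isNotNull();
  if (has_teach) teach = as<mat>(teacher.get());
  mat pred(N, t_f);
  mat prev(N, 1, arma::fill::zeros);  // GO symbol
  for (int t = 0; t < t_f; ++t) {
    mat X = prev;
    if (t > 0) {
      bool use_t = t - 1 < use_teacher.size() && use_teacher[t - 1];
      if (use_t && !has_teach) stop("teacher forcing requested but no teacher sequence supplied");
      X = use_t ? mat(teach.col(t - 1)) : mat(pred.col(t - 1));
    }
    for (int l = 0; l < L; ++l) {
      H[l] = cell_forward(X, H[l], m.dec[l], S, K, nullptr);
      X = H[l];
    }
    pred.col(t) = H[L - 1] * m.w + m.b;
  }
  return pred;
}

// Free-running forecasts for a list of input windows, run as one stacked
// batch (block-diagonal supports keep samples disconnected).
// [[Rcpp::export]]
List seq2seq_forecast_batch_cpp(const List& params, const List& supports,
                                int K, const List& x_batch, int t_f) {
  Model m = model_from_list(params);
  std::vector<sp_mat> S0 = supports_from_list(supports);
  const int B = x_batch.size();
  const int N = as<mat>(x_batch[0]).n_rows;
  std::vector<sp_mat> S;
  for (const sp_mat& s : S0) S.push_back(block_diag(s, B));
  mat x_seq = stack_batch(x_batch);
  const int L = m.enc.size(), Q = m.enc[0].br.n_elem;
  std::vector<mat> H(L, mat(x_seq.n_rows, Q, arma::fill::zeros));
  for (arma::uword t = 0; t < x_seq.n_cols; ++t) {
    mat X = x_seq.col(t);
    for (int l = 0; l < L; ++l) {
      H[l] = cell_forward(X, H[l], m.enc[l], S, K, nullptr);
      X = H[l];
    }
  }
  mat pred(x_seq.n_rows, t_f);
  mat prev(x_seq.n_rows, 1, arma::fill::zeros);
  for (int t = 0; t < t_f; ++t) {
    mat X = (t == 0) ? prev : mat(pred.col(t - 1));
    for (int l = 0; l < L; ++l) {
      H[l] = cell_forward(X, H[l], m.dec[l], S, K, nullptr);
      X = H[l];
    }
    pred.col(t) = H[L - 1] * m.w + m.b;
  }
  List out(B);
  for (int b = 0; b < B; ++b) out[b] = mat(pred.rows(b * N, (b + 1) * N - 1));
  return out;
}

// Full forward + BPTT over a mini-batch.  `use_teacher[t]` governs the input
// of decoder step t+1 (the first decoder input is always the GO zeros).
// Targets double as the teacher sequence during training.  The batch is
// stacked into one block-diagonal graph, which leaves the per-sample math
// unchanged (samples sit in disconnected components) but turns the many
// small matrix products into a few larger ones.
// [[Rcpp::export]]
List seq2seq_loss_grad_cpp(const List& params, const List& supports, int K,
                           const List& x_batch, const List& y_batch,
                           const LogicalVector& use_teacher) {
  Model m = model_from_list(params);
  std::vector<sp_mat> S = supports_from_list(supports);
  const int L = m.enc.size();
  const int Q = m.enc[0].br.n_elem;
  const int B = x_batch.size();

  auto zero_grads = [&](const std::vector<CellParams>& cells) {
    std::vector<CellGrads> g(cells.size());
    for (size_t l = 0; l < cells.size(); ++l) {
      g[l].Wr = arma::zeros<mat>(cells[l].Wr.n_rows, cells[l].Wr.n_cols);
      g[l].Wu = arma::zeros<mat>(cells[l].Wu.n_rows, cells[l].Wu.n_cols);
      g[l].Wc = arma::zeros<mat>(cells[l].Wc.n_rows, cells[l].Wc.n_cols);
      g[l].br = arma::zeros<vec>(cells[l].br.n_elem);
      g[l].bu = arma::zeros<vec>(cells[l].bu.n_elem);
      g[l].bc = arma::zeros<vec>(cells[l].bc.n_elem);
    }
    return g;
  };
  std::vector<CellGrads> genc = zero_grads(m.enc), gdec = zero_grads(m.dec);
  vec gw = arma::zeros<vec>(m.w.n_elem);
  double gb = 0.0, loss = 0.0;

  if (B > 1) {
    std::vector<sp_mat> Sb;
    for (const sp_mat& s : S) Sb.push_back(block_diag(s, B));
    S.swap(Sb);
  }
  {
    mat x_seq = stack_batch(x_batch);
    mat y_seq = stack_batch(y_batch);
    const int N = x_seq.n_rows;  // B * N0
    const int Tp = x_seq.n_cols, Tf = y_seq.n_cols;

    // ---- encoder forward with caches
    std::vector<std::vector<CellCache>> ecache(Tp, std::vector<CellCache>(L));
    std::vector<mat> H(L, mat(N, Q, arma::fill::zeros));
    for (int t = 0; t < Tp; ++t) {
      mat X = x_seq.col(t);
      for (int l = 0; l < L; ++l) {
        H[l] = cell_forward(X, H[l], m.enc[l], S, K, &ecache[t][l]);
        X = H[l];
      }
    }

    // ---- decoder forward with caches
    std::vector<std::vector<CellCache>> dcache(Tf, std::vector<CellCache>(L));
    std::vector<mat> Htop(Tf);  // top-layer hidden per step (for projection)
    mat pred(N, Tf);
    std::vector<mat> Hd = H;
    for (int t = 0; t < Tf; ++t) {
      mat X(N, 1, arma::fill::zeros);
      if (t > 0) X = use_teacher[t - 1] ? mat(y_seq.col(t - 1)) : mat(pred.col(t - 1));
      for (int l = 0; l < L; ++l) {
        Hd[l] = cell_forward(X, Hd[l], m.dec[l], S, K, &dcache[t][l]);
        X = Hd[l];
      }
      Htop[t] = Hd[L - 1];
      pred.col(t) = Htop[t] * m.w + m.b;
    }
    loss += arma::accu(arma::abs(pred - y_seq)) / (N * Tf);

    // ---- decoder backward
    const double sc = 1.0 / (N * Tf);
    std::vector<mat> dH(L, mat(N, Q, arma::fill::zeros));
    mat dfeed(N, 1, arma::fill::zeros);  // grad into pred.col(t-1) via input
    for (int t = Tf - 1; t >= 0; --t) {
      mat dpred = sc * arma::sign(pred.col(t) - y_seq.col(t));
      if (t + 1 < Tf && !use_teacher[t]) dpred += dfeed;
      gw += Htop[t].t() * dpred;
      gb += arma::accu(dpred);
      dH[L - 1] += dpred * m.w.t();
      mat dX;
      for (int l = L - 1; l >= 0; --l) {
        mat dHprev;
        dX = cell_backward(dH[l], dcache[t][l], m.dec[l], S, K, gdec[l], dHprev);
        dH[l] = dHprev;
        if (l > 0) dH[l - 1] += dX;
      }
      dfeed = dX;  // used at t-1 if that step was free-running
    }

    // ---- encoder backward (decoder initial states = encoder finals)
    for (int t = Tp - 1; t >= 0; --t) {
      for (int l = L - 1; l >= 0; --l) {
        mat dHprev;
        mat dX = cell_backward(dH[l], ecache[t][l], m.enc[l], S, K, genc[l], dHprev);
        dH[l] = dHprev;
        if (l > 0) dH[l - 1] += dX;
      }
    }
  }

  // Stacking already averages: the 1/(B*N0*Tf) loss scale propagates through
  // the whole backward pass.
  auto grads_to_list = [&](std::vector<CellGrads>& g) {
    List out(g.size());
    for (size_t l = 0; l < g.size(); ++l) {
      out[l] = List::create(_["Wr"] = g[l].Wr, _["Wu"] = g[l].Wu,
                            _["Wc"] = g[l].Wc, _["br"] = g[l].br,
                            _["bu"] = g[l].bu, _["bc"] = g[l].bc);
    }
    return out;
  };
  return List::create(
      _["loss"] = loss,
      _["grads"] = List::create(_["enc"] = grads_to_list(genc),
                                _["dec"] = grads_to_list(gdec),
                                _["w"] = gw, _["b"] = gb));
}

// ---------------------------------------------------------------------------
// VAR fitted by SGD on iterated multi-step forecasts (batch size 1), mirroring
// the windowed objective of the recurrent model.  A is N x (N*P), lag-block
// p (1-based) at columns (p-1)*N .. p*N-1.

namespace {

// Iterated forecast; z holds the rolling history (most recent last).
mat var_roll_forecast(const mat& A, const vec& b, const mat& history, int t_f) {
  const int N = A.n_rows, P = A.n_cols / N;
  mat pred(N, t_f);
  std::vector<vec> z;
  for (int j = history.n_cols - P; j < (int)history.n_cols; ++j)
    z.push_back(history.col(j));
  for (int t = 0; t < t_f; ++t) {
    vec x = b;
    for (int p = 1; p <= P; ++p)
      x += A.cols((p - 1) * N, p * N - 1) * z[z.size() - p];
    pred.col(t) = x;
    z.push_back(x);
  }
  return pred;
}

}  // namespace

// [[Rcpp::export]]
arma::mat var_forecast_cpp(const arma::mat& A, const arma::vec& b,
                           const arma::mat& history, int t_f) {
  return var_roll_forecast(A, b, history, t_f);
}

// [[Rcpp::export]]
List var_sgd_fit_cpp(arma::mat A, arma::vec b, const List& x_batch,
                     const List& y_batch, const arma::imat& order,
                     const arma::vec& lr_schedule) {
  const int N = A.n_rows, P = A.n_cols / N;
  const int epochs = order.n_rows;
  for (int e = 0; e < epochs; ++e) {
    const double lr = lr_schedule[e];
    for (arma::uword si = 0; si < order.n_cols; ++si) {
      const int s = order(e, si) - 1;  // 1-based from R
      mat x_seq = as<mat>(x_batch[s]);
      mat y_seq = as<mat>(y_batch[s]);
      const int Tf = y_seq.n_cols;
      // forward, keeping the full lag buffer
      std::vector<vec> z;
      for (int j = x_seq.n_cols - P; j < (int)x_seq.n_cols; ++j)
        z.push_back(x_seq.col(j));
      mat pred(N, Tf);
      for (int t = 0; t < Tf; ++t) {
        vec x = b;
        for (int p = 1; p <= P; ++p)
          x += A.cols((p - 1) * N, p * N - 1) * z[z.size() - p];
        pred.col(t) = x;
        z.push_back(x);
      }
      // backward through the recursion
      const double sc = 1.0 / (N * Tf);
      mat gA(N, N * P, arma::fill::zeros);
      vec gb(N, arma::fill::zeros);
      std::vector<vec> dz(z.size(), vec(N, arma::fill::zeros));
      for (int t = Tf - 1; t >= 0; --t) {
        const int zi = P + t;  // index of pred t in z
        vec dx = sc * arma::sign(pred.col(t) - y_seq.col(t)) + dz[zi];
        gb += dx;
        for (int p = 1; p <= P; ++p) {
          gA.cols((p - 1) * N, p * N - 1) += dx * z[zi - p].t();
          dz[zi - p] += A.cols((p - 1) * N, p * N - 1).t() * dx;
        }
      }
      A -= lr * gA;
      b -= lr * gb;
      if (!A.is_finite()) stop("VAR SGD diverged (non-finite coefficients)");
    }
  }
  return List::create(_["A"] = A, _["b"] = b);
}
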
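// Profiled marginal log-likelihood for the three-level linear growth model.
//
// Model per group j (individuals i, occasions t = 0..T-1):
//   y_j = X_j beta + Z3_j u_j + blockdiag_i(Z2 r_ij) + e_j,
//   u_j ~ N(0, G3) (4x4), r_ij ~ N(0, G2) (2x2), e ~ N(0, sigma2_e I).
// Marginally V_j = Z3_j G3 Z3_j' + blockdiag_i(W) with
//   W = Z2 G2 Z2' + sigma2_e I_T  (identical for every individual since all
//   share the occasion design Z2 = [1 t]).
//
// The fixed effects are concentrated out by GLS, leaving a likelihood in
// the covariance parameters only.  Two tricks keep an evaluation cheap:
//
// 1. Woodbury / matrix determinant lemma at the group level:
//      V^-1 = Wb^-1 - Wb^-1 Z3 (I + G3 S)^-1 G3 Z3' Wb^-1,  S = Z3'Wb^-1 Z3,
//      |V|  = |Wb| * prod_k (1 + mu_k),  mu = eig(G3 S),
//    which stays valid for negative or zero variance parameters; V is
//    positive definite iff W is and all mu_k > -1.
//
// 2. All quadratic forms reduce to per-group sufficient statistics
//      H_j^{ab} = sum_i t_ia' t_ib,  t_ia = [x_ia (6), y, z3_ia (4)],
//    computed once per dataset, so an evaluation costs O(J) small-matrix
//    work regardless of the number of individuals.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct SuffStats {
  arma::field<arma::cube> H; // per group: 11 x 11 x (T*T)
  arma::uvec ni;             // individuals per group
  int T;
  double N;                  // total observations
};

static const int P = 6;   // fixed effects
static const int D = 11;  // [X(6), y, Z3(4)]

// [[Rcpp::export(name = ".gmc_make_suffstats")]]
SEXP gmc_make_suffstats(const arma::mat& X, const arma::vec& y,
                        const arma::mat& Z3, const arma::ivec& ni, int T) {
  const int J = ni.n_elem;
  SuffStats* ss = new SuffStats;
  ss->T = T;
  ss->N = (double)y.n_elem;
  ss->ni = arma::conv_to<arma::uvec>::from(ni);
  ss->H.set_size(J);
  arma::uword row = 0;
  arma::rowvec ta(D), tb(D);
  for (int j = 0; j < J; ++j) {
    arma::cube Hj(D, D, T * T, fill::zeros);
    for (int i = 0; i < ni[j]; ++i) {
      for (int a = 0; a < T; ++a) {
        ta.subvec(0, P - 1) = X.row(row + a);
        ta(P) = y(row + a);
        ta.subvec(P + 1, D - 1) = Z3.row(row + a);
        for (int b = 0; b < T; ++b) {
          tb.subvec(0, P - 1) = X.row(row + b);
          tb(P) = y(row + b);
          tb.subvec(P + 1, D - 1) = Z3.row(row + b);
          Hj.slice(a * T + b) += ta.t() * tb;
        }
      }
      row += T;
    }
    ss->H(j) = Hj;
  }
  Rcpp::XPtr<SuffStats> ptr(ss, true);
  return ptr;
}

// Build G2 (2x2) and G3 (4x4) from the parameter vector.
// theta = sigma2_e, level-2 block, level-3 block.
// diagonal:  level-2 (r0, r1), level-3 (u00, u01, u10, u11)
// free adds: r01; then u-covariances in row-major upper-triangle order.
static void build_G(const arma::vec& theta, bool free2, bool free3,
                    double& s2e, arma::mat& G2, arma::mat& G3) {
  s2e = theta(0);
  int k = 1;
  G2.zeros(2, 2);
  G2(0, 0) = theta(k++);
  G2(1, 1) = theta(k++);
  if (free2) { G2(0, 1) = G2(1, 0) = theta(k++); }
  G3.zeros(4, 4);
  for (int d = 0; d < 4; ++d) G3(d, d) = theta(k++);
  if (free3)
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) { G3(a, b) = G3(b, a) = theta(k++); }
}

int gmc_n_theta(bool free2, bool free3) {
  return 1 + (free2 ? 3 : 2) + (free3 ? 10 : 4);
}

struct EvalResult {
  int status;    // 0 ok, 1 infeasible (V not pd), 2 singular GLS system
  double ll;
  arma::vec beta;
  arma::mat cov_beta;
};

static EvalResult eval_core(const SuffStats& ss, const arma::vec& theta,
                            bool free2, bool free3, bool full) {
  EvalResult out;
  out.status = 1;
  out.ll = NA_REAL;
  const int T = ss.T, J = ss.H.n_elem;

  double s2e;
  arma::mat G2, G3;
  build_G(theta, free2, free3, s2e, G2, G3);

  // occasion-level covariance, shared by every individual
  arma::mat Z2(T, 2);
  for (int t = 0; t < T; ++t) { Z2(t, 0) = 1.0; Z2(t, 1) = t; }
  arma::mat W = Z2 * G2 * Z2.t() + s2e * arma::eye(T, T);
  arma::mat cW;
  if (!arma::chol(cW, W, "lower")) return out;
  double ldW = 2.0 * arma::accu(arma::log(cW.diag()));
  arma::mat Winv = arma::inv_sympd(W);

  arma::mat XtVX(P, P, fill::zeros);
  arma::vec XtVy(P, fill::zeros);
  double ytVy = 0.0, ldet = 0.0;
  arma::mat A(D, D), Ssub(4, 4), Q(P + 1, 4), C(4, 4), B(P + 1, P + 1);
  arma::vec evS, mu;
  arma::mat Vs, Lt, Asm;

  for (int j = 0; j < J; ++j) {
    A.zeros();
    const arma::cube& Hj = ss.H(j);
    for (int a = 0; a < T; ++a)
      for (int b = 0; b < T; ++b)
        A += Winv(a, b) * Hj.slice(a * T + b);
    A = 0.5 * (A + A.t());
    Ssub = A.submat(P + 1, P + 1, D - 1, D - 1);
    Q = A.submat(0, P + 1, P, D - 1);
    if (!arma::eig_sym(evS, Vs, Ssub)) return out;
    evS = arma::clamp(evS, 0.0, datum::inf);
    Lt = arma::diagmat(arma::sqrt(evS)) * Vs.t();
    Asm = Lt * G3 * Lt.t();
    if (!arma::eig_sym(mu, Asm)) return out;
    if (mu.min() <= -1.0 + 1e-10) return out;
    ldet += ss.ni(j) * ldW + arma::accu(arma::log1p(mu));
    if (!arma::solve(C, arma::eye(4, 4) + G3 * Ssub, G3,
                     arma::solve_opts::no_approx))
      return out;
    C = 0.5 * (C + C.t());
    B = A.submat(0, 0, P, P) - Q * C * Q.t();
    XtVX += B.submat(0, 0, P - 1, P - 1);
    XtVy += B.submat(0, P, P - 1, P);
    ytVy += B(P, P);
  }

  XtVX = 0.5 * (XtVX + XtVX.t());
  arma::mat cXtVX;
  if (!arma::chol(cXtVX, XtVX, "lower")) { out.status = 2; return out; }
  arma::vec beta = arma::solve(arma::trimatl(cXtVX),  XtVy);
  beta = arma::solve(arma::trimatu(cXtVX.t()), beta);
  double quad = ytVy - arma::dot(beta, XtVy);
  out.ll = -0.5 * (ss.N * std::log(2.0 * M_PI) + ldet + quad);
  out.status = 0;
  if (full) {
    out.beta = beta;
    out.cov_beta = arma::inv_sympd(0.5 * (XtVX + XtVX.t()));
  }
  return out;
}

// [[Rcpp::export(name = ".gmc_ll")]]
double gmc_ll(SEXP ptr, const arma::vec& theta, bool free2, bool free3) {
  Rcpp::XPtr<SuffStats> ss(ptr);
  EvalResult r = eval_core(*ss, theta, free2, free3, false);
  return r.status == 0 ? r.ll : NA_REAL;
}

// [[Rcpp::export(name = ".gmc_ll_full")]]
Rcpp::List gmc_ll_full(SEXP ptr, const arma::vec& theta, bool free2,
                       bool free3) {
  Rcpp::XPtr<SuffStats> ss(ptr);
  EvalResult r = eval_core(*ss, theta, free2, free3, true);
  if (r.status != 0)
    return Rcpp::List::create(Rcpp::Named("status") = r.status,
                              Rcpp::Named("loglik") = NA_REAL);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("loglik") = r.ll,
                            Rcpp::Named("beta") = r.beta,
                            Rcpp::Named("cov_beta") = r.cov_beta);
}

// Central-difference gradient; falls back to one-sided steps at the edge
// of the feasible region, 0 if both sides are infeasible.
// [[Rcpp::export(name = ".gmc_grad")]]
arma::vec gmc_grad(SEXP ptr, const arma::vec& theta, bool free2, bool free3,
                   const arma::vec& h) {
  Rcpp::XPtr<SuffStats> ss(ptr);
  const int K = theta.n_elem;
  arma::vec g(K, fill::zeros);
  double f0 = NA_REAL;
  bool have_f0 = false;
  for (int k = 0; k < K; ++k) {
    arma::vec tp = theta, tm = theta;
    tp(k) += h(k); tm(k) -= h(k);
    EvalResult rp = eval_core(*ss, tp, free2, free3, false);
    EvalResult rm = eval_core(*ss, tm, free2, free3, false);
    if (rp.status == 0 && rm.status == 0) {
      g(k) = (rp.ll - rm.ll) / (2.0 * h(k));
    } else {
      if (!have_f0) {
        EvalResult r0 = eval_core(*ss, theta, free2, free3, false);
        f0 = (r0.status == 0) ? r0.ll : NA_REAL;
        have_f0 = true;
      }
      if (!ISNAN(f0) && rp.status == 0)      g(k) = (rp.ll - f0) / h(k);
      else if (!ISNAN(f0) && rm.status == 0) g(k) = (f0 - rm.ll) / h(k);
      else                                   g(k) = 0.0;
    }
  }
  return g;
}

// Observed information of the profile log-likelihood by central second
// differences; entries touching the infeasible region come back NaN.
// [[Rcpp::export(name = ".gmc_hess")]]
arma::mat gmc_hess(SEXP ptr, const arma::vec& theta, bool free2, bool free3,
                   const arma::vec& h) {
  Rcpp::XPtr<SuffStats> ss(ptr);
  const int K = theta.n_elem;
  arma::mat H(K, K, fill::value(NA_REAL));
  EvalResult r0 = eval_core(*ss, theta, free2, free3, false);
  if (r0.status != 0) return H;
  auto f = [&](const arma::vec& t) -> double {
    EvalResult r = eval_core(*ss, t, free2, free3, false);
    return r.status == 0 ? r.ll : NA_REAL;
  };
  for (int a = 0; a < K; ++a) {
    arma::vec tp = theta, tm = theta;
    tp(a) += h(a); tm(a) -= h(a);
    double fp = f(tp), fm = f(tm);
    if (!ISNAN(fp) && !ISNAN(fm))
      H(a, a) = (fp + fm - 2.0 * r0.ll) / (h(a) * h(a));
    for (int b = a + 1; b < K; ++b) {
      arma::vec tpp = theta, tpm = theta, tmp = theta, tmm = theta;
      tpp(a) += h(a); tpp(b) += h(b);
      tpm(a) += h(a); tpm(b) -= h(b);
      tmp(a) -= h(a); tmp(b) += h(b);
      tmm(a) -= h(a); tmm(b) -= h(b);
      double v1 = f(tpp), v2 = f(tpm), v3 = f(tmp), v4 = f(tmm);
      if (!ISNAN(v1) && !ISNAN(v2) && !ISNAN(v3) && !ISNAN(v4))
        H(a, b) = H(b, a) = (v1 - v2 - v3 + v4) / (4.0 * h(a) * h(b));
    }
  }
  return H;
}
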
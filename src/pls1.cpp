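// PLS-1 computational kernels.
//
// Two algebraically equivalent routes are used:
//  * sample-space NIPALS (cpp_pls1, cpp_loo_pred) for model fitting and
//    leave-one-out cross-validation;
//  * covariance-form NIPALS (cpp_mwplsr, cpp_search_subwindows) operating on
//    the Gram matrix G = Xc'Xc, so that every windowed candidate model is a
//    submatrix lookup instead of a fresh n x w decomposition.
// PLS-1 weights have a closed form per factor (w = X'y), so there is no
// iterative inner loop and no random initialisation anywhere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// SSR path for k = 1..kmax from the Gram form. Deflation of X translates to
// G <- G - vv'/tt and s <- s - q v with v = Gw. If the residual covariance
// vanishes before kmax factors, the SSR path is padded with its last value.
static arma::vec pls1_cov_ssr(arma::mat G, arma::vec s, double yy, int kmax) {
  const int p = G.n_rows;
  arma::vec ssr(kmax);
  double cur = yy;
  double scale = arma::norm(s);
  if (scale <= 0.0) scale = 1.0;
  for (int a = 0; a < kmax; ++a) {
    const double sn = arma::norm(s);
    if (a >= p || sn < 1e-13 * scale) {
      for (int b = a; b < kmax; ++b) ssr(b) = cur;
      return ssr;
    }
    arma::vec w = s / sn;
    arma::vec v = G * w;
    const double tt = arma::dot(w, v);
    if (!(tt > 1e-300)) {
      for (int b = a; b < kmax; ++b) ssr(b) = cur;
      return ssr;
    }
    const double q = arma::dot(w, s) / tt;
    cur -= q * q * tt;
    if (cur < 0.0) cur = 0.0;
    ssr(a) = cur;
    G -= (v * v.t()) / tt;
    s -= q * v;
  }
  return ssr;
}

// [[Rcpp::export]]
arma::vec cpp_pls1_cov_ssr(const arma::mat& G, const arma::vec& s, double yy,
                           int kmax) {
  return pls1_cov_ssr(G, s, yy, kmax);
}

// Full PLS-1 fit by sample-space NIPALS with deflation of X only.
// Returns weights W, loadings P, scores T, inner coefficients q, regression
// coefficient paths B (one column per latent-variable count), the SSR path,
// column means and the effective number of extractable factors.
// [[Rcpp::export]]
List cpp_pls1(const arma::mat& X, const arma::vec& y, int kmax) {
  const int n = X.n_rows, p = X.n_cols;
  arma::rowvec xm = arma::mean(X, 0);
  const double ym = arma::mean(y);
  arma::mat Xd = X.each_row() - xm;
  arma::vec yc = y - ym;

  arma::mat W(p, kmax, arma::fill::zeros), P(p, kmax, arma::fill::zeros);
  arma::mat T(n, kmax, arma::fill::zeros);
  arma::vec q(kmax, arma::fill::zeros), ssr(kmax, arma::fill::zeros);
  arma::vec res = yc;
  const double scale0 = std::max(arma::norm(Xd.t() * yc), 1e-300);
  int keff = 0;

  for (int a = 0; a < kmax; ++a) {
    arma::vec w = Xd.t() * yc;
    const double wn = arma::norm(w);
    if (wn < 1e-13 * scale0) break;
    w /= wn;
    arma::vec t = Xd * w;
    const double tt = arma::dot(t, t);
    if (!(tt > 1e-300)) break;
    arma::vec pv = Xd.t() * t / tt;
    const double qa = arma::dot(yc, t) / tt;
    Xd -= t * pv.t();
    W.col(a) = w;
    P.col(a) = pv;
    T.col(a) = t;
    q(a) = qa;
    res -= qa * t;
    ssr(a) = arma::dot(res, res);
    keff = a + 1;
  }
  for (int a = keff; a < kmax; ++a)
    ssr(a) = (keff > 0) ? ssr(keff - 1) : arma::dot(yc, yc);

  arma::mat B(p, kmax, arma::fill::zeros);
  for (int k = 1; k <= keff; ++k) {
    arma::mat Wk = W.cols(0, k - 1);
    arma::mat PtW = P.cols(0, k - 1).t() * Wk;
    arma::vec bk = Wk * arma::solve(PtW, q.subvec(0, k - 1));
    B.col(k - 1) = bk;
  }
  for (int k = keff + 1; k <= kmax; ++k)
    B.col(k - 1) = (keff > 0) ? B.col(keff - 1) : arma::vec(p, arma::fill::zeros);

  return List::create(_["W"] = W, _["P"] = P, _["T"] = T, _["q"] = q,
                      _["B"] = B, _["ssr"] = ssr,
                      _["x_mean"] = arma::vec(xm.t()), _["y_mean"] = ym,
                      _["k_eff"] = keff);
}

// Leave-one-out predictions for every latent-variable count 1..kmax.
// Centering is recomputed inside every fold. The held-out prediction is
// accumulated through the score path (exactly equivalent to forming the
// coefficient vector per k).
// [[Rcpp::export]]
arma::mat cpp_loo_pred(const arma::mat& X, const arma::vec& y, int kmax) {
  const int n = X.n_rows;
  arma::mat pred(n, kmax);
  for (int i = 0; i < n; ++i) {
    arma::mat Xd = X;
    Xd.shed_row(i);
    arma::vec yi = y;
    yi.shed_row(i);
    arma::rowvec xm = arma::mean(Xd, 0);
    const double ym = arma::mean(yi);
    Xd.each_row() -= xm;
    arma::vec yc = yi - ym;
    arma::rowvec xd = X.row(i) - xm;

    double acc = ym;
    const double scale0 = std::max(arma::norm(Xd.t() * yc), 1e-300);
    int a = 0;
    for (; a < kmax; ++a) {
      arma::vec w = Xd.t() * yc;
      const double wn = arma::norm(w);
      if (wn < 1e-13 * scale0) break;
      w /= wn;
      arma::vec t = Xd * w;
      const double tt = arma::dot(t, t);
      if (!(tt > 1e-300)) break;
      arma::vec pv = Xd.t() * t / tt;
      const double qa = arma::dot(yc, t) / tt;
      Xd -= t * pv.t();
      const double tnew = arma::dot(xd, w);
      acc += qa * tnew;
      xd -= tnew * pv.t();
      pred(i, a) = acc;
    }
    for (; a < kmax; ++a) pred(i, a) = acc;
  }
  return pred;
}

// Moving-window sweep over one contiguous segment: SSR for every window
// start position and every latent-variable count 1..kmax. Column centering
// of the whole segment equals per-window centering, so G and s are built
// once.
// [[Rcpp::export]]
arma::mat cpp_mwplsr(const arma::mat& X, const arma::vec& y, int H, int kmax) {
  const int n = X.n_rows, m = X.n_cols;
  arma::mat Xc = X.each_row() - arma::mean(X, 0);
  arma::vec yc = y - arma::mean(y);
  arma::mat G = Xc.t() * Xc;
  arma::vec s = Xc.t() * yc;
  const double yy = arma::dot(yc, yc);
  const int npos = m - H + 1;
  arma::mat out(npos, kmax);
  for (int i = 0; i < npos; ++i) {
    out.row(i) = pls1_cov_ssr(G.submat(i, i, i + H - 1, i + H - 1),
                              s.subvec(i, i + H - 1), yy, kmax).t();
  }
  return out;
}

// RMSEC of a PLS-1 model with k factors from the sample-space kernel
// M = Xc Xc'. The fitted values with k factors span the Krylov space
// K_k(M, M yc), so the calibration residual is obtained by projecting yc
// onto an orthonormal Krylov basis (modified Gram-Schmidt with one
// reorthogonalization pass). Width-independent: cost is O(k n^2) per
// candidate regardless of how many channels it holds. If the Krylov space
// exhausts early the residual simply stops shrinking, matching the NIPALS
// padding semantics.
static double krylov_rmsec(const arma::mat& M, const arma::vec& yc, int k,
                           arma::mat& Q /* n x >=k workspace */) {
  const int n = M.n_rows;
  arma::vec r = yc;
  arma::vec v = M * yc;
  const double v0 = arma::norm(v);
  if (v0 < 1e-300) return std::sqrt(arma::dot(r, r) / n);
  for (int j = 0; j < k; ++j) {
    if (j > 0) v = M * Q.col(j - 1);
    // orthogonalize against previous basis vectors, twice for stability
    for (int pass = 0; pass < 2; ++pass) {
      for (int i = 0; i < j; ++i) v -= arma::dot(Q.col(i), v) * Q.col(i);
    }
    const double nv = arma::norm(v);
    if (nv < 1e-10 * v0) break;  // Krylov space exhausted
    Q.col(j) = v / nv;
    r -= arma::dot(Q.col(j), r) * Q.col(j);
  }
  return std::sqrt(arma::dot(r, r) / n);
}

// Exhaustive sub-window search over one region, optionally in combination
// with a fixed base set of channels (SCMWPLS combination step).
//
// Xc is the centered sample-by-channel matrix over the columns
// [base (nb columns) | region (p columns)] in that order; yc the centered
// response. Every candidate is base + region[start .. start+w-1] for
// w = wmin..wmax (position stride `stride`), plus optionally the empty
// candidate (base alone). The model for a candidate uses
// k = min(kcap, #columns, n-1) latent variables. The kernel matrix
// M = Xc_S Xc_S' of a candidate is grown by symmetric rank-1 updates as
// the window widens, so the enumeration cost does not depend on widths.
//
// Tie-break on RMSEC equal within 1e-12: fewer candidate channels first,
// then smaller start index (higher starting wavenumber on a descending
// axis). Returns the winning start (1-based; 0 for the empty candidate),
// width, RMSEC, k used, and the number of models evaluated.
// [[Rcpp::export]]
List cpp_search_subwindows(const arma::mat& Xc, const arma::vec& yc,
                           int nb, int wmin, int wmax, int stride,
                           int kcap, bool include_empty) {
  const int n = Xc.n_rows;
  const int p = Xc.n_cols - nb;
  const double tol = 1e-12;
  double best_rmsec = R_PosInf;
  int best_w = -1, best_start = -1, best_k = 0;
  long nmodels = 0;
  arma::mat Q(n, std::min(kcap, n - 1), arma::fill::zeros);

  arma::mat Mbase(n, n, arma::fill::zeros);
  if (nb > 0) {
    arma::mat Xb = Xc.cols(0, nb - 1);
    Mbase = Xb * Xb.t();
  }

  if (include_empty && nb > 0) {
    const int k = std::min(kcap, std::min(nb, n - 1));
    best_rmsec = krylov_rmsec(Mbase, yc, k, Q);
    best_w = 0;
    best_start = 0;
    best_k = k;
    ++nmodels;
  }

  arma::mat M(n, n);
  for (int start = 0; start + wmin <= p; start += stride) {
    M = Mbase;
    const int wtop = std::min(wmax, p - start);
    for (int w = 1; w <= wtop; ++w) {
      const arma::vec x = Xc.col(nb + start + w - 1);
      M += x * x.t();
      if (w < wmin) continue;
      const int k = std::min(kcap, std::min(nb + w, n - 1));
      const double rm = krylov_rmsec(M, yc, k, Q);
      ++nmodels;
      bool better = rm < best_rmsec - tol;
      if (!better && std::abs(rm - best_rmsec) <= tol) {
        better = (w < best_w) || (w == best_w && start < best_start);
      }
      if (better) {
        best_rmsec = rm;
        best_w = w;
        best_start = start;
        best_k = k;
      }
    }
  }

  return List::create(_["start"] = best_start + 1, _["width"] = best_w,
                      _["rmsec"] = best_rmsec, _["k"] = best_k,
                      _["n_models"] = (double)nmodels);
}
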
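// Online Oja/Sanger training loop. The input activity is read through a
// lookup matrix (one column per distinct position / time step) indexed by
// `idx`, so a long random walk never materializes the full
// [neuron x time] stream. Weights are held transposed (inputs x outputs)
// so each output's vector is a contiguous column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List train_sanger_cpp(const arma::mat& lookup, const arma::ivec& idx,
                      const arma::mat& J_init, double eps0, double t0,
                      bool nonneg, bool derivative, double adapt_delta,
                      int record_every, double tol) {
  const arma::uword m = J_init.n_rows, n = J_init.n_cols;
  const arma::uword T = idx.n_elem;
  if (lookup.n_rows != n) stop("lookup/J dimension mismatch");
  if (record_every < 1) record_every = 1;

  arma::mat Jt = J_init.t();              // n x m
  arma::vec psibar(m, arma::fill::zeros);
  std::vector<double> norm_hist, delta_hist;
  double acc_delta = 0.0;
  arma::uword acc_n = 0;
  bool diverged = false, converged = false;
  arma::vec r(n), psi(m), cum(n);

  const arma::uword t_start = derivative ? 1 : 0;
  arma::uword steps = 0;
  for (arma::uword t = t_start; t < T; ++t) {
    const int j = idx[t];
    if (j < 0 || (arma::uword)j >= lookup.n_cols) stop("index out of range");
    if (derivative) {
      r = lookup.col(j) - lookup.col(idx[t - 1]);
    } else {
      r = lookup.col(j);
    }
    psi = Jt.t() * r;
    if (adapt_delta > 0.0) {
      psibar = (1.0 - adapt_delta) * psibar + adapt_delta * psi;
      psi -= psibar;
    }
    const double eps = eps0 / (1.0 + (double)steps / t0);
    const double* rp = r.memptr();
    double* cp = cum.memptr();
    double dsum = 0.0;
    std::fill(cp, cp + n, 0.0);
    for (arma::uword i = 0; i < m; ++i) {
      const double pi = psi[i], epi = eps * pi;
      double* Jc = Jt.colptr(i);
      // back-projection sum over outputs k <= i (pre-update values)
      for (arma::uword k = 0; k < n; ++k) cp[k] += pi * Jc[k];
      double rowsum = 0.0;
      for (arma::uword k = 0; k < n; ++k) {
        const double upd = epi * (rp[k] - cp[k]);
        dsum += std::fabs(upd);
        double v = Jc[k] + upd;
        if (nonneg && v < 0.0) v = 0.0;
        Jc[k] = v;
        rowsum += std::fabs(v);
      }
      if (nonneg && rowsum == 0.0) {
        // rectification annihilated the output: restart it at random
        for (arma::uword k = 0; k < n; ++k) Jc[k] = R::runif(0.0, 1.0);
        const double nrm = arma::norm(Jt.col(i), 2);
        for (arma::uword k = 0; k < n; ++k) Jc[k] /= nrm;
      }
    }
    ++steps;
    acc_delta += dsum / (double)(m * n);
    ++acc_n;
    if (steps % (arma::uword)record_every == 0) {
      const double nrm = arma::norm(Jt.col(0), 2);
      norm_hist.push_back(nrm);
      const double mean_delta = acc_delta / (double)acc_n;
      delta_hist.push_back(mean_delta);
      acc_delta = 0.0; acc_n = 0;
      if (nrm > 10.0 || !std::isfinite(nrm)) { diverged = true; break; }
      if (tol > 0.0 && mean_delta < tol) { converged = true; break; }
    }
  }
  if (!diverged && tol > 0.0 && !delta_hist.empty() &&
      delta_hist.back() < tol) {
    converged = true;
  }
  return List::create(
      _["J"] = Jt.t(), _["norm_history"] = norm_hist,
      _["delta_history"] = delta_hist, _["steps"] = (double)steps,
      _["converged"] = converged, _["diverged"] = diverged);
}
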
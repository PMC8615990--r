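// Cross-validated shrinkage-LDA decoding core.
//
// Implements the same estimator as the R-level fit_lda(): pooled
// class-centered covariance S = Z'Z/(n-1), analytic Ledoit-Wolf-style
// shrinkage toward nu*I (nu = mean diagonal), w = Sigma^{-1}(mu+ - mu-),
// b = -w'(mu+ + mu-)/2, predicted class = (w'x + b >= 0) ? +1 : -1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// `scatter` optionally carries the precomputed total train scatter
// Xtr' * Xtr (reused across label permutations); the class-centered
// scatter then follows by a rank-2 downdate.
static double fold_accuracy(const mat& Xtr, const vec& ytr,
                            const mat& Xte, const vec& yte,
                            double shrink, const mat* scatter = nullptr) {
  const uvec pos = find(ytr > 0);
  const uvec neg = find(ytr < 0);
  if (pos.n_elem == 0 || neg.n_elem == 0) {
    Rcpp::stop("a training split contains a single class; "
               "rebalance folds or labels before decoding");
  }
  const double n = Xtr.n_rows;
  const uword p = Xtr.n_cols;

  rowvec mup = mean(Xtr.rows(pos), 0);
  rowvec mum = mean(Xtr.rows(neg), 0);
  mat Z = Xtr;
  for (uword i = 0; i < Z.n_rows; ++i) {
    Z.row(i) -= (ytr(i) > 0) ? mup : mum;
  }
  mat P;
  if (scatter != nullptr) {
    P = *scatter - (double)pos.n_elem * (mup.t() * mup)
                 - (double)neg.n_elem * (mum.t() * mum);
  } else {
    P = Z.t() * Z;
  }
  mat S = P / (n - 1.0);
  const double nu = trace(S) / p;

  double lambda;
  if (shrink >= 0.0) {
    lambda = shrink;
  } else if (nu == 0.0) {
    lambda = 1.0;
  } else {
    mat Z2 = square(Z);
    mat Q = Z2.t() * Z2;
    mat var_s = (n / std::pow(n - 1.0, 2)) * (Q / n - square(P / n));
    mat D = S;
    D.diag() -= nu;
    const double den = accu(square(D));
    lambda = (den <= 0.0) ? 1.0
                          : std::min(1.0, std::max(0.0, accu(var_s) / den));
  }

  mat Sigma = (1.0 - lambda) * S;
  Sigma.diag() += lambda * nu;
  vec d = (mup - mum).t();
  vec w;
  if (!solve(w, Sigma, d, solve_opts::no_approx)) {
    w = pinv(Sigma) * d;
  }
  const double b = -dot(w, (mup + mum).t()) / 2.0;

  vec dv = Xte * w + b;
  double correct = 0.0;
  for (uword i = 0; i < dv.n_elem; ++i) {
    const double pred = (dv(i) >= 0.0) ? 1.0 : -1.0;
    if (pred == yte(i)) correct += 1.0;
  }
  return correct / dv.n_elem;
}

// X: n_trials x n_channels x n_times; y in {+1,-1}; fold in 1..F.
// shrink < 0 requests the analytic shrinkage. Returns n_times x F fold
// accuracies.
// [[Rcpp::export]]
arma::mat cpp_cv_accuracy(const arma::cube& X, const arma::vec& y,
                          const arma::ivec& fold, double shrink) {
  const uword T = X.n_slices;
  const uword F = fold.max();
  mat out(T, F);
  std::vector<uvec> tr(F), te(F);
  for (uword f = 0; f < F; ++f) {
    te[f] = find(fold == (sword)(f + 1));
    tr[f] = find(fold != (sword)(f + 1));
  }
  for (uword t = 0; t < T; ++t) {
    const mat Xt = X.slice(t);
    for (uword f = 0; f < F; ++f) {
      out(t, f) = fold_accuracy(Xt.rows(tr[f]), y(tr[f]),
                                Xt.rows(te[f]), y(te[f]), shrink);
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// perms: n_trials x n_perm matrix of permuted labels. Returns
// n_perm x n_times fold-averaged accuracies.
// [[Rcpp::export]]
arma::mat cpp_perm_null(const arma::cube& X, const arma::mat& perms,
                        const arma::ivec& fold, double shrink) {
  const uword T = X.n_slices;
  const uword F = fold.max();
  const uword n_perm = perms.n_cols;
  mat out(n_perm, T);
  std::vector<uvec> tr(F), te(F);
  for (uword f = 0; f < F; ++f) {
    te[f] = find(fold == (sword)(f + 1));
    tr[f] = find(fold != (sword)(f + 1));
  }
  std::vector<mat> Xtr(F), Xte(F), Ctr(F);
  for (uword t = 0; t < T; ++t) {
    const mat Xt = X.slice(t);
    for (uword f = 0; f < F; ++f) {
      Xtr[f] = Xt.rows(tr[f]);
      Xte[f] = Xt.rows(te[f]);
      Ctr[f] = Xtr[f].t() * Xtr[f];
    }
    for (uword j = 0; j < n_perm; ++j) {
      const vec yj = perms.col(j);
      double acc = 0.0;
      for (uword f = 0; f < F; ++f) {
        acc += fold_accuracy(Xtr[f], yj(tr[f]), Xte[f], yj(te[f]), shrink,
                             &Ctr[f]);
      }
      out(j, t) = acc / F;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
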
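#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Scaled forward-backward recursions for one scan.
//
// logB: T x K matrix of per-state Gaussian log-densities.
// Densities are exponentiated after subtracting the rowwise max, so the
// recursion never under/overflows even for T ~ 1e5 or extreme densities.
// Returns gamma (T x K), xi (K x K expected transition counts summed over
// t = 1..T-1) and the scan log-likelihood.
// [[Rcpp::export(name = ".fb_core")]]
Rcpp::List fb_core(const arma::mat& logB,
                   const arma::vec& init_probs,
                   const arma::mat& trans) {
  const uword T = logB.n_rows;
  const uword K = logB.n_cols;

  vec shift = max(logB, 1);           // per-timepoint max log-density
  mat B(T, K);
  for (uword t = 0; t < T; ++t)
    B.row(t) = exp(logB.row(t) - shift(t));

  mat alpha(T, K), beta(T, K);
  vec c(T);                            // scaling constants

  alpha.row(0) = init_probs.t() % B.row(0);
  c(0) = accu(alpha.row(0));
  alpha.row(0) /= c(0);
  for (uword t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * trans) % B.row(t);
    c(t) = accu(alpha.row(t));
    alpha.row(t) /= c(t);
  }

  beta.row(T - 1).ones();
  for (uword t = T - 1; t > 0; --t) {
    rowvec tmp = (beta.row(t) % B.row(t)) * trans.t();
    beta.row(t - 1) = tmp / c(t);
  }

  mat gamma = alpha % beta;
  gamma.each_col() /= sum(gamma, 1);   // renormalize against roundoff

  mat xi(K, K, fill::zeros);
  for (uword t = 0; t + 1 < T; ++t) {
    mat step = (alpha.row(t).t() * (beta.row(t + 1) % B.row(t + 1))) % trans;
    xi += step / c(t + 1);
  }

  double loglik = accu(log(c)) + accu(shift);

  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi") = xi,
                            Rcpp::Named("loglik") = loglik);
}

// Markov chain sampler: states are 1-based, driven by pre-drawn uniforms so
// the caller controls the RNG stream from R.
// [[Rcpp::export(name = ".mc_sample_path")]]
Rcpp::IntegerVector mc_sample_path(const arma::vec& init_probs,
                                   const arma::mat& trans,
                                   const arma::vec& u) {
  const uword T = u.n_elem;
  const uword K = init_probs.n_elem;
  Rcpp::IntegerVector path(T);

  mat cum_trans = cumsum(trans, 1);
  vec cum_init = cumsum(init_probs);

  uword s = 0;
  while (s + 1 < K && u(0) > cum_init(s)) ++s;
  path[0] = s + 1;
  for (uword t = 1; t < T; ++t) {
    uword j = 0;
    while (j + 1 < K && u(t) > cum_trans(s, j)) ++j;
    s = j;
    path[t] = s + 1;
  }
  return path;
}
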
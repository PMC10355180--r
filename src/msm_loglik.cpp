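// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Matrix exponential via Armadillo (Pade approximation with scaling and
// squaring). Exposed so the R-level transition_matrix() and the likelihood
// share one implementation.
// [[Rcpp::export]]
arma::mat expm_pade(const arma::mat& M) {
  return arma::expmat(M);
}

static arma::mat build_Q_arma(const arma::vec& theta, const arma::mat& beta,
                              const arma::ivec& pair_from, const arma::ivec& pair_to,
                              int nstates, const arma::rowvec& z) {
  arma::mat Q(nstates, nstates, arma::fill::zeros);
  const int npair = theta.n_elem;
  for (int p = 0; p < npair; ++p) {
    double lin = theta(p);
    if (beta.n_cols > 0) lin += arma::dot(beta.row(p), z);
    Q(pair_from(p) - 1, pair_to(p) - 1) = std::exp(lin);
  }
  for (int r = 0; r < nstates; ++r) {
    Q(r, r) = 0.0;
    Q(r, r) = -arma::accu(Q.row(r));
  }
  return Q;
}

// Panel-data log-likelihood for a continuous-time multi-state Markov model.
//
// Observed transitions are collapsed into "blocks" sharing one elapsed time
// and one covariate vector, so each block needs a single matrix exponential:
//   loglik = sum_blocks sum_rows count * log P_{from,to}(dt; Q(z)).
//
// theta       baseline log-intensities, one per allowed transition
// beta        npair x ncov covariate coefficients (0 where a covariate is
//             not attached to a transition)
// pair_from, pair_to  1-based states of the allowed transitions
// block_dt    elapsed time per block (model time units)
// block_z     nblock x ncov covariate values per block
// row_block, row_from, row_to  1-based block/state indices per collapsed row
// row_count   multiplicity of each collapsed row
//
// Returns -Inf when any observed transition has probability (numerically)
// zero under the model.
// [[Rcpp::export]]
double msm_panel_loglik_cpp(const arma::vec& theta, const arma::mat& beta,
                            const arma::ivec& pair_from, const arma::ivec& pair_to,
                            int nstates,
                            const arma::vec& block_dt, const arma::mat& block_z,
                            const arma::ivec& row_block, const arma::ivec& row_from,
                            const arma::ivec& row_to, const arma::vec& row_count) {
  const int nblock = block_dt.n_elem;
  const int nrow = row_block.n_elem;

  // log P for each block, filled lazily in block order (rows are sorted by
  // block on the R side, but do not rely on it)
  std::vector<arma::mat> logP(nblock);
  std::vector<bool> done(nblock, false);

  double ll = 0.0;
  for (int i = 0; i < nrow; ++i) {
    const int b = row_block(i) - 1;
    if (!done[b]) {
      arma::rowvec z(block_z.n_cols, arma::fill::zeros);
      if (block_z.n_cols > 0) z = block_z.row(b);
      arma::mat Q = build_Q_arma(theta, beta, pair_from, pair_to, nstates, z);
      arma::mat P = arma::expmat(Q * block_dt(b));
      logP[b] = P;
      done[b] = true;
    }
    const double p = logP[b](row_from(i) - 1, row_to(i) - 1);
    if (!(p > 1e-320) || !std::isfinite(p)) return -arma::datum::inf;
    ll += row_count(i) * std::log(p);
  }
  return ll;
}
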
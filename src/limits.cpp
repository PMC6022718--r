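// Forward stepwise regression with bagging (LIMITS inner loop).
//
// For each focal taxon i, the log-abundance increment y_i(t) is regressed on
// predictor abundances x_j(t). The self-interaction predictor is always kept;
// further predictors are added greedily while the held-out sum of squared
// errors improves by more than a relative threshold. Coefficients are
// aggregated over bags (random half splits) by the median, with a predictor
// absent from a bag contributing 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double test_sse(const arma::mat& Gte, const arma::vec& cte,
                       double yty, const arma::vec& beta) {
  return yty - 2.0 * arma::dot(beta, cte) + arma::as_scalar(beta.t() * Gte * beta);
}

// [[Rcpp::export(name = ".limits_bag_cpp")]]
List limits_bag_cpp(const arma::mat& X, const arma::mat& Y,
                    int n_bags, double threshold, int max_predictors) {
  const int n = X.n_rows;       // usable transitions
  const int S = X.n_cols;       // taxa (= predictors = responses)
  const int P = S + 1;          // + intercept column 0
  if (n < 4) stop("too few time points for a train/test split");

  arma::mat Xi(n, P);
  Xi.col(0).ones();
  Xi.cols(1, P - 1) = X;

  // bag-level coefficient store, one slice per focal taxon
  arma::cube coef(n_bags, S, S, arma::fill::zeros); // (bag, predictor, focal)
  arma::mat freq(S, S, arma::fill::zeros);          // selection frequency (focal, predictor)

  IntegerVector idx = seq(0, n - 1);
  const int ntr = n / 2;

  for (int b = 0; b < n_bags; ++b) {
    IntegerVector perm = sample(idx, n, false);
    arma::uvec tr(ntr), te(n - ntr);
    for (int k = 0; k < ntr; ++k) tr[k] = perm[k];
    for (int k = ntr; k < n; ++k) te[k - ntr] = perm[k];

    arma::mat Xtr = Xi.rows(tr), Xte = Xi.rows(te);
    arma::mat Gtr = Xtr.t() * Xtr, Gte = Xte.t() * Xte;
    arma::mat Ctr = Xtr.t() * Y.rows(tr), Cte = Xte.t() * Y.rows(te);
    arma::rowvec yty = arma::sum(arma::square(Y.rows(te)), 0);

    for (int i = 0; i < S; ++i) {
      std::vector<arma::uword> active;
      active.push_back(0);                 // intercept
      active.push_back((arma::uword) i + 1); // self-interaction
      std::vector<bool> in_model(P, false);
      in_model[0] = true;
      in_model[i + 1] = true;

      arma::uvec act(active);
      arma::vec beta;
      bool ok = arma::solve(beta, Gtr.submat(act, act), Ctr(act, arma::uvec{(arma::uword) i}),
                            arma::solve_opts::no_approx);
      if (!ok) continue;
      double sse = test_sse(Gte.submat(act, act), Cte(act, arma::uvec{(arma::uword) i}),
                            yty[i], beta);

      while ((int) active.size() - 1 < max_predictors) {
        if (!(sse > 0) || !std::isfinite(sse)) break;
        double best_sse = sse;
        int best_j = -1;
        arma::vec best_beta;
        for (int j = 1; j < P; ++j) {
          if (in_model[j]) continue;
          std::vector<arma::uword> cand = active;
          cand.push_back((arma::uword) j);
          arma::uvec cu(cand);
          arma::vec bc;
          if (!arma::solve(bc, Gtr.submat(cu, cu), Ctr(cu, arma::uvec{(arma::uword) i}),
                           arma::solve_opts::no_approx)) continue;
          double s = test_sse(Gte.submat(cu, cu), Cte(cu, arma::uvec{(arma::uword) i}),
                              yty[i], bc);
          if (std::isfinite(s) && s < best_sse) {
            best_sse = s;
            best_j = j;
            best_beta = bc;
          }
        }
        if (best_j < 0) break;
        if ((sse - best_sse) / sse <= threshold) break;
        active.push_back((arma::uword) best_j);
        in_model[best_j] = true;
        sse = best_sse;
        act = arma::uvec(active);
        beta = best_beta;
      }

      // store coefficients of this bag (skip intercept)
      for (size_t k = 1; k < active.size(); ++k) {
        int j = (int) active[k] - 1;
        coef(b, j, i) = beta[k];
        freq(i, j) += 1.0;
      }
    }
  }

  freq /= (double) n_bags;
  arma::mat Ahat(S, S, arma::fill::zeros);
  for (int i = 0; i < S; ++i) {
    for (int j = 0; j < S; ++j) {
      arma::vec v = coef.slice(i).col(j); // bag values, absent = 0
      Ahat(i, j) = arma::median(v);
    }
  }
  return List::create(_["matrix"] = Ahat, _["frequency"] = freq);
}
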
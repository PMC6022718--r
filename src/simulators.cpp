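// Individual-based community simulators.
//
// Both simulators use R's RNG (RNGScope via Rcpp attributes), so runs are
// reproducible with set.seed() from the R side.

#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric draw: remove `k` individuals uniformly at
// random without replacement from species pools `counts` (modified in place).
static void remove_hypergeometric(std::vector<int>& counts, int k) {
  int total = 0;
  for (size_t i = 0; i < counts.size(); ++i) total += counts[i];
  if (k >= total) {
    std::fill(counts.begin(), counts.end(), 0);
    return;
  }
  int remaining = k;
  int rest = total;
  for (size_t i = 0; i < counts.size() && remaining > 0; ++i) {
    rest -= counts[i];
    // deaths within species i among `remaining` draws from counts[i] + rest
    int d = (int) ::Rf_rhyper((double) counts[i], (double) rest, (double) remaining);
    counts[i] -= d;
    remaining -= d;
  }
}

// Weighted draw of a species index proportional to counts (sum > 0).
static int sample_species(const std::vector<int>& counts, int total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < counts.size(); ++i) {
    acc += counts[i];
    if (u < acc) return (int) i;
  }
  return (int) counts.size() - 1;
}

// Draw from a cumulative probability vector (last entry ~ 1).
static int sample_cum(const NumericVector& cum) {
  double u = unif_rand();
  int n = cum.size();
  for (int i = 0; i < n; ++i) if (u <= cum[i]) return i;
  return n - 1;
}

// [[Rcpp::export(name = ".hubbell_sim_cpp")]]
IntegerMatrix hubbell_sim_cpp(IntegerVector init_counts, NumericVector metacommunity,
                              int deaths, double m, int n_keep, int burn_in) {
  int S = init_counts.size();
  std::vector<int> counts(S);
  int total = 0;
  for (int i = 0; i < S; ++i) { counts[i] = init_counts[i]; total += counts[i]; }

  NumericVector cum_meta(S);
  double acc = 0.0;
  for (int i = 0; i < S; ++i) { acc += metacommunity[i]; cum_meta[i] = acc; }

  IntegerMatrix out(S, n_keep);
  int n_steps = burn_in + n_keep;
  for (int t = 0; t < n_steps; ++t) {
    remove_hypergeometric(counts, deaths);
    int occupied = total - deaths;
    for (int v = 0; v < deaths; ++v) {
      int sp;
      if (occupied == 0 || unif_rand() < m) {
        sp = sample_cum(cum_meta);
      } else {
        sp = sample_species(counts, occupied);
      }
      counts[sp] += 1;
      occupied += 1;
    }
    if (t >= burn_in) {
      int col = t - burn_in;
      for (int i = 0; i < S; ++i) out(i, col) = counts[i];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".soi_sim_cpp")]]
IntegerMatrix soi_sim_cpp(IntegerVector init_counts, int n_sites,
                          NumericVector immigration, NumericVector extinction,
                          NumericMatrix alpha, int n_keep) {
  int S = init_counts.size();
  std::vector<int> counts(S);
  int occupied = 0;
  for (int i = 0; i < S; ++i) { counts[i] = init_counts[i]; occupied += counts[i]; }
  if (occupied > n_sites) stop("initial individuals exceed the number of sites");

  IntegerMatrix out(S, n_keep);
  IntegerVector order = seq(0, S - 1);

  for (int t = 0; t < n_keep; ++t) {
    // (1) immigration: species colonize empty sites; species order randomized
    // each generation to avoid systematic priority.
    int empty = n_sites - occupied;
    IntegerVector perm = sample(order, S, false);
    for (int k = 0; k < S && empty > 0; ++k) {
      int i = perm[k];
      if (immigration[i] <= 0) continue;
      int col = (int) ::Rf_rbinom((double) empty, immigration[i]);
      counts[i] += col;
      empty -= col;
      occupied += col;
    }
    // (2) extinction: each individual dies independently.
    for (int i = 0; i < S; ++i) {
      if (counts[i] == 0 || extinction[i] <= 0) continue;
      int d = (int) ::Rf_rbinom((double) counts[i], extinction[i]);
      counts[i] -= d;
      occupied -= d;
    }
    // (3) interaction: sample as many ordered pairs as occupied sites;
    // the first individual (species i) replaces the second (species j)
    // when alpha[j, i] is negative and stronger than a uniform draw.
    int n_pairs = occupied;
    for (int p = 0; p < n_pairs; ++p) {
      if (occupied < 2) break;
      int i = sample_species(counts, occupied);
      int j = sample_species(counts, occupied);
      if (i == j) continue;
      double a = alpha(j, i);
      if (a < 0 && -a > unif_rand()) {
        counts[j] -= 1;
        counts[i] += 1;
      }
    }
    for (int i = 0; i < S; ++i) out(i, t) = counts[i];
  }
  return out;
}
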
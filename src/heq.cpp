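#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Constant-size coalescent of n gene copies with stepwise-type mutation,
// in coalescent time units (pairwise coalescence rate 1, mutation rate
// theta/2 per lineage). Each mutation moves the repeat count by +/-1 with
// probability p_step, otherwise by +/- (2 + Geom(p)) with p chosen so the
// multi-step mean is multi_step_mean. Returns an n_sims x 2 matrix with the
// simulated allele count k and the unbiased expected heterozygosity
// He = n (1 - sum p_a^2) / (n - 1) of each replicate. Uses R's RNG stream.
// [[Rcpp::export]]
NumericMatrix heq_replicates_cpp(int n, double theta, double p_step,
                                 double multi_step_mean, int n_sims) {
  if (n < 2) stop("need n >= 2 gene copies");
  if (theta < 0) stop("theta must be >= 0");
  const double pgeo = 1.0 / (multi_step_mean - 1.0);
  NumericMatrix out(n_sims, 2);
  const int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes);
  std::vector<double> ntime(n_nodes);
  std::vector<int> active(n);
  std::vector<double> state(n_nodes);
  RNGScope scope;
  for (int s = 0; s < n_sims; ++s) {
    for (int i = 0; i < n; ++i) { active[i] = i; ntime[i] = 0.0; }
    double t = 0.0;
    int next_node = n;
    for (int i = n; i >= 2; --i) {
      double rate = 0.5 * i * (i - 1);
      t += R::exp_rand() / rate;
      int a = (int)(unif_rand() * i); if (a == i) a = i - 1;
      int b = (int)(unif_rand() * (i - 1)); if (b == i - 1) b = i - 2;
      if (b >= a) ++b;
      parent[active[a]] = next_node;
      parent[active[b]] = next_node;
      ntime[next_node] = t;
      active[a] = next_node;
      active[b] = active[i - 1];
      ++next_node;
    }
    // propagate allele states from the root down (parent index > child)
    state[n_nodes - 1] = 0.0;
    for (int v = n_nodes - 2; v >= 0; --v) {
      double blen = ntime[parent[v]] - ntime[v];
      int m = (int)R::rpois(0.5 * theta * blen);
      double sv = state[parent[v]];
      for (int j = 0; j < m; ++j) {
        double step;
        if (unif_rand() < p_step) step = 1.0;
        else step = 2.0 + R::rgeom(pgeo);
        if (unif_rand() < 0.5) step = -step;
        sv += step;
      }
      state[v] = sv;
    }
    std::map<double, int> tab;
    for (int i = 0; i < n; ++i) tab[state[i]] += 1;
    double sum_p2 = 0.0;
    for (std::map<double, int>::iterator it = tab.begin(); it != tab.end();
         ++it) {
      double p = (double)it->second / n;
      sum_p2 += p * p;
    }
    out(s, 0) = (double)tab.size();
    out(s, 1) = n * (1.0 - sum_p2) / (n - 1.0);
  }
  return out;
}
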
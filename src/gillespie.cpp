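#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact event-driven (Gillespie) simulation of translation on independent
// mRNA copies. State per copy: sorted ribosome front positions (1-based,
// ascending; the lead ribosome has the largest position) plus an optional
// initiation-inhibitor bound/free flag. Moves, initiations and terminations
// follow the same footprint rules as the deterministic model:
//   initiation   : codons 1..L empty  (no front <= L), rate kappa (if free)
//   elongation   : front i -> i+1 needs codon i+L empty (none if i+L > n)
//   termination  : front at n, rate kT
// Uses R's RNG so set.seed() makes runs reproducible.

static double rexp_rate(double r) { return -std::log(unif_rand()) / r; }

// [[Rcpp::export]]
List rt_simulate(int n, int L, NumericVector kE_in, double kappa, double kT,
                 int n_copies, double t_end, double burn_in,
                 double k_on, double k_off, double p_bound0,
                 bool collect_completions) {
  std::vector<double> kE(kE_in.begin(), kE_in.end());
  if ((int)kE.size() == 1) kE.assign(n, kE[0]);

  NumericVector time_avg(n_copies);
  IntegerVector final_count(n_copies);
  List completions(collect_completions ? n_copies : 0);

  std::vector<double> rates;
  std::vector<double> comp;

  for (int c = 0; c < n_copies; ++c) {
    std::vector<int> pos;  // ascending fronts
    bool bound = (p_bound0 > 0.0) && (unif_rand() < p_bound0);
    double t = 0.0, acc = 0.0;
    comp.clear();

    while (t < t_end) {
      int P = (int)pos.size();
      rates.clear();
      double R = 0.0;
      // 0: initiation
      double r_init =
          (!bound && (P == 0 || pos[0] > L)) ? kappa : 0.0;
      rates.push_back(r_init); R += r_init;
      // 1..P: ribosome moves / termination
      for (int j = 0; j < P; ++j) {
        int i = pos[j];
        double r;
        if (i == n) r = kT;
        else if (i + L > n) r = kE[i - 1];
        else if (j == P - 1 || pos[j + 1] > i + L) r = kE[i - 1];
        else r = 0.0;
        rates.push_back(r); R += r;
      }
      // P+1: inhibitor exchange
      double r_sw = bound ? k_off : k_on;
      rates.push_back(r_sw); R += r_sw;

      double t_next = (R > 0.0) ? t + rexp_rate(R) : t_end;
      double a = std::max(t, burn_in), b = std::min(t_next, t_end);
      if (b > a) acc += P * (b - a);
      t = t_next;
      if (t >= t_end || R <= 0.0) break;

      double u = unif_rand() * R, csum = 0.0;
      int ev = -1;
      for (size_t k = 0; k < rates.size(); ++k) {
        csum += rates[k];
        if (u <= csum) { ev = (int)k; break; }
      }
      if (ev < 0) ev = (int)rates.size() - 1;

      if (ev == 0) {
        pos.insert(pos.begin(), 1);
      } else if (ev == P + 1) {
        bound = !bound;
      } else {
        int j = ev - 1;
        if (pos[j] == n) {
          pos.pop_back();
          if (collect_completions && t >= burn_in) comp.push_back(t);
        } else {
          pos[j] += 1;
        }
      }
    }
    double span = t_end - burn_in;
    time_avg[c] = (span > 0.0) ? acc / span : NA_REAL;
    final_count[c] = (int)pos.size();
    if (collect_completions)
      completions[c] = NumericVector(comp.begin(), comp.end());
  }
  return List::create(_["time_avg"] = time_avg,
                      _["final_count"] = final_count,
                      _["completions"] = completions);
}
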
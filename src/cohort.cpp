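#include <Rcpp.h>
using namespace Rcpp;

// Batch cohort engine: propagates the five-state occupancy vector for every
// draw and arm, accumulating discounted costs and QALYs. Rewards accrue on
// cycle-start occupancy by default; the half-cycle option averages start and
// end occupancy. State layout: 0..3 = NYHA I-IV (living), 4 = DEAD
// (absorbing). Transition array layout: (from 4, to 5, phase, arm 3, draw).
// Resource blocks: hosp_er (res_arms, 4, 2, draw), contacts
// (res_arms, 4, 5, draw) with res_arms 1 (shared) or 3; unit costs (7, draw)
// ordered as the concatenation of the two blocks.
// [[Rcpp::export]]
List cohort_batch_cpp(NumericVector trans, int n_phases, int n,
                      NumericMatrix util,        // 4 x n, living states
                      NumericVector hosp_er,     // res_arms x 4 x 2 x n
                      NumericVector contacts,    // res_arms x 4 x 5 x n
                      int res_arms,
                      NumericMatrix unit_costs,  // 7 x n
                      NumericVector install_fee, // n
                      NumericVector service_fee, // n
                      double nts_cost,
                      int replacement_cycles,
                      NumericMatrix init,        // 4 x n
                      NumericVector disc_c,      // n_cycles
                      NumericVector disc_e,      // n_cycles
                      int n_cycles, double cycle_years,
                      bool half_cycle) {
  NumericMatrix costs(n, 3), effects(n, 3);
  const double *tr = REAL(trans);
  const double *he = REAL(hosp_er);
  const double *co = REAL(contacts);

  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < 3; ++a) {
      const int ra = res_arms == 3 ? a : 0;
      // per-state cost this cycle: resource counts dotted with unit costs
      double sc[4];
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (int t = 0; t < 2; ++t)
          acc += he[ra + res_arms * (s + 4 * (t + 2 * (std::size_t)i))] *
                 unit_costs(t, i);
        for (int t = 0; t < 5; ++t)
          acc += co[ra + res_arms * (s + 4 * (t + 5 * (std::size_t)i))] *
                 unit_costs(2 + t, i);
        sc[s] = acc;
      }

      double pi[5], nxt[5], w[5];
      for (int s = 0; s < 4; ++s) pi[s] = init(s, i);
      pi[4] = 0.0;
      double cost = 0.0, qaly = 0.0;
      const std::size_t arm_off =
          (std::size_t)20 * n_phases * (a + (std::size_t)3 * i);

      for (int c = 0; c < n_cycles; ++c) {
        int p = c < n_phases ? c : n_phases - 1;
        const double *P = tr + arm_off + (std::size_t)20 * p;
        for (int to = 0; to < 5; ++to) {
          double acc = 0.0;
          for (int from = 0; from < 4; ++from)
            acc += pi[from] * P[from + 4 * to];
          nxt[to] = acc;
        }
        nxt[4] += pi[4]; // DEAD is absorbing

        if (half_cycle)
          for (int s = 0; s < 5; ++s) w[s] = 0.5 * (pi[s] + nxt[s]);
        else
          for (int s = 0; s < 5; ++s) w[s] = pi[s];

        double q = 0.0, sc_cycle = 0.0, alive = 0.0;
        for (int s = 0; s < 4; ++s) {
          q += w[s] * util(s, i);
          sc_cycle += w[s] * sc[s];
          alive += w[s];
        }
        qaly += q * cycle_years * disc_e[c];
        cost += sc_cycle * disc_c[c];
        if (a == 1) { // nurse telephone support
          cost += nts_cost * alive * disc_c[c];
        } else if (a == 2) { // home telemonitoring
          cost += service_fee[i] * alive * disc_c[c];
          if (replacement_cycles > 0 && c % replacement_cycles == 0)
            cost += install_fee[i] * alive * disc_c[c];
        }
        for (int s = 0; s < 5; ++s) pi[s] = nxt[s];
      }
      costs(i, a) = cost;
      effects(i, a) = qaly;
    }
  }
  return List::create(_["costs"] = costs, _["effects"] = effects);
}
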
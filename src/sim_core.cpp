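#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Compiled event loop for the prejudicial-groups model.
//
// State conventions (all 0-based internally):
//   trait      : immutable sub-population label, 0..n_traits-1
//   alpha_lvl  : prejudice level as an integer 0..4 (alpha = lvl / 4)
//   s, u, d    : binary action rules (donate on similarity / upward / downward)
//   S, P       : in-group interaction / in-group learning probabilities
//   rU, rG     : universal and in-group reputation, integers in [-5, 5]
//
// All reputation comparisons are done in quarter-units (scaled by 4) so that
// out-group discounting r_j^U * (1 - alpha_i) = r_j^U * (4 - lvl) / 4 is exact
// integer arithmetic: ties are never float-sensitive.
//
// RNG: uses R's own uniform stream (unif_rand). The order in which uniforms
// are consumed is part of the engine contract; the pure-R reference engine in
// R/engine.R consumes the identical sequence, so both produce bit-identical
// trajectories from the same seed.

static inline int unif_index(int m) {
  // uniform integer in 0..m-1, guarded against the (theoretical) u == 1 edge
  int k = (int)(unif_rand() * m);
  if (k >= m) k = m - 1;
  return k;
}

// [[Rcpp::export(name = ".sim_core_run")]]
List sim_core_run(IntegerVector trait0, IntegerVector s_in, IntegerVector u_in,
                  IntegerVector d_in, IntegerVector alpha_in, NumericVector S_in,
                  NumericVector P_in, int games, int generations, double b,
                  double cost, double mu, double repro_chance, double delta,
                  bool evolve_S, bool evolve_P, bool evolve_alpha,
                  int record_every, bool log_events) {
  const int n = trait0.size();
  int n_traits = 0;
  for (int i = 0; i < n; ++i) if (trait0[i] + 1 > n_traits) n_traits = trait0[i] + 1;
  const int n_groups = n_traits * 5;

  std::vector<int> trait(trait0.begin(), trait0.end());
  std::vector<int> s(s_in.begin(), s_in.end()), u(u_in.begin(), u_in.end()),
      d(d_in.begin(), d_in.end()), a(alpha_in.begin(), alpha_in.end());
  std::vector<double> S(S_in.begin(), S_in.end()), P(P_in.begin(), P_in.end());
  std::vector<int> rU(n, 0), rG(n, 0);
  std::vector<double> tp(n, 0.0);

  // group index (CSR): agents ordered by (group id, agent id)
  std::vector<int> gsize(n_groups), gstart(n_groups), order(n), pos(n);

  // snapshots for synchronous reproduction
  std::vector<int> s0(n), u0(n), d0(n), a0(n);
  std::vector<double> S0(n), P0(n), f(n), gf(n_groups);

  // recorded generations: every record_every-th plus the final one
  std::vector<int> rec_gens;
  for (int g = 1; g <= generations; ++g)
    if (g % record_every == 0 || g == generations) rec_gens.push_back(g);
  const int n_rec = (int)rec_gens.size();

  const int n_base = 25;
  const int ncol = n_base + 10 + 10 + n_traits + n_traits * 5;
  NumericMatrix metrics(n_rec, ncol);

  IntegerMatrix events;
  long ev_row = 0;
  if (log_events) events = IntegerMatrix((R_xlen_t)games * generations, 7);

  GetRNGstate();
  int rec_i = 0;
  for (int gen = 1; gen <= generations; ++gen) {
    // ---- rebuild group index (counting sort by group id) ----
    std::fill(gsize.begin(), gsize.end(), 0);
    for (int i = 0; i < n; ++i) gsize[trait[i] * 5 + a[i]]++;
    gstart[0] = 0;
    for (int g = 1; g < n_groups; ++g) gstart[g] = gstart[g - 1] + gsize[g - 1];
    {
      std::vector<int> cur(gstart);
      for (int i = 0; i < n; ++i) {
        int gid = trait[i] * 5 + a[i];
        order[cur[gid]] = i;
        pos[i] = cur[gid] - gstart[gid];
        cur[gid]++;
      }
    }

    // ---- play games ----
    long n_null = 0, n_don = 0, n_in = 0, n_out = 0, n_outdef = 0, n_pd = 0;
    for (int g = 0; g < games; ++g) {
      int donor = unif_index(n);
      int gid = trait[donor] * 5 + a[donor];
      int rec = -1;
      bool ing = false;
      if (unif_rand() < S[donor]) {  // in-group branch
        int m = gsize[gid] - 1;
        if (m >= 1) {
          int k = unif_index(m);
          if (k >= pos[donor]) k++;
          rec = order[gstart[gid] + k];
          ing = true;
        }
      } else {  // out-group branch
        int m = n - gsize[gid];
        if (m >= 1) {
          int k = unif_index(m);
          if (k >= gstart[gid]) k += gsize[gid];
          rec = order[k];
        }
      }
      int donated = 0, outcome = 3, cf = 0;
      if (rec < 0) {
        n_null++;
      } else {
        int L = 4 * rG[donor];
        int R = ing ? 4 * rG[rec] : rU[rec] * (4 - a[donor]);
        outcome = (R == L) ? 0 : (R > L ? 1 : 2);
        donated = (outcome == 0) ? s[donor] : (outcome == 1 ? u[donor] : d[donor]);
        cf = donated;
        if (ing) {
          n_in++;
        } else {
          int R0 = 4 * rU[rec];
          int oc0 = (R0 == L) ? 0 : (R0 > L ? 1 : 2);
          cf = (oc0 == 0) ? s[donor] : (oc0 == 1 ? u[donor] : d[donor]);
          n_out++;
          if (!donated) {
            n_outdef++;
            if (cf) n_pd++;
          }
        }
        if (donated) {
          tp[donor] -= cost;
          tp[rec] += b;
          n_don++;
        }
        // assessment: universal reputation (standing; raw reputations)
        if (donated) {
          if (rU[donor] < 5) rU[donor]++;
        } else if (!(rU[rec] < rU[donor])) {
          if (rU[donor] > -5) rU[donor]--;
        }
        // assessment: in-group reputation (prejudice-aware legitimacy)
        if (donated) {
          if (rG[donor] < 5) rG[donor]++;
        } else {
          bool legit = ing ? (rG[rec] < rG[donor])
                           : (rU[rec] * (4 - a[donor]) < 4 * rG[donor]);
          if (!legit && rG[donor] > -5) rG[donor]--;
        }
      }
      if (log_events) {
        events(ev_row, 0) = gen;
        events(ev_row, 1) = donor + 1;
        events(ev_row, 2) = rec < 0 ? NA_INTEGER : rec + 1;
        events(ev_row, 3) = rec < 0 ? 2 : (ing ? 0 : 1);
        events(ev_row, 4) = outcome;
        events(ev_row, 5) = donated;
        events(ev_row, 6) = cf;
        ev_row++;
      }
    }

    // ---- record metrics (population as it played this generation) ----
    bool record = (gen % record_every == 0) || (gen == generations);
    int row = -1;
    if (record) {
      row = rec_i++;
      long nn = games - n_null;
      double mean_a = 0, mean_S = 0, mean_P = 0, tot_tp = 0;
      int adist[5] = {0, 0, 0, 0, 0};
      int f110 = 0, f000 = 0, gap = 0;
      std::vector<int> Sdist(10, 0), Pdist(10, 0);
      std::vector<double> tr_a(n_traits, 0.0);
      std::vector<int> tr_n(n_traits, 0), tr_ad(n_traits * 5, 0);
      for (int i = 0; i < n; ++i) {
        mean_a += a[i] / 4.0;
        mean_S += S[i];
        mean_P += P[i];
        tot_tp += tp[i];
        adist[a[i]]++;
        if (s[i] == 1 && u[i] == 1 && d[i] == 0) f110++;
        if (s[i] == 0 && u[i] == 0 && d[i] == 0) f000++;
        int gp = rG[i] - rU[i];
        if (gp < 0) gp = -gp;
        if (gp > gap) gap = gp;
        int sb = (int)(S[i] * 10 + 0.5);
        if (sb > 9) sb = 9;
        int pb = (int)(P[i] * 10 + 0.5);
        if (pb > 9) pb = 9;
        Sdist[sb]++;
        Pdist[pb]++;
        tr_a[trait[i]] += a[i] / 4.0;
        tr_n[trait[i]]++;
        tr_ad[trait[i] * 5 + a[i]]++;
      }
      metrics(row, 0) = gen;
      metrics(row, 1) = games;
      metrics(row, 2) = n_null;
      metrics(row, 3) = n_don;
      metrics(row, 4) = nn > 0 ? (double)n_don / nn : NA_REAL;
      metrics(row, 5) = games > 0 ? (double)n_don / games : NA_REAL;
      metrics(row, 6) = n_in;
      metrics(row, 7) = n_out;
      metrics(row, 8) = n_outdef;
      metrics(row, 9) = n_pd;
      metrics(row, 10) = n_out > 0 ? (double)n_pd / n_out : 0.0;
      metrics(row, 11) = mean_a / n;
      for (int k = 0; k < 5; ++k) metrics(row, 12 + k) = (double)adist[k] / n;
      metrics(row, 17) = (double)(adist[3] + adist[4]) / n;
      metrics(row, 18) = (double)f110 / n;
      metrics(row, 19) = (double)f000 / n;
      metrics(row, 20) = mean_S / n;
      metrics(row, 21) = mean_P / n;
      metrics(row, 22) = tot_tp;
      metrics(row, 23) = gap;
      for (int k = 0; k < 10; ++k) metrics(row, n_base + k) = (double)Sdist[k] / n;
      for (int k = 0; k < 10; ++k) metrics(row, n_base + 10 + k) = (double)Pdist[k] / n;
      for (int t = 0; t < n_traits; ++t)
        metrics(row, n_base + 20 + t) = tr_n[t] > 0 ? tr_a[t] / tr_n[t] : NA_REAL;
      for (int t = 0; t < n_traits; ++t)
        for (int k = 0; k < 5; ++k)
          metrics(row, n_base + 20 + n_traits + t * 5 + k) =
              tr_n[t] > 0 ? (double)tr_ad[t * 5 + k] / tr_n[t] : NA_REAL;
    }

    // ---- selection & reproduction (synchronous, snapshot-based) ----
    int n_rep = 0;
    if (repro_chance > 0) {
      double mn = tp[0];
      for (int i = 1; i < n; ++i) if (tp[i] < mn) mn = tp[i];
      double tps = mn < 0 ? -mn : 0.0;
      for (int i = 0; i < n; ++i) f[i] = tps + tp[i] + delta;
      double ftot = 0;
      for (int i = 0; i < n; ++i) ftot += f[i];
      for (int g = 0; g < n_groups; ++g) {
        double acc = 0;
        for (int k = gstart[g]; k < gstart[g] + gsize[g]; ++k) acc += f[order[k]];
        gf[g] = acc;
      }
      for (int i = 0; i < n; ++i) {
        s0[i] = s[i]; u0[i] = u[i]; d0[i] = d[i]; a0[i] = a[i];
        S0[i] = S[i]; P0[i] = P[i];
      }
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < repro_chance) {
          n_rep++;
          int parent;
          if (unif_rand() < P0[i]) {  // in-group learning: copier's own group
            int gid = trait[i] * 5 + a0[i];
            double r = unif_rand() * gf[gid];
            double acc = 0;
            parent = order[gstart[gid] + gsize[gid] - 1];
            for (int k = gstart[gid]; k < gstart[gid] + gsize[gid]; ++k) {
              acc += f[order[k]];
              if (acc >= r) { parent = order[k]; break; }
            }
          } else {  // global learning: whole population
            double r = unif_rand() * ftot;
            double acc = 0;
            parent = n - 1;
            for (int j = 0; j < n; ++j) {
              acc += f[j];
              if (acc >= r) { parent = j; break; }
            }
          }
          s[i] = s0[parent]; u[i] = u0[parent]; d[i] = d0[parent];
          a[i] = a0[parent];
          if (evolve_S) S[i] = S0[parent];
          if (evolve_P) P[i] = P0[parent];
          // per-element mutation on the newly copied heuristic
          if (unif_rand() < mu) s[i] = 1 - s[i];
          if (unif_rand() < mu) u[i] = 1 - u[i];
          if (unif_rand() < mu) d[i] = 1 - d[i];
          if (evolve_alpha && unif_rand() < mu) a[i] = unif_index(5);
          if (evolve_S && unif_rand() < mu) S[i] = 0.1 * unif_index(10);
          if (evolve_P && unif_rand() < mu) P[i] = 0.1 * unif_index(10);
        }
      }
    }
    if (record) metrics(row, 24) = n_rep;

    // ---- generation boundary: reset payoffs and reputations ----
    std::fill(tp.begin(), tp.end(), 0.0);
    std::fill(rU.begin(), rU.end(), 0);
    std::fill(rG.begin(), rG.end(), 0);
  }
  PutRNGstate();

  CharacterVector cn(ncol);
  const char *base[] = {"gen", "n_games", "n_null", "n_donated", "coop_rate",
                        "coop_rate_raw", "n_ingroup", "n_outgroup",
                        "n_outgroup_def", "n_prej_def", "prej_def_share",
                        "mean_alpha", "alpha_0", "alpha_25", "alpha_50",
                        "alpha_75", "alpha_100", "share_high_alpha", "freq_110",
                        "freq_000", "mean_S", "mean_P", "total_payoff",
                        "max_rep_gap", "n_reproduced"};
  for (int k = 0; k < n_base; ++k) cn[k] = base[k];
  for (int k = 0; k < 10; ++k) cn[n_base + k] = "S_" + std::to_string(k);
  for (int k = 0; k < 10; ++k) cn[n_base + 10 + k] = "P_" + std::to_string(k);
  const char *lv[] = {"0", "25", "50", "75", "100"};
  for (int t = 0; t < n_traits; ++t) {
    cn[n_base + 20 + t] = "trait" + std::to_string(t + 1) + "_mean_alpha";
    for (int k = 0; k < 5; ++k)
      cn[n_base + 20 + n_traits + t * 5 + k] =
          "trait" + std::to_string(t + 1) + "_alpha_" + lv[k];
  }
  colnames(metrics) = cn;

  List fin = List::create(
      _["trait"] = IntegerVector(trait.begin(), trait.end()),
      _["s"] = IntegerVector(s.begin(), s.end()),
      _["u"] = IntegerVector(u.begin(), u.end()),
      _["d"] = IntegerVector(d.begin(), d.end()),
      _["alpha_lvl"] = IntegerVector(a.begin(), a.end()),
      _["S"] = NumericVector(S.begin(), S.end()),
      _["P"] = NumericVector(P.begin(), P.end()));

  List out = List::create(_["metrics"] = metrics, _["final"] = fin);
  if (log_events) {
    colnames(events) = CharacterVector::create("gen", "donor", "recipient",
                                               "scope", "outcome", "donated",
                                               "counterfactual");
    out["events"] = events;
  }
  return out;
}
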
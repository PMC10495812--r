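#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Event-driven structured Kingman coalescent, backwards in time.
//
// Demes hold diploid sizes, so a deme with k lineages and size N coalesces
// at rate k(k-1)/2 / (2N) per generation. Piecewise-constant demography is
// handled by jumping to phase boundaries; a single-deme exponential size
// trajectory N(s) = N0 * exp(G * s) (backward time s, literal growth-model
// reconstruction) is handled by closed-form inversion of the hazard.
// Lineage migration: a lineage in deme i moves to deme j at backward rate
// mig(i, j), active only before merge_time. At merge_time all lineages drop
// into deme 0 with size merge_size (migration off). change_time applies an
// instantaneous size change of deme 0 to change_size.
//
// Node numbering: tips 1..n (time 0, in deme block order), internal nodes
// n+1..2n-1 in coalescence order; parent[root] = 0.

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector n_per_deme,
                       NumericVector deme_sizes,
                       NumericMatrix mig,
                       double merge_time,
                       double merge_size,
                       double change_time,
                       double change_size,
                       double growth_rate,
                       double growth_end) {
  const int D = n_per_deme.size();
  int n = 0;
  for (int d = 0; d < D; ++d) n += n_per_deme[d];
  if (n < 1) stop("zero sampled lineages");
  if (D != deme_sizes.size()) stop("deme size/count mismatch");
  const int n_nodes = 2 * n - 1;

  IntegerVector parent(n_nodes, 0);
  NumericVector node_time(n_nodes, 0.0);
  IntegerVector tip_deme(n);

  std::vector<int> lin_node;  // active lineage -> node id (1-based)
  std::vector<int> lin_deme;  // active lineage -> deme
  lin_node.reserve(n); lin_deme.reserve(n);
  {
    int id = 1;
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < n_per_deme[d]; ++k) {
        lin_node.push_back(id);
        lin_deme.push_back(d);
        tip_deme[id - 1] = d + 1;
        ++id;
      }
  }

  std::vector<double> N(deme_sizes.begin(), deme_sizes.end());
  double t = 0.0;
  int next_internal = n + 1;
  bool merged = (merge_time == R_PosInf) || (D == 1);
  bool changed = (change_time == R_PosInf);
  bool growing = (growth_rate != 0.0) && (growth_end > 0.0);
  if (growing && D > 1) stop("exponential growth supported for one deme only");
  const double G = growth_rate;
  const double N0 = N.empty() ? 1.0 : N[0];

  std::vector<int> kd(D, 0);
  for (size_t i = 0; i < lin_deme.size(); ++i) kd[lin_deme[i]]++;

  int guard = 0;
  const int guard_max = 200000000;
  while ((int)lin_node.size() > 1) {
    if (++guard > guard_max) stop("coalescent event budget exceeded");

    // next demographic boundary
    double tb = R_PosInf;
    if (!changed && change_time > t && change_time < tb) tb = change_time;
    if (!merged && merge_time > t && merge_time < tb) tb = merge_time;
    if (growing && growth_end > t && growth_end < tb) tb = growth_end;

    double t_next; int ev_type = -1; int ev_deme = -1;
    if (growing && t < growth_end) {
      // single deme, time-varying hazard c * exp(-G s)
      int k = (int)lin_node.size();
      double c = (double)k * (k - 1) / (4.0 * N0);
      double E = exp_rand();
      double s;
      if (G == 0.0) s = t + E / c;
      else {
        double arg = std::exp(-G * t) - G * E / c;
        s = (arg <= 0.0) ? R_PosInf : -std::log(arg) / G;
      }
      t_next = s; ev_type = 0; ev_deme = 0;
    } else {
      double total = 0.0;
      std::vector<double> coal_rate(D, 0.0);
      for (int d = 0; d < D; ++d) {
        coal_rate[d] = (double)kd[d] * (kd[d] - 1) / (4.0 * N[d]);
        total += coal_rate[d];
      }
      double mig_total = 0.0;
      std::vector<double> out_rate(D, 0.0);
      if (!merged && t < merge_time) {
        for (int d = 0; d < D; ++d) {
          double r = 0.0;
          for (int j = 0; j < D; ++j) if (j != d) r += mig(d, j);
          out_rate[d] = r;
          mig_total += kd[d] * r;
        }
      }
      total += mig_total;
      if (total <= 0.0) {
        if (tb == R_PosInf) stop("stalled coalescent: zero total rate");
        t_next = R_PosInf;
      } else {
        t_next = t + exp_rand() / total;
      }
      if (t_next <= tb) {
        // choose event
        double u = unif_rand() * total;
        ev_type = 1;  // migration unless a coal interval is hit
        for (int d = 0; d < D; ++d) {
          if (u < coal_rate[d]) { ev_type = 0; ev_deme = d; break; }
          u -= coal_rate[d];
        }
        if (ev_type == 1) {
          // migration: pick lineage weighted by deme out-rate
          double v = u;  // remaining mass within mig_total
          int chosen = -1;
          for (size_t i = 0; i < lin_deme.size(); ++i) {
            double w = out_rate[lin_deme[i]];
            if (v < w) { chosen = (int)i; break; }
            v -= w;
          }
          if (chosen < 0) chosen = (int)lin_deme.size() - 1;
          int d = lin_deme[chosen];
          double w = unif_rand() * out_rate[d];
          int target = d;
          for (int j = 0; j < D; ++j) {
            if (j == d) continue;
            if (w < mig(d, j)) { target = j; break; }
            w -= mig(d, j);
          }
          kd[d]--; kd[target]++;
          lin_deme[chosen] = target;
          t = t_next;
          continue;
        }
      }
    }

    if (t_next > tb) {
      // apply demographic boundary event
      t = tb;
      if (!changed && tb == change_time) { N[0] = change_size; changed = true; }
      else if (!merged && tb == merge_time) {
        for (size_t i = 0; i < lin_deme.size(); ++i) lin_deme[i] = 0;
        std::fill(kd.begin(), kd.end(), 0);
        kd[0] = (int)lin_node.size();
        N[0] = merge_size;
        merged = true;
      } else if (growing && tb == growth_end) {
        N[0] = N0 * std::exp(G * growth_end);
        growing = false;
      }
      continue;
    }

    // coalescence in deme ev_deme: pick random pair
    t = t_next;
    int k = kd[ev_deme];
    int pick1 = (int)std::floor(unif_rand() * k);
    int pick2 = (int)std::floor(unif_rand() * (k - 1));
    if (pick2 >= pick1) pick2++;
    int i1 = -1, i2 = -1, seen = 0;
    for (size_t i = 0; i < lin_deme.size(); ++i) {
      if (lin_deme[i] == ev_deme) {
        if (seen == pick1) i1 = (int)i;
        if (seen == pick2) i2 = (int)i;
        ++seen;
      }
    }
    int anc = next_internal++;
    parent[lin_node[i1] - 1] = anc;
    parent[lin_node[i2] - 1] = anc;
    node_time[anc - 1] = t;
    // replace i1 by ancestor, drop i2
    lin_node[i1] = anc;
    lin_node.erase(lin_node.begin() + i2);
    lin_deme.erase(lin_deme.begin() + i2);
    kd[ev_deme]--;
  }

  return List::create(_["parent"] = parent,
                      _["time"] = node_time,
                      _["n_tips"] = n,
                      _["tip_deme"] = tip_deme);
}
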
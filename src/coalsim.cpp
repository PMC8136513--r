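#include <Rcpp.h>
#include <set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Structured-coalescent genealogy + infinite-sites mutation for one window.
//
// Demes are indexed 0..(D-1).  Each non-root deme has a parent deme into
// which its lineages (a) migrate backward in time at rate `deme_mig` per
// lineage per generation while the deme exists, and (b) are moved wholesale
// at `deme_tdiv` generations before present, after which the deme no longer
// exists.  Deme sizes are piecewise constant: `deme_size` at present,
// overridden by bottleneck epochs [epoch_start, epoch_end) of size
// `epoch_size`.  Coalescence within a deme of diploid size N occurs at rate
// k(k-1)/2 * 1/(2N) per generation.  Time is continuous, in generations.
//
// Mutations: infinite sites on the integer grid 0..L-1; the number of
// mutations is Poisson(mu * L * total branch length) and each mutation is
// placed on a branch with probability proportional to branch length;
// position collisions are redrawn.
//
// Uses R's RNG throughout so results are reproducible under set.seed().

static double deme_size_at(int d, double t,
                           const std::vector<double>& base,
                           const std::vector<int>& ep_deme,
                           const std::vector<double>& ep_start,
                           const std::vector<double>& ep_end,
                           const std::vector<double>& ep_size) {
  for (size_t e = 0; e < ep_deme.size(); ++e) {
    if (ep_deme[e] == d && t >= ep_start[e] && t < ep_end[e]) return ep_size[e];
  }
  return base[d];
}

// [[Rcpp::export]]
List sim_window_cpp(IntegerVector lineage_deme,
                    NumericVector deme_size,
                    NumericVector deme_mig,
                    IntegerVector deme_parent,
                    NumericVector deme_tdiv,
                    IntegerVector epoch_deme,
                    NumericVector epoch_start,
                    NumericVector epoch_end,
                    NumericVector epoch_size,
                    double mu,
                    double window_length,
                    double max_time) {
  const int n_tips = lineage_deme.size();
  const int D = deme_size.size();
  if (n_tips < 2) stop("need at least two sampled lineages");

  std::vector<double> base(deme_size.begin(), deme_size.end());
  std::vector<int> ep_d(epoch_deme.begin(), epoch_deme.end());
  std::vector<double> ep_s(epoch_start.begin(), epoch_start.end());
  std::vector<double> ep_e(epoch_end.begin(), epoch_end.end());
  std::vector<double> ep_n(epoch_size.begin(), epoch_size.end());

  // node bookkeeping: tips 0..n_tips-1 at time 0
  int n_nodes = 2 * n_tips - 1;
  std::vector<double> node_time(n_nodes, 0.0);
  std::vector<int> parent(n_nodes, -1);
  int next_node = n_tips;

  // active lineages
  std::vector<int> act_node(n_tips), act_deme(n_tips);
  for (int i = 0; i < n_tips; ++i) { act_node[i] = i; act_deme[i] = lineage_deme[i]; }
  std::vector<bool> deme_alive(D, true);

  // fixed event time grid: divergences + epoch boundaries
  std::vector<double> grid;
  for (int d = 0; d < D; ++d)
    if (R_finite(deme_tdiv[d])) grid.push_back(deme_tdiv[d]);
  for (size_t e = 0; e < ep_s.size(); ++e) { grid.push_back(ep_s[e]); grid.push_back(ep_e[e]); }
  std::sort(grid.begin(), grid.end());
  grid.erase(std::unique(grid.begin(), grid.end()), grid.end());
  size_t gi = 0;

  double t = 0.0;
  std::vector<double> coal_rate(D), mig_rate(D);
  std::vector<int> kcount(D);

  while ((int)act_node.size() > 1) {
    if (t > max_time) stop("simulation exceeded max_time without coalescing; model likely non-coalescing");
    // deme divergences due at or before t
    bool moved = true;
    while (moved) {
      moved = false;
      for (int d = 0; d < D; ++d) {
        if (deme_alive[d] && R_finite(deme_tdiv[d]) && deme_tdiv[d] <= t + 1e-9) {
          int p = deme_parent[d];
          if (p < 0) stop("deme with finite divergence time has no parent");
          for (size_t i = 0; i < act_deme.size(); ++i)
            if (act_deme[i] == d) act_deme[i] = p;
          deme_alive[d] = false;
          moved = true;
        }
      }
    }
    while (gi < grid.size() && grid[gi] <= t + 1e-9) ++gi;

    // current rates
    std::fill(kcount.begin(), kcount.end(), 0);
    for (size_t i = 0; i < act_deme.size(); ++i) kcount[act_deme[i]]++;
    double total = 0.0;
    for (int d = 0; d < D; ++d) {
      double N = deme_size_at(d, t, base, ep_d, ep_s, ep_e, ep_n);
      coal_rate[d] = (kcount[d] >= 2) ? kcount[d] * (kcount[d] - 1) / 2.0 / (2.0 * N) : 0.0;
      mig_rate[d] = (deme_alive[d] && deme_parent[d] >= 0) ? kcount[d] * deme_mig[d] : 0.0;
      total += coal_rate[d] + mig_rate[d];
    }

    double t_next = (gi < grid.size()) ? grid[gi] : R_PosInf;
    if (total <= 0.0) {
      if (!R_finite(t_next))
        stop("no coalescence possible and no pending demographic events; model non-coalescing");
      t = t_next;
      continue;
    }
    double dt = R::rexp(1.0 / total);
    if (t + dt >= t_next) { t = t_next; continue; }
    t += dt;

    // choose event
    double u = unif_rand() * total;
    int ev_deme = -1; bool is_coal = false;
    for (int d = 0; d < D; ++d) {
      if (u < coal_rate[d]) { ev_deme = d; is_coal = true; break; }
      u -= coal_rate[d];
      if (u < mig_rate[d]) { ev_deme = d; is_coal = false; break; }
      u -= mig_rate[d];
    }
    if (ev_deme < 0) ev_deme = D - 1, is_coal = (coal_rate[D-1] > 0); // fp guard

    // indices of active lineages in ev_deme
    std::vector<int> idx;
    for (size_t i = 0; i < act_deme.size(); ++i)
      if (act_deme[i] == ev_deme) idx.push_back((int)i);
    if (idx.empty()) continue;

    if (is_coal) {
      int a = idx[(int)(unif_rand() * idx.size())];
      int b;
      do { b = idx[(int)(unif_rand() * idx.size())]; } while (b == a);
      int anc = next_node++;
      node_time[anc] = t;
      parent[act_node[a]] = anc;
      parent[act_node[b]] = anc;
      // replace a with ancestor, drop b
      act_node[a] = anc;
      act_node.erase(act_node.begin() + b);
      act_deme.erase(act_deme.begin() + b);
    } else {
      int a = idx[(int)(unif_rand() * idx.size())];
      act_deme[a] = deme_parent[ev_deme];
    }
  }

  // mutations
  double total_len = 0.0;
  for (int v = 0; v < n_nodes - 1; ++v) total_len += node_time[parent[v]] - node_time[v];
  int S = (int)R::rpois(mu * window_length * total_len);
  int Lint = (int)window_length;
  if (S > Lint) stop("more mutations than sites in window; infinite-sites model violated");

  // branch choice cumulative
  std::vector<double> cum(n_nodes - 1);
  double acc = 0.0;
  for (int v = 0; v < n_nodes - 1; ++v) {
    acc += node_time[parent[v]] - node_time[v];
    cum[v] = acc;
  }

  // children lists for descendant marking
  std::vector<std::vector<int> > children(n_nodes);
  for (int v = 0; v < n_nodes - 1; ++v) children[parent[v]].push_back(v);

  std::set<int> used;
  std::vector<int> positions(S);
  IntegerMatrix alleles(S, n_tips);
  for (int s = 0; s < S; ++s) {
    double u = unif_rand() * total_len;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= n_nodes - 1) v = n_nodes - 2;
    int pos;
    do { pos = (int)(unif_rand() * window_length); } while (used.count(pos));
    used.insert(pos);
    positions[s] = pos;
    // mark tips below v
    std::vector<int> stack(1, v);
    while (!stack.empty()) {
      int w = stack.back(); stack.pop_back();
      if (w < n_tips) alleles(s, w) = 1;
      else for (size_t c = 0; c < children[w].size(); ++c) stack.push_back(children[w][c]);
    }
  }

  // order sites by position
  std::vector<int> ord(S);
  for (int s = 0; s < S; ++s) ord[s] = s;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return positions[a] < positions[b]; });
  IntegerVector pos_out(S);
  IntegerMatrix all_out(S, n_tips);
  for (int s = 0; s < S; ++s) {
    pos_out[s] = positions[ord[s]];
    for (int i = 0; i < n_tips; ++i) all_out(s, i) = alleles(ord[s], i);
  }

  return List::create(_["positions"] = pos_out,
                      _["alleles"] = all_out,
                      _["node_time"] = NumericVector(node_time.begin(), node_time.end()),
                      _["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["tmrca"] = node_time[n_nodes - 1],
                      _["total_branch_length"] = total_len);
}
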
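#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
using namespace Rcpp;

// Sum of the top_k largest values in a multiset of positive component
// scores; when the multiset has <= top_k elements this is just their sum.
static inline double topk_sum(const std::multiset<double>& pos, int top_k) {
  double s = 0.0;
  int k = 0;
  for (std::multiset<double>::const_reverse_iterator it = pos.rbegin();
       it != pos.rend() && k < top_k; ++it, ++k)
    s += *it;
  return s;
}

static inline void pos_erase(std::multiset<double>& pos, double v) {
  std::multiset<double>::iterator it = pos.find(v);
  if (it != pos.end()) pos.erase(it);
}

// Union-find over component records. comp[node] holds a record id; the live
// root of a record is reached by find(). Records are append-only: turning a
// node on creates a fresh record that absorbs the neighbouring roots in O(1)
// each, with no relabelling of member nodes.
static inline int uf_find(std::vector<int>& parent, int r) {
  while (parent[r] != r) {
    parent[r] = parent[parent[r]];
    r = parent[r];
  }
  return r;
}

// Simulated annealing over binary on/off node states of an undirected graph
// given in CSR form (adj, ptr; 0-based). Objective: sum over the top_k
// highest-scoring connected components of the on-subgraph of
// max(component score, 0) — the total score of the modules the analysis
// reports. Moves are single-node toggles with uniform proposal; worsening
// moves are accepted with probability exp(delta/T), T_k = t0 * alpha^k.
// Uses R's RNG so results are reproducible under set.seed().
//
// Component bookkeeping: union-find records give O(alpha) merges when a node
// turns on. Turning a node off may split its component; the split pieces are
// discovered by a round-robin multi-source search from the on-neighbours of
// the removed node that stops as soon as at most one search is still open,
// so only the smaller pieces are ever traversed and the largest piece keeps
// the old record untouched.
// [[Rcpp::export]]
List anneal_run(IntegerVector adj, IntegerVector ptr, NumericVector score,
                double t0, double alpha, int n_temps, int steps_per_temp,
                int top_k) {
  const int n = score.size();
  std::vector<char> on(n, 0), best_state(n, 0);
  std::vector<int> comp(n, -1);

  // component records
  std::vector<int> rparent;
  std::vector<double> rscore;
  rparent.reserve(4 * n + 16);
  rscore.reserve(4 * n + 16);

  // scratch for ON moves
  std::vector<int> root_stamp;           // per record, grown lazily
  std::vector<int> merge_roots;
  merge_roots.reserve(64);

  // scratch for OFF moves: round-robin multi-source search
  std::vector<int> owner(n, -1);         // search id owning a node
  std::vector<int> owner_stamp(n, 0);    // proposal stamp for `owner`
  int cur_stamp = 0;
  int max_src = 1;
  for (int i = 0; i < n; ++i) {
    int d = ptr[i + 1] - ptr[i];
    if (d > max_src) max_src = d;
  }
  std::vector<std::vector<int> > squeue(max_src), smember(max_src);
  std::vector<double> sscore(max_src);
  std::vector<int> sparent(max_src);     // tiny union-find over searches
  std::vector<int> shead(max_src);       // queue read position
  std::vector<char> sopen(max_src);

  std::multiset<double> pos;

  double obj = 0.0, best = 0.0;
  double T = t0;
  RNGScope rng;

  for (int t = 0; t < n_temps; ++t, T *= alpha) {
    for (int s = 0; s < steps_per_temp; ++s) {
      int v = (int)(unif_rand() * n);
      if (v >= n) v = n - 1;

      if (!on[v]) {
        // hypothetically merge v with the distinct components among its
        // on-neighbours
        double merged = score[v];
        merge_roots.clear();
        for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
          int u = adj[e];
          if (!on[u]) continue;
          int r = uf_find(rparent, comp[u]);
          bool seen = false;
          for (size_t k = 0; k < merge_roots.size(); ++k)
            if (merge_roots[k] == r) { seen = true; break; }
          if (!seen) {
            merged += rscore[r];
            merge_roots.push_back(r);
          }
        }
        for (size_t k = 0; k < merge_roots.size(); ++k)
          if (rscore[merge_roots[k]] > 0.0) pos_erase(pos, rscore[merge_roots[k]]);
        if (merged > 0.0) pos.insert(merged);
        double new_obj = topk_sum(pos, top_k);
        double dobj = new_obj - obj;
        if (dobj >= 0.0 || unif_rand() < std::exp(dobj / T)) {
          on[v] = 1;
          int nr = (int)rparent.size();
          rparent.push_back(nr);
          rscore.push_back(merged);
          comp[v] = nr;
          for (size_t k = 0; k < merge_roots.size(); ++k)
            rparent[merge_roots[k]] = nr;
          obj = new_obj;
          if (obj > best + 1e-12) {
            best = obj;
            best_state = on;
          }
        } else {
          if (merged > 0.0) pos_erase(pos, merged);
          for (size_t k = 0; k < merge_roots.size(); ++k)
            if (rscore[merge_roots[k]] > 0.0) pos.insert(rscore[merge_roots[k]]);
        }
        continue;
      }

      // OFF move: removing v may split its component.
      int r = uf_find(rparent, comp[v]);
      double old_score = rscore[r];

      // collect on-neighbours as search sources
      ++cur_stamp;
      owner[v] = -2;                 // block v
      owner_stamp[v] = cur_stamp;
      int nsrc = 0;
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        int u = adj[e];
        if (!on[u] || owner_stamp[u] == cur_stamp) continue;
        owner[u] = nsrc;
        owner_stamp[u] = cur_stamp;
        squeue[nsrc].clear();
        smember[nsrc].clear();
        squeue[nsrc].push_back(u);
        smember[nsrc].push_back(u);
        sscore[nsrc] = score[u];
        sparent[nsrc] = nsrc;
        shead[nsrc] = 0;
        sopen[nsrc] = 1;
        ++nsrc;
      }

      // round-robin expansion, one node per open search per sweep; stop when
      // at most one search remains open — that one keeps the old record.
      int n_open = nsrc;
      while (n_open > 1) {
        for (int i = 0; i < nsrc && n_open > 1; ++i) {
          if (!sopen[i] || sparent[i] != i) continue;
          if (shead[i] >= (int)squeue[i].size()) {
            sopen[i] = 0;            // piece fully explored
            --n_open;
            continue;
          }
          int x = squeue[i][shead[i]++];
          for (int e = ptr[x]; e < ptr[x + 1]; ++e) {
            int u = adj[e];
            if (!on[u]) continue;
            if (owner_stamp[u] != cur_stamp) {
              owner[u] = i;
              owner_stamp[u] = cur_stamp;
              squeue[i].push_back(u);
              smember[i].push_back(u);
              sscore[i] += score[u];
            } else if (owner[u] >= 0) {
              // collision with another search: merge it into this one
              int j = owner[u];
              while (sparent[j] != j) j = sparent[j] = sparent[sparent[j]];
              if (j != i) {
                sparent[j] = i;
                sscore[i] += sscore[j];
                for (size_t q = (size_t)shead[j]; q < squeue[j].size(); ++q)
                  squeue[i].push_back(squeue[j][q]);
                smember[i].insert(smember[i].end(), smember[j].begin(),
                                  smember[j].end());
                if (sopen[j]) { sopen[j] = 0; --n_open; }
              }
            }
          }
        }
        // a lone open search may also run out of frontier
        if (n_open == 1) break;
        bool any_frontier = false;
        for (int i = 0; i < nsrc; ++i)
          if (sopen[i] && sparent[i] == i && shead[i] < (int)squeue[i].size())
            { any_frontier = true; break; }
        if (!any_frontier) {
          for (int i = 0; i < nsrc; ++i)
            if (sopen[i] && sparent[i] == i) { sopen[i] = 0; --n_open; }
        }
      }

      // completed searches become new components; an open survivor (if any)
      // keeps the old record with the leftover score.
      double completed_sum = 0.0;
      int survivor = -1;
      for (int i = 0; i < nsrc; ++i) {
        if (sparent[i] != i) continue;
        if (sopen[i]) survivor = i;
        else completed_sum += sscore[i];
      }
      double remainder = old_score - score[v] - completed_sum;

      if (old_score > 0.0) pos_erase(pos, old_score);
      for (int i = 0; i < nsrc; ++i)
        if (sparent[i] == i && !sopen[i] && sscore[i] > 0.0)
          pos.insert(sscore[i]);
      if (survivor >= 0 && remainder > 0.0) pos.insert(remainder);
      double new_obj = topk_sum(pos, top_k);
      double dobj = new_obj - obj;

      if (dobj >= 0.0 || unif_rand() < std::exp(dobj / T)) {
        on[v] = 0;
        comp[v] = -1;
        for (int i = 0; i < nsrc; ++i) {
          if (sparent[i] != i || sopen[i]) continue;
          int nr = (int)rparent.size();
          rparent.push_back(nr);
          rscore.push_back(sscore[i]);
          for (size_t q = 0; q < smember[i].size(); ++q)
            comp[smember[i][q]] = nr;
        }
        if (survivor >= 0) rscore[r] = remainder;
        obj = new_obj;
        if (obj > best + 1e-12) {
          best = obj;
          best_state = on;
        }
      } else {
        for (int i = 0; i < nsrc; ++i)
          if (sparent[i] == i && !sopen[i] && sscore[i] > 0.0)
            pos_erase(pos, sscore[i]);
        if (survivor >= 0 && remainder > 0.0) pos_erase(pos, remainder);
        if (old_score > 0.0) pos.insert(old_score);
      }
    }
  }

  LogicalVector state(n);
  for (int i = 0; i < n; ++i) state[i] = best_state[i] != 0;
  return List::create(_["state"] = state,
                      _["objective"] = best,
                      _["final_objective"] = obj);
}

// Exact optimum of the same objective by exhaustive enumeration over all
// 2^n node subsets (n <= 20). Independent of the annealer: plain subset
// sweep with union-find per subset, component scores sorted per subset.
// [[Rcpp::export]]
List exhaustive_best(IntegerVector edge_from, IntegerVector edge_to,
                     NumericVector score, int top_k) {
  const int n = score.size();
  if (n > 20) stop("exhaustive enumeration limited to 20 nodes");
  const int m = edge_from.size();
  std::vector<int> parent(n);
  std::vector<double> acc(n), comps(n);
  double best = 0.0;
  unsigned long best_mask = 0UL;

  const unsigned long lim = 1UL << n;
  for (unsigned long mask = 0; mask < lim; ++mask) {
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int e = 0; e < m; ++e) {
      int a = edge_from[e], b = edge_to[e];
      if (((mask >> a) & 1UL) && ((mask >> b) & 1UL)) {
        int ra = a, rb = b;
        while (parent[ra] != ra) ra = parent[ra] = parent[parent[ra]];
        while (parent[rb] != rb) rb = parent[rb] = parent[parent[rb]];
        if (ra != rb) parent[rb] = ra;
      }
    }
    for (int i = 0; i < n; ++i) acc[i] = 0.0;
    for (int i = 0; i < n; ++i) {
      if ((mask >> i) & 1UL) {
        int r = i;
        while (parent[r] != r) r = parent[r];
        acc[r] += score[i];
      }
    }
    int nc = 0;
    for (int i = 0; i < n; ++i)
      if (((mask >> i) & 1UL) && parent[i] == i && acc[i] > 0.0)
        comps[nc++] = acc[i];
    double objv = 0.0;
    if (nc <= top_k) {
      for (int i = 0; i < nc; ++i) objv += comps[i];
    } else {
      std::sort(comps.begin(), comps.begin() + nc);
      for (int i = nc - top_k; i < nc; ++i) objv += comps[i];
    }
    if (objv > best + 1e-12) {
      best = objv;
      best_mask = mask;
    }
  }

  LogicalVector state(n);
  for (int i = 0; i < n; ++i) state[i] = ((best_mask >> i) & 1UL) != 0;
  return List::create(_["state"] = state, _["objective"] = best);
}
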
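#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Analytic contact-probability surrogate from 1-D loop configurations.
//
// A loop-extruded phantom (Gaussian) chain is a network of harmonic springs:
// the backbone plus one short bond across each extruded loop. For a Gaussian
// spring network the variance of the vector between two monomers is the
// effective resistance between them (backbone segment of length n = n units,
// loop bond = 1 unit), and the contact probability scales as
// R_eff^(3/2 * exponent/1.5) = R_eff^-1.5 for the default exponent.
//
// Loops produced by mutually blocking LEFs are laminar (nested or disjoint),
// so the spring network seen from any two terminals is series-parallel and
// the resistance is computed exactly by reduction, in ~O(depth) per query:
//   - every loop reduces to parallel(bond = 1, interior),
//   - a terminal inside a loop chain reduces via triangle-to-star steps,
//   - the innermost loop containing both terminals contributes the final
//     two-arc cycle.

struct LoopNode {
  int l, r, parent;
  std::vector<int> kids;       // sorted by l
  std::vector<double> kidpre;  // prefix sums of kid (span - red)
  double red;                  // reduced two-terminal resistance
};

struct Snapshot {
  std::vector<LoopNode> loops;     // sorted by l
  std::vector<int> top;            // top-level loop ids, sorted by l
  std::vector<double> toppre;      // prefix sums of (span - red) for top
  double bond_res = 1.0;           // resistance of the loop-closing bond

  void build(const IntegerMatrix& legs) {
    int nl = legs.nrow();
    std::vector<std::pair<int, int>> iv(nl);
    for (int k = 0; k < nl; ++k) iv[k] = {legs(k, 0), legs(k, 1)};
    std::sort(iv.begin(), iv.end());
    loops.assign(nl, LoopNode());
    std::vector<int> stack;
    for (int k = 0; k < nl; ++k) {
      loops[k].l = iv[k].first;
      loops[k].r = iv[k].second;
      while (!stack.empty() && loops[stack.back()].r < loops[k].l)
        stack.pop_back();
      loops[k].parent = stack.empty() ? -1 : stack.back();
      if (loops[k].parent >= 0)
        loops[loops[k].parent].kids.push_back(k);
      else
        top.push_back(k);
      stack.push_back(k);
    }
    // children appear after parents in l-order: reverse pass is bottom-up
    for (int k = nl - 1; k >= 0; --k) {
      double internal = loops[k].r - loops[k].l;
      for (int c : loops[k].kids)
        internal -= (loops[c].r - loops[c].l) - loops[c].red;
      loops[k].red = internal * bond_res / (internal + bond_res);
      loops[k].kidpre.resize(loops[k].kids.size() + 1, 0.0);
      for (size_t t = 0; t < loops[k].kids.size(); ++t) {
        int c = loops[k].kids[t];
        loops[k].kidpre[t + 1] = loops[k].kidpre[t] +
          (loops[c].r - loops[c].l) - loops[c].red;
      }
    }
    toppre.resize(top.size() + 1, 0.0);
    for (size_t t = 0; t < top.size(); ++t) {
      int c = top[t];
      toppre[t + 1] = toppre[t] + (loops[c].r - loops[c].l) - loops[c].red;
    }
  }

  // reduced backbone distance from a to b (a <= b) using a sorted id list
  // with prefix sums; only loops fully inside [a, b] shorten the path
  double reduced_dist(const std::vector<int>& ids,
                      const std::vector<double>& pre, int a, int b) const {
    double d = b - a;
    // ids with l >= a
    int lo = std::lower_bound(ids.begin(), ids.end(), a,
               [&](int id, int v) { return loops[id].l < v; }) - ids.begin();
    // ids with r <= b: since intervals in the same context are disjoint and
    // sorted, find the last id with l < b and check r
    int hi = std::lower_bound(ids.begin(), ids.end(), b,
               [&](int id, int v) { return loops[id].l < v; }) - ids.begin();
    while (hi > lo && loops[ids[hi - 1]].r > b) --hi;
    if (hi > lo) d -= pre[hi] - pre[lo];
    return d;
  }

  double dist_in(int ctx, int a, int b) const {
    if (ctx < 0) return reduced_dist(top, toppre, a, b);
    return reduced_dist(loops[ctx].kids, loops[ctx].kidpre, a, b);
  }

  // chain of loops strictly containing pos, outermost first
  void chain_of(int pos, std::vector<int>& out) const {
    out.clear();
    const std::vector<int>* ids = &top;
    while (true) {
      int k = -1;
      // find interval with l < pos < r in the sorted disjoint list
      int t = std::upper_bound(ids->begin(), ids->end(), pos,
                [&](int v, int id) { return v < loops[id].l; }) - ids->begin();
      if (t > 0) {
        int cand = (*ids)[t - 1];
        if (loops[cand].l < pos && pos < loops[cand].r) k = cand;
      }
      if (k < 0) return;
      out.push_back(k);
      ids = &loops[k].kids;
      if (ids->empty()) return;
    }
  }

  // collapse pos through its chain below `stop_at` (exclusive); returns the
  // attachment anchors (La, Ra), arm resistances (al, ar) and the series
  // resistance rho from pos to the star centre
  void star_of(int pos, const std::vector<int>& chain, int stop_depth,
               int& La, int& Ra, double& al, double& ar, double& rho) const {
    La = Ra = pos;
    al = ar = 0.0;
    rho = 0.0;
    for (int d = (int)chain.size() - 1; d >= stop_depth; --d) {
      int A = chain[d];
      double x = dist_in(A, loops[A].l, La) + al;
      double y = ar + dist_in(A, Ra, loops[A].r);
      double S = x + y + bond_res;
      rho += x * y / S;
      al = x * bond_res / S;
      ar = y * bond_res / S;
      La = loops[A].l;
      Ra = loops[A].r;
    }
  }

  double resistance(int i, int j) const {
    if (i == j) return 0.0;
    if (i > j) std::swap(i, j);
    std::vector<int> ci, cj;
    chain_of(i, ci);
    chain_of(j, cj);
    // innermost loop containing both = longest common prefix
    int common = 0;
    while (common < (int)ci.size() && common < (int)cj.size() &&
           ci[common] == cj[common])
      ++common;
    int C = common > 0 ? ci[common - 1] : -1;
    int La, Ra, Lb, Rb;
    double al, ar, bl, br, rho_i, rho_j;
    star_of(i, ci, common, La, Ra, al, ar, rho_i);
    star_of(j, cj, common, Lb, Rb, bl, br, rho_j);
    double arc1 = ar + dist_in(C, Ra, Lb) + bl;
    if (C < 0) return rho_i + arc1 + rho_j;
    double arc2 = al + dist_in(C, loops[C].l, La) + bond_res +
                  dist_in(C, Rb, loops[C].r) + br;
    return rho_i + (arc1 * arc2) / (arc1 + arc2) + rho_j;
  }
};

// [[Rcpp::export]]
List cpp_loop_pcs(List snapshots,        // each: IntegerMatrix n_lef x 2 (0-based)
                  int n_monomers,
                  IntegerVector s_values, // separations in monomers
                  int pairs_per_s,
                  double exponent,
                  double bond_res,
                  double capture_radius) {
  const int ns = s_values.size();
  NumericVector p_sum(ns), deff_sum(ns);
  IntegerVector n_obs(ns);

  for (int snap = 0; snap < snapshots.size(); ++snap) {
    IntegerMatrix legs = snapshots[snap];
    Snapshot S;
    S.bond_res = bond_res;
    S.build(legs);
    for (int si = 0; si < ns; ++si) {
      int s = s_values[si];
      if (s < 1 || s >= n_monomers) continue;
      for (int rep = 0; rep < pairs_per_s; ++rep) {
        int i = (int)(unif_rand() * (n_monomers - s));
        if (i >= n_monomers - s) i = n_monomers - s - 1;
        int j = i + s;
        double reff = S.resistance(i, j);
        if (reff < 1e-9) reff = 1e-9;
        double p;
        if (capture_radius > 0) {
          // exact capture probability of a Gaussian chain: |x|^2 ~ (R/3) chi2_3,
          // generalized to exponents other than -1.5 via the tail power
          double q = R::pchisq(3.0 * capture_radius * capture_radius / reff,
                               3.0, 1, 0);
          p = std::pow(q, -exponent / 1.5);
        } else {
          p = std::pow(std::max(reff, 1.0), exponent);
        }
        p_sum[si] += p;
        deff_sum[si] += reff;
        n_obs[si] += 1;
      }
    }
  }
  return List::create(_["s"] = s_values, _["p_sum"] = p_sum,
                      _["deff_sum"] = deff_sum, _["n"] = n_obs);
}
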
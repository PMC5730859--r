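#include <Rcpp.h>
using namespace Rcpp;

// Fixed-number loop-extruding-factor (LEF) dynamics on a 1-D monomer lattice.
//
// Each extrusion step:
//   1. LEF order is freshly shuffled.
//   2. Release pass: every LEF releases with probability p_off and rebinds
//      immediately at a uniformly random free adjacent site pair (fixed-N
//      model: the number of bound LEFs never changes).
//   3. Movement pass: each leg attempts one outward move; the move is
//      rejected if the target site is occupied or outside the lattice, or,
//      when the leg sits on a boundary site, with probability pause_prob.
//
// Uses R's RNG so results are reproducible under set.seed().

static inline int unif_index(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  if (k == n) k = n - 1;
  return k;
}

// [[Rcpp::export]]
List cpp_lef_run(int n_monomers,
                 IntegerVector left0,
                 IntegerVector right0,
                 double p_off,
                 double pause_prob,
                 LogicalVector is_boundary,
                 int n_steps,
                 int record_every,
                 bool record_initial) {
  const int n_lef = left0.size();
  if (right0.size() != n_lef)
    stop("left and right leg vectors must have equal length");
  if (is_boundary.size() != n_monomers)
    stop("boundary indicator must have length n_monomers");

  std::vector<int> left(left0.begin(), left0.end());
  std::vector<int> right(right0.begin(), right0.end());
  std::vector<int> occ(n_monomers, -1);
  for (int k = 0; k < n_lef; ++k) {
    if (left[k] < 0 || right[k] >= n_monomers || left[k] >= right[k])
      stop("invalid initial leg positions for LEF %d", k + 1);
    if (occ[left[k]] != -1 || occ[right[k]] != -1)
      stop("initial leg positions collide");
    occ[left[k]] = k;
    occ[right[k]] = k;
  }

  int n_rec = (record_every > 0) ? (n_steps / record_every) : 0;
  if (record_initial) n_rec += 1;
  IntegerMatrix rec_left(n_rec, n_lef), rec_right(n_rec, n_lef);
  IntegerVector rec_step(n_rec);
  int ri = 0;
  if (record_initial) {
    for (int k = 0; k < n_lef; ++k) {
      rec_left(ri, k) = left[k];
      rec_right(ri, k) = right[k];
    }
    rec_step[ri++] = 0;
  }

  std::vector<int> order(n_lef);
  for (int k = 0; k < n_lef; ++k) order[k] = k;

  for (int step = 1; step <= n_steps; ++step) {
    // Fisher-Yates shuffle of the processing order
    for (int k = n_lef - 1; k > 0; --k) {
      int j = unif_index(k + 1);
      std::swap(order[k], order[j]);
    }
    // release / rebind pass
    for (int o = 0; o < n_lef; ++o) {
      int k = order[o];
      if (unif_rand() < p_off) {
        occ[left[k]] = -1;
        occ[right[k]] = -1;
        bool placed = false;
        // rejection sampling is uniform over free adjacent pairs
        for (long attempt = 0; attempt < 100000L; ++attempt) {
          int x = unif_index(n_monomers - 1);
          if (occ[x] == -1 && occ[x + 1] == -1) {
            left[k] = x;
            right[k] = x + 1;
            occ[x] = k;
            occ[x + 1] = k;
            placed = true;
            break;
          }
        }
        if (!placed) stop("could not rebind LEF: lattice too crowded");
      }
    }
    // movement pass
    for (int o = 0; o < n_lef; ++o) {
      int k = order[o];
      int l = left[k];
      if (l > 0 && occ[l - 1] == -1) {
        if (!(is_boundary[l] && unif_rand() < pause_prob)) {
          occ[l] = -1;
          occ[l - 1] = k;
          left[k] = l - 1;
        }
      }
      int r = right[k];
      if (r < n_monomers - 1 && occ[r + 1] == -1) {
        if (!(is_boundary[r] && unif_rand() < pause_prob)) {
          occ[r] = -1;
          occ[r + 1] = k;
          right[k] = r + 1;
        }
      }
    }
    if (record_every > 0 && step % record_every == 0) {
      for (int k = 0; k < n_lef; ++k) {
        rec_left(ri, k) = left[k];
        rec_right(ri, k) = right[k];
      }
      rec_step[ri++] = step;
    }
  }

  return List::create(_["step"] = rec_step,
                      _["left"] = rec_left,
                      _["right"] = rec_right,
                      _["final_left"] = IntegerVector(left.begin(), left.end()),
                      _["final_right"] = IntegerVector(right.begin(), right.end()));
}
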
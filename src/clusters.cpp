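#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labelling of suprathreshold samples on a
// channels x timepoints grid. Adjacency: spatial neighbours at the same
// timepoint (from `adj`, 1-based channel index lists) and the same channel
// at adjacent timepoints. With require_nb = true, a sample must have at
// least one suprathreshold spatial neighbour AND at least one
// suprathreshold temporal neighbour to enter any cluster (single pruning
// pass before labelling).
// [[Rcpp::export]]
IntegerMatrix cluster_label_cpp(LogicalMatrix mask, List adj, bool require_nb) {
  int nch = mask.nrow(), nt = mask.ncol();
  LogicalMatrix keep(nch, nt);
  if (require_nb) {
    for (int c = 0; c < nch; ++c) {
      IntegerVector nb = adj[c];
      for (int t = 0; t < nt; ++t) {
        if (!mask(c, t)) { keep(c, t) = false; continue; }
        bool sp = false, tp = false;
        for (int j = 0; j < nb.size(); ++j)
          if (mask(nb[j] - 1, t)) { sp = true; break; }
        if (t > 0 && mask(c, t - 1)) tp = true;
        if (t + 1 < nt && mask(c, t + 1)) tp = true;
        keep(c, t) = sp && tp;
      }
    }
  } else {
    keep = mask;
  }
  IntegerMatrix lab(nch, nt);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nch; ++c0) {
    for (int t0 = 0; t0 < nt; ++t0) {
      if (!keep(c0, t0) || lab(c0, t0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(c0 + t0 * nch);
      lab(c0, t0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int c = idx % nch, t = idx / nch;
        IntegerVector nb = adj[c];
        for (int j = 0; j < nb.size(); ++j) {
          int c2 = nb[j] - 1;
          if (keep(c2, t) && lab(c2, t) == 0) {
            lab(c2, t) = next; stack.push_back(c2 + t * nch);
          }
        }
        if (t > 0 && keep(c, t - 1) && lab(c, t - 1) == 0) {
          lab(c, t - 1) = next; stack.push_back(c + (t - 1) * nch);
        }
        if (t + 1 < nt && keep(c, t + 1) && lab(c, t + 1) == 0) {
          lab(c, t + 1) = next; stack.push_back(c + (t + 1) * nch);
        }
      }
    }
  }
  return lab;
}

// Most extreme summed-t cluster statistics of a t-map: returns
// (max positive cluster mass, min negative cluster mass), zero when a sign
// has no clusters. Used for the permutation null.
// [[Rcpp::export]]
NumericVector max_cluster_masses_cpp(NumericMatrix tmap, double thresh,
                                     List adj, bool require_nb) {
  int nch = tmap.nrow(), nt = tmap.ncol();
  NumericVector out(2);
  for (int sgn = 0; sgn < 2; ++sgn) {
    LogicalMatrix mask(nch, nt);
    for (int c = 0; c < nch; ++c)
      for (int t = 0; t < nt; ++t)
        mask(c, t) = sgn == 0 ? (tmap(c, t) > thresh) : (tmap(c, t) < -thresh);
    IntegerMatrix lab = cluster_label_cpp(mask, adj, require_nb);
    int nclust = 0;
    for (int i = 0; i < nch * nt; ++i) nclust = std::max(nclust, lab[i]);
    if (nclust == 0) { out[sgn] = 0.0; continue; }
    std::vector<double> mass(nclust, 0.0);
    for (int c = 0; c < nch; ++c)
      for (int t = 0; t < nt; ++t)
        if (lab(c, t) > 0) mass[lab(c, t) - 1] += tmap(c, t);
    double best = mass[0];
    for (int k = 1; k < nclust; ++k)
      best = sgn == 0 ? std::max(best, mass[k]) : std::min(best, mass[k]);
    out[sgn] = best;
  }
  return out;
}
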
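#include <Rcpp.h>
using namespace Rcpp;

// 4-connected suprathreshold cluster labelling of a statistic map and the
// per-cluster mass (sum of |t| over member cells).  Used by the
// cluster-based permutation test, where the same labelling runs once per
// permutation.

static void floodFill(const NumericMatrix &m, double thresh,
                      IntegerMatrix &lab, int r0, int c0, int id,
                      double &mass, std::vector<int> &stack) {
  int nr = m.nrow(), nc = m.ncol();
  stack.clear();
  stack.push_back(r0 + c0 * nr);
  lab(r0, c0) = id;
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int r = idx % nr, c = idx / nr;
    mass += std::abs(m(r, c));
    const int dr[4] = {1, -1, 0, 0};
    const int dc[4] = {0, 0, 1, -1};
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) != 0) continue;
      if (std::abs(m(rr, cc)) <= thresh) continue;
      lab(rr, cc) = id;
      stack.push_back(rr + cc * nr);
    }
  }
}

// [[Rcpp::export(name = ".labelClusters")]]
List labelClusters(NumericMatrix tmap, double thresh) {
  int nr = tmap.nrow(), nc = tmap.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<double> masses;
  std::vector<int> stack;
  int id = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) == 0 && std::abs(tmap(r, c)) > thresh) {
        double mass = 0.0;
        floodFill(tmap, thresh, lab, r, c, ++id, mass, stack);
        masses.push_back(mass);
      }
  return List::create(_["labels"] = lab,
                      _["mass"] = NumericVector(masses.begin(), masses.end()));
}

// [[Rcpp::export(name = ".maxClusterMass")]]
double maxClusterMass(NumericMatrix tmap, double thresh) {
  List res = labelClusters(tmap, thresh);
  NumericVector mass = res["mass"];
  double best = 0.0;
  for (double m : mass) if (m > best) best = m;
  return best;
}
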
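// Affinity propagation (Frey & Dueck message passing) on a dense similarity
// matrix. Matrices R and A are stored transposed (column i holds row i of the
// conceptual matrix) so that both update sweeps run down contiguous memory;
// S is required symmetric so S(k, i) reads row i as a column.
//
// A deterministic, monotone perturbation of the preferences (i * 1e-9)
// breaks exact ties between duplicate points, which would otherwise keep the
// messages oscillating between all-exemplar and no-exemplar states.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".ap_cluster")]]
List ap_cluster(NumericMatrix S, double preference, double damping,
                int maxit, int convits) {
  const int n = S.nrow();
  if (S.ncol() != n) stop("similarity matrix must be square");
  const double dmp = damping, omd = 1.0 - damping;
  std::vector<double> Rt((size_t)n * n, 0.0), At((size_t)n * n, 0.0);
  std::vector<double> pref(n), sp(n);
  std::vector<int> ex(n, 0), exOld(n, -1);
  for (int i = 0; i < n; ++i) pref[i] = preference + i * 1e-9;

  const double* Sp = S.begin();
  auto sval = [&](int k, int i) -> double {
    return (k == i) ? pref[i] : Sp[(size_t)k + (size_t)i * n];
  };

  int stable = 0, it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    // responsibilities: column i at a time
    for (int i = 0; i < n; ++i) {
      double* Rc = &Rt[(size_t)i * n];
      const double* Ac = &At[(size_t)i * n];
      double max1 = -1e300, max2 = -1e300;
      int k1 = -1;
      for (int k = 0; k < n; ++k) {
        double v = Ac[k] + sval(k, i);
        if (v > max1) { max2 = max1; max1 = v; k1 = k; }
        else if (v > max2) max2 = v;
      }
      for (int k = 0; k < n; ++k) {
        double target = sval(k, i) - (k == k1 ? max2 : max1);
        Rc[k] = dmp * Rc[k] + omd * target;
      }
    }
    // availabilities
    std::fill(sp.begin(), sp.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* Rc = &Rt[(size_t)i * n];
      for (int k = 0; k < n; ++k)
        if (k != i && Rc[k] > 0) sp[k] += Rc[k];
    }
    for (int i = 0; i < n; ++i) {
      double* Ac = &At[(size_t)i * n];
      const double* Rc = &Rt[(size_t)i * n];
      for (int k = 0; k < n; ++k) {
        double target;
        if (k == i) target = sp[k];
        else {
          double rik = Rc[k] > 0 ? Rc[k] : 0.0;
          target = Rt[(size_t)k + (size_t)k * n] + sp[k] - rik;
          if (target > 0) target = 0.0;
        }
        Ac[k] = dmp * Ac[k] + omd * target;
      }
    }
    // exemplar set stability
    bool same = true;
    int nex = 0;
    for (int k = 0; k < n; ++k) {
      ex[k] = (At[(size_t)k + (size_t)k * n] + Rt[(size_t)k + (size_t)k * n]) > 0;
      nex += ex[k];
      if (ex[k] != exOld[k]) same = false;
    }
    exOld = ex;
    stable = same ? stable + 1 : 0;
    if (stable >= convits && nex > 0) { converged = true; ++it; break; }
  }

  std::vector<int> exemplars;
  for (int k = 0; k < n; ++k) if (ex[k]) exemplars.push_back(k);
  if (exemplars.empty())
    return List::create(_["converged"] = false, _["iterations"] = it,
                        _["exemplars"] = IntegerVector(0),
                        _["assign"] = IntegerVector(0));
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    double best = -1e300;
    int arg = exemplars[0];
    bool selfEx = false;
    for (int e : exemplars) {
      if (e == i) { selfEx = true; break; }
      double v = sval(e, i);
      if (v > best) { best = v; arg = e; }
    }
    assign[i] = (selfEx ? i : arg) + 1;  // 1-based exemplar index
  }
  IntegerVector exv(exemplars.size());
  for (size_t j = 0; j < exemplars.size(); ++j) exv[j] = exemplars[j] + 1;
  return List::create(_["converged"] = converged, _["iterations"] = it,
                      _["exemplars"] = exv, _["assign"] = assign);
}
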
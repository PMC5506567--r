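// Linear-chain conditional random field: penalised negative log-likelihood
// with analytic gradient (scaled forward-backward), and Viterbi decoding with
// the best-path conditional probability.
//
// Weight layout (length F*L + L*L + 2L):
//   emission  w[f*L + y]                  feature f, label y
//   transition w[F*L + from + to*L]       column-major L x L
//   start     w[F*L + L*L + y]
//   stop      w[F*L + L*L + L + y]
//
// Sentences arrive flattened: featIdx holds 0-based feature ids, tokPtr[t]
// .. tokPtr[t+1] delimits token t's features, sentPtr[s] .. sentPtr[s+1]
// delimits sentence s's tokens. Structurally illegal BIO transitions are
// excluded via transOK / startOK masks (zero probability mass).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double emitScore(const double* w, const int* feat, int a, int b,
                               int L, int y) {
  double s = 0.0;
  for (int j = a; j < b; ++j) s += w[feat[j] * L + y];
  return s;
}

// [[Rcpp::export(name = ".crf_nll_grad")]]
List crf_nll_grad(NumericVector w, IntegerVector featIdx, IntegerVector tokPtr,
                  IntegerVector sentPtr, IntegerVector gold, int L, int F,
                  LogicalMatrix transOK, LogicalVector startOK, double l2) {
  const int nSent = sentPtr.size() - 1;
  const double* wp = w.begin();
  const int* feat = featIdx.begin();
  const int FL = F * L;
  NumericVector grad(w.size());
  double* g = grad.begin();
  double nll = 0.0;

  std::vector<double> expT(L * L);
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b)
      expT[a + b * L] = transOK(a, b) ? std::exp(wp[FL + a + b * L]) : 0.0;

  for (int s = 0; s < nSent; ++s) {
    const int t0 = sentPtr[s], t1 = sentPtr[s + 1];
    const int T = t1 - t0;
    if (T <= 0) continue;
    std::vector<double> E(T * L), expE(T * L), mshift(T);
    for (int t = 0; t < T; ++t) {
      double m = -1e300;
      for (int y = 0; y < L; ++y) {
        double e = emitScore(wp, feat, tokPtr[t0 + t], tokPtr[t0 + t + 1], L, y);
        E[t * L + y] = e;
        if (e > m) m = e;
      }
      mshift[t] = m;
      for (int y = 0; y < L; ++y)
        expE[t * L + y] = std::exp(E[t * L + y] - m);
    }
    // scaled forward
    std::vector<double> alpha(T * L), cscale(T);
    double logZ = 0.0;
    {
      double c = 0.0;
      for (int y = 0; y < L; ++y) {
        double v = startOK[y] ? std::exp(wp[FL + L * L + y]) * expE[y] : 0.0;
        alpha[y] = v;
        c += v;
      }
      cscale[0] = c;
      for (int y = 0; y < L; ++y) alpha[y] /= c;
      logZ += std::log(c) + mshift[0];
    }
    for (int t = 1; t < T; ++t) {
      double c = 0.0;
      for (int y = 0; y < L; ++y) {
        double acc = 0.0;
        for (int yp = 0; yp < L; ++yp)
          acc += alpha[(t - 1) * L + yp] * expT[yp + y * L];
        double v = acc * expE[t * L + y];
        alpha[t * L + y] = v;
        c += v;
      }
      cscale[t] = c;
      for (int y = 0; y < L; ++y) alpha[t * L + y] /= c;
      logZ += std::log(c) + mshift[t];
    }
    double zTail = 0.0;
    for (int y = 0; y < L; ++y)
      zTail += alpha[(T - 1) * L + y] * std::exp(wp[FL + L * L + L + y]);
    logZ += std::log(zTail);

    // scaled backward (per-step normalisation; marginals self-normalise)
    std::vector<double> beta(T * L);
    {
      double c = 0.0;
      for (int y = 0; y < L; ++y) {
        double v = std::exp(wp[FL + L * L + L + y]);
        beta[(T - 1) * L + y] = v;
        c += v;
      }
      for (int y = 0; y < L; ++y) beta[(T - 1) * L + y] /= c;
    }
    for (int t = T - 2; t >= 0; --t) {
      double c = 0.0;
      for (int y = 0; y < L; ++y) {
        double acc = 0.0;
        for (int yn = 0; yn < L; ++yn)
          acc += expT[y + yn * L] * expE[(t + 1) * L + yn] * beta[(t + 1) * L + yn];
        beta[t * L + y] = acc;
        c += acc;
      }
      for (int y = 0; y < L; ++y) beta[t * L + y] /= c;
    }

    // gold path score
    double gscore = wp[FL + L * L + gold[t0]];
    for (int t = 0; t < T; ++t) gscore += E[t * L + gold[t0 + t]];
    for (int t = 1; t < T; ++t)
      gscore += wp[FL + gold[t0 + t - 1] + gold[t0 + t] * L];
    gscore += wp[FL + L * L + L + gold[t0 + T - 1]];
    nll += logZ - gscore;

    // node marginals -> emission + start/stop gradient
    std::vector<double> marg(L);
    for (int t = 0; t < T; ++t) {
      double zn = 0.0;
      for (int y = 0; y < L; ++y) {
        marg[y] = alpha[t * L + y] * beta[t * L + y];
        zn += marg[y];
      }
      for (int y = 0; y < L; ++y) marg[y] /= zn;
      marg[gold[t0 + t]] -= 1.0;
      for (int j = tokPtr[t0 + t]; j < tokPtr[t0 + t + 1]; ++j) {
        double* gf = g + feat[j] * L;
        for (int y = 0; y < L; ++y) gf[y] += marg[y];
      }
      // marg already holds (expected - empirical); boundary weights share it
      if (t == 0)
        for (int y = 0; y < L; ++y) g[FL + L * L + y] += marg[y];
      if (t == T - 1)
        for (int y = 0; y < L; ++y) g[FL + L * L + L + y] += marg[y];
    }
    // edge marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      double zn = 0.0;
      std::vector<double> em(L * L);
      for (int yp = 0; yp < L; ++yp) {
        double a = alpha[(t - 1) * L + yp];
        for (int y = 0; y < L; ++y) {
          double v = a * expT[yp + y * L] * expE[t * L + y] * beta[t * L + y];
          em[yp + y * L] = v;
          zn += v;
        }
      }
      for (int yp = 0; yp < L; ++yp)
        for (int y = 0; y < L; ++y)
          g[FL + yp + y * L] += em[yp + y * L] / zn;
      g[FL + gold[t0 + t - 1] + gold[t0 + t] * L] -= 1.0;
    }
  }

  // L2 penalty
  double pen = 0.0;
  for (R_xlen_t i = 0; i < w.size(); ++i) {
    pen += wp[i] * wp[i];
    g[i] += l2 * wp[i];
  }
  nll += 0.5 * l2 * pen;
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// [[Rcpp::export(name = ".crf_decode_all")]]
List crf_decode_all(NumericVector w, IntegerVector featIdx, IntegerVector tokPtr,
                    IntegerVector sentPtr, int L, int F,
                    LogicalMatrix transOK, LogicalVector startOK,
                    bool wantProb = true) {
  const int nSent = sentPtr.size() - 1;
  const double* wp = w.begin();
  const int* feat = featIdx.begin();
  const int FL = F * L;
  const double NEG = -1e300;

  std::vector<double> Tw(L * L), expT(L * L);
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b) {
      Tw[a + b * L] = transOK(a, b) ? wp[FL + a + b * L] : NEG;
      expT[a + b * L] = transOK(a, b) ? std::exp(wp[FL + a + b * L]) : 0.0;
    }

  List paths(nSent);
  NumericVector logProb(nSent);
  for (int s = 0; s < nSent; ++s) {
    const int t0 = sentPtr[s], t1 = sentPtr[s + 1];
    const int T = t1 - t0;
    if (T <= 0) { paths[s] = IntegerVector(0); logProb[s] = 0.0; continue; }
    std::vector<double> E(T * L);
    for (int t = 0; t < T; ++t)
      for (int y = 0; y < L; ++y)
        E[t * L + y] = emitScore(wp, feat, tokPtr[t0 + t], tokPtr[t0 + t + 1], L, y);

    // Viterbi
    std::vector<double> delta(T * L);
    std::vector<int> back(T * L);
    for (int y = 0; y < L; ++y)
      delta[y] = (startOK[y] ? wp[FL + L * L + y] + E[y] : NEG);
    for (int t = 1; t < T; ++t)
      for (int y = 0; y < L; ++y) {
        double best = NEG; int arg = 0;
        for (int yp = 0; yp < L; ++yp) {
          double v = delta[(t - 1) * L + yp] + Tw[yp + y * L];
          if (v > best) { best = v; arg = yp; }
        }
        delta[t * L + y] = best + E[t * L + y];
        back[t * L + y] = arg;
      }
    double bestScore = NEG; int bestY = 0;
    for (int y = 0; y < L; ++y) {
      double v = delta[(T - 1) * L + y] + wp[FL + L * L + L + y];
      if (v > bestScore) { bestScore = v; bestY = y; }
    }
    IntegerVector path(T);
    path[T - 1] = bestY;
    for (int t = T - 1; t > 0; --t)
      path[t - 1] = back[t * L + path[t]];
    paths[s] = path;

    if (!wantProb) { logProb[s] = NA_REAL; continue; }

    // log partition (scaled forward over legal paths)
    std::vector<double> alpha(L), nxt(L);
    double logZ = 0.0;
    {
      double m = NEG;
      for (int y = 0; y < L; ++y) m = std::max(m, E[y]);
      double c = 0.0;
      for (int y = 0; y < L; ++y) {
        alpha[y] = startOK[y] ? std::exp(wp[FL + L * L + y] + E[y] - m) : 0.0;
        c += alpha[y];
      }
      for (int y = 0; y < L; ++y) alpha[y] /= c;
      logZ += std::log(c) + m;
    }
    for (int t = 1; t < T; ++t) {
      double m = NEG;
      for (int y = 0; y < L; ++y) m = std::max(m, E[t * L + y]);
      double c = 0.0;
      for (int y = 0; y < L; ++y) {
        double acc = 0.0;
        for (int yp = 0; yp < L; ++yp)
          acc += alpha[yp] * expT[yp + y * L];
        nxt[y] = acc * std::exp(E[t * L + y] - m);
        c += nxt[y];
      }
      for (int y = 0; y < L; ++y) alpha[y] = nxt[y] / c;
      logZ += std::log(c) + m;
    }
    double zTail = 0.0;
    for (int y = 0; y < L; ++y)
      zTail += alpha[y] * std::exp(wp[FL + L * L + L + y]);
    logZ += std::log(zTail);
    logProb[s] = bestScore - logZ;
  }
  return List::create(_["paths"] = paths, _["logProb"] = logProb);
}
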
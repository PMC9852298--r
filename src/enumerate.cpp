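// Exhaustive enumeration of two-agent typed bipartite configurations.
//
// A configuration class is the sufficient statistic (r, c, o): agent i's
// per-type link counts r_k, agent j's per-type counts c_k, and the per-type
// overlaps o_k. Every p-value, the Herfindahl-Hirschman concentration and
// the overlap fraction depend on the configuration only through (r, c, o),
// so enumerating classes covers the whole configuration space. The optional
// multiplicity weight counts, for each class, the number of labeled
// assignments of the T distinguishable events realizing it (computed by
// inclusion-exclusion over forced same-type matches).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Comp {
  std::vector<int> parts;
  int degree;
};

void gen_comps(int remaining, int pos, int n_types, std::vector<int>& cur,
               int degree, std::vector<Comp>& out) {
  if (pos == n_types - 1) {
    cur[pos] = remaining;
    out.push_back({cur, degree});
    return;
  }
  for (int v = 0; v <= remaining; ++v) {
    cur[pos] = v;
    gen_comps(remaining - v, pos + 1, n_types, cur, degree, out);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_enumerate_two_agent(int n_events, int n_types, NumericVector alpha,
                             NumericVector hh_breaks, bool multiplicity) {
  const int T = n_events;
  const int K = n_types;
  const int nA = alpha.size();
  const int nb = hh_breaks.size() - 1;
  if (T < 1 || K < 1) stop("n_events and n_types must be >= 1");
  // guard against infeasible enumeration sizes (compositions grow as
  // C(T + K - 1, K - 1) per agent, squared across the pair)
  double n_comp_est = 1.0;
  for (int k = 1; k <= K; ++k) n_comp_est *= (T + k) / double(k);
  if (n_comp_est * n_comp_est > 4e7) {
    stop("enumeration infeasible at this size; reduce n_events or n_types");
  }

  std::vector<double> lf(2 * T + 2);
  lf[0] = 0.0;
  for (int i = 1; i < (int)lf.size(); ++i) lf[i] = lf[i - 1] + std::log((double)i);
  auto lchoose = [&](int n, int k) { return lf[n] - lf[k] - lf[n - k]; };

  // PH[k][m][n] = P(X >= k | T, m, n), hypergeometric upper tail
  const int D = T + 1;
  std::vector<double> PH((size_t)D * D * D, 0.0);
  for (int m = 0; m <= T; ++m) {
    for (int n = 0; n <= T; ++n) {
      int lo = std::max(0, m + n - T), hi = std::min(m, n);
      std::vector<double> pmf(hi + 1, 0.0);
      for (int x = lo; x <= hi; ++x) {
        pmf[x] = std::exp(lchoose(m, x) + lchoose(T - m, n - x) - lchoose(T, n));
      }
      double tail = 0.0;
      std::vector<double> sv(hi + 2, 0.0);
      for (int x = hi; x >= 0; --x) { tail += pmf[x]; sv[x] = std::min(tail, 1.0); }
      for (int k = 0; k <= T; ++k) {
        double v = (k == 0) ? 1.0 : (k <= hi ? sv[k] : 0.0);
        PH[(size_t)k * D * D + (size_t)m * D + n] = v;
      }
    }
  }
  auto ph = [&](int k, int m, int n) -> double {
    return PH[(size_t)k * D * D + (size_t)m * D + n];
  };

  std::vector<Comp> comps;
  {
    std::vector<int> cur(K);
    for (int d = 1; d <= T; ++d) gen_comps(d, 0, K, cur, d, comps);
  }
  const int nC = comps.size();

  // accumulators
  NumericMatrix cell_count(nb, T), cell_sum_p(nb, T), cell_lt(nb, T);
  NumericMatrix cell_wcount(nb, T), cell_wsum_p(nb, T), cell_wlt(nb, T);
  const int n_models = 4;  // mixture, ref-min, ref-mean, ref-max
  NumericMatrix vcnt(nA + 1, n_models), wvcnt(nA + 1, n_models);
  NumericVector minima(n_models, 1.0);
  double n_classes = 0.0, total_weight = 0.0;

  std::vector<double> survmix(T + 2), fY(T + 1), brow(T + 1);
  std::vector<int> o(K);
  std::vector<double> g, gnew, fk;

  for (int a = 0; a < nC; ++a) {
    const std::vector<int>& r = comps[a].parts;
    const int Ni = comps[a].degree;
    Rcpp::checkUserInterrupt();
    for (int b = 0; b < nC; ++b) {
      const std::vector<int>& c = comps[b].parts;
      const int Nj = comps[b].degree;
      double dot = 0.0;
      for (int k = 0; k < K; ++k) dot += (double)r[k] * c[k];
      const double p = dot / ((double)Ni * Nj);
      const double q = 1.0 - p;
      const int lo = std::max(0, Ni + Nj - T), hi = std::min(Ni, Nj);

      // distribution of Y = same-type matches under the mixture null
      std::fill(fY.begin(), fY.begin() + hi + 1, 0.0);
      for (int X = lo; X <= hi; ++X) {
        double H = std::exp(lchoose(Ni, X) + lchoose(T - Ni, Nj - X) -
                            lchoose(T, Nj));
        if (X == 0) { fY[0] += H; continue; }
        if (p >= 1.0) { fY[X] += H; continue; }
        if (p <= 0.0) { fY[0] += H; continue; }
        brow[0] = std::pow(q, X);
        const double ratio = p / q;
        for (int y = 1; y <= X; ++y) {
          brow[y] = brow[y - 1] * ratio * (double)(X - y + 1) / (double)y;
        }
        for (int y = 0; y <= X; ++y) fY[y] += H * brow[y];
      }
      double tail = 0.0;
      survmix[hi + 1] = 0.0;
      for (int y = hi; y >= 1; --y) {
        tail += fY[y];
        survmix[y] = std::min(tail, 1.0);
      }
      survmix[0] = 1.0;

      // enumerate per-type overlaps o_k <= min(r_k, c_k) with a feasible
      // off-diagonal completion: (r_k - o_k) + (c_k - o_k) <= T - sum(o)
      int depth = 0;
      o.assign(K, 0);
      while (true) {
        if (depth == K) {
          int S = 0, ssq = 0;
          bool ok = true;
          for (int k = 0; k < K; ++k) S += o[k];
          for (int k = 0; k < K; ++k) {
            ssq += o[k] * o[k];
            if ((r[k] - o[k]) + (c[k] - o[k]) > T - S) { ok = false; break; }
          }
          if (ok) {
            const double pmix = (S > 0) ? survmix[std::min(S, hi + 1)] : 1.0;
            double minr = 1.0, maxr = 0.0, sumr = 0.0;
            for (int k = 0; k < K; ++k) {
              double pr = ph(o[k], r[k], c[k]);
              minr = std::min(minr, pr);
              maxr = std::max(maxr, pr);
              sumr += pr;
            }
            const double meanr = sumr / K;
            const double pm[4] = {pmix, minr, meanr, maxr};
            n_classes += 1.0;
            for (int mdl = 0; mdl < n_models; ++mdl) {
              if (pm[mdl] < minima[mdl]) minima[mdl] = pm[mdl];
              int idx = std::upper_bound(alpha.begin(), alpha.end(), pm[mdl]) -
                        alpha.begin();
              vcnt(idx, mdl) += 1.0;
            }
            double W = 0.0;
            if (multiplicity) {
              const int Tp = T - S;
              double ldiag = lf[T] - lf[Tp];
              for (int k = 0; k < K; ++k) ldiag -= lf[o[k]];
              g.assign(1, 1.0);
              for (int k = 0; k < K; ++k) {
                const int rp = r[k] - o[k], cp = c[k] - o[k];
                const int dk = std::min(rp, cp);
                fk.resize(dk + 1);
                for (int j = 0; j <= dk; ++j) {
                  fk[j] = std::exp(-(lf[j] + lf[rp - j] + lf[cp - j]));
                }
                gnew.assign(g.size() + dk, 0.0);
                for (size_t u = 0; u < g.size(); ++u) {
                  for (int j = 0; j <= dk; ++j) gnew[u + j] += g[u] * fk[j];
                }
                g.swap(gnew);
              }
              double A = 0.0;
              for (size_t s2 = 0; s2 < g.size() && (int)s2 <= Tp; ++s2) {
                double term = std::exp(lf[Tp - (int)s2]) * g[s2];
                A += (s2 % 2 == 0) ? term : -term;
              }
              A *= std::exp(lf[Tp] - lf[T - Ni] - lf[T - Nj]);
              W = std::exp(ldiag) * std::max(A, 0.0);
              total_weight += W;
              for (int mdl = 0; mdl < n_models; ++mdl) {
                int idx = std::upper_bound(alpha.begin(), alpha.end(), pm[mdl]) -
                          alpha.begin();
                wvcnt(idx, mdl) += W;
              }
            }
            if (S > 0) {
              const double hh = (double)ssq / ((double)S * S);
              int bin = nb - 1;
              for (int i2 = 0; i2 < nb; ++i2) {
                if (hh < hh_breaks[i2 + 1]) { bin = i2; break; }
              }
              cell_count(bin, S - 1) += 1.0;
              cell_sum_p(bin, S - 1) += pmix;
              if (pmix < minr) cell_lt(bin, S - 1) += 1.0;
              if (multiplicity) {
                cell_wcount(bin, S - 1) += W;
                cell_wsum_p(bin, S - 1) += W * pmix;
                if (pmix < minr) cell_wlt(bin, S - 1) += W;
              }
            }
          }
          --depth;
          if (depth < 0) break;
          ++o[depth];
          continue;
        }
        const int cap = std::min(r[depth], c[depth]);
        if (o[depth] > cap) {
          o[depth] = 0;
          --depth;
          if (depth < 0) break;
          ++o[depth];
          continue;
        }
        ++depth;
        if (depth < K) o[depth] = 0;
      }
    }
  }

  // prefix sums: validated(a) = number of classes with p < alpha[a]
  NumericMatrix validated(nA, n_models), wvalidated(nA, n_models);
  for (int mdl = 0; mdl < n_models; ++mdl) {
    double acc = 0.0, wacc = 0.0;
    for (int a = 0; a < nA; ++a) {
      acc += vcnt(a, mdl);
      wacc += wvcnt(a, mdl);
      validated(a, mdl) = acc;
      wvalidated(a, mdl) = wacc;
    }
  }

  return List::create(
    _["n_classes"] = n_classes,
    _["total_weight"] = total_weight,
    _["cell_count"] = cell_count,
    _["cell_sum_p"] = cell_sum_p,
    _["cell_lt"] = cell_lt,
    _["cell_wcount"] = cell_wcount,
    _["cell_wsum_p"] = cell_wsum_p,
    _["cell_wlt"] = cell_wlt,
    _["validated"] = validated,
    _["wvalidated"] = wvalidated,
    _["minima"] = minima
  );
}
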
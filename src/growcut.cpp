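#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Synchronous GrowCut cellular automaton.  State per cell: (label, strength,
// feature).  Neighbour q attacks p with g(|C_p - C_q|) * theta_q where
// g(d) = 1 - d / 255; p adopts q's label when the attack exceeds theta_p.
// Ties between equally strong attackers are broken by the smallest label.
// labels use 0 for "unlabeled"; seed cells carry strength 1.
// Iterates until a full sweep changes neither labels nor strengths, or
// max_iters sweeps have run.
// [[Rcpp::export]]
List growcut_cpp(const IntegerMatrix &feat, const IntegerMatrix &labels0,
                 const NumericMatrix &strength0, bool moore, int max_iters) {
  const int R = feat.nrow(), C = feat.ncol();
  IntegerMatrix lab = clone(labels0), lab2(R, C);
  NumericMatrix th = clone(strength0), th2(R, C);
  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = moore ? 8 : 4;
  int it = 0;
  bool converged = false;
  while (it < max_iters) {
    ++it;
    bool changed = false;
    for (int c = 0; c < C; ++c) {
      for (int r = 0; r < R; ++r) {
        double best_av = -1.0;
        int best_lab = 0;
        for (int i = 0; i < nn; ++i) {
          const int rr = r + dr8[i], cc = c + dc8[i];
          if (rr < 0 || rr >= R || cc < 0 || cc >= C) continue;
          const int lq = lab(rr, cc);
          if (lq == 0) continue;
          const double g =
              1.0 - std::abs(feat(r, c) - feat(rr, cc)) / 255.0;
          const double av = g * th(rr, cc);
          if (av > best_av || (av == best_av && lq < best_lab)) {
            best_av = av;
            best_lab = lq;
          }
        }
        if (best_lab != 0 && best_av > th(r, c)) {
          lab2(r, c) = best_lab;
          th2(r, c) = best_av;
          if (best_lab != lab(r, c) || best_av != th(r, c)) changed = true;
        } else {
          lab2(r, c) = lab(r, c);
          th2(r, c) = th(r, c);
        }
      }
    }
    IntegerMatrix tl = lab; lab = lab2; lab2 = tl;
    NumericMatrix tt = th; th = th2; th2 = tt;
    if (!changed) { converged = true; break; }
  }
  return List::create(Named("labels") = lab, Named("strengths") = th,
                      Named("iterations") = it,
                      Named("converged") = converged);
}
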
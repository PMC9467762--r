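#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// replicate padding: clamp out-of-range indices to the border
static inline int pget(const IntegerMatrix &m, int r, int c) {
  const int R = m.nrow(), C = m.ncol();
  if (r < 0) r = 0; else if (r >= R) r = R - 1;
  if (c < 0) c = 0; else if (c >= C) c = C - 1;
  return m(r, c);
}

static inline bool mget(const LogicalMatrix &m, int r, int c) {
  const int R = m.nrow(), C = m.ncol();
  if (r < 0) r = 0; else if (r >= R) r = R - 1;
  if (c < 0) c = 0; else if (c >= C) c = C - 1;
  return m(r, c);
}

// lower median of a multiset (deterministic for even sizes)
static inline int lower_median(std::vector<int> &v) {
  const size_t k = (v.size() - 1) / 2;
  std::nth_element(v.begin(), v.begin() + k, v.end());
  return v[k];
}

// [[Rcpp::export]]
IntegerMatrix road_map_cpp(const IntegerMatrix &img, int k) {
  const int R = img.nrow(), C = img.ncol();
  IntegerMatrix out(R, C);
  int d[8];
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      const int v = img(r, c);
      int n = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          d[n++] = std::abs(pget(img, r + dr, c + dc) - v);
        }
      std::sort(d, d + 8);
      int s = 0;
      for (int i = 0; i < k; ++i) s += d[i];
      out(r, c) = s;
    }
  }
  return out;
}

// Impulse detector: ROAD rule OR fixed-valued extreme rule on an adaptively
// grown window.  The window grows by 2 (up to max_w) while the fraction of
// window pixels equal to the window min or max exceeds growth_frac (constant
// windows never grow).
// [[Rcpp::export]]
LogicalMatrix detect_noise_cpp(const IntegerMatrix &img, int base_w, int max_w,
                               int road_k, double road_thr,
                               double growth_frac) {
  const int R = img.nrow(), C = img.ncol();
  LogicalMatrix out(R, C);
  IntegerMatrix road = road_map_cpp(img, road_k);
  std::vector<int> win;
  win.reserve((size_t)max_w * max_w);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      bool flag = road(r, c) > road_thr;
      if (!flag) {
        int w = base_w;
        for (;;) {
          const int h = w / 2;
          win.clear();
          for (int dr = -h; dr <= h; ++dr)
            for (int dc = -h; dc <= h; ++dc)
              win.push_back(pget(img, r + dr, c + dc));
          int wmin = win[0], wmax = win[0];
          for (size_t i = 1; i < win.size(); ++i) {
            if (win[i] < wmin) wmin = win[i];
            if (win[i] > wmax) wmax = win[i];
          }
          if (wmin < wmax && w < max_w) {
            int ext = 0;
            for (size_t i = 0; i < win.size(); ++i)
              if (win[i] == wmin || win[i] == wmax) ++ext;
            if ((double)ext / (double)win.size() > growth_frac) {
              w += 2;
              continue;
            }
          }
          const int med = lower_median(win);
          const int v = img(r, c);
          flag = (v == wmin || v == wmax) && (wmin < med && med < wmax);
          break;
        }
      }
      out(r, c) = flag;
    }
  }
  return out;
}

// Replace flagged pixels by the center-weighted median of the non-flagged
// pixels of an adaptive window (grown until >= 3 non-flagged pixels or max_w).
// The center weight is applied to the nearest non-flagged pixel; among
// equally near pixels the one most consistent with the local non-flagged
// median wins (remaining ties in window scan order), so a falsely flagged
// clean pixel is restored from its own region rather than an arbitrary
// neighbour.  Windows exhausted with zero non-flagged pixels fall back to
// the plain median of the full max window.
// [[Rcpp::export]]
List acwm_replace_cpp(const IntegerMatrix &img, const LogicalMatrix &mask,
                      int base_w, int max_w, int weight) {
  const int R = img.nrow(), C = img.ncol();
  IntegerMatrix out = clone(img);
  int fallbacks = 0;
  std::vector<int> vals, d2s;
  vals.reserve((size_t)max_w * max_w + weight);
  d2s.reserve((size_t)max_w * max_w);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      if (!mask(r, c)) continue;
      int w = base_w;
      for (;;) {
        const int h = w / 2;
        vals.clear();
        d2s.clear();
        for (int dr = -h; dr <= h; ++dr)
          for (int dc = -h; dc <= h; ++dc) {
            if (dr == 0 && dc == 0) continue;
            if (mget(mask, r + dr, c + dc)) continue;
            vals.push_back(pget(img, r + dr, c + dc));
            d2s.push_back(dr * dr + dc * dc);
          }
        if ((int)vals.size() >= 3 || w >= max_w) break;
        w += 2;
      }
      if (vals.empty()) {
        ++fallbacks;
        const int h = max_w / 2;
        for (int dr = -h; dr <= h; ++dr)
          for (int dc = -h; dc <= h; ++dc)
            vals.push_back(pget(img, r + dr, c + dc));
        out(r, c) = lower_median(vals);
      } else {
        std::vector<int> tmp(vals);
        const int med = lower_median(tmp);
        // tie-break among equally near pixels: a flagged pixel whose own
        // value is off the impulse rails may be a false alarm, so its own
        // value anchors the choice; rail values carry no information and
        // defer to the local non-flagged median
        const int v0 = img(r, c);
        const int anchor = (v0 == 0 || v0 == 255) ? med : v0;
        int best = 0;
        for (size_t i = 1; i < vals.size(); ++i) {
          if (d2s[i] < d2s[best] ||
              (d2s[i] == d2s[best] &&
               std::abs(vals[i] - anchor) < std::abs(vals[best] - anchor)))
            best = (int)i;
        }
        const int nearest_val = vals[best];
        for (int i = 0; i < weight - 1; ++i) vals.push_back(nearest_val);
        out(r, c) = lower_median(vals);
      }
    }
  }
  return List::create(Named("image") = out, Named("fallbacks") = fallbacks);
}

// Sliding weighted median with a non-negative integer weight stencil.
// [[Rcpp::export]]
IntegerMatrix weighted_median_cpp(const IntegerMatrix &img,
                                  const IntegerMatrix &weights) {
  const int R = img.nrow(), C = img.ncol();
  const int w = weights.nrow(), h = w / 2;
  IntegerMatrix out(R, C);
  int total = 0;
  for (int i = 0; i < w * w; ++i) total += weights[i];
  const int target = (total + 1) / 2;  // lower weighted median
  std::vector<std::pair<int, int> > vw;
  vw.reserve((size_t)w * w);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      vw.clear();
      for (int dc = -h; dc <= h; ++dc)
        for (int dr = -h; dr <= h; ++dr) {
          const int wt = weights(dr + h, dc + h);
          if (wt > 0)
            vw.push_back(std::make_pair(pget(img, r + dr, c + dc), wt));
        }
      std::sort(vw.begin(), vw.end());
      int cum = 0, med = vw.back().first;
      for (size_t i = 0; i < vw.size(); ++i) {
        cum += vw[i].second;
        if (cum >= target) { med = vw[i].first; break; }
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Two-stage adaptive median for impulse noise: stage A grows the window
// while the window median is an extreme gray level (0 or L-1, the impulse
// rails); stage B replaces the pixel only if the pixel itself is an
// extreme, otherwise it passes through.  At the maximum window the median
// is output as a best effort.
// [[Rcpp::export]]
IntegerMatrix adaptive_median_cpp(const IntegerMatrix &img, int max_w,
                                  int L) {
  const int R = img.nrow(), C = img.ncol();
  const int lo = 0, hi = L - 1;
  IntegerMatrix out(R, C);
  std::vector<int> win;
  win.reserve((size_t)max_w * max_w);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < R; ++r) {
      const int v = img(r, c);
      if (v != lo && v != hi) { out(r, c) = v; continue; }  // stage B early
      int w = 3;
      for (;;) {
        const int h = w / 2;
        win.clear();
        for (int dr = -h; dr <= h; ++dr)
          for (int dc = -h; dc <= h; ++dc)
            win.push_back(pget(img, r + dr, c + dc));
        const int med = lower_median(win);
        if (med != lo && med != hi) { out(r, c) = med; break; }
        if (w >= max_w) { out(r, c) = med; break; }
        w += 2;
      }
    }
  }
  return out;
}
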
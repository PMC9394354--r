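#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Volumes are R arrays with dim (ni, nj, nk) ~ (X, Y, Z); i varies fastest.
// All C++ indices are 0-based; R wrappers convert.

static inline R_xlen_t vidx(int i, int j, int k, int ni, int nj) {
  return (R_xlen_t)i + (R_xlen_t)ni * ((R_xlen_t)j + (R_xlen_t)nj * (R_xlen_t)k);
}

// Full-volume forward/backward path density of length l.
//
// FPD(i,j,k;l) is the maximum, over all monotone paths that advance one
// Y-slice per step with lateral steps in {-1,0,1}^2, of the sum of the l+1
// densities along the path (origin included). Any such path stays inside the
// 45-degree search pyramid of its origin and inside the reverse influence
// pyramid of whichever base target it reaches, so the constrained bipyramid
// maximum over all targets collapses to l sweeps of a 9-neighbour recurrence.
// dir = +1 accumulates towards +Y (FPD), dir = -1 towards -Y (BPD).
// Origins whose pyramid exits the Y range are set to 0; X/Z neighbours
// outside the grid simply do not contribute.
// [[Rcpp::export]]
NumericVector cpp_path_density(NumericVector d, IntegerVector dims, int l, int dir) {
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  std::vector<double> prev(d.begin(), d.end()), cur(d.size());
  for (int s = 1; s <= l; ++s) {
    // valid origin slices at sweep s: those with j + dir*s inside the grid
    const int jlo = dir > 0 ? 0 : s;
    const int jhi = dir > 0 ? nj - 1 - s : nj - 1;
    for (int k = 0; k < nk; ++k) {
      for (int j = jlo; j <= jhi; ++j) {
        const int jn = j + dir;
        for (int i = 0; i < ni; ++i) {
          double best = -1.0;
          for (int n = -1; n <= 1; ++n) {
            const int kk = k + n;
            if (kk < 0 || kk >= nk) continue;
            for (int mm = -1; mm <= 1; ++mm) {
              const int ii = i + mm;
              if (ii < 0 || ii >= ni) continue;
              const double v = prev[vidx(ii, jn, kk, ni, nj)];
              if (v > best) best = v;
            }
          }
          cur[vidx(i, j, k, ni, nj)] = d[vidx(i, j, k, ni, nj)] + best;
        }
      }
    }
    std::swap(prev, cur);
  }
  // origins within l of the Y boundary have no complete pyramid: value 0
  NumericVector out(d.size());
  for (int k = 0; k < nk; ++k)
    for (int j = 0; j < nj; ++j) {
      const bool valid = dir > 0 ? (j + l <= nj - 1) : (j - l >= 0);
      for (int i = 0; i < ni; ++i)
        out[vidx(i, j, k, ni, nj)] =
          valid ? prev[vidx(i, j, k, ni, nj)] : 0.0;
    }
  out.attr("dim") = dims;
  return out;
}

// Full-volume straight-line accumulation (the simpler alternative to the
// bipyramid DP): for each origin, the best over the (2l+1)^2 base targets of
// the sum of densities along the nearest-voxel rounded straight line.
// [[Rcpp::export]]
NumericVector cpp_path_density_line(NumericVector d, IntegerVector dims, int l, int dir) {
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  NumericVector out(d.size());
  // rounded lateral offset of a line to target offset u (|u|<=l) at step t
  std::vector<int> roff((2 * l + 1) * (l + 1));
  for (int u = -l; u <= l; ++u)
    for (int t = 0; t <= l; ++t)
      roff[(u + l) * (l + 1) + t] = (int)std::floor((double)u * t / l + 0.5);
  for (int k = 0; k < nk; ++k) {
    for (int j = 0; j < nj; ++j) {
      const int jbase = j + dir * l;
      if (jbase < 0 || jbase >= nj) continue; // leave 0 at the boundary band
      for (int i = 0; i < ni; ++i) {
        double best = -1.0;
        for (int di = -l; di <= l; ++di) {
          if (i + di < 0 || i + di >= ni) continue;
          for (int dk = -l; dk <= l; ++dk) {
            if (k + dk < 0 || k + dk >= nk) continue;
            double s = 0.0;
            for (int t = 0; t <= l; ++t) {
              const int ii = i + roff[(di + l) * (l + 1) + t];
              const int kk = k + roff[(dk + l) * (l + 1) + t];
              s += d[vidx(ii, j + dir * t, kk, ni, nj)];
            }
            if (s > best) best = s;
          }
        }
        out[vidx(i, j, k, ni, nj)] = best < 0 ? 0.0 : best;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Per-seed traced segment of Y-extent l. method 0 = bipyramid DP (with path
// backtracking), method 1 = straight-line accumulation. Ties in the target
// maximum break towards the lexicographically smallest (i', k'); DP
// backtracking ties break the same way. seeds are 0-based (n x 3).
// Returns fpd values, end voxels and the full voxel path per seed; seeds too
// close to the Y boundary get fpd = NA.
// [[Rcpp::export]]
List cpp_trace_seeds(NumericVector d, IntegerVector dims, IntegerMatrix seeds,
                     int l, int dir, int method) {
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  const int n = seeds.nrow(), w = 2 * l + 1;
  NumericVector fpd(n);
  IntegerMatrix ends(n, 3);
  IntegerVector path(Dimension(n, l + 1, 3));
  const double NEG = -DBL_MAX;
  std::vector<double> pd((size_t)(l + 1) * w * w);
  std::vector<int> roff(w * (l + 1));
  if (method == 1)
    for (int u = -l; u <= l; ++u)
      for (int t = 0; t <= l; ++t)
        roff[(u + l) * (l + 1) + t] = (int)std::floor((double)u * t / l + 0.5);

  for (int s = 0; s < n; ++s) {
    const int i0 = seeds(s, 0), j0 = seeds(s, 1), k0 = seeds(s, 2);
    if (j0 + dir * l < 0 || j0 + dir * l >= nj ||
        i0 < 0 || i0 >= ni || j0 < 0 || j0 >= nj || k0 < 0 || k0 >= nk) {
      fpd[s] = NA_REAL;
      continue;
    }
    double best = NEG; int bi = 0, bk = 0;
    if (method == 0) {
      std::fill(pd.begin(), pd.end(), NEG);
      pd[(size_t)0 * w * w + l * w + l] = d[vidx(i0, j0, k0, ni, nj)];
      for (int t = 1; t <= l; ++t) {
        const int j = j0 + dir * t;
        for (int di = -t; di <= t; ++di) {
          const int ii = i0 + di;
          if (ii < 0 || ii >= ni) continue;
          for (int dk = -t; dk <= t; ++dk) {
            const int kk = k0 + dk;
            if (kk < 0 || kk >= nk) continue;
            double b = NEG;
            for (int mm = -1; mm <= 1; ++mm) {
              const int pi = di + mm;
              if (pi < -(t - 1) || pi > t - 1) continue;
              for (int nn = -1; nn <= 1; ++nn) {
                const int pk = dk + nn;
                if (pk < -(t - 1) || pk > t - 1) continue;
                const double v = pd[(size_t)(t - 1) * w * w + (pi + l) * w + (pk + l)];
                if (v > b) b = v;
              }
            }
            if (b > NEG)
              pd[(size_t)t * w * w + (di + l) * w + (dk + l)] =
                d[vidx(ii, j, kk, ni, nj)] + b;
          }
        }
      }
      for (int di = -l; di <= l; ++di)
        for (int dk = -l; dk <= l; ++dk) {
          const double v = pd[(size_t)l * w * w + (di + l) * w + (dk + l)];
          if (v > best) { best = v; bi = di; bk = dk; }
        }
      // backtrack the argmax path (smallest (i,k) on ties)
      int ci = bi, ck = bk;
      path[s + (R_xlen_t)n * (l + (R_xlen_t)(l + 1) * 0)] = i0 + ci;
      path[s + (R_xlen_t)n * (l + (R_xlen_t)(l + 1) * 1)] = j0 + dir * l;
      path[s + (R_xlen_t)n * (l + (R_xlen_t)(l + 1) * 2)] = k0 + ck;
      for (int t = l; t >= 1; --t) {
        double b = NEG; int ni2 = ci, nk2 = ck;
        for (int mm = -1; mm <= 1; ++mm) {
          const int pi = ci + mm;
          if (pi < -(t - 1) || pi > t - 1) continue;
          for (int nn = -1; nn <= 1; ++nn) {
            const int pk = ck + nn;
            if (pk < -(t - 1) || pk > t - 1) continue;
            const double v = pd[(size_t)(t - 1) * w * w + (pi + l) * w + (pk + l)];
            if (v > b) { b = v; ni2 = pi; nk2 = pk; }
          }
        }
        ci = ni2; ck = nk2;
        path[s + (R_xlen_t)n * ((t - 1) + (R_xlen_t)(l + 1) * 0)] = i0 + ci;
        path[s + (R_xlen_t)n * ((t - 1) + (R_xlen_t)(l + 1) * 1)] = j0 + dir * (t - 1);
        path[s + (R_xlen_t)n * ((t - 1) + (R_xlen_t)(l + 1) * 2)] = k0 + ck;
      }
    } else {
      for (int di = -l; di <= l; ++di) {
        if (i0 + di < 0 || i0 + di >= ni) continue;
        for (int dk = -l; dk <= l; ++dk) {
          if (k0 + dk < 0 || k0 + dk >= nk) continue;
          double sum = 0.0;
          for (int t = 0; t <= l; ++t)
            sum += d[vidx(i0 + roff[(di + l) * (l + 1) + t],
                          j0 + dir * t,
                          k0 + roff[(dk + l) * (l + 1) + t], ni, nj)];
          if (sum > best) { best = sum; bi = di; bk = dk; }
        }
      }
      for (int t = 0; t <= l; ++t) {
        path[s + (R_xlen_t)n * (t + (R_xlen_t)(l + 1) * 0)] =
          i0 + roff[(bi + l) * (l + 1) + t];
        path[s + (R_xlen_t)n * (t + (R_xlen_t)(l + 1) * 1)] = j0 + dir * t;
        path[s + (R_xlen_t)n * (t + (R_xlen_t)(l + 1) * 2)] =
          k0 + roff[(bk + l) * (l + 1) + t];
      }
    }
    fpd[s] = best;
    ends(s, 0) = i0 + bi; ends(s, 1) = j0 + dir * l; ends(s, 2) = k0 + bk;
  }
  return List::create(_["fpd"] = fpd, _["end"] = ends, _["path"] = path);
}

// One seed per cube of the spatial decomposition: the cube's highest-density
// voxel (ties: smallest linear index). Partial edge cubes included.
// [[Rcpp::export]]
IntegerMatrix cpp_csp(NumericVector d, IntegerVector dims, int cube) {
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  const int ci = (ni + cube - 1) / cube, cj = (nj + cube - 1) / cube,
            ck = (nk + cube - 1) / cube;
  IntegerMatrix out(ci * cj * ck, 3);
  int r = 0;
  for (int ak = 0; ak < ck; ++ak)
    for (int aj = 0; aj < cj; ++aj)
      for (int ai = 0; ai < ci; ++ai) {
        double best = -DBL_MAX; int wi = 0, wj = 0, wk = 0;
        for (int k = ak * cube; k < std::min((ak + 1) * cube, nk); ++k)
          for (int j = aj * cube; j < std::min((aj + 1) * cube, nj); ++j)
            for (int i = ai * cube; i < std::min((ai + 1) * cube, ni); ++i) {
              const double v = d[vidx(i, j, k, ni, nj)];
              if (v > best) { best = v; wi = i; wj = j; wk = k; }
            }
        out(r, 0) = wi; out(r, 1) = wj; out(r, 2) = wk; ++r;
      }
  return out;
}

// Chebyshev (per-axis) binary dilation by radius r: separable max filter.
// [[Rcpp::export]]
LogicalVector cpp_dilate_cheb(LogicalVector mask, IntegerVector dims, int r) {
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  std::vector<char> a(mask.size()), b(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t) a[t] = mask[t] ? 1 : 0;
  // i axis
  for (int k = 0; k < nk; ++k)
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        char v = 0;
        for (int o = std::max(0, i - r); o <= std::min(ni - 1, i + r); ++o)
          if (a[vidx(o, j, k, ni, nj)]) { v = 1; break; }
        b[vidx(i, j, k, ni, nj)] = v;
      }
  // j axis
  for (int k = 0; k < nk; ++k)
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        char v = 0;
        for (int o = std::max(0, j - r); o <= std::min(nj - 1, j + r); ++o)
          if (b[vidx(i, o, k, ni, nj)]) { v = 1; break; }
        a[vidx(i, j, k, ni, nj)] = v;
      }
  // k axis
  LogicalVector out(mask.size());
  for (int k = 0; k < nk; ++k)
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        char v = 0;
        for (int o = std::max(0, k - r); o <= std::min(nk - 1, k + r); ++o)
          if (a[vidx(i, j, o, ni, nj)]) { v = 1; break; }
        out[vidx(i, j, k, ni, nj)] = v;
      }
  out.attr("dim") = dims;
  return out;
}

// Redundancy screen over filament segments. Segments are processed in
// descending length order (ties: earlier first). A segment is discarded when
// more than overlap_frac of its voxels lie within Chebyshev distance
// `dilate` of a single already-kept (longer) segment. Returns a keep flag
// per segment.
// [[Rcpp::export]]
LogicalVector cpp_remove_redundant(List fss, IntegerVector dims,
                                   double overlap_frac, int dilate) {
  const int n = fss.size();
  const long long ni = dims[0], nj = dims[1], nk = dims[2];
  std::vector<int> len(n);
  for (int s = 0; s < n; ++s)
    len[s] = as<IntegerMatrix>(fss[s]).nrow();
  std::vector<int> ord(n);
  for (int s = 0; s < n; ++s) ord[s] = s;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return len[a] > len[b]; });
  // voxel -> list of kept segment ids whose dilation covers it
  std::unordered_map<long long, std::vector<int>> cover;
  cover.reserve(1 << 20);
  LogicalVector keep(n);
  std::vector<int> hits;
  for (int oi = 0; oi < n; ++oi) {
    const int s = ord[oi];
    IntegerMatrix m = fss[s];
    const int L = m.nrow();
    // count, per kept segment, how many of our voxels it covers
    std::unordered_map<int, int> cnt;
    for (int r = 0; r < L; ++r) {
      const long long id = (long long)(m(r, 0) - 1) +
        ni * ((long long)(m(r, 1) - 1) + nj * (long long)(m(r, 2) - 1));
      auto it = cover.find(id);
      if (it != cover.end())
        for (int k : it->second) ++cnt[k];
    }
    bool drop = false;
    for (auto &kv : cnt)
      if (kv.second > overlap_frac * L) { drop = true; break; }
    keep[s] = !drop;
    if (drop) continue;
    // register this segment's dilated coverage
    for (int r = 0; r < L; ++r) {
      const int i0 = m(r, 0) - 1, j0 = m(r, 1) - 1, k0 = m(r, 2) - 1;
      for (int di = -dilate; di <= dilate; ++di) {
        const int ii = i0 + di;
        if (ii < 0 || ii >= ni) continue;
        for (int dj = -dilate; dj <= dilate; ++dj) {
          const int jj = j0 + dj;
          if (jj < 0 || jj >= nj) continue;
          for (int dk = -dilate; dk <= dilate; ++dk) {
            const int kk = k0 + dk;
            if (kk < 0 || kk >= nk) continue;
            const long long id = (long long)ii + ni * ((long long)jj +
                                  nj * (long long)kk);
            auto &v = cover[id];
            if (v.empty() || v.back() != s) v.push_back(s);
          }
        }
      }
    }
  }
  return keep;
}

// Separable convolution with one odd-length kernel applied along all three
// axes (zero padding outside the grid).
// [[Rcpp::export]]
NumericVector cpp_sepconv(NumericVector x, IntegerVector dims, NumericVector kernel) {
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  const int r = ((int)kernel.size() - 1) / 2;
  NumericVector a = clone(x), b(x.size());
  for (int axis = 0; axis < 3; ++axis) {
    for (int k = 0; k < nk; ++k)
      for (int j = 0; j < nj; ++j)
        for (int i = 0; i < ni; ++i) {
          double s = 0.0;
          for (int o = -r; o <= r; ++o) {
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii += o; else if (axis == 1) jj += o; else kk += o;
            if (ii < 0 || ii >= ni || jj < 0 || jj >= nj || kk < 0 || kk >= nk)
              continue;
            s += kernel[o + r] * a[vidx(ii, jj, kk, ni, nj)];
          }
          b[vidx(i, j, k, ni, nj)] = s;
        }
    std::swap(a, b);
  }
  a.attr("dim") = dims;
  return a;
}
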
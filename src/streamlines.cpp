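#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Arc-length resampling shared by the intersection test and the density map:
// sample positions are equally spaced along the polyline with spacing <= step,
// and both endpoints are always included.  Degenerate (zero-length) polylines
// return their two endpoints unchanged.

static inline double seg_len(const NumericMatrix& p, int i) {
  double dx = p(i + 1, 0) - p(i, 0);
  double dy = p(i + 1, 1) - p(i, 1);
  double dz = p(i + 1, 2) - p(i, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static std::vector<double> cum_lengths(const NumericMatrix& p) {
  int n = p.nrow();
  std::vector<double> cl(n, 0.0);
  for (int i = 0; i < n - 1; ++i) cl[i + 1] = cl[i] + seg_len(p, i);
  return cl;
}

static void interp_at(const NumericMatrix& p, const std::vector<double>& cl,
                      double s, double* out) {
  int n = p.nrow();
  if (s <= 0) {
    for (int d = 0; d < 3; ++d) out[d] = p(0, d);
    return;
  }
  if (s >= cl[n - 1]) {
    for (int d = 0; d < 3; ++d) out[d] = p(n - 1, d);
    return;
  }
  int j = int(std::upper_bound(cl.begin(), cl.end(), s) - cl.begin()) - 1;
  if (j >= n - 1) j = n - 2;
  double den = cl[j + 1] - cl[j];
  double t = den > 0 ? (s - cl[j]) / den : 0.0;
  for (int d = 0; d < 3; ++d) out[d] = p(j, d) + t * (p(j + 1, d) - p(j, d));
}

// [[Rcpp::export]]
NumericMatrix resample_polyline_cpp(NumericMatrix pts, double step) {
  int n = pts.nrow();
  if (n < 2 || step <= 0) return pts;
  std::vector<double> cl = cum_lengths(pts);
  double L = cl[n - 1];
  int nseg = L > 0 ? int(std::ceil(L / step)) : 1;
  int nout = nseg + 1;
  NumericMatrix out(nout, 3);
  double buf[3];
  for (int k = 0; k < nout; ++k) {
    double s = L * double(k) / double(nseg);
    interp_at(pts, cl, s, buf);
    for (int d = 0; d < 3; ++d) out(k, d) = buf[d];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix resample_fixed_cpp(NumericMatrix pts, int n_out) {
  int n = pts.nrow();
  if (n < 2 || n_out < 2) return pts;
  std::vector<double> cl = cum_lengths(pts);
  double L = cl[n - 1];
  NumericMatrix out(n_out, 3);
  double buf[3];
  for (int k = 0; k < n_out; ++k) {
    double s = L * double(k) / double(n_out - 1);
    interp_at(pts, cl, s, buf);
    for (int d = 0; d < 3; ++d) out(k, d) = buf[d];
  }
  return out;
}

// voxel index of a world point under inv_affine, voxel-center convention:
// index i covers voxel coordinate [i - 0.5, i + 0.5).
static inline void world_to_idx(const double* w, const NumericMatrix& inv_affine,
                                int* idx) {
  for (int d = 0; d < 3; ++d) {
    double v = inv_affine(d, 0) * w[0] + inv_affine(d, 1) * w[1] +
               inv_affine(d, 2) * w[2] + inv_affine(d, 3);
    idx[d] = int(std::floor(v + 0.5));
  }
}

// [[Rcpp::export]]
IntegerVector density_counts_cpp(List streamlines, NumericMatrix inv_affine,
                                 IntegerVector shape, double step) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  IntegerVector counts(nx * ny * nz);
  std::vector<int> seen;
  double buf[3];
  int idx[3];
  for (int si = 0; si < streamlines.size(); ++si) {
    NumericMatrix p = streamlines[si];
    if (p.nrow() < 2) continue;
    std::vector<double> cl = cum_lengths(p);
    double L = cl[p.nrow() - 1];
    int nseg = L > 0 ? int(std::ceil(L / step)) : 1;
    seen.clear();
    for (int k = 0; k <= nseg; ++k) {
      double s = L * double(k) / double(nseg);
      interp_at(p, cl, s, buf);
      world_to_idx(buf, inv_affine, idx);
      if (idx[0] < 0 || idx[0] >= nx || idx[1] < 0 || idx[1] >= ny ||
          idx[2] < 0 || idx[2] >= nz)
        continue;
      seen.push_back(idx[0] + nx * (idx[1] + ny * idx[2]));
    }
    std::sort(seen.begin(), seen.end());
    seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
    for (size_t k = 0; k < seen.size(); ++k) counts[seen[k]] += 1;
  }
  counts.attr("dim") = shape;
  return counts;
}

// [[Rcpp::export]]
LogicalVector hits_mask_cpp(List streamlines, LogicalVector mask,
                            IntegerVector shape, NumericMatrix inv_affine,
                            double step) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int n = streamlines.size();
  LogicalVector out(n);
  double buf[3];
  int idx[3];
  for (int si = 0; si < n; ++si) {
    NumericMatrix p = streamlines[si];
    bool hit = false;
    if (p.nrow() >= 2) {
      std::vector<double> cl = cum_lengths(p);
      double L = cl[p.nrow() - 1];
      int nseg = L > 0 ? int(std::ceil(L / step)) : 1;
      for (int k = 0; k <= nseg && !hit; ++k) {
        double s = L * double(k) / double(nseg);
        interp_at(p, cl, s, buf);
        world_to_idx(buf, inv_affine, idx);
        if (idx[0] < 0 || idx[0] >= nx || idx[1] < 0 || idx[1] >= ny ||
            idx[2] < 0 || idx[2] >= nz)
          continue;
        if (mask[idx[0] + nx * (idx[1] + ny * idx[2])]) hit = true;
      }
    }
    out[si] = hit;
  }
  return out;
}

// Symmetric mean-closest-point distance between two equal-length point sets.
static double mcp_dist(const NumericMatrix& a, const NumericMatrix& b) {
  int na = a.nrow(), nb = b.nrow();
  double sa = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    sa += std::sqrt(best);
  }
  double sb = 0.0;
  for (int j = 0; j < nb; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < na; ++i) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    sb += std::sqrt(best);
  }
  return 0.5 * (sa / na + sb / nb);
}

// [[Rcpp::export]]
NumericMatrix mcp_matrix_cpp(List streamlines) {
  int n = streamlines.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix a = streamlines[i];
    for (int j = i + 1; j < n; ++j) {
      NumericMatrix b = streamlines[j];
      double d = mcp_dist(a, b);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
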
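#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quartic (biweight) kernel density surface on a regular grid.
// Cell (i, j) has center (x0 + (j + 0.5) c, y0 + (i + 0.5) c); i indexes rows
// (northing), j columns (easting). Each fix only touches cells within h of it,
// so work per fix is ~(2h/c + 1)^2.
// [[Rcpp::export]]
NumericMatrix cpp_kde_surface(NumericVector px, NumericVector py,
                              double x0, double y0, double cell,
                              int nrows, int ncols, double h) {
  NumericMatrix out(nrows, ncols);
  const double h2 = h * h;
  const double norm = 3.0 / (M_PI * h2);
  const int n = px.size();
  for (int k = 0; k < n; ++k) {
    const double fx = px[k], fy = py[k];
    int j0 = (int)std::floor((fx - h - x0) / cell - 0.5);
    int j1 = (int)std::ceil((fx + h - x0) / cell - 0.5);
    int i0 = (int)std::floor((fy - h - y0) / cell - 0.5);
    int i1 = (int)std::ceil((fy + h - y0) / cell - 0.5);
    if (j0 < 0) j0 = 0;
    if (i0 < 0) i0 = 0;
    if (j1 > ncols - 1) j1 = ncols - 1;
    if (i1 > nrows - 1) i1 = nrows - 1;
    for (int i = i0; i <= i1; ++i) {
      const double dy = y0 + (i + 0.5) * cell - fy;
      const double dy2 = dy * dy;
      if (dy2 > h2) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dx = x0 + (j + 0.5) * cell - fx;
        const double d2 = dx * dx + dy2;
        if (d2 <= h2) {
          const double u = 1.0 - d2 / h2;
          out(i, j) += norm * u * u;
        }
      }
    }
  }
  return out;
}

// Local maxima of a density grid. A cell qualifies when its value is positive
// and >= all 8 neighbours; connected plateaus of equal value collapse to a
// single peak located at the plateau's cell centroid. Returns one row per
// peak: (i, j) fractional 0-based cell coordinates of the centroid plus the
// peak density, ordered by decreasing density then row-major position.
// [[Rcpp::export]]
DataFrame cpp_find_peaks(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<char> marked((size_t)nr * nc, 0);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const double v = m(i, j);
      if (v <= 0) continue;
      bool ok = true;
      for (int di = -1; di <= 1 && ok; ++di) {
        for (int dj = -1; dj <= 1 && ok; ++dj) {
          if (di == 0 && dj == 0) continue;
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (m(ii, jj) > v) ok = false;
        }
      }
      if (ok) marked[(size_t)i * nc + j] = 1;
    }
  }
  // flood-fill equal-valued marked components (8-connectivity)
  std::vector<double> pi, pj, pd;
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const size_t idx = (size_t)i * nc + j;
      if (!marked[idx] || seen[idx]) continue;
      const double v = m(i, j);
      double si = 0, sj = 0;
      int cnt = 0;
      stack.clear();
      stack.push_back(i * nc + j);
      seen[idx] = 1;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int ci = cur / nc, cj = cur % nc;
        si += ci; sj += cj; ++cnt;
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            const int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            const size_t nx = (size_t)ii * nc + jj;
            if (marked[nx] && !seen[nx] && m(ii, jj) == v) {
              seen[nx] = 1;
              stack.push_back(ii * nc + jj);
            }
          }
        }
      }
      pi.push_back(si / cnt);
      pj.push_back(sj / cnt);
      pd.push_back(v);
    }
  }
  // order: density descending, then row-major cell index
  const int np = pd.size();
  std::vector<int> ord(np);
  for (int k = 0; k < np; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (pd[a] != pd[b]) return pd[a] > pd[b];
    const double ra = pi[a] * nc + pj[a], rb = pi[b] * nc + pj[b];
    return ra < rb;
  });
  NumericVector oi(np), oj(np), od(np);
  for (int k = 0; k < np; ++k) {
    oi[k] = pi[ord[k]];
    oj[k] = pj[ord[k]];
    od[k] = pd[ord[k]];
  }
  return DataFrame::create(_["i"] = oi, _["j"] = oj, _["density"] = od);
}

// Greedy non-maximum suppression over peaks already sorted by decreasing
// density: a peak within `radius` of an earlier retained peak is dropped.
// Returns a logical keep mask.
// [[Rcpp::export]]
LogicalVector cpp_nms(NumericVector x, NumericVector y, double radius) {
  const int n = x.size();
  LogicalVector keep(n, true);
  const double r2 = radius * radius;
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      if (!keep[j]) continue;
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) {
        keep[i] = false;
        break;
      }
    }
  }
  return keep;
}

// Nearest-peak allocation: each fix gets the id (1-based position) of the
// closest peak if that distance is <= h, else NA (trip). Ties within 1e-9 m
// resolve to the lowest peak id (peaks are pre-ordered by id).
// [[Rcpp::export]]
IntegerVector cpp_assign_nearest(NumericVector fx, NumericVector fy,
                                 NumericVector px, NumericVector py,
                                 double h) {
  const int n = fx.size(), np = px.size();
  const double h2 = h * h;
  IntegerVector out(n, NA_INTEGER);
  for (int k = 0; k < n; ++k) {
    double best = R_PosInf;
    int bi = -1;
    for (int p = 0; p < np; ++p) {
      const double dx = fx[k] - px[p], dy = fy[k] - py[p];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d < best - 1e-9) {
        best = d;
        bi = p;
      }
    }
    if (bi >= 0 && best * best <= h2) out[k] = bi + 1;
  }
  return out;
}

// Sequential fixed-threshold (roaming radius) clustering. Scans fixes in time
// order keeping a running cluster; a fix within `radius` of the cluster
// centroid (or of the cluster's first fix when centroid_test is false) joins
// it, otherwise the cluster is emitted as a stop if its time span reaches
// min_duration and a new cluster starts at the breaking fix.
// [[Rcpp::export]]
DataFrame cpp_ft_cluster(NumericVector t, NumericVector x, NumericVector y,
                         double radius, double min_duration,
                         bool centroid_test) {
  const int n = t.size();
  std::vector<double> cx, cy, t0v, t1v;
  std::vector<int> nf;
  if (n == 0)
    return DataFrame::create(_["x"] = NumericVector(0),
                             _["y"] = NumericVector(0),
                             _["t_start"] = NumericVector(0),
                             _["t_end"] = NumericVector(0),
                             _["n_fixes"] = IntegerVector(0));
  int s = 0;
  double sx = x[0], sy = y[0];
  int cnt = 1;
  const double r2 = radius * radius;
  for (int i = 1; i <= n; ++i) {
    bool brk = true;
    if (i < n) {
      const double rx = centroid_test ? sx / cnt : x[s];
      const double ry = centroid_test ? sy / cnt : y[s];
      const double dx = x[i] - rx, dy = y[i] - ry;
      brk = (dx * dx + dy * dy) > r2;
    }
    if (!brk) {
      sx += x[i];
      sy += y[i];
      ++cnt;
    } else {
      if (t[i - 1] - t[s] >= min_duration) {
        cx.push_back(sx / cnt);
        cy.push_back(sy / cnt);
        t0v.push_back(t[s]);
        t1v.push_back(t[i - 1]);
        nf.push_back(cnt);
      }
      if (i < n) {
        s = i;
        sx = x[i];
        sy = y[i];
        cnt = 1;
      }
    }
  }
  return DataFrame::create(_["x"] = wrap(cx), _["y"] = wrap(cy),
                           _["t_start"] = wrap(t0v), _["t_end"] = wrap(t1v),
                           _["n_fixes"] = wrap(nf));
}
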
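#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bucketed k-nearest IDW gridding. Cell value = sum(w_j z_j)/sum(w_j),
// w_j = d_j^-power over the <=k nearest points within max_radius; a cell
// coincident with a point (d < 1e-9) takes that point's z; no neighbour -> NA.
// [[Rcpp::export]]
NumericMatrix cpp_idw_grid(NumericVector px, NumericVector py, NumericVector pz,
                           double ox, double oy, double cell,
                           int nrow, int ncol,
                           double power, int k, double max_radius) {
  const int n = px.size();
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), NA_REAL);
  if (n == 0) return out;

  // spatial hash buckets sized to max_radius capped for efficiency
  double bsz = std::max(cell, std::min(max_radius, 4.0 * cell));
  double bx0 = *std::min_element(px.begin(), px.end());
  double by0 = *std::min_element(py.begin(), py.end());
  double bx1 = *std::max_element(px.begin(), px.end());
  double by1 = *std::max_element(py.begin(), py.end());
  int nbx = std::max(1, (int)std::floor((bx1 - bx0) / bsz) + 1);
  int nby = std::max(1, (int)std::floor((by1 - by0) / bsz) + 1);
  std::vector<std::vector<int> > bucket((size_t)nbx * nby);
  for (int i = 0; i < n; i++) {
    int bi = std::min(nbx - 1, std::max(0, (int)std::floor((px[i] - bx0) / bsz)));
    int bj = std::min(nby - 1, std::max(0, (int)std::floor((py[i] - by0) / bsz)));
    bucket[(size_t)bj * nbx + bi].push_back(i);
  }

  const double r2max = max_radius * max_radius;
  std::vector<std::pair<double,int> > cand;
  int max_ring = (int)std::ceil(max_radius / bsz) + 1;

  for (int r = 0; r < nrow; r++) {
    double cy = oy + r * cell;
    for (int c = 0; c < ncol; c++) {
      double cx = ox + c * cell;
      int ci = (int)std::floor((cx - bx0) / bsz);
      int cj = (int)std::floor((cy - by0) / bsz);
      cand.clear();
      // expanding ring search: stop when k found and next ring cannot be nearer
      for (int ring = 0; ring <= max_ring; ring++) {
        if ((int)cand.size() >= k) {
          // ring (ring-1) fully scanned; min distance to ring `ring` buckets
          double dmin = (ring - 1) * bsz;
          std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
          if (cand[k - 1].first <= dmin * dmin) break;
        }
        bool any = false;
        for (int bj = cj - ring; bj <= cj + ring; bj++) {
          if (bj < 0 || bj >= nby) continue;
          for (int bi = ci - ring; bi <= ci + ring; bi++) {
            if (bi < 0 || bi >= nbx) continue;
            if (std::max(std::abs(bi - ci), std::abs(bj - cj)) != ring) continue;
            any = true;
            const std::vector<int>& b = bucket[(size_t)bj * nbx + bi];
            for (size_t q = 0; q < b.size(); q++) {
              int i = b[q];
              double dx = px[i] - cx, dy = py[i] - cy;
              double d2 = dx * dx + dy * dy;
              if (d2 <= r2max) cand.push_back(std::make_pair(d2, i));
            }
          }
        }
        if (!any && ring > max_ring) break;
      }
      if (cand.empty()) continue;
      int kk = std::min((int)cand.size(), k);
      std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
      if (cand[0].first < 1e-18) { out(r, c) = pz[cand[0].second]; continue; }
      double sw = 0.0, swz = 0.0;
      for (int q = 0; q < kk; q++) {
        double w = std::pow(std::sqrt(cand[q].first), -power);
        sw += w; swz += w * pz[cand[q].second];
      }
      out(r, c) = swz / sw;
    }
  }
  return out;
}

// Point-in-ring with deterministic boundary detection.
// Returns 0 outside, 1 inside, 2 on boundary (within eps of an edge).
// [[Rcpp::export]]
IntegerVector cpp_point_in_ring(NumericVector x, NumericVector y,
                                NumericVector rx, NumericVector ry,
                                double eps) {
  const int n = x.size(), m = rx.size();
  IntegerVector out(n);
  for (int p = 0; p < n; p++) {
    double xp = x[p], yp = y[p];
    bool inside = false, boundary = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double xi = rx[i], yi = ry[i], xj = rx[j], yj = ry[j];
      // distance point-segment
      double vx = xj - xi, vy = yj - yi;
      double L2 = vx * vx + vy * vy;
      double t = L2 > 0 ? ((xp - xi) * vx + (yp - yi) * vy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      double dx = xp - (xi + t * vx), dy = yp - (yi + t * vy);
      if (dx * dx + dy * dy <= eps * eps) { boundary = true; break; }
      if (((yi > yp) != (yj > yp)) &&
          (xp < (xj - xi) * (yp - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[p] = boundary ? 2 : (inside ? 1 : 0);
  }
  return out;
}

// Do any two non-adjacent edges of a closed ring properly intersect?
// [[Rcpp::export]]
bool cpp_ring_self_intersects(NumericVector rx, NumericVector ry) {
  int m = rx.size();
  // rx/ry: open ring (no repeated last vertex)
  auto cross = [](double ax, double ay, double bx, double by) {
    return ax * by - ay * bx;
  };
  for (int i = 0; i < m; i++) {
    int i2 = (i + 1) % m;
    for (int j = i + 1; j < m; j++) {
      int j2 = (j + 1) % m;
      if (j == i || j2 == i || j == i2) continue;  // shared endpoint
      double p0x = rx[i], p0y = ry[i], p1x = rx[i2], p1y = ry[i2];
      double q0x = rx[j], q0y = ry[j], q1x = rx[j2], q1y = ry[j2];
      double d1 = cross(p1x - p0x, p1y - p0y, q0x - p0x, q0y - p0y);
      double d2 = cross(p1x - p0x, p1y - p0y, q1x - p0x, q1y - p0y);
      double d3 = cross(q1x - q0x, q1y - q0y, p0x - q0x, p0y - q0y);
      double d4 = cross(q1x - q0x, q1y - q0y, p1x - q0x, p1y - q0y);
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return true;
    }
  }
  return false;
}

// Marker-based watershed on the inverted surface: cells are processed in
// order of decreasing height starting from the seeds; each masked cell takes
// the label of the highest already-labelled 4-neighbour that reaches it.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix z, LogicalMatrix mask,
                                   IntegerVector seed_row, IntegerVector seed_col,
                                   IntegerVector seed_label) {
  const int nr = z.nrow(), nc = z.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), NA_INTEGER);
  typedef std::pair<double, std::pair<int,int> > Item;  // (height, (cell, order))
  std::priority_queue<Item> pq;
  int order = 0;
  for (int s = 0; s < seed_row.size(); s++) {
    int r = seed_row[s], c = seed_col[s];
    if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
    if (!mask(r, c)) continue;
    lab(r, c) = seed_label[s];
    pq.push(Item(z(r, c), std::make_pair(r * nc + c, order++)));
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    int cellid = pq.top().second.first;
    pq.pop();
    int r = cellid / nc, c = cellid % nc;
    int L = lab(r, c);
    for (int d = 0; d < 4; d++) {
      int r2 = r + dr[d], c2 = c + dc[d];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2)) continue;
      if (lab(r2, c2) != NA_INTEGER) continue;
      if (NumericMatrix::is_na(z(r2, c2))) continue;
      lab(r2, c2) = L;
      pq.push(Item(z(r2, c2), std::make_pair(r2 * nc + c2, order++)));
    }
  }
  return lab;
}
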
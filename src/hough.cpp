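#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Iterative circle Hough transform on an edge map.
//
// Votes are cast for candidate centres at every integer radius in
// [rmin, rmax]. Circles are extracted greedily: take the strongest
// accumulator cell, verify its perimeter support against the remaining
// (unclaimed) edge pixels, then claim the edge pixels on that circle and
// subtract their votes before searching for the next peak. Claiming makes
// the extraction robust against spurious peaks assembled from arcs that
// belong to already-found circles.

namespace {

struct Acc {
  int H, W, nr, rmin;
  std::vector<int> a; // nr planes of H*W votes
  std::vector<std::vector<double>> rc, rs; // per-radius perimeter offsets
  Acc(int H_, int W_, int rmin_, int rmax_)
      : H(H_), W(W_), nr(rmax_ - rmin_ + 1), rmin(rmin_),
        a((size_t)nr * H_ * W_, 0), rc(nr), rs(nr) {
    for (int ri = 0; ri < nr; ++ri) {
      int r = rmin + ri;
      int na = std::max(int(std::lround(2.0 * M_PI * r)), 8);
      rc[ri].resize(na);
      rs[ri].resize(na);
      for (int t = 0; t < na; ++t) {
        double th = 2.0 * M_PI * t / na;
        rc[ri][t] = r * std::cos(th);
        rs[ri][t] = r * std::sin(th);
      }
    }
  }
  inline int get(int ri, int y, int x) const {
    if (y < 0 || y >= H || x < 0 || x >= W) return 0;
    return a[(size_t)ri * H * W + (size_t)y * W + x];
  }
  int box3(int ri, int y, int x) const {
    int s = 0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) s += get(ri, y + dy, x + dx);
    return s;
  }
  void cast(const std::vector<int> &ey, const std::vector<int> &ex, int sign) {
    for (int ri = 0; ri < nr; ++ri) {
      int *plane = &a[(size_t)ri * H * W];
      const size_t na = rc[ri].size();
      for (size_t p = 0; p < ey.size(); ++p) {
        const double px = ex[p], py = ey[p];
        for (size_t t = 0; t < na; ++t) {
          int cx = int(std::lround(px - rc[ri][t]));
          int cy = int(std::lround(py - rs[ri][t]));
          if (cx < 0 || cx >= W || cy < 0 || cy >= H) continue;
          plane[(size_t)cy * W + cx] += sign;
        }
      }
    }
  }
};

} // namespace

// edge: 0/1 integer matrix (rows = y). Returns matrix with columns
// x, y, r, score (0-based pixel coordinates).
// [[Rcpp::export]]
NumericMatrix hough_circles_cpp(IntegerMatrix edge, int rmin, int rmax,
                                double thresh, double support_min,
                                int max_circles) {
  const int H = edge.nrow(), W = edge.ncol();
  if (rmin > rmax) stop("rmin must not exceed rmax");

  std::vector<int> ey, ex;
  std::vector<char> alive;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      if (edge(y, x) != 0) {
        ey.push_back(y);
        ex.push_back(x);
        alive.push_back(1);
      }

  std::vector<double> out_x, out_y, out_r, out_s;
  if (!ey.empty()) {
    Acc acc(H, W, rmin, rmax);
    acc.cast(ey, ex, +1);

    // lazily maintained per-plane maxima: a plane is rescanned only when
    // vote subtraction touched its recorded argmax
    std::vector<int> pmax(acc.nr, -1), pidx(acc.nr, 0);
    auto rescan = [&](int ri) {
      const int *plane = &acc.a[(size_t)ri * H * W];
      int mv = -1, mi = 0;
      for (int i = 0; i < H * W; ++i)
        if (plane[i] > mv) {
          mv = plane[i];
          mi = i;
        }
      pmax[ri] = mv;
      pidx[ri] = mi;
    };
    for (int ri = 0; ri < acc.nr; ++ri) rescan(ri);

    for (int iter = 0; iter < max_circles; ++iter) {
      int bri = -1, by = -1, bx = -1;
      double bnorm = -1.0;
      for (int ri = 0; ri < acc.nr; ++ri) {
        if (acc.a[(size_t)ri * H * W + pidx[ri]] != pmax[ri]) rescan(ri);
        double v = pmax[ri] / (2.0 * M_PI * (acc.rmin + ri));
        if (v > bnorm) {
          bnorm = v;
          bri = ri;
          by = pidx[ri] / W;
          bx = pidx[ri] % W;
        }
      }
      if (bri < 0) break;
      double score = acc.box3(bri, by, bx) / (2.0 * M_PI * (acc.rmin + bri));
      if (score < thresh) break;

      // refine centre: vote-weighted centroid over the 3x3 neighbourhood
      double sw = 0.0, sx = 0.0, sy = 0.0;
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          double wv = acc.get(bri, by + dy, bx + dx);
          sw += wv;
          sx += wv * (bx + dx);
          sy += wv * (by + dy);
        }
      double cx = sw > 0 ? sx / sw : bx;
      double cy = sw > 0 ? sy / sw : by;

      // refine radius: weighted over neighbouring radius planes
      double rw = 0.0, rsum = 0.0;
      for (int ri = std::max(0, bri - 2); ri <= std::min(acc.nr - 1, bri + 2);
           ++ri) {
        double wv = acc.box3(ri, by, bx);
        rw += wv;
        rsum += wv * (acc.rmin + ri);
      }
      double r = rw > 0 ? rsum / rw : acc.rmin + bri;

      // perimeter support against unclaimed edges: fraction of perimeter
      // samples with an edge pixel within 1.5 px
      int na = std::max(int(std::lround(2.0 * M_PI * r)), 8);
      int gw = (W + 3) / 4, gh = (H + 3) / 4;
      std::vector<std::vector<int>> grid((size_t)gw * gh);
      for (size_t p = 0; p < ey.size(); ++p)
        if (alive[p]) grid[(size_t)(ey[p] / 4) * gw + ex[p] / 4].push_back(p);
      int hit = 0;
      for (int t = 0; t < na; ++t) {
        double th = 2.0 * M_PI * t / na;
        double px = cx + r * std::cos(th), py = cy + r * std::sin(th);
        if (px < -2 || px > W + 1 || py < -2 || py > H + 1) continue;
        bool found = false;
        int gx0 = std::max(0, int(px) / 4 - 1),
            gx1 = std::min(gw - 1, int(std::max(px, 0.0)) / 4 + 1);
        int gy0 = std::max(0, int(py) / 4 - 1),
            gy1 = std::min(gh - 1, int(std::max(py, 0.0)) / 4 + 1);
        for (int gy = gy0; gy <= gy1 && !found; ++gy)
          for (int gx = gx0; gx <= gx1 && !found; ++gx)
            for (int p : grid[(size_t)gy * gw + gx]) {
              double dx = ex[p] - px, dy2 = ey[p] - py;
              if (dx * dx + dy2 * dy2 <= 1.5 * 1.5) {
                found = true;
                break;
              }
            }
        if (found) ++hit;
      }
      double support = double(hit) / na;

      // claim edge pixels lying on the circle band |dist - r| <= 2
      std::vector<int> cy_cl, cx_cl;
      for (size_t p = 0; p < ey.size(); ++p) {
        if (!alive[p]) continue;
        double d = std::hypot(ex[p] - cx, ey[p] - cy);
        if (std::fabs(d - r) <= 2.0) {
          alive[p] = 0;
          cy_cl.push_back(ey[p]);
          cx_cl.push_back(ex[p]);
        }
      }
      if (cy_cl.empty()) break; // nothing left to explain this peak
      acc.cast(cy_cl, cx_cl, -1);

      if (support >= support_min) {
        out_x.push_back(cx);
        out_y.push_back(cy);
        out_r.push_back(std::min(std::max(r, double(rmin)), double(rmax)));
        out_s.push_back(score);
      }
    }
  }

  NumericMatrix res(out_x.size(), 4);
  for (size_t i = 0; i < out_x.size(); ++i) {
    res(i, 0) = out_x[i];
    res(i, 1) = out_y[i];
    res(i, 2) = out_r[i];
    res(i, 3) = out_s[i];
  }
  colnames(res) = CharacterVector::create("x", "y", "r", "score");
  return res;
}
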
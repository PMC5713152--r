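#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tamura texture statistics on a grayscale patch (values 0..255).
// Windows are clamped at the patch border so every dyadic scale up to
// 2^kmax is defined at every pixel.

namespace {

struct Integral {
  int H, W;
  std::vector<double> s; // (H+1) x (W+1), row-major
  Integral(const NumericMatrix &g, int r0, int r1, int c0, int c1)
      : H(r1 - r0 + 1), W(c1 - c0 + 1), s((H + 1) * (W + 1), 0.0) {
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j)
        s[(i + 1) * (W + 1) + (j + 1)] = g(r0 + i, c0 + j) +
          s[i * (W + 1) + (j + 1)] + s[(i + 1) * (W + 1) + j] -
          s[i * (W + 1) + j];
  }
  // mean over rows [a,b] x cols [c,d], clamped, inclusive, 0-based local
  double mean(int a, int b, int c, int d) const {
    if (a < 0) a = 0;
    if (c < 0) c = 0;
    if (b > H - 1) b = H - 1;
    if (d > W - 1) d = W - 1;
    if (a > b || c > d) return 0.0;
    double v = s[(b + 1) * (W + 1) + (d + 1)] - s[a * (W + 1) + (d + 1)] -
               s[(b + 1) * (W + 1) + c] + s[a * (W + 1) + c];
    return v / double((b - a + 1) * (d - c + 1));
  }
};

const int NBINS = 16;
const double EDGE_T = 12.0; // gradient-magnitude threshold (0..255 scale)

// coarseness, contrast, directionality, line-likeness on a sub-rectangle
void core4(const NumericMatrix &g, int r0, int r1, int c0, int c1,
           double out[4]) {
  const int H = r1 - r0 + 1, W = c1 - c0 + 1;
  const int n = H * W;
  Integral I(g, r0, r1, c0, c1);

  int kmax = 1;
  while ((1 << (kmax + 1)) <= std::min(H, W) && kmax + 1 <= 5) ++kmax;

  // --- coarseness: best dyadic window scale per pixel; a scale only
  // competes where its two comparison windows fit inside the patch
  // (border-clamped windows would fake large-scale energy everywhere in
  // a 40x40 patch)
  double crs = 0.0;
  int n_crs = 0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double best_e = -1.0;
      int best_k = 0;
      for (int k = 1; k <= kmax; ++k) {
        int h = 1 << (k - 1); // half window
        if (x - 2 * h < 0 || x + 2 * h - 1 > W - 1 || y - 2 * h < 0 ||
            y + 2 * h - 1 > H - 1)
          break;
        // adjacent non-overlapping 2^k windows left/right and above/below
        double ah1 = I.mean(y - h, y + h - 1, x - 2 * h, x - 1);
        double ah2 = I.mean(y - h, y + h - 1, x, x + 2 * h - 1);
        double av1 = I.mean(y - 2 * h, y - 1, x - h, x + h - 1);
        double av2 = I.mean(y, y + 2 * h - 1, x - h, x + h - 1);
        double e = std::max(std::fabs(ah1 - ah2), std::fabs(av1 - av2));
        if (e > best_e + 1e-12) {
          best_e = e;
          best_k = k;
        }
      }
      if (best_k > 0) {
        crs += double(1 << best_k);
        ++n_crs;
      }
    }
  }
  crs = n_crs > 0 ? crs / n_crs : 0.0;

  // --- contrast: sigma / kurtosis^(1/4)
  double mu = 0.0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) mu += g(r0 + y, c0 + x);
  mu /= double(n);
  double m2 = 0.0, m4 = 0.0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double d = g(r0 + y, c0 + x) - mu;
      m2 += d * d;
      m4 += d * d * d * d;
    }
  m2 /= double(n);
  m4 /= double(n);
  double con = 0.0;
  if (m2 > 1e-12) {
    double kurt = m4 / (m2 * m2);
    con = std::sqrt(m2) / std::pow(kurt, 0.25);
  }

  // --- gradient field (3x3 Prewitt), interior pixels only
  std::vector<double> mag(n, 0.0), theta(n, 0.0);
  for (int y = 1; y < H - 1; ++y) {
    for (int x = 1; x < W - 1; ++x) {
      double dh = 0.0, dv = 0.0;
      for (int dy = -1; dy <= 1; ++dy) {
        dh += g(r0 + y + dy, c0 + x + 1) - g(r0 + y + dy, c0 + x - 1);
        dv += g(r0 + y + 1, c0 + x + dy) - g(r0 + y - 1, c0 + x + dy);
      }
      double m = 0.5 * (std::fabs(dh) + std::fabs(dv));
      double th = std::atan2(dv, dh) + M_PI / 2.0; // edge direction in [.. )
      while (th < 0) th += M_PI;
      while (th >= M_PI) th -= M_PI;
      mag[y * W + x] = m;
      theta[y * W + x] = th;
    }
  }

  // --- directionality: sharpness of the 16-bin angle histogram
  double hist[NBINS] = {0};
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    if (mag[i] >= EDGE_T) {
      int b = int(theta[i] / M_PI * NBINS);
      if (b >= NBINS) b = NBINS - 1;
      hist[b] += 1.0;
      tot += 1.0;
    }
  }
  double dir = 0.0;
  if (tot > 0) {
    int pk = 0;
    for (int b = 1; b < NBINS; ++b)
      if (hist[b] > hist[pk]) pk = b;
    double phi_p = (pk + 0.5) * M_PI / NBINS;
    double spread = 0.0;
    for (int b = 0; b < NBINS; ++b) {
      double phi = (b + 0.5) * M_PI / NBINS;
      double d = std::fabs(phi - phi_p);
      if (d > M_PI / 2.0) d = M_PI - d; // wrap on the half-circle
      spread += d * d * (hist[b] / tot);
    }
    dir = 1.0 - (4.0 / (M_PI * M_PI)) * spread; // in [0, 1]
  }

  // --- line-likeness: direction co-occurrence at distance 4 along the edge
  double num = 0.0, den = 0.0;
  const int DD = 4;
  for (int y = 1; y < H - 1; ++y) {
    for (int x = 1; x < W - 1; ++x) {
      int i = y * W + x;
      if (mag[i] < EDGE_T) continue;
      int xx = x + int(std::lround(DD * std::cos(theta[i])));
      int yy = y + int(std::lround(DD * std::sin(theta[i])));
      if (xx < 1 || xx > W - 2 || yy < 1 || yy > H - 2) continue;
      int j = yy * W + xx;
      if (mag[j] < EDGE_T) continue;
      num += std::cos(theta[i] - theta[j]);
      den += 1.0;
    }
  }
  double lin = den > 0 ? num / den : 0.0;

  out[0] = crs;
  out[1] = con;
  out[2] = dir;
  out[3] = lin;
}

} // namespace

namespace {

// all six features for a sub-rectangle (inclusive 0-based bounds)
void tamura6(const NumericMatrix &g, int r0, int r1, int c0, int c1,
             double out6[6]) {
  const int H = r1 - r0 + 1, W = c1 - c0 + 1;
  double f[4];
  core4(g, r0, r1, c0, c1, f);

  // regularity: 1 - r * summed variation of the four features over quadrants
  double reg = 1.0;
  if (H >= 16 && W >= 16) {
    double q[4][4];
    int hr = H / 2, hc = W / 2;
    core4(g, r0, r0 + hr - 1, c0, c0 + hc - 1, q[0]);
    core4(g, r0, r0 + hr - 1, c0 + hc, c1, q[1]);
    core4(g, r0 + hr, r1, c0, c0 + hc - 1, q[2]);
    core4(g, r0 + hr, r1, c0 + hc, c1, q[3]);
    double sd_sum = 0.0;
    for (int fidx = 0; fidx < 4; ++fidx) {
      double m = 0.0;
      for (int s = 0; s < 4; ++s) m += q[s][fidx];
      m /= 4.0;
      double v = 0.0;
      for (int s = 0; s < 4; ++s) v += (q[s][fidx] - m) * (q[s][fidx] - m);
      v /= 3.0;
      // scale-normalized spread so heterogeneous units are comparable
      sd_sum += std::sqrt(v) / (std::fabs(m) + 1.0);
    }
    reg = 1.0 - 0.25 * sd_sum;
  }

  out6[0] = f[0];        // coarseness
  out6[1] = f[1];        // contrast
  out6[2] = f[2];        // directionality
  out6[3] = f[3];        // line-likeness
  out6[4] = reg;         // regularity
  out6[5] = f[0] + f[1]; // roughness
}

} // namespace

// [[Rcpp::export]]
NumericVector tamura_cpp(NumericMatrix g) {
  const int H = g.nrow(), W = g.ncol();
  if (H < 8 || W < 8) stop("patch must be at least 8x8 for Tamura features");
  double f6[6];
  tamura6(g, 0, H - 1, 0, W - 1, f6);
  NumericVector out(6);
  for (int i = 0; i < 6; ++i) out[i] = f6[i];
  out.attr("names") = CharacterVector::create(
      "coarseness", "contrast", "directionality", "line_likeness",
      "regularity", "roughness");
  return out;
}

// batch evaluation over sliding windows (x0, y0 are 0-based top-left
// corners); rows of the result follow the input order
// [[Rcpp::export]]
NumericMatrix tamura_windows_cpp(NumericMatrix g, IntegerVector x0,
                                 IntegerVector y0, int size) {
  const int n = x0.size();
  if (size < 8) stop("window must be at least 8x8 for Tamura features");
  NumericMatrix out(n, 6);
  double f6[6];
  for (int i = 0; i < n; ++i) {
    if (y0[i] < 0 || x0[i] < 0 || y0[i] + size > g.nrow() ||
        x0[i] + size > g.ncol())
      stop("window out of bounds");
    tamura6(g, y0[i], y0[i] + size - 1, x0[i], x0[i] + size - 1, f6);
    for (int j = 0; j < 6; ++j) out(i, j) = f6[j];
  }
  return out;
}
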
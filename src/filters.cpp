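#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Symmetric (edge-inclusive) reflection of an out-of-range 0-based index.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_mean_filter(NumericMatrix img, int w) {
  int nr = img.nrow(), nc = img.ncol(), h = w / 2;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc)
          s += img(reflect_idx(r + dr, nr), reflect_idx(c + dc, nc));
      out(r, c) = s / (double)(w * w);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int w) {
  int nr = img.nrow(), nc = img.ncol(), h = w / 2, n = w * w;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(n);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int k = 0;
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc)
          buf[k++] = img(reflect_idx(r + dr, nr), reflect_idx(c + dc, nc));
      std::sort(buf.begin(), buf.end());
      // R-style median of an odd/even count
      out(r, c) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return out;
}

// Local mean and variance maps (population variance) over a w x w window,
// symmetric-reflect borders. Returned as a list used by the Lee filter.
// [[Rcpp::export]]
List cpp_local_stats(NumericMatrix img, int w) {
  int nr = img.nrow(), nc = img.ncol(), h = w / 2;
  NumericMatrix m(nr, nc), v(nr, nc);
  double nn = (double)(w * w);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc) {
          double x = img(reflect_idx(r + dr, nr), reflect_idx(c + dc, nc));
          s += x; s2 += x * x;
        }
      double mu = s / nn;
      m(r, c) = mu;
      double var = s2 / nn - mu * mu;
      v(r, c) = var > 0 ? var : 0.0;
    }
  }
  return List::create(Named("mean") = m, Named("var") = v);
}

// [[Rcpp::export]]
NumericMatrix cpp_nlm_filter(NumericMatrix img, int p, int s, double h) {
  int nr = img.nrow(), nc = img.ncol();
  int ph = p / 2, sh = s / 2;
  NumericMatrix out(nr, nc);
  double h2 = h * h;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double wsum = 0.0, acc = 0.0;
      for (int dr = -sh; dr <= sh; ++dr) {
        for (int dc = -sh; dc <= sh; ++dc) {
          int r2 = r + dr, c2 = c + dc;
          // patch squared distance, symmetric-reflect borders
          double d2 = 0.0;
          for (int pr = -ph; pr <= ph; ++pr) {
            for (int pc = -ph; pc <= ph; ++pc) {
              double a = img(reflect_idx(r + pr, nr), reflect_idx(c + pc, nc));
              double b = img(reflect_idx(r2 + pr, nr), reflect_idx(c2 + pc, nc));
              double d = a - b;
              d2 += d * d;
            }
          }
          double wgt = std::exp(-d2 / h2);
          wsum += wgt;
          acc += wgt * img(reflect_idx(r2, nr), reflect_idx(c2, nc));
        }
      }
      out(r, c) = acc / wsum;
    }
  }
  return out;
}

static inline int circ_transitions(const std::vector<int>& b) {
  int P = (int)b.size(), u = 0;
  for (int k = 0; k < P; ++k) u += (b[k] != b[(k + 1) % P]);
  return u;
}

// LBP code image with riu2 (variant = 0) or u2 (variant = 1) mapping.
// Border of width R carries label -1 (excluded from histograms).
// riu2 labels: 0..P (count of ones when uniform), P+1 non-uniform.
// u2 labels: 0 all-zeros; 1 + (n-1)*P + rot for a uniform run of n ones
// starting at bit `rot`; P*(P-1)+1 all-ones; P*(P-1)+2 non-uniform.
// [[Rcpp::export]]
IntegerMatrix cpp_lbp_code(NumericMatrix img, int P, double R, int variant) {
  int nr = img.nrow(), nc = img.ncol();
  int Ri = (int)std::ceil(R - 1e-8);
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), -1);
  std::vector<double> dy(P), dx(P);
  for (int k = 0; k < P; ++k) {
    double ang = 2.0 * M_PI * k / P;
    // neighbor k at (row - R sin, col + R cos)
    dy[k] = -R * std::sin(ang);
    dx[k] =  R * std::cos(ang);
    if (std::fabs(dy[k] - std::round(dy[k])) < 1e-8) dy[k] = std::round(dy[k]);
    if (std::fabs(dx[k] - std::round(dx[k])) < 1e-8) dx[k] = std::round(dx[k]);
  }
  std::vector<int> bits(P);
  for (int r = Ri; r < nr - Ri; ++r) {
    for (int c = Ri; c < nc - Ri; ++c) {
      double ctr = img(r, c);
      for (int k = 0; k < P; ++k) {
        double yy = r + dy[k], xx = c + dx[k], val;
        double fy = std::floor(yy), fx = std::floor(xx);
        if (yy == fy && xx == fx) {
          val = img((int)fy, (int)fx);
        } else {
          int y0 = (int)fy, x0 = (int)fx;
          double ty = yy - fy, tx = xx - fx;
          val = (1 - ty) * (1 - tx) * img(y0, x0)
              + (1 - ty) * tx       * img(y0, x0 + 1)
              + ty       * (1 - tx) * img(y0 + 1, x0)
              + ty       * tx       * img(y0 + 1, x0 + 1);
        }
        // >= with a tiny tolerance so bilinear round-off on locally
        // constant data still counts equality as 1
        bits[k] = (val >= ctr - 1e-12) ? 1 : 0;
      }
      int U = circ_transitions(bits);
      int ones = 0;
      for (int k = 0; k < P; ++k) ones += bits[k];
      int lab;
      if (variant == 0) {               // riu2
        lab = (U <= 2) ? ones : (P + 1);
      } else {                          // u2
        if (U == 0) {
          lab = (ones == 0) ? 0 : P * (P - 1) + 1;
        } else if (U == 2) {
          int rot = -1;                 // first bit of the run of ones
          for (int k = 0; k < P; ++k)
            if (bits[k] == 1 && bits[(k - 1 + P) % P] == 0) { rot = k; break; }
          lab = 1 + (ones - 1) * P + rot;
        } else {
          lab = P * (P - 1) + 2;
        }
      }
      out(r, c) = lab;
    }
  }
  return out;
}
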
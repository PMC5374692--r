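#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// 8-neighbour ring in the conventional clockwise order starting north:
// p2 p3 p4 p5 p6 p7 p8 p9 = N NE E SE S SW W NW (row, col offsets)
static const int RING_DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int RING_DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline int at(const std::vector<unsigned char>& m, int nr, int nc,
                     int r, int c) {
  if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
  return m[(size_t)c * nr + r];
}

// Number of 0->1 transitions around the ring (Hilditch crossing number A)
// and number of foreground neighbours (B).
static inline void ring_stats(const std::vector<unsigned char>& m, int nr,
                              int nc, int r, int c, int& A, int& B) {
  int p[8];
  for (int k = 0; k < 8; ++k)
    p[k] = at(m, nr, nc, r + RING_DR[k], c + RING_DC[k]);
  A = 0; B = 0;
  for (int k = 0; k < 8; ++k) {
    B += p[k];
    if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
  }
}

// [[Rcpp::export(name = ".thin_mask_cpp")]]
LogicalMatrix thin_mask_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> m((size_t)nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      m[(size_t)c * nr + r] = mask(r, c) ? 1 : 0;

  // Zhang-Suen thinning: two sub-iterations per pass until stable.
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m[(size_t)c * nr + r]) continue;
          int A, B;
          ring_stats(m, nr, nc, r, c, A, B);
          if (B < 2 || B > 6 || A != 1) continue;
          int p2 = at(m, nr, nc, r - 1, c);
          int p4 = at(m, nr, nc, r, c + 1);
          int p6 = at(m, nr, nc, r + 1, c);
          int p8 = at(m, nr, nc, r, c - 1);
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        m[(size_t)kill[i].second * nr + kill[i].first] = 0;
    }
  }

  // Sequential cleanup: delete remaining simple non-endpoint pixels
  // (staircase corners Zhang-Suen leaves behind). A pixel is 8-simple iff
  // its Yokoi connectivity number equals 1; sequential deletion of simple
  // pixels preserves topology exactly.
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!m[(size_t)c * nr + r]) continue;
        // ring indexed E, NE, N, NW, W, SW, S, SE for the Yokoi formula
        static const int YDR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
        static const int YDC[8] = {1, 1, 0, -1, -1, -1, 0, 1};
        int q[8], B = 0;
        for (int k = 0; k < 8; ++k) {
          int v = at(m, nr, nc, r + YDR[k], c + YDC[k]);
          B += v;
          q[k] = 1 - v;
        }
        if (B < 2) continue; // endpoints and isolated pixels stay
        int C = 0;
        for (int k = 0; k < 8; k += 2)
          C += q[k] - q[k] * q[(k + 1) % 8] * q[(k + 2) % 8];
        if (C == 1) {
          m[(size_t)c * nr + r] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = m[(size_t)c * nr + r] != 0;
  return out;
}

// [[Rcpp::export(name = ".label_components8_cpp")]]
IntegerMatrix label_components8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = cr + RING_DR[k], c2 = cc + RING_DC[k];
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(c2 * nr + r2);
          }
        }
      }
    }
  }
  return lab;
}

// Stamp filled discs of radius `radius` centred at (rows[i], cols[i])
// (1-based, fractional allowed) onto an nr x nc canvas.
// [[Rcpp::export(name = ".stamp_discs_cpp")]]
LogicalMatrix stamp_discs_cpp(int nr, int nc, NumericVector rows,
                              NumericVector cols, double radius) {
  LogicalMatrix out(nr, nc);
  const double r2 = radius * radius;
  const int ir = (int)std::ceil(radius);
  for (int i = 0; i < rows.size(); ++i) {
    const double cr = rows[i] - 1.0, cc = cols[i] - 1.0;
    const int rlo = std::max(0, (int)std::floor(cr) - ir);
    const int rhi = std::min(nr - 1, (int)std::ceil(cr) + ir);
    const int clo = std::max(0, (int)std::floor(cc) - ir);
    const int chi = std::min(nc - 1, (int)std::ceil(cc) + ir);
    for (int c = clo; c <= chi; ++c) {
      const double dc = c - cc;
      for (int r = rlo; r <= rhi; ++r) {
        const double dr = r - cr;
        if (dr * dr + dc * dc <= r2) out(r, c) = true;
      }
    }
  }
  return out;
}

// Separable convolution with a 1-D kernel applied along rows then columns,
// replicating edge values (exact direct convolution, no FFT).
// [[Rcpp::export(name = ".sep_convolve_cpp")]]
NumericMatrix sep_convolve_cpp(NumericMatrix x, NumericVector k) {
  const int nr = x.nrow(), nc = x.ncol(), m = k.size(), h = (m - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns (vertical pass)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int j = 0; j < m; ++j) {
        int rr = r + j - h;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        acc += x(rr, c) * k[j];
      }
      tmp(r, c) = acc;
    }
  }
  // along rows (horizontal pass)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int j = 0; j < m; ++j) {
        int cc = c + j - h;
        if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
        acc += tmp(r, cc) * k[j];
      }
      out(r, c) = acc;
    }
  }
  return out;
}
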
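#include <Rcpp.h>
using namespace Rcpp;

// Anti-aliased disc rendering: per-pixel coverage by ss x ss sub-pixel
// sampling. Coordinates are continuous pixel units with pixel (row j, col i)
// covering [i, i+1) x [j, j+1). Dots partly outside the raster are clipped.
// [[Rcpp::export]]
NumericMatrix render_discs_cpp(int nx, int ny, NumericVector x,
                               NumericVector y, NumericVector pol,
                               double radius, int ss) {
  NumericMatrix out(ny, nx);
  const double r2 = radius * radius;
  const double step = 1.0 / ss;
  const double w = 1.0 / (ss * ss);
  for (int d = 0; d < x.size(); ++d) {
    int i0 = std::max(0, (int)std::floor(x[d] - radius));
    int i1 = std::min(nx - 1, (int)std::floor(x[d] + radius));
    int j0 = std::max(0, (int)std::floor(y[d] - radius));
    int j1 = std::min(ny - 1, (int)std::floor(y[d] + radius));
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        double cov = 0.0;
        for (int sj = 0; sj < ss; ++sj) {
          double yy = j + (sj + 0.5) * step - y[d];
          for (int si = 0; si < ss; ++si) {
            double xx = i + (si + 0.5) * step - x[d];
            if (xx * xx + yy * yy < r2) cov += w;
          }
        }
        if (cov > 0) out(j, i) += pol[d] * cov;
      }
    }
  }
  return out;
}

// Splat a radially symmetric kernel (values kvals sampled every dr pixel
// units of radius) at each dot position; linear interpolation in radius.
// [[Rcpp::export]]
NumericMatrix splat_kernel_cpp(int nx, int ny, NumericVector x,
                               NumericVector y, NumericVector pol,
                               NumericVector kvals, double dr) {
  NumericMatrix out(ny, nx);
  const int nk = kvals.size();
  const double rmax = (nk - 1) * dr;
  for (int d = 0; d < x.size(); ++d) {
    int i0 = std::max(0, (int)std::floor(x[d] - rmax - 0.5));
    int i1 = std::min(nx - 1, (int)std::floor(x[d] + rmax + 0.5));
    int j0 = std::max(0, (int)std::floor(y[d] - rmax - 0.5));
    int j1 = std::min(ny - 1, (int)std::floor(y[d] + rmax + 0.5));
    for (int j = j0; j <= j1; ++j) {
      double yy = j + 0.5 - y[d];
      for (int i = i0; i <= i1; ++i) {
        double xx = i + 0.5 - x[d];
        double r = std::sqrt(xx * xx + yy * yy);
        if (r >= rmax) continue;
        double u = r / dr;
        int k = (int)u;
        double f = u - k;
        out(j, i) += pol[d] * (kvals[k] * (1 - f) + kvals[k + 1] * f);
      }
    }
  }
  return out;
}

// Separable same-size 2-D convolution with a symmetric 1-D kernel,
// zero-padded borders (background is mean gray = 0).
// [[Rcpp::export]]
NumericMatrix sepconv2_cpp(NumericMatrix m, NumericVector k) {
  const int ny = m.nrow(), nx = m.ncol();
  const int h = (k.size() - 1) / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int i = 0; i < nx; ++i) {        // vertical pass
    for (int j = 0; j < ny; ++j) {
      double s = 0.0;
      int o0 = std::max(-h, -j), o1 = std::min(h, ny - 1 - j);
      for (int o = o0; o <= o1; ++o) s += k[o + h] * m(j + o, i);
      tmp(j, i) = s;
    }
  }
  for (int j = 0; j < ny; ++j) {        // horizontal pass
    for (int i = 0; i < nx; ++i) {
      double s = 0.0;
      int o0 = std::max(-h, -i), o1 = std::min(h, nx - 1 - i);
      for (int o = o0; o <= o1; ++o) s += k[o + h] * tmp(j, i + o);
      out(j, i) = s;
    }
  }
  return out;
}

// Area-true block averaging by an integer factor.
// [[Rcpp::export]]
NumericMatrix block_average_cpp(NumericMatrix m, int f) {
  const int ny = m.nrow() / f, nx = m.ncol() / f;
  NumericMatrix out(ny, nx);
  const double w = 1.0 / (f * f);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double s = 0.0;
      for (int bj = 0; bj < f; ++bj)
        for (int bi = 0; bi < f; ++bi) s += m(j * f + bj, i * f + bi);
      out(j, i) = s * w;
    }
  return out;
}

// Population correlation surface C(y, dx).
//
// For each preferred disparity dx (horizontal window offset s_px pixels,
// Gaussian SD sigma_px pixels, truncation half-width m_px pixels) and each
// vertical position y, computes the Pearson correlation of the two sets
// {w_ij L(i,j)} and {w_ij R(i+s, j)} over the square window |i-x|,|j-y| <=
// m, where w is the separable 2-D Gaussian. Separability allows one
// x-weighted pass per row followed by 1-D sums over y, so the cost per
// (y, dx) is linear, not quadratic, in the window width.
//
// Columns where the window does not fit horizontally, and rows where it
// does not fit vertically, are NA (edge policy: flag, never shrink).
// Windows with (numerically) zero variance in either eye are NA.
// [[Rcpp::export]]
NumericMatrix corr_surface_cpp(NumericMatrix L, NumericMatrix R, int x_col,
                               IntegerVector s_px, IntegerVector m_px,
                               NumericVector sigma_px) {
  const int ny = L.nrow(), nx = L.ncol(), nd = s_px.size();
  const int x = x_col - 1;  // 0-based
  NumericMatrix out(ny, nd);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> g, g2, p1(ny), p2(ny), q1(ny), q2(ny), r12(ny);
  for (int d = 0; d < nd; ++d) {
    const int m = m_px[d], s = s_px[d];
    const double sig = sigma_px[d];
    if (x - m < 0 || x + m >= nx || x + s - m < 0 || x + s + m >= nx)
      continue;
    const int W = 2 * m + 1;
    g.resize(W); g2.resize(W);
    for (int o = -m; o <= m; ++o) {
      g[o + m] = std::exp(-0.5 * o * o / (sig * sig));
      g2[o + m] = g[o + m] * g[o + m];
    }
    for (int j = 0; j < ny; ++j) {      // x-weighted row aggregates
      double a1 = 0, a2 = 0, b1 = 0, b2 = 0, c12 = 0;
      for (int o = -m; o <= m; ++o) {
        double lv = L(j, x + o), rv = R(j, x + s + o);
        a1 += g[o + m] * lv;  b1 += g2[o + m] * lv * lv;
        a2 += g[o + m] * rv;  b2 += g2[o + m] * rv * rv;
        c12 += g2[o + m] * lv * rv;
      }
      p1[j] = a1; q1[j] = b1; p2[j] = a2; q2[j] = b2; r12[j] = c12;
    }
    const double n = (double)W * W;
    for (int y = m; y < ny - m; ++y) {
      double Sa = 0, Sb = 0, Saa = 0, Sbb = 0, Sab = 0;
      for (int o = -m; o <= m; ++o) {
        Sa += g[o + m] * p1[y + o];
        Sb += g[o + m] * p2[y + o];
        Saa += g2[o + m] * q1[y + o];
        Sbb += g2[o + m] * q2[y + o];
        Sab += g2[o + m] * r12[y + o];
      }
      double va = Saa - Sa * Sa / n, vb = Sbb - Sb * Sb / n;
      if (va <= 1e-12 * Saa || vb <= 1e-12 * Sbb || Saa <= 0 || Sbb <= 0)
        continue;
      double c = (Sab - Sa * Sb / n) / std::sqrt(va * vb);
      out(y, d) = std::max(-1.0, std::min(1.0, c));
    }
  }
  return out;
}
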
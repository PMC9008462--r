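#include <Rcpp.h>
using namespace Rcpp;

// Integrated symmetric Gaussian PSF on the unit pixel grid.
// Continuous coordinates: pixel with (1-based) index j spans [j-1, j), so a
// coordinate x in [0, ncol) has sub-pixel phase x - floor(x).

static inline double pix_integral(double edge_lo, double center, double sigma) {
  // integral of N(center, sigma^2) over [edge_lo, edge_lo + 1]
  const double s2 = sigma * M_SQRT2;
  return 0.5 * (std::erf((edge_lo + 1.0 - center) / s2) -
                std::erf((edge_lo - center) / s2));
}

static inline double pix_integral_deriv(double edge_lo, double center, double sigma) {
  // d/dcenter of pix_integral
  const double c = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  double a = (edge_lo - center) / sigma;
  double b = (edge_lo + 1.0 - center) / sigma;
  return c * (std::exp(-0.5 * a * a) - std::exp(-0.5 * b * b));
}

// Solve 4x4 linear system in place (Gaussian elimination, partial pivot).
static bool solve4(double A[4][4], double b[4], double x[4]) {
  int idx[4] = {0, 1, 2, 3};
  for (int k = 0; k < 4; ++k) {
    int p = k;
    for (int i = k + 1; i < 4; ++i)
      if (std::fabs(A[idx[i]][k]) > std::fabs(A[idx[p]][k])) p = i;
    std::swap(idx[k], idx[p]);
    double piv = A[idx[k]][k];
    if (std::fabs(piv) < 1e-300) return false;
    for (int i = k + 1; i < 4; ++i) {
      double f = A[idx[i]][k] / piv;
      for (int j = k; j < 4; ++j) A[idx[i]][j] -= f * A[idx[k]][j];
      b[idx[i]] -= f * b[idx[k]];
    }
  }
  for (int k = 3; k >= 0; --k) {
    double s = b[idx[k]];
    for (int j = k + 1; j < 4; ++j) s -= A[idx[k]][j] * x[j];
    x[k] = s / A[idx[k]][k];
  }
  return true;
}

// invert 4x4 symmetric positive-definite matrix via Gauss-Jordan; returns false if singular
static bool inv4(const double Ain[4][4], double out[4][4]) {
  double A[4][8];
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) { A[i][j] = Ain[i][j]; A[i][j + 4] = (i == j) ? 1.0 : 0.0; }
  }
  for (int k = 0; k < 4; ++k) {
    int p = k;
    for (int i = k + 1; i < 4; ++i) if (std::fabs(A[i][k]) > std::fabs(A[p][k])) p = i;
    if (std::fabs(A[p][k]) < 1e-300) return false;
    if (p != k) for (int j = 0; j < 8; ++j) std::swap(A[p][j], A[k][j]);
    double piv = A[k][k];
    for (int j = 0; j < 8; ++j) A[k][j] /= piv;
    for (int i = 0; i < 4; ++i) {
      if (i == k) continue;
      double f = A[i][k];
      for (int j = 0; j < 8; ++j) A[i][j] -= f * A[k][j];
    }
  }
  for (int i = 0; i < 4; ++i) for (int j = 0; j < 4; ++j) out[i][j] = A[i][j + 4];
  return true;
}

// Maximum-likelihood fit of an integrated-Gaussian spot (Poisson noise model)
// in a square window around each candidate. Parameters: x, y (continuous px),
// photons, background (photons/px). Fisher-scoring ascent; precision = CRLB.
// fit_quality = Poisson deviance 2*(ll_saturated - ll_fit).
// [[Rcpp::export(name = ".fit_spots_cpp")]]
DataFrame fit_spots_cpp(NumericMatrix img, IntegerVector cand_row, IntegerVector cand_col,
                        int win, double psf_sigma, int max_iter, double tol_px) {
  int nr = img.nrow(), nc = img.ncol();
  int half = win / 2;
  int ncand = cand_row.size();
  NumericVector out_x(ncand), out_y(ncand), out_N(ncand), out_b(ncand),
      out_cx(ncand), out_cy(ncand), out_dev(ncand);
  IntegerVector out_it(ncand), out_npx(ncand);
  LogicalVector out_conv(ncand);

  std::vector<double> Ex(win), Ey(win), dEx(win), dEy(win);

  for (int q = 0; q < ncand; ++q) {
    int ci = cand_row[q] - 1, cj = cand_col[q] - 1;
    int i0 = std::max(0, ci - half), i1 = std::min(nr - 1, ci + half);
    int j0 = std::max(0, cj - half), j1 = std::min(nc - 1, cj + half);
    int wy = i1 - i0 + 1, wx = j1 - j0 + 1;
    int npx = wx * wy;

    // initial values: centre of candidate pixel; background from window minimum
    double y0 = ci + 0.5, x0 = cj + 0.5;
    double bg = R_PosInf, tot = 0.0;
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) { bg = std::min(bg, img(i, j)); tot += img(i, j); }
    bg = std::max(bg, 1e-6);
    double N = std::max(tot - bg * npx, 10.0);

    bool conv = false;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      // per-axis pixel integrals and derivatives
      for (int j = j0; j <= j1; ++j) {
        Ex[j - j0] = pix_integral((double)j, x0, psf_sigma);
        dEx[j - j0] = pix_integral_deriv((double)j, x0, psf_sigma);
      }
      for (int i = i0; i <= i1; ++i) {
        Ey[i - i0] = pix_integral((double)i, y0, psf_sigma);
        dEy[i - i0] = pix_integral_deriv((double)i, y0, psf_sigma);
      }
      double g[4] = {0, 0, 0, 0};
      double FI[4][4] = {{0}};
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double ex = Ex[j - j0], ey = Ey[i - i0];
          double mu = bg + N * ex * ey;
          if (mu < 1e-12) mu = 1e-12;
          double d[4];
          d[0] = N * dEx[j - j0] * ey;  // d mu / d x
          d[1] = N * ex * dEy[i - i0];  // d mu / d y
          d[2] = ex * ey;               // d mu / d N
          d[3] = 1.0;                   // d mu / d bg
          double resid = img(i, j) / mu - 1.0;
          for (int a = 0; a < 4; ++a) {
            g[a] += resid * d[a];
            for (int b2 = a; b2 < 4; ++b2) FI[a][b2] += d[a] * d[b2] / mu;
          }
        }
      for (int a = 0; a < 4; ++a)
        for (int b2 = 0; b2 < a; ++b2) FI[a][b2] = FI[b2][a];
      // Levenberg-style ridge for stability
      for (int a = 0; a < 4; ++a) FI[a][a] *= 1.0 + 1e-8;
      double A[4][4], rhs[4], step[4];
      for (int a = 0; a < 4; ++a) { rhs[a] = g[a]; for (int b2 = 0; b2 < 4; ++b2) A[a][b2] = FI[a][b2]; }
      if (!solve4(A, rhs, step)) break;
      // clamp positional step to 1 px per iteration
      double m = std::max(std::fabs(step[0]), std::fabs(step[1]));
      if (m > 1.0) { for (int a = 0; a < 4; ++a) step[a] /= m; }
      x0 += step[0]; y0 += step[1]; N += step[2]; bg += step[3];
      // keep parameters in their feasible ranges
      x0 = std::min(std::max(x0, (double)j0 - 1.0), (double)j1 + 2.0);
      y0 = std::min(std::max(y0, (double)i0 - 1.0), (double)i1 + 2.0);
      N = std::max(N, 1e-3);
      bg = std::max(bg, 1e-6);
      if (std::fabs(step[0]) < tol_px && std::fabs(step[1]) < tol_px) { conv = true; ++it; break; }
      // a fit still jumping by > 0.5 px after 15 iterations is oscillating
      // on noise, not refining a spot; stop early as non-converged
      if (it >= 15 && m > 0.5) { ++it; break; }
    }

    // a fit that left its window is a noise artefact, not a spot
    if (x0 < (double)j0 || x0 > (double)j1 + 1.0 ||
        y0 < (double)i0 || y0 > (double)i1 + 1.0) conv = false;

    // final model: deviance and CRLB
    for (int j = j0; j <= j1; ++j) {
      Ex[j - j0] = pix_integral((double)j, x0, psf_sigma);
      dEx[j - j0] = pix_integral_deriv((double)j, x0, psf_sigma);
    }
    for (int i = i0; i <= i1; ++i) {
      Ey[i - i0] = pix_integral((double)i, y0, psf_sigma);
      dEy[i - i0] = pix_integral_deriv((double)i, y0, psf_sigma);
    }
    double dev = 0.0;
    double FI[4][4] = {{0}};
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double ex = Ex[j - j0], ey = Ey[i - i0];
        double mu = bg + N * ex * ey;
        if (mu < 1e-12) mu = 1e-12;
        double n = img(i, j);
        if (n > 0) dev += 2.0 * (n * std::log(n / mu) - (n - mu));
        else dev += 2.0 * mu;
        double d[4];
        d[0] = N * dEx[j - j0] * ey;
        d[1] = N * ex * dEy[i - i0];
        d[2] = ex * ey;
        d[3] = 1.0;
        for (int a = 0; a < 4; ++a)
          for (int b2 = a; b2 < 4; ++b2) FI[a][b2] += d[a] * d[b2] / mu;
      }
    for (int a = 0; a < 4; ++a)
      for (int b2 = 0; b2 < a; ++b2) FI[a][b2] = FI[b2][a];
    double FIinv[4][4];
    double cx = NA_REAL, cy = NA_REAL;
    if (inv4(FI, FIinv) && FIinv[0][0] > 0 && FIinv[1][1] > 0) {
      cx = std::sqrt(FIinv[0][0]);
      cy = std::sqrt(FIinv[1][1]);
    }
    out_x[q] = x0; out_y[q] = y0; out_N[q] = N; out_b[q] = bg;
    out_cx[q] = cx; out_cy[q] = cy; out_dev[q] = dev;
    out_it[q] = it; out_conv[q] = conv; out_npx[q] = npx;
  }
  return DataFrame::create(_["x_px"] = out_x, _["y_px"] = out_y,
                           _["photons"] = out_N, _["background"] = out_b,
                           _["crlb_x_px"] = out_cx, _["crlb_y_px"] = out_cy,
                           _["fit_quality"] = out_dev, _["n_px"] = out_npx,
                           _["iterations"] = out_it, _["converged"] = out_conv);
}

// Render one or more frames: integrated-Gaussian emitters on constant
// background, then Poisson shot noise, EM-register excess noise (gamma stage,
// variance multiplied by em_factor), conversion to ADU (divide by gain in
// photons/ADU), offset, Gaussian read noise, rounding, clamp to 16-bit.
// Emitters given as (frame 1-based, x_px, y_px, photons). Uses R's RNG.
// [[Rcpp::export(name = ".render_movie_cpp")]]
IntegerVector render_movie_cpp(int nrow, int ncol, int nframes,
                               IntegerVector em_frame, NumericVector em_x,
                               NumericVector em_y, NumericVector em_photons,
                               double psf_sigma, double bg_photons,
                               double gain, double offset, double read_noise,
                               double em_factor) {
  IntegerVector out((R_xlen_t)nrow * ncol * nframes);
  out.attr("dim") = IntegerVector::create(nrow, ncol, nframes);
  std::vector<double> buf((size_t)nrow * ncol);
  int ne = em_frame.size();
  int radius = (int)std::ceil(5.0 * psf_sigma) + 1;
  // emitters sorted by frame index for a single sweep
  std::vector<int> ord(ne);
  for (int i = 0; i < ne; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) { return em_frame[a] < em_frame[b]; });
  int ptr = 0;
  for (int f = 1; f <= nframes; ++f) {
    std::fill(buf.begin(), buf.end(), bg_photons);
    while (ptr < ne && em_frame[ord[ptr]] == f) {
      int e = ord[ptr++];
      double x = em_x[e], y = em_y[e], N = em_photons[e];
      int jc = (int)std::floor(x), ic = (int)std::floor(y);
      int j0 = std::max(0, jc - radius), j1 = std::min(ncol - 1, jc + radius);
      int i0 = std::max(0, ic - radius), i1 = std::min(nrow - 1, ic + radius);
      if (j1 < j0 || i1 < i0) continue;
      for (int j = j0; j <= j1; ++j) {
        double ex = pix_integral((double)j, x, psf_sigma);
        for (int i = i0; i <= i1; ++i)
          buf[(size_t)j * nrow + i] += N * ex * pix_integral((double)i, y, psf_sigma);
      }
    }
    R_xlen_t base = (R_xlen_t)(f - 1) * nrow * ncol;
    bool em_on = em_factor > 1.0;
    double em_scale = em_factor - 1.0;
    for (size_t p = 0; p < buf.size(); ++p) {
      double mu = buf[p];
      double n = (mu > 0) ? R::rpois(mu) : 0.0;
      double e = n;
      if (em_on && n > 0) e = R::rgamma(n / em_scale, em_scale);
      double adu = e / gain + offset;
      if (read_noise > 0) adu += R::norm_rand() * read_noise;
      long v = std::lround(adu);
      if (v < 0) v = 0;
      if (v > 65535) v = 65535;
      out[base + (R_xlen_t)p] = (int)v;
    }
  }
  return out;
}

// Noiseless expected-photon rendering of a single frame (model image).
// [[Rcpp::export(name = ".render_frame_ideal_cpp")]]
NumericMatrix render_frame_ideal_cpp(int nrow, int ncol, NumericVector em_x,
                                     NumericVector em_y, NumericVector em_photons,
                                     double psf_sigma, double bg_photons) {
  NumericMatrix out(nrow, ncol);
  std::fill(out.begin(), out.end(), bg_photons);
  int radius = (int)std::ceil(5.0 * psf_sigma) + 1;
  for (int e = 0; e < em_x.size(); ++e) {
    double x = em_x[e], y = em_y[e], N = em_photons[e];
    int jc = (int)std::floor(x), ic = (int)std::floor(y);
    int j0 = std::max(0, jc - radius), j1 = std::min(ncol - 1, jc + radius);
    int i0 = std::max(0, ic - radius), i1 = std::min(nrow - 1, ic + radius);
    for (int j = j0; j <= j1; ++j) {
      double ex = pix_integral((double)j, x, psf_sigma);
      for (int i = i0; i <= i1; ++i)
        out(i, j) += N * ex * pix_integral((double)i, y, psf_sigma);
    }
  }
  return out;
}
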
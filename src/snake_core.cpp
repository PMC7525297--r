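#include <Rcpp.h>
using namespace Rcpp;

// Band-limited interior indicator: 1 for phi <= -eps (interior), 0 for
// phi >= eps, smooth interpolant in between.  Interior is phi < 0
// throughout.
static inline double heavi_in(double p, double eps) {
  if (p <= -eps) return 1.0;
  if (p >= eps)  return 0.0;
  return 0.5 * (1.0 - p / eps - std::sin(M_PI * p / eps) / M_PI);
}

// Localized uniform-modelling (mean-separation) force over the narrow band
// |phi| < eps.  For each band pixel, interior/exterior means are taken over
// the (2*radius+1)^2 window clipped to the image, weighted by the smoothed
// Heaviside of phi; summed-area tables make each window O(1).  Returns
// 1-based linear indices of the band, the raw force
// (I-u_in)^2 - (I-u_ex)^2, and the summed band energy.
// [[Rcpp::export]]
List ac_force_band(NumericMatrix I, NumericMatrix phi, double eps, int radius) {
  int nr = I.nrow(), nc = I.ncol();
  int nr1 = nr + 1;

  std::vector<double> H((size_t) nr * nc);
  std::vector<int> band;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double p = phi(i, j);
      H[(size_t) i + (size_t) j * nr] = heavi_in(p, eps);
      if (std::fabs(p) < eps) band.push_back(i + j * nr);
    }

  // summed-area tables with a zero top row / left column
  std::vector<double> satH((size_t) nr1 * (nc + 1), 0.0);
  std::vector<double> satHI((size_t) nr1 * (nc + 1), 0.0);
  std::vector<double> satI((size_t) nr1 * (nc + 1), 0.0);
  for (int j = 1; j <= nc; ++j) {
    double colH = 0.0, colHI = 0.0, colI = 0.0;
    for (int i = 1; i <= nr; ++i) {
      double h = H[(size_t)(i - 1) + (size_t)(j - 1) * nr];
      double v = I(i - 1, j - 1);
      colH += h; colHI += h * v; colI += v;
      size_t k = (size_t) i + (size_t) j * nr1;
      size_t kprev = (size_t) i + (size_t)(j - 1) * nr1;
      satH[k] = satH[kprev] + colH;
      satHI[k] = satHI[kprev] + colHI;
      satI[k] = satI[kprev] + colI;
    }
  }

  int nb = (int) band.size();
  IntegerVector idx(nb);
  NumericVector force(nb);
  double energy = 0.0;

  for (int k = 0; k < nb; ++k) {
    int lin = band[k];
    int i = lin % nr, j = lin / nr;
    int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
    int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
    double area = (double) (i1 - i0 + 1) * (j1 - j0 + 1);
    size_t a = (size_t) i0 + (size_t) j0 * nr1;
    size_t b = (size_t) (i1 + 1) + (size_t) j0 * nr1;
    size_t c = (size_t) i0 + (size_t) (j1 + 1) * nr1;
    size_t d = (size_t) (i1 + 1) + (size_t) (j1 + 1) * nr1;
    double sH  = satH[d]  - satH[b]  - satH[c]  + satH[a];
    double sHI = satHI[d] - satHI[b] - satHI[c] + satHI[a];
    double sI  = satI[d]  - satI[b]  - satI[c]  + satI[a];
    double v = I(i, j);
    double u_in = (sH > 1e-8) ? sHI / sH : v;
    double sEx = area - sH;
    double u_ex = (sEx > 1e-8) ? (sI - sHI) / sEx : v;
    double rin = v - u_in, rex = v - u_ex;
    force[k] = rin * rin - rex * rex;
    double h = H[(size_t) lin];
    energy += h * rin * rin + (1.0 - h) * rex * rex;
    idx[k] = lin + 1;  // 1-based for R
  }
  return List::create(_["idx"] = idx, _["force"] = force, _["energy"] = energy);
}

static inline double phival(const NumericMatrix& phi, int i, int j) {
  int nr = phi.nrow(), nc = phi.ncol();
  if (i < 0) i = 0;
  if (i >= nr) i = nr - 1;
  if (j < 0) j = 0;
  if (j >= nc) j = nc - 1;
  return phi(i, j);
}

// Mean curvature of the level sets of phi at the given 1-based linear
// indices, central differences with replicated borders.  Positive for a
// shrinking circle under interior-negative phi.
// [[Rcpp::export]]
NumericVector curvature_at(NumericMatrix phi, IntegerVector idx) {
  int nr = phi.nrow();
  int n = idx.size();
  NumericVector kap(n);
  for (int k = 0; k < n; ++k) {
    int lin = idx[k] - 1;
    int i = lin % nr, j = lin / nr;
    double px = 0.5 * (phival(phi, i, j + 1) - phival(phi, i, j - 1));
    double py = 0.5 * (phival(phi, i + 1, j) - phival(phi, i - 1, j));
    double pxx = phival(phi, i, j + 1) - 2.0 * phi(i, j) + phival(phi, i, j - 1);
    double pyy = phival(phi, i + 1, j) - 2.0 * phi(i, j) + phival(phi, i - 1, j);
    double pxy = 0.25 * (phival(phi, i + 1, j + 1) - phival(phi, i + 1, j - 1)
                       - phival(phi, i - 1, j + 1) + phival(phi, i - 1, j - 1));
    double g2 = px * px + py * py;
    kap[k] = (pxx * py * py - 2.0 * px * py * pxy + pyy * px * px)
             / (g2 * std::sqrt(g2) + 1e-10);
  }
  return kap;
}

static inline double sussman_update(double p, double a, double b,
                                    double c, double d, double dt) {
  double G = 0.0;
  if (p > 0.0) {
    double ap = std::max(a, 0.0), bm = std::min(b, 0.0);
    double cp = std::max(c, 0.0), dm = std::min(d, 0.0);
    G = std::sqrt(std::max(ap * ap, bm * bm) + std::max(cp * cp, dm * dm)) - 1.0;
  } else if (p < 0.0) {
    double am = std::min(a, 0.0), bp = std::max(b, 0.0);
    double cm = std::min(c, 0.0), dp = std::max(d, 0.0);
    G = std::sqrt(std::max(am * am, bp * bp) + std::max(cm * cm, dp * dp)) - 1.0;
  }
  double s = p / std::sqrt(p * p + 1.0);  // smoothed sign
  return p - dt * s * G;
}

// One sweep of Sussman's PDE reinitialization: relaxes phi toward
// |grad phi| = 1 without moving the zero level set (to first order).
// [[Rcpp::export]]
NumericMatrix sussman_step(NumericMatrix phi, double dt) {
  int nr = phi.nrow(), nc = phi.ncol();
  NumericMatrix out(nr, nc);
  const double* P = phi.begin();
  double* O = out.begin();
  // interior: no bounds checks
  for (int j = 1; j < nc - 1; ++j) {
    const double* col = P + (size_t) j * nr;
    const double* colm = col - nr;
    const double* colp = col + nr;
    double* oc = O + (size_t) j * nr;
    for (int i = 1; i < nr - 1; ++i) {
      double p = col[i];
      oc[i] = sussman_update(p, p - colm[i], colp[i] - p,
                             p - col[i - 1], col[i + 1] - p, dt);
    }
  }
  // borders: clamped neighbours
  for (int j = 0; j < nc; ++j) {
    int step = (j == 0 || j == nc - 1) ? 1 : std::max(1, nr - 1);
    for (int i = 0; i < nr; i += step) {
      double p = phi(i, j);
      O[(size_t) i + (size_t) j * nr] =
        sussman_update(p,
                       p - phival(phi, i, j - 1), phival(phi, i, j + 1) - p,
                       p - phival(phi, i - 1, j), phival(phi, i + 1, j) - p, dt);
    }
  }
  return out;
}
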
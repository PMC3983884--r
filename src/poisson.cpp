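// Variable-dielectric Poisson solver on a uniform cubic grid:
// div( eps(r) grad phi ) = -rho / eps0, 7-point stencil with harmonic-mean
// dielectric on half-edges, trilinear charge splatting, Dirichlet boundary
// from the Coulomb sum in the solvent dielectric, red-black SOR.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// e / (eps0 * 1 Angstrom) in volts
static const double SRC_V = 180.9512801;
// 1 / (4 pi eps0) in V * Angstrom / e
static const double COUL_V = 14.3996454;

static inline int idx3(int i, int j, int k, int n) {
  return (k * n + j) * n + i;
}

// [[Rcpp::export(name = ".poisson_cpp")]]
List poisson_cpp(NumericMatrix pos, NumericVector q, NumericVector radius,
                 int n, double h, NumericVector origin, double eps_in,
                 double eps_out, double tol, int max_iter) {
  const int nn = n * n * n;
  const int nq = q.size();
  std::vector<double> eps(nn, eps_out);

  // dielectric map: eps_in inside any atom's vdW sphere
  for (int a = 0; a < nq; ++a) {
    const double r = radius[a];
    if (r <= 0) continue;
    const double x = (pos(a, 0) - origin[0]) / h;
    const double y = (pos(a, 1) - origin[1]) / h;
    const double z = (pos(a, 2) - origin[2]) / h;
    const double rg = r / h;
    const int i0 = std::max(0, (int)std::floor(x - rg));
    const int i1 = std::min(n - 1, (int)std::ceil(x + rg));
    const int j0 = std::max(0, (int)std::floor(y - rg));
    const int j1 = std::min(n - 1, (int)std::ceil(y + rg));
    const int k0 = std::max(0, (int)std::floor(z - rg));
    const int k1 = std::min(n - 1, (int)std::ceil(z + rg));
    const double rg2 = rg * rg;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          const double dx = i - x, dy = j - y, dz = k - z;
          if (dx * dx + dy * dy + dz * dz <= rg2)
            eps[idx3(i, j, k, n)] = eps_in;
        }
  }

  // source: trilinear splat, scaled so the update reads
  //   phi_c = (sum_f eps_f phi_nbr + src_c) / sum_f eps_f
  std::vector<double> src(nn, 0.0);
  double src_norm2 = 0.0;
  for (int a = 0; a < nq; ++a) {
    const double x = (pos(a, 0) - origin[0]) / h;
    const double y = (pos(a, 1) - origin[1]) / h;
    const double z = (pos(a, 2) - origin[2]) / h;
    const int i = std::max(0, std::min(n - 2, (int)std::floor(x)));
    const int j = std::max(0, std::min(n - 2, (int)std::floor(y)));
    const int k = std::max(0, std::min(n - 2, (int)std::floor(z)));
    const double fx = x - i, fy = y - j, fz = z - k;
    const double scale = SRC_V * q[a] / h;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                           (dk ? fz : 1 - fz);
          src[idx3(i + di, j + dj, k + dk, n)] += scale * w;
        }
  }
  for (int c = 0; c < nn; ++c) src_norm2 += src[c] * src[c];

  std::vector<double> phi(nn, 0.0);
  // Dirichlet boundary: Coulomb sum in the solvent dielectric
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        if (i != 0 && i != n - 1 && j != 0 && j != n - 1 && k != 0 && k != n - 1)
          continue;
        const double gx = origin[0] + i * h;
        const double gy = origin[1] + j * h;
        const double gz = origin[2] + k * h;
        double v = 0.0;
        for (int a = 0; a < nq; ++a) {
          const double dx = gx - pos(a, 0), dy = gy - pos(a, 1),
                       dz = gz - pos(a, 2);
          const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          v += COUL_V * q[a] / (eps_out * std::max(r, 0.5 * h));
        }
        phi[idx3(i, j, k, n)] = v;
      }

  auto face_eps = [&](int c1, int c2) {
    const double e1 = eps[c1], e2 = eps[c2];
    return 2.0 * e1 * e2 / (e1 + e2);
  };

  const double omega = 2.0 / (1.0 + std::sin(M_PI / (n - 1)));
  double resid = R_PosInf;
  int iter = 0;
  const double ref = std::sqrt(src_norm2) > 0 ? std::sqrt(src_norm2) : 1.0;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < n - 1; ++k)
        for (int j = 1; j < n - 1; ++j) {
          int i = 1 + ((j + k + color) & 1);
          for (; i < n - 1; i += 2) {
            const int c = idx3(i, j, k, n);
            const double exm = face_eps(c, c - 1), exp_ = face_eps(c, c + 1);
            const double eym = face_eps(c, c - n), eyp = face_eps(c, c + n);
            const double ezm = face_eps(c, c - n * n), ezp = face_eps(c, c + n * n);
            const double denom = exm + exp_ + eym + eyp + ezm + ezp;
            const double rhs = exm * phi[c - 1] + exp_ * phi[c + 1] +
                               eym * phi[c - n] + eyp * phi[c + n] +
                               ezm * phi[c - n * n] + ezp * phi[c + n * n] +
                               src[c];
            phi[c] += omega * (rhs / denom - phi[c]);
          }
        }
    }
    if ((iter + 1) % 20 == 0 || iter == max_iter - 1) {
      double r2 = 0.0;
      for (int k = 1; k < n - 1; ++k)
        for (int j = 1; j < n - 1; ++j)
          for (int i = 1; i < n - 1; ++i) {
            const int c = idx3(i, j, k, n);
            const double exm = face_eps(c, c - 1), exp_ = face_eps(c, c + 1);
            const double eym = face_eps(c, c - n), eyp = face_eps(c, c + n);
            const double ezm = face_eps(c, c - n * n), ezp = face_eps(c, c + n * n);
            const double res = exm * (phi[c - 1] - phi[c]) +
                               exp_ * (phi[c + 1] - phi[c]) +
                               eym * (phi[c - n] - phi[c]) +
                               eyp * (phi[c + n] - phi[c]) +
                               ezm * (phi[c - n * n] - phi[c]) +
                               ezp * (phi[c + n * n] - phi[c]) + src[c];
            r2 += res * res;
          }
      resid = std::sqrt(r2) / ref;
      if (resid < tol) { ++iter; break; }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericVector out(nn);
  for (int c = 0; c < nn; ++c) out[c] = phi[c] * 1000.0; // volts -> mV
  out.attr("dim") = IntegerVector::create(n, n, n);
  return List::create(_["phi"] = out, _["iterations"] = iter,
                      _["residual"] = resid);
}
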
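#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler integration of the coupled adult/potential biomass system:
//   dA/dt = eps*C + rho0*A - kappa*A^2
//   dC/dt = D*lap(C) + nu.grad(C) - C + gamma*A^2/(beta^2 + A^2)
// Five-point Laplacian, mirror ghost points (zero-flux boundaries),
// first-order upwind for the advective term.  Parameter fields rho0, kappa
// and gamma are full matrices (constants are expanded on the R side).
//
// Invasion metrics (mean/second-moment of the unsigned distance of invaded
// nodes to the source, invaded fraction) are accumulated every
// `record_every` steps against the precomputed distance matrix `dist`.

static inline int reflect_lo(int i) { return i == 0 ? 1 : i - 1; }

// [[Rcpp::export]]
List simulate_core(NumericMatrix A0, NumericMatrix C0,
                   NumericMatrix rho0, NumericMatrix kappa,
                   NumericMatrix gamma_, double eps, double D, double beta,
                   double nu1, double nu2, double dx, double dt,
                   int n_steps, int record_every, NumericMatrix dist,
                   double threshold, IntegerVector snapshot_steps) {
  const int nx = A0.nrow(), ny = A0.ncol();
  const int nn = nx * ny;
  const double dx2 = dx * dx, b2 = beta * beta;

  std::vector<double> A(A0.begin(), A0.end()), C(C0.begin(), C0.end());
  std::vector<double> An(nn), Cn(nn);
  const double *rh = rho0.begin(), *ka = kappa.begin(), *ga = gamma_.begin();
  const double *dd = dist.begin();

  const int n_rec = n_steps / record_every + 1 +
                    (n_steps % record_every != 0 ? 1 : 0);
  NumericMatrix trace(n_rec, 4);  // step, mean, second central moment, frac
  int rec = 0;

  std::vector<int> snaps(snapshot_steps.begin(), snapshot_steps.end());
  List snapA(snaps.size()), snapC(snaps.size());

  auto record = [&](int step) {
    long cnt = 0;
    double s = 0.0, s2 = 0.0;
    for (int k = 0; k < nn; ++k) {
      if (!R_finite(A[k]) || !R_finite(C[k])) {
        int i = k % nx, j = k / nx;
        stop("non-finite state at node (%d, %d), t = %.6g",
             i + 1, j + 1, step * dt);
      }
      if (A[k] > threshold) {
        ++cnt;
        s += dd[k];
        s2 += dd[k] * dd[k];
      }
    }
    trace(rec, 0) = step;
    if (cnt > 0) {
      double m = s / cnt;
      trace(rec, 1) = m;
      trace(rec, 2) = s2 / cnt - m * m;
    } else {
      trace(rec, 1) = NA_REAL;
      trace(rec, 2) = NA_REAL;
    }
    trace(rec, 3) = (double)cnt / nn;
    ++rec;
  };

  auto snapshot = [&](int step) {
    for (size_t q = 0; q < snaps.size(); ++q) {
      if (snaps[q] == step) {
        NumericMatrix sa(nx, ny), sc(nx, ny);
        std::copy(A.begin(), A.end(), sa.begin());
        std::copy(C.begin(), C.end(), sc.begin());
        snapA[q] = sa;
        snapC[q] = sc;
      }
    }
  };

  // running minima over every step, for positivity diagnostics
  double minA = R_PosInf, minC = R_PosInf;
  auto track_min = [&]() {
    for (int k = 0; k < nn; ++k) {
      if (A[k] < minA) minA = A[k];
      if (C[k] < minC) minC = C[k];
    }
  };

  record(0);
  snapshot(0);
  track_min();

  for (int step = 1; step <= n_steps; ++step) {
    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? 1 : j - 1;
      const int jp = (j == ny - 1) ? ny - 2 : j + 1;
      for (int i = 0; i < nx; ++i) {
        const int im = (i == 0) ? 1 : i - 1;
        const int ip = (i == nx - 1) ? nx - 2 : i + 1;
        const int k = i + nx * j;
        const double a = A[k], c = C[k];

        double lap = (C[im + nx * j] + C[ip + nx * j] +
                      C[i + nx * jm] + C[i + nx * jp] - 4.0 * c) / dx2;

        double adv = 0.0;
        if (nu1 != 0.0) {
          // +nu.grad(C) on the RHS transports mass toward -nu; the
          // stable upwind side is downstream of that effective flow.
          adv += nu1 * ((nu1 > 0.0) ? (C[ip + nx * j] - c)
                                    : (c - C[im + nx * j])) / dx;
        }
        if (nu2 != 0.0) {
          adv += nu2 * ((nu2 > 0.0) ? (C[i + nx * jp] - c)
                                    : (c - C[i + nx * jm])) / dx;
        }

        const double src = ga[k] * a * a / (b2 + a * a);
        An[k] = a + dt * (eps * c + rh[k] * a - ka[k] * a * a);
        Cn[k] = c + dt * (D * lap + adv - c + src);
      }
    }
    A.swap(An);
    C.swap(Cn);
    if (step % record_every == 0 || step == n_steps) record(step);
    snapshot(step);
    track_min();
  }

  NumericMatrix Af(nx, ny), Cf(nx, ny);
  std::copy(A.begin(), A.end(), Af.begin());
  std::copy(C.begin(), C.end(), Cf.begin());

  return List::create(_["trace"] = trace, _["A"] = Af, _["C"] = Cf,
                      _["snapA"] = snapA, _["snapC"] = snapC,
                      _["minA"] = minA, _["minC"] = minC);
}
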
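# Independent brute-force oracles for the finite-difference operators and a
# 1D reference integrator, used to cross-check the vectorised/compiled paths.

oracle_laplacian <- function(C, dx) {
  n <- nrow(C); m <- ncol(C)
  refl <- function(i, k) if (i < 1) 2 else if (i > k) k - 1 else i
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      out[i, j] <- (C[refl(i - 1, n), j] + C[refl(i + 1, n), j] +
                    C[i, refl(j - 1, m)] + C[i, refl(j + 1, m)] -
                    4 * C[i, j]) / dx^2
    }
  }
  out
}

oracle_advection <- function(C, nu, dx) {
  n <- nrow(C); m <- ncol(C)
  refl <- function(i, k) if (i < 1) 2 else if (i > k) k - 1 else i
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      gx <- if (nu[1] > 0) {
        C[refl(i + 1, n), j] - C[i, j]
      } else {
        C[i, j] - C[refl(i - 1, n), j]
      }
      gy <- if (nu[2] > 0) {
        C[i, refl(j + 1, m)] - C[i, j]
      } else {
        C[i, j] - C[i, refl(j - 1, m)]
      }
      out[i, j] <- (if (nu[1] != 0) nu[1] * gx / dx else 0) +
        (if (nu[2] != 0) nu[2] * gy / dx else 0)
    }
  }
  out
}

# Explicit Euler integration of the 1D system (the y-invariant limit of the
# 2D model), same stencil and mirror ghosts, scalar parameters only.
oracle_1d <- function(x, dx, dt, n_steps, eps, rho0, kappa, gam, D, beta,
                      strip_halfwidth) {
  A <- as.numeric(abs(x) <= strip_halfwidth + 1e-12)
  C <- numeric(length(x))
  n <- length(x)
  im <- c(2, seq_len(n - 1)); ip <- c(seq_len(n - 1) + 1, n - 1)
  for (s in seq_len(n_steps)) {
    lap <- (C[im] + C[ip] - 2 * C) / dx^2
    src <- gam * A^2 / (beta^2 + A^2)
    A1 <- A + dt * (eps * C + rho0 * A - kappa * A^2)
    C1 <- C + dt * (D * lap - C + src)
    A <- A1; C <- C1
  }
  list(A = A, C = C)
}

# Small shared run objects for fast unit tests.
tiny_grid <- function() grid_spec(L = 1, dx = 0.1)
tiny_settings <- function(t_end = 1) {
  solver_settings(dt = 1e-3, t_end = t_end, record_interval = 0.1)
}
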
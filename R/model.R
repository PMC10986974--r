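#' Simulation grid
#'
#' A uniform square grid of nodes spanning \[-L, L\] in both axes with
#' spacing `dx`.  2L must be an integer multiple of `dx` (to tolerance) so
#' that the nodes land exactly on the domain boundary.
#'
#' @param L Half-width of the square domain (default 5).
#' @param dx Node spacing (default 0.1).
#'
#' @return A `grid_spec` with elements `L`, `dx`, `x`, `y` and `n` (nodes
#'   per side).
#' @export
grid_spec <- function(L = 5, dx = 0.1) {
  stopifnot(is.numeric(L), L > 0, is.numeric(dx), dx > 0)
  n_cells <- 2 * L / dx
  if (abs(n_cells - round(n_cells)) > 1e-8) {
    stop("2L must be an integer multiple of dx", call. = FALSE)
  }
  n <- as.integer(round(n_cells)) + 1L
  x <- seq(-L, L, length.out = n)
  structure(list(L = L, dx = dx, x = x, y = x, n = n), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> [", -x$L, ",", x$L, "]^2, dx =", x$dx,
      "->", x$n, "x", x$n, "nodes\n")
  invisible(x)
}

#' Model parameters
#'
#' Parameters of the coupled adult/potential biomass system.  `rho0`
#' (linear growth rate), `kappa` (crowding coefficient; carrying capacity is
#' rho0/kappa up to O(epsilon)) and `gamma` (fecundity scale of the seed
#' source) may each be either a scalar or an N x N `landscape_field`
#' matching the grid; `epsilon` (potential-to-adult transition rate), `D`
#' (diffusion coefficient of potential biomass), `beta_allee`
#' (half-saturation of the weak-Allee seed-production hill function) and
#' `nu` (advection velocity, zero by default) are scalars.
#'
#' Homogeneous defaults: epsilon 1e-2, rho0 = kappa = gamma = D = 1,
#' beta_allee 1, nu = (0, 0).
#'
#' @param epsilon Transition rate of potential to adult biomass (> 0, small).
#' @param rho0,kappa,gamma Scalars or `landscape_field` matrices.
#' @param D Diffusion coefficient (>= 0).
#' @param beta_allee Half-saturation of the seed-production hill function.
#' @param nu Length-2 advection velocity.
#'
#' @return A `model_params` list.
#' @export
model_params <- function(epsilon = 1e-2, rho0 = 1, kappa = 1, gamma = 1,
                         D = 1, beta_allee = 1, nu = c(0, 0)) {
  stopifnot(is.numeric(epsilon), epsilon > 0,
            is.numeric(D), D >= 0,
            is.numeric(beta_allee), beta_allee > 0,
            is.numeric(nu), length(nu) == 2)
  for (nm in c("kappa", "gamma")) {
    v <- get(nm)
    if (any(v <= 0)) stop("`", nm, "` must be strictly positive", call. = FALSE)
  }
  structure(list(epsilon = epsilon, rho0 = rho0, kappa = kappa,
                 gamma = gamma, D = D, beta_allee = beta_allee, nu = nu),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  fmt <- function(v) {
    if (is.matrix(v)) paste0("<field ", nrow(v), "x", ncol(v), ">") else v
  }
  cat("<model_params> epsilon =", x$epsilon,
      " rho0 =", fmt(x$rho0), " kappa =", fmt(x$kappa),
      " gamma =", fmt(x$gamma), "\n  D =", x$D,
      " beta_allee =", x$beta_allee, " nu = (",
      x$nu[1], ",", x$nu[2], ")\n")
  invisible(x)
}

# Expand a scalar-or-field parameter to a full matrix on the grid.
as_field <- function(v, n, name) {
  if (is.matrix(v)) {
    if (nrow(v) != n || ncol(v) != n) {
      stop("parameter field `", name, "` is ", nrow(v), "x", ncol(v),
           " but the grid has ", n, " nodes per side", call. = FALSE)
    }
    matrix(as.numeric(v), n, n)
  } else {
    matrix(v, n, n)
  }
}

check_same_shape <- function(A, C) {
  if (!identical(dim(A), dim(C))) {
    stop("fields have mismatched dimensions", call. = FALSE)
  }
}

#' Reaction term of the adult-biomass equation
#'
#' Pointwise rate epsilon*C + rho0*A - kappa*A^2.  With kappa = rho0 this is
#' the logistic form rho0*A*(1 - A) plus the epsilon*C recruitment term.
#'
#' @param A,C Adult and potential biomass matrices on the same grid.
#' @param params A [model_params] (fields must match the grid of `A`).
#' @return Matrix of dA/dt values.
#' @export
adult_reaction <- function(A, C, params) {
  check_same_shape(A, C)
  n <- nrow(A)
  rho0 <- as_field(params$rho0, n, "rho0")
  kappa <- as_field(params$kappa, n, "kappa")
  params$epsilon * C + rho0 * A - kappa * A^2
}

#' Seed-production source term
#'
#' The weak-Allee hill function gamma * A^2 / (beta_allee^2 + A^2):
#' per-capita seed output is suppressed at low adult density and saturates
#' at `gamma` for dense stands.
#'
#' @param A Adult biomass matrix.
#' @param params A [model_params].
#' @return Matrix of source values, in \[0, gamma).
#' @export
seed_source <- function(A, params) {
  n <- nrow(A)
  gamma <- as_field(params$gamma, n, "gamma")
  gamma * A^2 / (params$beta_allee^2 + A^2)
}

new_sim_state <- function(A, C, t, grid, source) {
  structure(list(A = A, C = C, t = t, grid = grid, source = source),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state> t =", x$t, " grid", x$grid$n, "x", x$grid$n,
      " max A =", signif(max(x$A), 4), "\n")
  invisible(x)
}

#' Central-strip initial condition
#'
#' Adult biomass at carrying capacity (A = 1) on the vertical strip
#' |x| <= L/n (the idealised shelterbelt source), zero elsewhere; potential
#' biomass zero everywhere.
#'
#' @param grid A [grid_spec].
#' @param n Strip divisor: the strip half-width is L/n (default 25, i.e.
#'   half-width 0.2 on the default domain).
#'
#' @return A `sim_state` at t = 0 with a `source` descriptor used by the
#'   distance metrics.
#' @export
strip_initial_condition <- function(grid, n = 25) {
  stopifnot(inherits(grid, "grid_spec"), is.numeric(n), n > 0)
  hw <- grid$L / n
  if (hw < grid$dx - 1e-12) {
    stop("strip half-width L/n = ", hw,
         " is narrower than one grid cell (dx = ", grid$dx, ")",
         call. = FALSE)
  }
  if (hw >= grid$L) {
    warning("strip covers the whole domain (L/n >= L)", call. = FALSE)
  }
  cols <- abs(grid$x) <= hw + 1e-12
  A <- matrix(0, grid$n, grid$n)
  A[cols, ] <- 1
  new_sim_state(A, matrix(0, grid$n, grid$n), 0, grid,
                source = list(type = "strip", halfwidth = hw))
}

#' Circular-blob initial condition
#'
#' Adult biomass at carrying capacity on nodes within `width / 2` of
#' `center`, zero elsewhere; potential biomass zero.  Used for the
#' advective, preferred-direction spread scenario.
#'
#' @param grid A [grid_spec].
#' @param center Length-2 centre coordinates (must lie inside the domain).
#' @param width Blob diameter (must exceed `dx` so at least one node is
#'   covered).
#'
#' @return A `sim_state` at t = 0.
#' @export
blob_initial_condition <- function(grid, center = c(0, 0), width = 0.4) {
  stopifnot(inherits(grid, "grid_spec"),
            is.numeric(center), length(center) == 2)
  if (any(abs(center) > grid$L)) {
    stop("blob `center` lies outside the domain", call. = FALSE)
  }
  if (!is.numeric(width) || width <= grid$dx) {
    stop("blob `width` must exceed the grid spacing", call. = FALSE)
  }
  r <- width / 2
  d2 <- outer((grid$x - center[1])^2, (grid$y - center[2])^2, "+")
  inside <- d2 <= r^2 + 1e-12
  if (!any(inside)) stop("blob contains no grid node", call. = FALSE)
  A <- matrix(0, grid$n, grid$n)
  A[inside] <- 1
  new_sim_state(A, matrix(0, grid$n, grid$n), 0, grid,
                source = list(type = "blob", center = center, radius = r))
}
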
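#' Solver settings
#'
#' Time-stepping and recording controls for the explicit finite-difference
#' integrator.  Defaults match the reference discretisation: dx = 0.1,
#' dt = 1e-3, integration to t = 10 with invasion metrics recorded every
#' 0.01 time units.
#'
#' @param dt Timestep.
#' @param t_end Final time (must be an integer multiple of `dt` to
#'   tolerance).
#' @param record_interval Metric-sampling period (an integer multiple of
#'   `dt`, at least `dt`).
#' @param snapshot_times Times at which full A/C fields are kept.
#'
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(dt = 1e-3, t_end = 10, record_interval = 1e-2,
                            snapshot_times = numeric(0)) {
  stopifnot(is.numeric(dt), dt > 0, is.numeric(t_end), t_end >= 0,
            is.numeric(record_interval), record_interval >= dt)
  for (v in list(t_end / dt, record_interval / dt)) {
    if (abs(v - round(v)) > 1e-6) {
      stop("`t_end` and `record_interval` must be integer multiples of `dt`",
           call. = FALSE)
    }
  }
  structure(list(dt = dt, t_end = t_end,
                 record_interval = record_interval,
                 snapshot_times = snapshot_times),
            class = "solver_settings")
}

# Reflected-index helpers: mirror ghost points (ghost = first interior
# neighbour) give a second-order zero-flux boundary.
idx_minus <- function(n) c(2L, seq_len(n - 1L))
idx_plus <- function(n) c(seq_len(n - 1L) + 1L, n - 1L)

#' Five-point Laplacian with zero-flux boundaries
#'
#' Second-order centred stencil
#' (C\[i+1,j\] + C\[i-1,j\] + C\[i,j+1\] + C\[i,j-1\] - 4 C\[i,j\]) / dx^2
#' with mirror ghost values on all four edges, enforcing a zero normal
#' derivative.
#'
#' @param C Numeric matrix, at least 3 x 3.
#' @param dx Grid spacing.
#' @return Matrix of the same shape.
#' @export
laplacian <- function(C, dx) {
  if (!is.matrix(C) || nrow(C) < 3 || ncol(C) < 3) {
    stop("`C` must be a matrix of at least 3x3", call. = FALSE)
  }
  im <- idx_minus(nrow(C)); ip <- idx_plus(nrow(C))
  jm <- idx_minus(ncol(C)); jp <- idx_plus(ncol(C))
  (C[im, ] + C[ip, ] + C[, jm] + C[, jp] - 4 * C) / dx^2
}

#' First-order upwind advective term
#'
#' Discretises the +nu.grad(C) term of the potential-biomass equation.  As
#' written that term transports mass toward -nu, so the upwind
#' (stability-preserving) difference looks toward +nu: a forward difference
#' for positive velocity components, backward for negative, with the same
#' mirror ghost values as the Laplacian at the edges.  Zero when nu is zero.
#'
#' @param C Numeric matrix.
#' @param nu Length-2 velocity.
#' @param dx Grid spacing.
#' @return Matrix of the same shape.
#' @export
advection <- function(C, nu, dx) {
  if (!is.matrix(C) || nrow(C) < 3 || ncol(C) < 3) {
    stop("`C` must be a matrix of at least 3x3", call. = FALSE)
  }
  out <- matrix(0, nrow(C), ncol(C))
  if (nu[1] != 0) {
    d <- if (nu[1] > 0) C[idx_plus(nrow(C)), ] - C else C - C[idx_minus(nrow(C)), ]
    out <- out + nu[1] * d / dx
  }
  if (nu[2] != 0) {
    d <- if (nu[2] > 0) C[, idx_plus(ncol(C))] - C else C - C[, idx_minus(ncol(C))]
    out <- out + nu[2] * d / dx
  }
  out
}

#' Timestep stability check
#'
#' Explicit-Euler admissibility of the settings for the given parameters:
#' the diffusion number 4 D dt / dx^2 must be below 1, the reaction number
#' dt (1 + max |rho0|) below 1, and, when advection is active, the Courant
#' number (|nu1| + |nu2|) dt / dx below 1.
#'
#' @param params A [model_params].
#' @param settings A [solver_settings].
#' @param dx Grid spacing.
#' @return A list with `ok` (logical) and a tibble `margins` of the three
#'   named numbers and their limits.  Never raises.
#' @export
stability_check <- function(params, settings, dx) {
  rho_max <- max(abs(params$rho0))
  checks <- tibble::tibble(
    condition = c("diffusion", "reaction", "advection"),
    value = c(4 * params$D * settings$dt / dx^2,
              settings$dt * (1 + rho_max),
              sum(abs(params$nu)) * settings$dt / dx),
    limit = 1
  )
  list(ok = all(checks$value < checks$limit), margins = checks)
}

#' Advance the state by one explicit Euler step
#'
#' Fully explicit update from the current fields:
#' A <- A + dt * (epsilon C + rho0 A - kappa A^2),
#' C <- C + dt * (D lap(C) + nu.grad(C) - C + seed source(A)).
#' Both updates read the same-step A and C.  This is the reference R
#' implementation of the update used (in compiled form) by
#' [simulate_invasion()].
#'
#' @param state A `sim_state`.
#' @param params A [model_params].
#' @param settings A [solver_settings].
#' @return The updated `sim_state` at t + dt.
#' @export
step_state <- function(state, params, settings) {
  A <- state$A; C <- state$C
  dx <- state$grid$dx; dt <- settings$dt
  dC <- params$D * laplacian(C, dx) + advection(C, params$nu, dx) -
    C + seed_source(A, params)
  A2 <- A + dt * adult_reaction(A, C, params)
  C2 <- C + dt * dC
  if (!all(is.finite(A2)) || !all(is.finite(C2))) {
    k <- which(!is.finite(A2) | !is.finite(C2))[1]
    stop("non-finite state at node ", k, ", t = ", state$t + dt,
         call. = FALSE)
  }
  new_sim_state(A2, C2, state$t + dt, state$grid, state$source)
}

#' Simulate an invasion
#'
#' Integrates the coupled system from the given initial state to
#' `settings$t_end` with the compiled explicit scheme, recording the
#' invasion metrics (mean and second central moment of the unsigned
#' distance of invaded nodes to the source, invaded fraction) every
#' `record_interval`, and keeping full field snapshots at
#' `settings$snapshot_times`.
#'
#' @param params A [model_params]; parameter fields must match the grid.
#' @param ic A `sim_state` from [strip_initial_condition()] or
#'   [blob_initial_condition()].
#' @param settings A [solver_settings].
#' @param threshold Invasion threshold T in (0, 1) (default 0.5).
#' @param distance Distance convention: `"edge"` (distance to the source
#'   boundary, zero inside — the default) or `"raw"` (|x| to the strip
#'   midline / radial distance to the blob centre).
#' @param check_stability Refuse inadmissible timesteps (default TRUE).
#'
#' @return An `invasion_run` with elements `trace` (tibble: `t`,
#'   `mean_distance`, `var_distance`, `invaded_fraction`), `state` (final
#'   `sim_state`), `snapshots` (list of `sim_state`), `min_A`/`min_C` (the
#'   smallest value either field took at any node and step, for positivity
#'   diagnostics), plus the inputs.
#' @export
simulate_invasion <- function(params, ic, settings = solver_settings(),
                              threshold = 0.5, distance = c("edge", "raw"),
                              check_stability = TRUE) {
  stopifnot(inherits(params, "model_params"), inherits(ic, "sim_state"),
            inherits(settings, "solver_settings"))
  distance <- match.arg(distance)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  grid <- ic$grid
  if (check_stability) {
    st <- stability_check(params, settings, grid$dx)
    if (!st$ok) {
      bad <- st$margins[st$margins$value >= st$margins$limit, ]
      stop("timestep fails the stability check (",
           paste(bad$condition, "=", signif(bad$value, 3), collapse = ", "),
           "; each must be < 1)", call. = FALSE)
    }
  }
  n <- grid$n
  n_steps <- as.integer(round(settings$t_end / settings$dt))
  rec_every <- as.integer(round(settings$record_interval / settings$dt))
  snap_steps <- as.integer(round(settings$snapshot_times / settings$dt))
  dist <- distance_field(grid, ic$source, convention = distance)

  res <- simulate_core(
    ic$A, ic$C,
    as_field(params$rho0, n, "rho0"),
    as_field(params$kappa, n, "kappa"),
    as_field(params$gamma, n, "gamma"),
    params$epsilon, params$D, params$beta_allee,
    params$nu[1], params$nu[2], grid$dx, settings$dt,
    n_steps, rec_every, dist, threshold, snap_steps)

  tr <- res$trace
  trace <- tibble::tibble(
    t = tr[, 1] * settings$dt,
    mean_distance = tr[, 2],
    var_distance = tr[, 3],
    invaded_fraction = tr[, 4]
  )
  snapshots <- vector("list", length(snap_steps))
  for (q in seq_along(snap_steps)) {
    snapshots[[q]] <- new_sim_state(res$snapA[[q]], res$snapC[[q]],
                                    snap_steps[q] * settings$dt,
                                    grid, ic$source)
  }
  structure(list(
    trace = trace,
    state = new_sim_state(res$A, res$C, n_steps * settings$dt, grid,
                          ic$source),
    snapshots = snapshots,
    min_A = res$minA, min_C = res$minC,
    params = params, settings = settings,
    threshold = threshold, distance = distance
  ), class = "invasion_run")
}

#' @export
print.invasion_run <- function(x, ...) {
  cat("<invasion_run> t_end =", x$state$t,
      " grid", x$state$grid$n, "x", x$state$grid$n,
      " invaded fraction =",
      signif(utils::tail(x$trace$invaded_fraction, 1), 4), "\n")
  invisible(x)
}
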
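#' Invaded-cell mask and fraction
#'
#' A grid node counts as invaded when its adult biomass strictly exceeds
#' the threshold T.  Working with per-cell occupancy avoids having to
#' identify an invasion front, which is ill-defined on a heterogeneous
#' landscape.
#'
#' @param A Adult-biomass matrix.
#' @param threshold T, strictly between 0 and 1.
#' @return `invaded_mask()`: a logical matrix; `invaded_fraction()`: the
#'   proportion of invaded nodes.
#' @export
invaded_mask <- function(A, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  A > threshold
}

#' @rdname invaded_mask
#' @export
invaded_fraction <- function(A, threshold = 0.5) {
  mean(invaded_mask(A, threshold))
}

#' Signed distance to the strip source
#'
#' Distance of a point to the nearest edge of the central strip, signed by
#' side: zero inside the strip, sign(x) * (|x| - halfwidth) outside.
#'
#' @param x x coordinate(s).
#' @param halfwidth Strip half-width L/n.
#' @return Signed distance(s).
#' @export
signed_distance <- function(x, halfwidth) {
  sign(x) * pmax(abs(x) - halfwidth, 0)
}

#' Unsigned distance of every grid node to the source
#'
#' For the strip source the distance depends on x only; for the blob it is
#' radial.  Under the default `"edge"` convention distance is measured to
#' the source boundary (zero inside); `"raw"` measures to the strip midline
#' or blob centre.
#'
#' @param grid A [grid_spec].
#' @param source Source descriptor from the initial-condition constructors.
#' @param convention `"edge"` or `"raw"`.
#' @return An n x n matrix of unsigned distances.
#' @export
distance_field <- function(grid, source, convention = c("edge", "raw")) {
  convention <- match.arg(convention)
  if (source$type == "strip") {
    dx_col <- if (convention == "edge") {
      abs(signed_distance(grid$x, source$halfwidth))
    } else {
      abs(grid$x)
    }
    matrix(dx_col, grid$n, grid$n)
  } else {
    r <- sqrt(outer((grid$x - source$center[1])^2,
                    (grid$y - source$center[2])^2, "+"))
    if (convention == "edge") pmax(r - source$radius, 0) else r
  }
}

#' Moments of the invaded-distance distribution
#'
#' Mean and second central moment of the unsigned distance to the source
#' over invaded nodes only.  Source nodes (distance zero) are included, so
#' with only the source invaded both moments are zero.
#'
#' @param A Adult-biomass matrix.
#' @param threshold Invasion threshold.
#' @param grid A [grid_spec].
#' @param source Source descriptor.
#' @param convention Distance convention, see [distance_field()].
#' @return A one-row tibble with `mean_distance`, `var_distance` and
#'   `invaded_fraction` (`NA` moments when no node is invaded).
#' @export
distance_moments <- function(A, threshold, grid, source,
                             convention = c("edge", "raw")) {
  mask <- invaded_mask(A, threshold)
  d <- distance_field(grid, source, match.arg(convention))[mask]
  if (length(d) == 0L) {
    return(tibble::tibble(mean_distance = NA_real_, var_distance = NA_real_,
                          invaded_fraction = 0))
  }
  m <- mean(d)
  tibble::tibble(mean_distance = m,
                 var_distance = mean((d - m)^2),
                 invaded_fraction = mean(mask))
}

#' Fit the piecewise-linear take-off model
#'
#' Least-squares fit of the hinge mu_hat(t) = max(0, intercept + slope * t)
#' to a mean-distance curve.  During the quiescent phase the mean distance
#' of invaded cells stays at (essentially) zero; once the solution locks
#' onto a travelling wave the mean grows linearly at half the wave speed,
#' so the fitted slope doubles to the spread rate and the hinge breakpoint
#' -intercept/slope estimates the onset of spatial spread.
#'
#' The fit is deterministic: candidate breakpoints are taken where the
#' curve first crosses each of 20 quantile levels of its range, a
#' one-parameter profile fit is solved in closed form at each candidate,
#' and the best candidate seeds a Nelder-Mead refinement of (intercept,
#' slope) on the exact hinge residual.
#'
#' @param times Sample times (at least 10, increasing).
#' @param mu Mean-distance values at `times` (NAs dropped pairwise).
#' @return A `spread_fit` with `intercept`, `slope`, `spread_rate`
#'   (2 * slope), `onset_time` (-intercept/slope clipped to the data span,
#'   `NA` when censored), `residual` (sum of squared errors), `status`
#'   (`"ok"` or `"no-takeoff"`), `t_end` and the data.
#' @export
fit_takeoff <- function(times, mu) {
  keep <- is.finite(times) & is.finite(mu)
  times <- times[keep]; mu <- mu[keep]
  if (length(times) < 10L) {
    stop("need at least 10 finite (time, mu) samples", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    o <- order(times)
    times <- times[o]; mu <- mu[o]
  }
  t_end <- max(times)

  mk <- function(intercept, slope, residual, status) {
    onset <- NA_real_
    if (status == "ok") {
      onset <- if (slope > 0) max(0, min(-intercept / slope, t_end)) else 0
    }
    structure(list(intercept = intercept, slope = slope,
                   spread_rate = if (status == "ok") 2 * slope else NA_real_,
                   onset_time = onset, residual = residual,
                   status = status, t_end = t_end,
                   data = tibble::tibble(t = times, mu = mu)),
              class = "spread_fit")
  }

  if (max(mu) <= 1e-6) {
    return(mk(NA_real_, NA_real_, sum(mu^2), "no-takeoff"))
  }

  sse <- function(p) sum((mu - pmax(0, p[1] + p[2] * times))^2)

  # candidate breakpoints: first crossing of each quantile level
  levels <- stats::quantile(mu[mu > 0], probs = seq(0.05, 1, length.out = 20),
                            names = FALSE)
  cand <- unique(vapply(levels, function(l) times[which(mu >= l)[1]],
                        numeric(1)))
  cand <- c(cand, min(times))
  best <- NULL
  for (tc in cand) {
    h <- pmax(times - tc, 0)
    s2 <- sum(h^2)
    if (s2 == 0) next
    b <- sum(mu * h) / s2           # profile slope for breakpoint tc
    p <- c(-b * tc, b)
    v <- sse(p)
    if (is.null(best) || v < best$v) best <- list(p = p, v = v)
  }
  # straight-line fit (hinge inactive) as a further candidate
  ols <- stats::lm.fit(cbind(1, times), mu)$coefficients
  if (sse(ols) < best$v) best <- list(p = unname(ols), v = sse(ols))

  opt <- stats::optim(best$p, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- if (opt$value < best$v) opt$par else best$p
  v <- min(opt$value, best$v)

  if (p[2] <= 0) return(mk(p[1], p[2], v, "no-takeoff"))
  mk(p[1], p[2], v, "ok")
}

#' Spread rate of a fitted take-off model
#'
#' The mean invaded distance advances at half the front speed, so the
#' spread rate is twice the fitted hinge slope.
#'
#' @param fit A `spread_fit`.
#' @return The spread rate s.  Errors for `no-takeoff` fits.
#' @export
spread_rate <- function(fit) {
  stopifnot(inherits(fit, "spread_fit"))
  if (fit$status != "ok") {
    stop("spread rate undefined: fit status is ", fit$status, call. = FALSE)
  }
  fit$spread_rate
}

#' Onset time of spatial spread
#'
#' The largest time at which the fitted hinge equals zero,
#' -intercept/slope, clipped to \[0, t_end\].  Fits with no take-off are
#' censored and reported as `"> t_end"`.
#'
#' @param fit A `spread_fit`.
#' @param t_end End of the observation window (defaults to the fit's).
#' @return A list with `value` (numeric, `NA` when censored), `censored`
#'   and `label` (e.g. `"8.33"` or `"> 10"`).
#' @export
onset_time <- function(fit, t_end = fit$t_end) {
  stopifnot(inherits(fit, "spread_fit"))
  if (fit$status != "ok") {
    return(list(value = NA_real_, censored = TRUE,
                label = paste(">", format(t_end))))
  }
  v <- max(0, min(-fit$intercept / fit$slope, t_end))
  list(value = v, censored = FALSE, label = format(round(v, 2)))
}

#' @export
print.spread_fit <- function(x, ...) {
  if (x$status == "ok") {
    cat("<spread_fit> s =", signif(x$spread_rate, 4),
        " onset =", signif(x$onset_time, 4),
        " SSE =", signif(x$residual, 4), "\n")
  } else {
    cat("<spread_fit> no take-off within the observation window\n")
  }
  invisible(x)
}

#' Tidy a take-off fit
#'
#' @param x A `spread_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity.
#' @export
tidy.spread_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope", "spread_rate", "onset_time"),
    estimate = c(x$intercept, x$slope, x$spread_rate, x$onset_time)
  )
}

#' Glance at a take-off fit
#'
#' @param x A `spread_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the headline statistics.
#' @export
glance.spread_fit <- function(x, ...) {
  tibble::tibble(
    spread_rate = x$spread_rate,
    onset_time = x$onset_time,
    intercept = x$intercept,
    slope = x$slope,
    residual = x$residual,
    status = x$status,
    nobs = nrow(x$data)
  )
}

#' Plot a take-off fit over its data
#'
#' @param object A `spread_fit`.
#' @param ... Unused.
#' @return A ggplot of the mean-distance curve with the fitted hinge.
#' @export
autoplot.spread_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mu)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t", y = "mean invaded distance")
  if (object$status == "ok") {
    df$fit <- pmax(0, object$intercept + object$slope * df$t)
    p <- p + ggplot2::geom_line(data = df,
                                ggplot2::aes(y = .data$fit),
                                colour = "red", linetype = 2)
  }
  p
}

#' Re-fit the take-off model to a recorded trace
#'
#' @param trace A trace tibble with columns `t` and `mean_distance` (as
#'   produced by [simulate_invasion()]), or an `invasion_run`.
#' @return A `spread_fit`.
#' @export
fit_trace <- function(trace) {
  if (inherits(trace, "invasion_run")) trace <- trace$trace
  fit_takeoff(trace$t, trace$mean_distance)
}
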
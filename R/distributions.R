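#' Distribution specifications for random landscapes
#'
#' A `dist_spec` describes the marginal distribution of the i.i.d. variates
#' on the raw lattice from which a smoothed parameter field is built.  Five
#' families are supported; the three named presets ([preset_truncnorm()],
#' [preset_uniform()], [preset_shifted_exp()]) all have expectation exactly 1
#' and support bounded below by 0.1, so that the smoothed fields they
#' generate are unit-mean and strictly positive.
#'
#' @param mean,sd Mean and standard deviation (normal family).
#' @param lower,upper Support bounds (uniform and truncated-normal families).
#' @param variance Variance of the parent normal before truncation.
#' @param exp_mean Mean of the exponential part of the shifted exponential.
#' @param shift Additive shift of the shifted exponential.
#' @param value The single support point of a point mass.
#'
#' @return An object of class `dist_spec`.
#' @name dist_spec
NULL

new_dist_spec <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "dist_spec")
}

chk_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("distribution parameter `", name, "` must be a finite number",
         call. = FALSE)
  }
  x
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean = 1, sd = 1) {
  chk_num(mean, "mean")
  if (chk_num(sd, "sd") <= 0) stop("`sd` must be positive", call. = FALSE)
  new_dist_spec("normal", mean = mean, sd = sd)
}

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(lower, upper, mean, variance) {
  chk_num(lower, "lower"); chk_num(upper, "upper"); chk_num(mean, "mean")
  if (lower >= upper) stop("`lower` must be less than `upper`", call. = FALSE)
  if (chk_num(variance, "variance") <= 0) {
    stop("`variance` must be positive", call. = FALSE)
  }
  new_dist_spec("truncnorm", lower = lower, upper = upper, mean = mean,
                variance = variance)
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(lower, upper) {
  chk_num(lower, "lower")
  if (chk_num(upper, "upper") <= lower) {
    stop("`lower` must be less than `upper`", call. = FALSE)
  }
  new_dist_spec("uniform", lower = lower, upper = upper)
}

#' @rdname dist_spec
#' @export
dist_shifted_exp <- function(exp_mean = 0.9, shift = 0.1) {
  if (chk_num(exp_mean, "exp_mean") <= 0) {
    stop("`exp_mean` must be positive", call. = FALSE)
  }
  chk_num(shift, "shift")
  new_dist_spec("shifted_exp", exp_mean = exp_mean, shift = shift)
}

#' @rdname dist_spec
#' @export
dist_point_mass <- function(value = 1) {
  chk_num(value, "value")
  new_dist_spec("point_mass", value = value)
}

#' Preset landscape distributions
#'
#' The three stock distributions used for the parameter-by-distribution
#' experiment grid.  Each has expectation 1 (so heterogeneous landscapes are
#' mean-equivalent to the homogeneous baseline) and support bounded below by
#' 0.1.  The truncated normal has parent mean 1 and parent variance 0.3,
#' truncated symmetrically to \[0.1, 1.9\]; the uniform covers \[0.1, 1.9\];
#' the shifted exponential is an exponential with mean 0.9 shifted up by 0.1.
#'
#' @return A `dist_spec`.
#' @export
preset_truncnorm <- function() dist_truncnorm(0.1, 1.9, 1, 0.3)

#' @rdname preset_truncnorm
#' @export
preset_uniform <- function() dist_uniform(0.1, 1.9)

#' @rdname preset_truncnorm
#' @export
preset_shifted_exp <- function() dist_shifted_exp(0.9, 0.1)

#' Theoretical mean of a distribution specification
#'
#' @param dist A [dist_spec].
#' @return The expectation of the distribution.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "dist_spec"))
  switch(dist$kind,
    normal = dist$mean,
    uniform = (dist$lower + dist$upper) / 2,
    shifted_exp = dist$exp_mean + dist$shift,
    point_mass = dist$value,
    truncnorm = {
      s <- sqrt(dist$variance)
      a <- (dist$lower - dist$mean) / s
      b <- (dist$upper - dist$mean) / s
      dist$mean + s * (stats::dnorm(a) - stats::dnorm(b)) /
        (stats::pnorm(b) - stats::pnorm(a))
    }
  )
}

#' Lower bound of the support of a distribution specification
#'
#' @param dist A [dist_spec].
#' @return The infimum of the support (`-Inf` for the unbounded normal).
#' @export
dist_support_min <- function(dist) {
  switch(dist$kind,
    normal = -Inf,
    uniform = dist$lower,
    truncnorm = dist$lower,
    shifted_exp = dist$shift,
    point_mass = dist$value
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<dist_spec> ", x$kind, "(",
      paste(names(pars), unlist(pars), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# n i.i.d. draws from a dist_spec using the current RNG stream.
draw_dist <- function(dist, n) {
  switch(dist$kind,
    normal = stats::rnorm(n, dist$mean, dist$sd),
    uniform = stats::runif(n, dist$lower, dist$upper),
    shifted_exp = dist$shift + stats::rexp(n, rate = 1 / dist$exp_mean),
    point_mass = rep(dist$value, n),
    truncnorm = {
      # inverse-CDF sampling of the truncated normal
      s <- sqrt(dist$variance)
      pa <- stats::pnorm(dist$lower, dist$mean, s)
      pb <- stats::pnorm(dist$upper, dist$mean, s)
      stats::qnorm(stats::runif(n, pa, pb), dist$mean, s)
    }
  )
}
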
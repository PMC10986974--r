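#' Specify a Monte Carlo landscape experiment
#'
#' One cell of the parameter-by-distribution experiment grid: a single
#' model parameter (`rho0`, `kappa` or `gamma`) is drawn afresh for each
#' replicate as a smoothed random field while the other parameters stay at
#' their homogeneous defaults.
#'
#' @param varying Which parameter varies: `"rho0"`, `"kappa"` or `"gamma"`.
#' @param dist A [dist_spec] for the raw lattice variates.
#' @param replicates Number of independent landscape realisations.
#' @param base_seed Integer; replicate k uses seed `base_seed + k`.
#' @param grid A [grid_spec].
#' @param params Baseline [model_params] for the non-varying constants.
#' @param settings A [solver_settings].
#' @param strip_n Strip divisor of the initial condition.
#' @param threshold Invasion threshold.
#'
#' @return An `experiment_spec`.
#' @export
experiment_spec <- function(varying = c("rho0", "kappa", "gamma"),
                            dist, replicates = 1000, base_seed = 1,
                            grid = grid_spec(), params = model_params(),
                            settings = solver_settings(), strip_n = 25,
                            threshold = 0.5) {
  varying <- match.arg(varying)
  stopifnot(inherits(dist, "dist_spec"),
            is.numeric(replicates), replicates >= 1,
            is.numeric(base_seed))
  structure(list(varying = varying, dist = dist,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), grid = grid,
                 params = params, settings = settings, strip_n = strip_n,
                 threshold = threshold),
            class = "experiment_spec")
}

#' Run a Monte Carlo landscape experiment
#'
#' Simulates `replicates` independent invasions, each on a fresh smoothed
#' random field for the varying parameter (replicate k seeded with
#' `base_seed + k`), and summarises the ensemble: the pointwise mean of the
#' per-replicate mean-distance curves, pointwise 2.5th/97.5th percentile
#' curves, the hinge fit to the ensemble-mean curve (the pooled point
#' estimate), per-replicate hinge fits, and 95% percentile intervals of the
#' per-replicate spread rates and onset times.  Onsets of replicates that
#' never take off are censored at `t_end` and propagate as `"> t_end"`.
#'
#' @param spec An [experiment_spec].
#' @param keep_traces Keep the per-replicate traces (default TRUE).
#' @param progress Print one line per replicate.
#'
#' @return An `ensemble_summary` with `curves` (tibble: `t`, `mean`,
#'   `lower`, `upper`), `pooled_fit`, `replicate_fits` (list),
#'   `replicate_stats` (tibble: replicate, seed, spread_rate, onset,
#'   censored), `rate_interval`, `onset_interval`, `onset_labels`, `spec`
#'   and optionally `traces`.
#' @export
run_experiment <- function(spec, keep_traces = TRUE, progress = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  ic <- strip_initial_condition(spec$grid, spec$strip_n)
  n_side <- spec$grid$n

  traces <- vector("list", spec$replicates)
  fits <- vector("list", spec$replicates)
  seeds <- spec$base_seed + seq_len(spec$replicates)
  for (k in seq_len(spec$replicates)) {
    field <- generate_field(spec$dist, n_side, seed = seeds[k])
    pars <- spec$params
    pars[[spec$varying]] <- field
    run <- simulate_invasion(pars, ic, spec$settings,
                             threshold = spec$threshold)
    traces[[k]] <- run$trace
    fits[[k]] <- fit_trace(run)
    if (progress) {
      message("replicate ", k, "/", spec$replicates, " (seed ", seeds[k],
              ")")
    }
  }

  tmat <- vapply(traces, function(tr) tr$mean_distance,
                 numeric(nrow(traces[[1]])))
  tmat <- matrix(tmat, nrow = nrow(traces[[1]]))
  curves <- tibble::tibble(
    t = traces[[1]]$t,
    mean = rowMeans(tmat),
    lower = apply(tmat, 1, stats::quantile, probs = 0.025),
    upper = apply(tmat, 1, stats::quantile, probs = 0.975)
  )
  pooled <- fit_takeoff(curves$t, curves$mean)

  onsets <- purrr::map(fits, onset_time)
  stats_tbl <- tibble::tibble(
    replicate = seq_len(spec$replicates),
    seed = seeds,
    spread_rate = purrr::map_dbl(fits, function(f) {
      if (f$status == "ok") f$spread_rate else NA_real_
    }),
    onset = purrr::map_dbl(onsets, "value"),
    censored = purrr::map_lgl(onsets, "censored")
  )

  t_end <- spec$settings$t_end
  rate_iv <- if (all(is.na(stats_tbl$spread_rate))) {
    c(NA_real_, NA_real_)
  } else {
    stats::quantile(stats_tbl$spread_rate, c(0.025, 0.975),
                    na.rm = TRUE, names = FALSE)
  }
  # censored onsets sort above t_end
  onset_sort <- ifelse(stats_tbl$censored, Inf, stats_tbl$onset)
  onset_iv <- stats::quantile(onset_sort, c(0.025, 0.975), names = FALSE,
                              type = 1)
  onset_labels <- vapply(onset_iv, function(v) {
    if (is.finite(v)) format(round(v, 2)) else paste(">", format(t_end))
  }, character(1))

  structure(list(
    curves = curves,
    pooled_fit = pooled,
    replicate_fits = fits,
    replicate_stats = stats_tbl,
    rate_interval = rate_iv,
    onset_interval = ifelse(is.finite(onset_iv), onset_iv, NA_real_),
    onset_censored = !is.finite(onset_iv),
    onset_labels = onset_labels,
    spec = spec,
    traces = if (keep_traces) traces
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  ot <- onset_time(x$pooled_fit)
  cat("<ensemble_summary>", x$spec$varying, "~", x$spec$dist$kind,
      "x", x$spec$replicates, "replicates\n",
      " pooled s =", signif(x$pooled_fit$spread_rate, 3),
      "[", paste(signif(x$rate_interval, 3), collapse = ", "), "]",
      " onset =", ot$label,
      "[", paste(x$onset_labels, collapse = ", "), "]\n")
  invisible(x)
}

#' Glance at an ensemble summary
#'
#' @param x An `ensemble_summary`.
#' @param ... Unused.
#' @return A one-row tibble with the pooled spread rate and onset and
#'   their 95% percentile intervals.
#' @export
glance.ensemble_summary <- function(x, ...) {
  ot <- onset_time(x$pooled_fit)
  tibble::tibble(
    varying = x$spec$varying,
    dist = x$spec$dist$kind,
    replicates = x$spec$replicates,
    spread_rate = x$pooled_fit$spread_rate,
    rate_lower = x$rate_interval[1],
    rate_upper = x$rate_interval[2],
    onset = ot$value,
    onset_lower = x$onset_interval[1],
    onset_upper = x$onset_interval[2],
    onset_label = ot$label,
    onset_interval_label = paste0("[", x$onset_labels[1], ", ",
                                  x$onset_labels[2], "]")
  )
}

#' Plot an ensemble's mean-distance curves
#'
#' @param object An `ensemble_summary`.
#' @param ... Unused.
#' @return A ggplot of the ensemble mean curve with its 95% interval band.
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "t", y = "mean invaded distance",
                  title = paste(object$spec$varying, "~",
                                object$spec$dist$kind))
}

#' Summary tables across experiment cells
#'
#' Collates a list of `ensemble_summary` objects into spread-rate and
#' onset-time tables: the point estimate is the hinge fit to the
#' ensemble-mean curve, brackets are 95% percentile intervals of the
#' per-replicate statistics, and censored onsets appear as `"> t_end"`.
#'
#' @param summaries A list of `ensemble_summary` objects (one per cell).
#' @return A list with tibbles `rates` and `onsets`, one row per cell.
#' @export
summarize_tables <- function(summaries) {
  rows <- purrr::map_dfr(summaries, glance)
  list(
    rates = dplyr::transmute(
      rows, .data$varying, .data$dist,
      estimate = .data$spread_rate,
      lower = .data$rate_lower, upper = .data$rate_upper,
      label = sprintf("%.2f [%.2f, %.2f]", .data$spread_rate,
                      .data$rate_lower, .data$rate_upper)
    ),
    onsets = dplyr::transmute(
      rows, .data$varying, .data$dist,
      estimate = .data$onset,
      lower = .data$onset_lower, upper = .data$onset_upper,
      label = paste0(.data$onset_label, " ", .data$onset_interval_label)
    )
  )
}

#' Compare an ensemble against a homogeneous baseline
#'
#' @param summary An `ensemble_summary`.
#' @param homogeneous An `invasion_run` (or its trace tibble) on the same
#'   recording grid.
#' @return A list with `curve_diff` (tibble of per-time mean-curve
#'   differences, ensemble minus homogeneous), `rate_diff` and
#'   `onset_diff`.
#' @export
compare_homogeneous <- function(summary, homogeneous) {
  stopifnot(inherits(summary, "ensemble_summary"))
  tr <- if (inherits(homogeneous, "invasion_run")) {
    homogeneous$trace
  } else {
    homogeneous
  }
  if (nrow(tr) != nrow(summary$curves) ||
      max(abs(tr$t - summary$curves$t)) > 1e-9) {
    stop("time grids of the ensemble and the baseline do not match",
         call. = FALSE)
  }
  hfit <- fit_takeoff(tr$t, tr$mean_distance)
  list(
    curve_diff = tibble::tibble(t = tr$t,
                                diff = summary$curves$mean -
                                  tr$mean_distance),
    rate_diff = summary$pooled_fit$spread_rate - hfit$spread_rate,
    onset_diff = onset_time(summary$pooled_fit)$value -
      onset_time(hfit)$value
  )
}
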
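#' Read and validate a run configuration
#'
#' Configurations are flat YAML or JSON maps.  Recognised keys (all
#' optional, with the package defaults): `epsilon`, `rho0`, `kappa`,
#' `gamma`, `D`, `beta_allee`, `nu` (length 2), `L`, `dx`, `dt`, `t_end`,
#' `record_interval`, `snapshot_times`, `threshold`, `ic` (`"strip"` or
#' `"blob"`), `strip_n`, `blob_center`, `blob_width`, `varying`, `dist`
#' (a map with `kind` and its parameters), `replicates`, `seed`.
#' A parameter among `rho0`/`kappa`/`gamma` may also be given as a path to
#' a field CSV.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list.
#' @return A validated `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(epsilon = 1e-2, rho0 = 1, kappa = 1, gamma = 1, D = 1,
       beta_allee = 1, nu = c(0, 0), L = 5, dx = 0.1, dt = 1e-3,
       t_end = 10, record_interval = 1e-2, snapshot_times = numeric(0),
       threshold = 0.5, ic = "strip", strip_n = 25,
       blob_center = c(0, 0), blob_width = 0.4, seed = 1)
}

validate_config <- function(cfg) {
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg),
                     c(names(defaults), "varying", "dist", "replicates"))
  problems <- character(0)
  if (length(unknown)) {
    problems <- c(problems, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, cfg[setdiff(names(cfg), "dist")])
  if (!is.null(cfg$dist)) out$dist <- cfg$dist
  if (!is.numeric(out$D) || out$D < 0) {
    problems <- c(problems, "`D` must be non-negative")
  }
  if (!is.numeric(out$threshold) || out$threshold <= 0 ||
      out$threshold >= 1) {
    problems <- c(problems, "`threshold` must lie strictly in (0, 1)")
  }
  if (!out$ic %in% c("strip", "blob")) {
    problems <- c(problems, "`ic` must be \"strip\" or \"blob\"")
  }
  if (out$ic == "strip" && is.numeric(out$strip_n) && out$strip_n <= 1) {
    problems <- c(problems, "`strip_n` must exceed 1 (strip wider than the domain)")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(out, class = "run_config")
}

config_to_objects <- function(cfg) {
  grid <- grid_spec(cfg$L, cfg$dx)
  for (nm in c("rho0", "kappa", "gamma")) {
    if (is.character(cfg[[nm]])) cfg[[nm]] <- read_field_csv(cfg[[nm]])
  }
  params <- model_params(epsilon = cfg$epsilon, rho0 = cfg$rho0,
                         kappa = cfg$kappa, gamma = cfg$gamma, D = cfg$D,
                         beta_allee = cfg$beta_allee, nu = cfg$nu)
  settings <- solver_settings(dt = cfg$dt, t_end = cfg$t_end,
                              record_interval = cfg$record_interval,
                              snapshot_times = cfg$snapshot_times)
  ic <- if (cfg$ic == "strip") {
    strip_initial_condition(grid, cfg$strip_n)
  } else {
    blob_initial_condition(grid, cfg$blob_center, cfg$blob_width)
  }
  list(grid = grid, params = params, settings = settings, ic = ic)
}

config_dist <- function(cfg) {
  d <- cfg$dist
  if (is.null(d)) stop("configuration lacks a `dist` entry", call. = FALSE)
  if (inherits(d, "dist_spec")) return(d)
  switch(d$kind,
    normal = dist_normal(d$mean %||% 1, d$sd %||% 1),
    truncnorm = dist_truncnorm(d$lower, d$upper, d$mean, d$variance),
    uniform = dist_uniform(d$lower, d$upper),
    shifted_exp = dist_shifted_exp(d$exp_mean %||% 0.9, d$shift %||% 0.1),
    point_mass = dist_point_mass(d$value %||% 1),
    stop("unknown distribution kind: ", d$kind, call. = FALSE)
  )
}

write_manifest <- function(out_dir, cfg, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("landspread")),
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      unname(tools::md5sum(f))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Run a single invasion from a configuration
#'
#' Simulates one invasion (generating the varying-parameter field first
#' when the configuration names one), writes the metric trace, the hinge
#' fit, any snapshots and a manifest with per-file checksums to `out_dir`,
#' and returns the run.
#'
#' @param config Path to a config file or a named list (see
#'   [read_config()]).
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return A list with `run` (`invasion_run`), `fit` (`spread_fit`) and
#'   `files`.
#' @export
run_single <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  if (!is.null(cfg$varying)) {
    grid <- grid_spec(cfg$L, cfg$dx)
    cfg[[cfg$varying]] <- generate_field(config_dist(cfg), grid$n,
                                         seed = cfg$seed)
  }
  obj <- config_to_objects(cfg)
  run <- simulate_invasion(obj$params, obj$ic, obj$settings,
                           threshold = cfg$threshold)
  fit <- fit_trace(run)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    trace_file <- file.path(out_dir, "trace.csv")
    utils::write.csv(run$trace, trace_file, row.names = FALSE)
    fit_file <- file.path(out_dir, "fit.json")
    ot <- onset_time(fit)
    jsonlite::write_json(
      list(intercept = fit$intercept, slope = fit$slope,
           spread_rate = fit$spread_rate, onset_time = ot$value,
           onset_label = ot$label, residual = fit$residual,
           status = fit$status),
      fit_file, auto_unbox = TRUE, digits = NA, null = "null",
      na = "null")
    files <- c(trace_file, fit_file)
    for (snap in run$snapshots) {
      f <- file.path(out_dir, sprintf("snapshot_A_t%s.csv",
                                      format(snap$t)))
      write_field_csv(snap$A, f, grid = snap$grid)
      files <- c(files, f)
    }
    write_manifest(out_dir, cfg, files)
  }
  list(run = run, fit = fit, files = files)
}

#' Run the full parameter-by-distribution experiment grid
#'
#' Runs one Monte Carlo ensemble per requested (parameter, distribution)
#' cell and collates the spread-rate and onset tables.  Completed cells are
#' written to disk as they finish (curves CSV plus a cell summary JSON);
#' when `resume = TRUE`, cells whose summary file already exists are
#' reloaded instead of recomputed.
#'
#' @param varying Parameters to vary (default all three).
#' @param dists Named list of [dist_spec]s (default the three presets).
#' @param replicates Replicates per cell.
#' @param base_seed Base seed; cell i uses `base_seed + 10000 * i`.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param grid,params,settings,strip_n,threshold Shared run components.
#' @param resume Reuse completed cells found in `out_dir`.
#' @param progress Print per-replicate progress.
#' @return A list with `summaries` (list of `ensemble_summary` or reloaded
#'   cell records) and `tables` (from [summarize_tables()], cells run in
#'   this session only when resuming reloads).
#' @export
run_grid <- function(varying = c("rho0", "kappa", "gamma"),
                     dists = list(truncnorm = preset_truncnorm(),
                                  uniform = preset_uniform(),
                                  shifted_exp = preset_shifted_exp()),
                     replicates = 1000, base_seed = 1, out_dir = NULL,
                     grid = grid_spec(), params = model_params(),
                     settings = solver_settings(), strip_n = 25,
                     threshold = 0.5, resume = TRUE, progress = FALSE) {
  cells <- expand.grid(varying = varying, dist = names(dists),
                       stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  summaries <- vector("list", nrow(cells))
  fresh <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tag <- paste(cells$varying[i], cells$dist[i], sep = "_")
    cell_json <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0("cell_", tag, ".json"))
    }
    if (resume && !is.null(cell_json) && file.exists(cell_json)) {
      summaries[[i]] <- jsonlite::read_json(cell_json,
                                            simplifyVector = TRUE)
      next
    }
    spec <- experiment_spec(cells$varying[i], dists[[cells$dist[i]]],
                            replicates = replicates,
                            base_seed = base_seed + 10000L * i,
                            grid = grid, params = params,
                            settings = settings, strip_n = strip_n,
                            threshold = threshold)
    sm <- run_experiment(spec, keep_traces = FALSE, progress = progress)
    summaries[[i]] <- sm
    fresh[i] <- TRUE
    if (!is.null(out_dir)) {
      utils::write.csv(sm$curves,
                       file.path(out_dir, paste0("curves_", tag, ".csv")),
                       row.names = FALSE)
      g <- glance(sm)
      jsonlite::write_json(as.list(g), cell_json, auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null")
    }
  }
  run_now <- summaries[fresh]
  tables <- if (length(run_now)) summarize_tables(run_now)
  if (!is.null(out_dir) && !is.null(tables)) {
    utils::write.csv(tables$rates, file.path(out_dir, "rates.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$onsets, file.path(out_dir, "onsets.csv"),
                     row.names = FALSE)
  }
  list(summaries = summaries, tables = tables)
}

#' Run the advective blob scenario
#'
#' Blob initial condition with an advective velocity in the
#' potential-biomass equation, producing preferred-direction spread over a
#' random landscape.  The as-written form of the advective term (+nu.grad C)
#' transports mass toward -nu; set `flip_advection = TRUE` to reverse it.
#'
#' @param config Path or named list, as [read_config()] (should set
#'   `ic: blob` and a non-zero `nu`; defaults are filled in otherwise).
#' @param out_dir Output directory or `NULL`.
#' @param flip_advection Reverse the advection sign convention.
#' @return As [run_single()].
#' @export
run_advective <- function(config = list(), out_dir = NULL,
                          flip_advection = FALSE) {
  cfg <- read_config(config)
  if (is.null(config$ic)) cfg$ic <- "blob"
  if (flip_advection) cfg$nu <- -cfg$nu
  run_single(unclass(cfg), out_dir = out_dir)
}

#' Centroid of the invaded region
#'
#' @param A Adult-biomass matrix.
#' @param grid A [grid_spec].
#' @param threshold Invasion threshold.
#' @return Length-2 (x, y) centroid of invaded nodes (`NA` if none).
#' @export
invaded_centroid <- function(A, grid, threshold = 0.5) {
  mask <- invaded_mask(A, threshold)
  if (!any(mask)) return(c(NA_real_, NA_real_))
  idx <- which(mask, arr.ind = TRUE)
  c(mean(grid$x[idx[, 1]]), mean(grid$y[idx[, 2]]))
}
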
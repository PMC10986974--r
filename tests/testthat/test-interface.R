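tiny_cfg <- function(...) {
  utils::modifyList(
    list(L = 2, dx = 0.1, dt = 1e-3, t_end = 1, record_interval = 0.05,
         strip_n = 10, seed = 3),
    list(...))
}

test_that("configuration validation reports offending fields", {
  expect_error(read_config(tiny_cfg(D = -1)), "`D`")
  expect_error(read_config(tiny_cfg(threshold = 1.5)), "threshold")
  expect_error(read_config(tiny_cfg(ic = "ring")), "strip")
  expect_error(read_config(tiny_cfg(strip_n = 0.5)), "strip_n")
  expect_error(read_config(tiny_cfg(bogus_key = 1)), "unknown key")
  # several problems are reported together
  err <- tryCatch(read_config(tiny_cfg(D = -1, threshold = 2)),
                  error = conditionMessage)
  expect_match(err, "`D`")
  expect_match(err, "threshold")
})

test_that("config files round-trip through YAML and JSON", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cfg(varying = "rho0",
                  dist = list(kind = "uniform", lower = 0.1, upper = 1.9))
  yml <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  a <- read_config(yml)
  b <- read_config(jsn)
  expect_equal(a$dist$kind, "uniform")
  expect_equal(a$t_end, b$t_end)
  expect_equal(landspread:::config_dist(a), dist_uniform(0.1, 1.9))
})

test_that("run_single writes trace, fit and a checksum manifest deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- tiny_cfg(varying = "rho0",
                  dist = list(kind = "normal", mean = 1, sd = 1))
  r1 <- run_single(cfg, out_dir = dir1)
  r2 <- run_single(cfg, out_dir = dir2)

  expect_true(file.exists(file.path(dir1, "trace.csv")))
  expect_true(file.exists(file.path(dir1, "fit.json")))
  m1 <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                            simplifyVector = TRUE)
  m2 <- jsonlite::read_json(file.path(dir2, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(m1$files, m2$files)  # identical checksums
  expect_equal(r1$run$trace, r2$run$trace)

  fit <- jsonlite::read_json(file.path(dir1, "fit.json"),
                             simplifyVector = TRUE)
  expect_true(fit$status %in% c("ok", "no-takeoff"))
})

test_that("run_single refuses configurations that fail the stability check", {
  expect_error(run_single(tiny_cfg(dt = 5e-3, record_interval = 5e-3)),
               "stability")
})

test_that("run_grid runs cells, writes tables and resumes from disk", {
  dir <- withr::local_tempdir()
  out <- run_grid(varying = "rho0",
                  dists = list(pm = dist_point_mass(1)),
                  replicates = 2, base_seed = 5, out_dir = dir,
                  grid = grid_spec(L = 2, dx = 0.1),
                  settings = solver_settings(dt = 1e-3, t_end = 1,
                                             record_interval = 0.05),
                  strip_n = 10)
  expect_true(file.exists(file.path(dir, "cell_rho0_pm.json")))
  expect_true(file.exists(file.path(dir, "curves_rho0_pm.csv")))

  # resuming reloads the finished cell instead of recomputing
  t0 <- Sys.time()
  again <- run_grid(varying = "rho0",
                    dists = list(pm = dist_point_mass(1)),
                    replicates = 2, base_seed = 5, out_dir = dir,
                    grid = grid_spec(L = 2, dx = 0.1),
                    settings = solver_settings(dt = 1e-3, t_end = 1,
                                               record_interval = 0.05),
                    strip_n = 10)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(again$summaries[[1]]$replicates,
               glance(out$summaries[[1]])$replicates)
})

test_that("advective runs displace the invasion along the transport direction", {
  base <- tiny_cfg(ic = "blob", blob_center = c(0, 0), blob_width = 0.4,
                   t_end = 5, epsilon = 0.5)
  T <- 0.3

  still <- run_advective(base)
  # nu = 0: identical to a plain blob run
  plain <- run_single(base)
  expect_equal(still$run$state$A, plain$run$state$A)

  g <- grid_spec(L = 2, dx = 0.1)
  east <- run_advective(utils::modifyList(base, list(nu = c(1, 0))))
  west <- run_advective(utils::modifyList(base, list(nu = c(-1, 0))))
  c0 <- invaded_centroid(still$run$state$A, g, T)
  ce <- invaded_centroid(east$run$state$A, g, T)
  cw <- invaded_centroid(west$run$state$A, g, T)

  # the as-written +nu.grad(C) form transports mass toward -nu
  expect_lt(ce[1], c0[1] - 0.05)
  expect_gt(cw[1], c0[1] + 0.05)
  # reflecting nu mirrors the invaded mask in x (homogeneous landscape)
  me <- invaded_mask(east$run$state$A, T)
  mw <- invaded_mask(west$run$state$A, T)
  expect_equal(me, mw[rev(seq_len(nrow(mw))), ])

  # flip flag reverses the convention
  east_flipped <- run_advective(utils::modifyList(base, list(nu = c(1, 0))),
                                flip_advection = TRUE)
  expect_equal(invaded_centroid(east_flipped$run$state$A, g, T)[1], cw[1])
})
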
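test_that("lattice draws honour the distribution, the seed and the support", {
  # degenerate point mass
  lat <- draw_lattice(dist_point_mass(1), 4, seed = 1)
  expect_equal(unclass(lat), matrix(1, 4, 4), ignore_attr = TRUE)

  # shifted exponential support bound
  lat <- draw_lattice(preset_shifted_exp(), 30, seed = 2)
  expect_gte(min(lat), 0.1)

  # truncated normal bounds
  lat <- draw_lattice(preset_truncnorm(), 50, seed = 3)
  expect_gte(min(lat), 0.1)
  expect_lte(max(lat), 1.9)

  # uniform(0.1, 1.9): sample mean within 3 SE of 1, SE = sqrt(0.27)/500
  lat <- draw_lattice(preset_uniform(), 500, seed = 4)
  expect_lt(abs(mean(lat) - 1), 3 * sqrt(0.27) / 500)

  # identical seed => identical lattice; different seed => different
  expect_identical(draw_lattice(dist_normal(), 10, seed = 7),
                   draw_lattice(dist_normal(), 10, seed = 7))
  expect_false(identical(draw_lattice(dist_normal(), 10, seed = 7),
                         draw_lattice(dist_normal(), 10, seed = 8)))
})

test_that("invalid distribution parameters are refused by name", {
  expect_error(dist_uniform(2, 1), "lower")
  expect_error(dist_truncnorm(0.1, 1.9, 1, -1), "variance")
  expect_error(dist_normal(1, 0), "sd")
  expect_error(dist_shifted_exp(-1), "exp_mean")
  expect_error(draw_lattice(dist_normal(), 2), "n_points")
})

test_that("preset distributions have expectation 1 and bounded support", {
  for (d in list(preset_truncnorm(), preset_uniform(), preset_shifted_exp())) {
    expect_equal(dist_mean(d), 1, tolerance = 1e-12)
    expect_equal(dist_support_min(d), 0.1)
  }
})

test_that("3x3 smoothing has the exact averaging structure", {
  # averaging identity on a constant lattice
  expect_equal(unclass(smooth_lattice(matrix(1, 6, 6))),
               matrix(1, 4, 4), ignore_attr = TRUE)

  # single-impulse response: value 9 at an interior entry spreads a plateau
  # of ones over exactly the output points whose window contains it
  lat <- matrix(0, 7, 7)
  lat[4, 4] <- 9
  f <- smooth_lattice(lat)
  expect_equal(dim(f), c(5L, 5L))
  expect_equal(sum(f == 1), 9)
  expect_equal(sum(f), 9)
  expect_true(all(f[2:4, 2:4] == 1))

  # equality with a brute-force double loop on a random lattice
  set.seed(11)
  lat <- matrix(rnorm(49), 7, 7)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) ref[i, j] <- mean(lat[i:(i + 2), j:(j + 2)])
  expect_equal(unclass(smooth_lattice(lat)), ref, ignore_attr = TRUE)

  expect_error(smooth_lattice(matrix(0, 2, 2)), "side")
})

test_that("smoothing is linear", {
  set.seed(21)
  l1 <- matrix(rnorm(36), 6, 6)
  l2 <- matrix(rnorm(36), 6, 6)
  expect_equal(unclass(smooth_lattice(2 * l1 - 3 * l2)),
               unclass(2 * smooth_lattice(l1) - 3 * smooth_lattice(l2)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("smoothed normal fields have pointwise sd 1/3 and lag-1 correlation 2/3", {
  # pointwise sd: 2e4 independent centre values of 3x3-averaged N(1,1)
  set.seed(31)
  centres <- replicate(2e4, mean(rnorm(9, 1, 1)))
  expect_equal(sd(centres), 1 / 3, tolerance = 0.02)

  # one large field: horizontally adjacent windows share 6 of 9 variates
  f <- generate_field(dist_normal(1, 1), 250, seed = 32)
  fs <- field_summary(f)
  expect_equal(fs$lag1_cor, 2 / 3, tolerance = 0.03)
  expect_equal(fs$mean, 1, tolerance = 5 * 3 * (1 / 3) / 250)
  expect_equal(fs$sd, 1 / 3, tolerance = 0.02)
})

test_that("bounded sources yield bounded, reproducible fields", {
  f <- generate_field(preset_truncnorm(), 40, seed = 5)
  expect_gte(min(f), 0.1)
  expect_lte(max(f), 1.9)
  expect_identical(f, generate_field(preset_truncnorm(), 40, seed = 5))

  # point mass reproduces the homogeneous landscape
  expect_equal(unclass(generate_field(dist_point_mass(1), 10, seed = 1)),
               matrix(1, 10, 10), ignore_attr = TRUE)
})

test_that("field_summary handles degenerate and structured fields", {
  cs <- field_summary(matrix(3, 5, 5))
  expect_equal(cs$mean, 3)
  expect_equal(cs$sd, 0)
  expect_true(is.na(cs$lag1_cor))

  checker <- outer(1:6, 1:6, function(i, j) (-1)^(i + j))
  expect_equal(field_summary(checker)$mean, 0)

  expect_error(field_summary(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("fields round-trip through CSV with metadata sidecar", {
  f <- generate_field(preset_uniform(), 12, seed = 9)
  path <- file.path(withr::local_tempdir(), "field.csv")
  write_field_csv(f, path)
  back <- read_field_csv(path)
  expect_equal(unclass(back), unclass(f), ignore_attr = TRUE,
               tolerance = 1e-12)
  meta <- jsonlite::read_json(sub("csv$", "json", path),
                              simplifyVector = TRUE)
  expect_equal(meta$side, 12)
  expect_equal(meta$seed, 9)
  expect_equal(meta$dist$kind, "uniform")
})
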
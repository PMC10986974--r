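#' Draw a raw lattice of i.i.d. variates
#'
#' Generates the (N + 2) x (N + 2) lattice of independent draws from which a
#' smoothed parameter field is constructed.  The two extra rows and columns
#' are consumed by the 3x3 averaging in [smooth_lattice()], so an
#' `n_points`-sided lattice yields an `(n_points - 2)`-sided field.
#'
#' @param dist A [dist_spec] giving the marginal distribution.
#' @param n_points Side length of the lattice (at least 3).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return A `raw_lattice`: a numeric matrix with attributes `dist` and
#'   `seed`.
#' @export
draw_lattice <- function(dist, n_points, seed = NULL) {
  stopifnot(inherits(dist, "dist_spec"))
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 3) {
    stop("`n_points` must be a single integer >= 3", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  vals <- with_seed(seed, draw_dist(dist, n_points * n_points))
  structure(matrix(vals, n_points, n_points),
            dist = dist, seed = seed, class = c("raw_lattice", "matrix"))
}

#' Smooth a raw lattice into a landscape field
#'
#' Each field value is the arithmetic mean of the 3x3 neighbourhood of raw
#' lattice variates centred on the corresponding interior lattice point, so
#' an (N + 2)-sided lattice produces an N-sided field.  For i.i.d. unit-mean
#' sources this produces a unit-mean field whose pointwise standard
#' deviation is one third of the source's and whose horizontally adjacent
#' values have correlation 2/3 (adjacent windows share six of nine
#' variates).
#'
#' @param lattice A numeric matrix with side length at least 3 (typically a
#'   `raw_lattice`).
#'
#' @return A `landscape_field`: a numeric matrix two rows and columns
#'   smaller than the input.
#' @export
smooth_lattice <- function(lattice) {
  if (!is.matrix(lattice) || !is.numeric(lattice)) {
    stop("`lattice` must be a numeric matrix", call. = FALSE)
  }
  m <- nrow(lattice)
  if (m < 3 || ncol(lattice) != m) {
    stop("`lattice` must be square with side >= 3", call. = FALSE)
  }
  n <- m - 2L
  # sum of the 9 shifted copies, divided by 9
  acc <- matrix(0, n, n)
  for (di in 0:2) {
    for (dj in 0:2) {
      acc <- acc + lattice[di + seq_len(n), dj + seq_len(n)]
    }
  }
  structure(acc / 9, dist = attr(lattice, "dist"),
            seed = attr(lattice, "seed"),
            class = c("landscape_field", "matrix"))
}

#' Generate a spatially correlated parameter field
#'
#' Composes [draw_lattice()] and [smooth_lattice()]: an
#' `(grid_side + 2)`-sided lattice of i.i.d. draws is averaged over 3x3
#' neighbourhoods to give a `grid_side`-sided field aligned with the
#' simulation grid (field point (i, j) sits on grid node (x_i, y_j)).
#'
#' @param dist A [dist_spec].
#' @param grid_side Side length N of the field.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A `landscape_field` matrix of size `grid_side` x `grid_side`.
#' @export
generate_field <- function(dist, grid_side, seed = NULL) {
  smooth_lattice(draw_lattice(dist, grid_side + 2L, seed = seed))
}

#' Summary statistics of a landscape field
#'
#' @param field A numeric matrix (typically a `landscape_field`).
#' @return A one-row tibble with the field side length, mean, standard
#'   deviation, min, max and the lag-1 (horizontal-neighbour) correlation
#'   (`NA` for constant fields, where it is undefined).
#' @export
field_summary <- function(field) {
  if (!is.matrix(field) || length(field) == 0L) {
    stop("`field` must be a non-empty numeric matrix", call. = FALSE)
  }
  v <- as.vector(field)
  lag1 <- NA_real_
  if (ncol(field) >= 2 && stats::sd(v) > 0) {
    a <- as.vector(field[, -ncol(field)])
    b <- as.vector(field[, -1])
    if (stats::sd(a) > 0 && stats::sd(b) > 0) lag1 <- stats::cor(a, b)
  }
  tibble::tibble(
    side = nrow(field),
    mean = mean(v),
    sd = stats::sd(v),
    min = min(v),
    max = max(v),
    lag1_cor = lag1
  )
}

#' Write or read a landscape field as CSV
#'
#' Fields are stored transposed so that CSV rows run along the y axis and
#' columns along the x axis, with a header row of x coordinates when a grid
#' is supplied.  A JSON sidecar (same path with extension `.json`) records
#' the distribution, seed and side length.
#'
#' @param field A `landscape_field` or plain numeric matrix.
#' @param path Output CSV path.
#' @param grid Optional [grid_spec] supplying the x coordinates used as the
#'   CSV header.
#' @return `write_field_csv()` returns `path` invisibly; `read_field_csv()`
#'   returns the field matrix (x along rows, y along columns).
#' @export
write_field_csv <- function(field, path, grid = NULL) {
  hdr <- if (!is.null(grid)) grid$x else seq_len(nrow(field))
  m <- t(field)
  colnames(m) <- format(hdr, trim = TRUE)
  utils::write.csv(m, path, row.names = FALSE)
  meta <- list(side = nrow(field), seed = attr(field, "seed"))
  d <- attr(field, "dist")
  if (!is.null(d)) meta$dist <- unclass(d)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  structure(t(unname(m)), class = c("landscape_field", "matrix"))
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
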
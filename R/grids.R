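#' Georeferenced raster grid
#'
#' `env_grid()` wraps a numeric matrix with a simple geographic lattice:
#' the upper-left corner (`origin_lon`, `origin_lat`), a square cell size in
#' decimal degrees, and `NA` entries marking no-data cells. Row 1 is the
#' northernmost row; column 1 is the westernmost column.
#'
#' Cells are half-open: a point with longitude `lon` falls in column
#' `floor((lon - origin_lon) / cellsize) + 1`, and likewise for rows counted
#' down from `origin_lat`, so points exactly on a shared edge belong to the
#' higher-index cell.
#'
#' @param values Numeric matrix; `NA` marks no-data.
#' @param origin_lon,origin_lat Upper-left corner, decimal degrees.
#' @param cellsize Cell edge, decimal degrees (2.5 arc-minutes = 2.5/60).
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, origin_lon = 0, origin_lat = 0,
                     cellsize = 2.5 / 60) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)))
    stop("grid values must be finite or NA", call. = FALSE)
  structure(
    list(values = values,
         origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cellsize = as.numeric(cellsize)),
    class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf(
    "<env_grid> %d x %d cells, %.4f deg (%.2f arc-min), origin (%.4f, %.4f)\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$cellsize * 60,
    x$origin_lon, x$origin_lat))
  nv <- sum(!is.na(x$values))
  cat(sprintf("  valid cells: %d / %d\n", nv, length(x$values)))
  invisible(x)
}

#' @export
dim.env_grid <- function(x) dim(x$values)

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)

#' Test whether two grids share the same lattice
#' @param a,b `env_grid` objects.
#' @param tol Tolerance on origin/cellsize comparison, degrees.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_misaligned <- function(a, b) {
  if (!same_geometry(a, b))
    stop("grids do not share the same geometry (dims/origin/cellsize)",
         call. = FALSE)
  invisible(TRUE)
}

#' Row/column index of the cell containing each point
#'
#' Half-open cell convention: `row = floor((origin_lat - lat)/cellsize) + 1`,
#' `col = floor((lon - origin_lon)/cellsize) + 1`; points on a shared edge
#' fall in the higher-index cell.
#'
#' @param grid An `env_grid`.
#' @param lon,lat Numeric vectors, decimal degrees.
#' @return A tibble with columns `row`, `col`, `inside`.
#' @export
cell_of <- function(grid, lon, lat) {
  row <- floor((grid$origin_lat - lat) / grid$cellsize) + 1
  col <- floor((lon - grid$origin_lon) / grid$cellsize) + 1
  inside <- row >= 1 & row <= grid_nrow(grid) & col >= 1 & col <= grid_ncol(grid)
  tibble::tibble(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Longitude/latitude of cell centres
#' @param grid An `env_grid`.
#' @param row,col Integer vectors of 1-based indices.
#' @return A tibble with columns `lon`, `lat`.
#' @export
cell_center <- function(grid, row, col) {
  tibble::tibble(
    lon = grid$origin_lon + (col - 0.5) * grid$cellsize,
    lat = grid$origin_lat - (row - 0.5) * grid$cellsize)
}

#' Stack of aligned raster layers
#'
#' A named, ordered collection of [env_grid()] layers sharing one lattice.
#' The effective no-data mask of the stack is the union of the layers' masks.
#'
#' @param layers Named list of `env_grid` objects.
#' @return An object of class `grid_stack`.
#' @export
grid_stack <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty named list of env_grid objects",
         call. = FALSE)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layer names must be present and unique", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), what = "env_grid")
  if (!all(ok)) stop("all layers must be env_grid objects", call. = FALSE)
  for (i in seq_along(layers)[-1]) stop_if_misaligned(layers[[1]], layers[[i]])
  structure(list(layers = layers), class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<grid_stack> %d layer(s): %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(g)
  invisible(x)
}

#' @export
names.grid_stack <- function(x) names(x$layers)

#' Shared valid-cell mask of a stack (logical matrix; TRUE = valid)
#' @param stack A `grid_stack`.
#' @return Logical matrix.
#' @export
stack_valid_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]]$values)
  for (g in stack$layers[-1]) m <- m & !is.na(g$values)
  m
}

#' Extract layer values at point locations
#'
#' Values are taken from the cell containing each point (nearest-cell, no
#' interpolation). Points on a no-data cell yield `NA` values and
#' `missing = TRUE`; points outside the grid extent are an error.
#'
#' @param stack A `grid_stack` (or single `env_grid`).
#' @param points Data frame with `lon` and `lat` columns, decimal degrees.
#' @return A tibble: one row per point with `lon`, `lat`, one column per
#'   layer, and a logical `missing` flag.
#' @export
extract_values <- function(stack, points) {
  if (inherits(stack, "env_grid")) stack <- grid_stack(list(layer = stack))
  stopifnot(inherits(stack, "grid_stack"))
  pts <- as.data.frame(points)
  if (!all(c("lon", "lat") %in% names(pts)))
    stop("`points` must have `lon` and `lat` columns", call. = FALSE)
  g <- stack$layers[[1]]
  idx <- cell_of(g, pts$lon, pts$lat)
  if (any(!idx$inside)) {
    bad <- which(!idx$inside)
    stop(sprintf("point(s) outside grid extent at index: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  lin <- cbind(idx$row, idx$col)
  out <- tibble::tibble(lon = pts$lon, lat = pts$lat)
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]]$values[lin]
  vals <- as.matrix(out[names(stack$layers)])
  out$missing <- apply(is.na(vals), 1L, any)
  out
}

#' Sample random points over the valid cells of a grid
#'
#' Cells are drawn uniformly among valid (non-`NA`) cells, then each point is
#' jittered uniformly within its cell, so the draw is uniform over the lattice
#' in lon/lat. Reproducible for a given `seed`.
#'
#' @param mask_grid An `env_grid`; `NA` cells are excluded.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return A tibble with columns `lon`, `lat`, `row`, `col`.
#' @export
sample_random_points <- function(mask_grid, n, seed = 1L) {
  stopifnot(inherits(mask_grid, "env_grid"))
  valid <- which(!is.na(mask_grid$values))
  if (length(valid) == 0L)
    stop("mask grid has no valid cells", call. = FALSE)
  withr::local_seed(seed)
  pick <- valid[sample.int(length(valid), n, replace = TRUE)]
  nr <- grid_nrow(mask_grid)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  u <- stats::runif(n)
  v <- stats::runif(n)
  tibble::tibble(
    lon = mask_grid$origin_lon + (col - 1 + u) * mask_grid$cellsize,
    lat = mask_grid$origin_lat - (row - 1 + v) * mask_grid$cellsize,
    row = as.integer(row), col = as.integer(col))
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

pairwise_km <- function(lon, lat) {
  m <- geosphere::distm(cbind(lon, lat), fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371))
  m
}
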
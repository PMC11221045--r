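#' Categorical benthoscape raster
#'
#' A `bentho_raster` is a square-celled categorical grid in planar metre
#' coordinates holding substrate class codes 0-4 plus `NA` for nodata cells.
#' Row 1 of the value matrix is the *southernmost* row (south-up); file
#' readers convert from north-up formats on the way in. Cells are half-open
#' intervals `[x0, x0 + cell)` x `[y0, y0 + cell)`, so every in-bounds point
#' maps to exactly one cell and points on shared edges are assigned
#' deterministically.
#'
#' @param values Integer matrix (`n_rows` x `n_cols`), row 1 = south; values
#'   must be declared class codes (0-4) or `NA` for nodata.
#' @param origin_x,origin_y Coordinates (m) of the south-west corner.
#' @param cell_size Cell edge length in metres; must be > 0.
#' @return An object of class `bentho_raster`.
#' @export
#' @examples
#' r <- bentho_raster(matrix(c(0L, 1L, 2L, 3L), 2, 2), 0, 0, 10)
#' extract_class(r, 5, 5)
bentho_raster <- function(values, origin_x = 0, origin_y = 0, cell_size = 1) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    abort("`cell_size` must be a single positive number (metres)")
  }
  codes <- substrate_classes()$code
  bad <- setdiff(unique(values[!is.na(values)]), codes)
  if (length(bad) > 0) {
    abort(paste0("unknown class code(s) in raster: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
         n_rows = nrow(values), n_cols = ncol(values)),
    class = "bentho_raster"
  )
}

#' @export
print.bentho_raster <- function(x, ...) {
  cat("<bentho_raster> ", x$n_rows, " x ", x$n_cols, " cells, ",
      x$cell_size, " m cells, origin (", x$origin_x, ", ", x$origin_y, ")\n",
      sep = "")
  tab <- table(substrate_factor(as.vector(x$values)))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

raster_xmax <- function(r) r$origin_x + r$n_cols * r$cell_size
raster_ymax <- function(r) r$origin_y + r$n_rows * r$cell_size

# TRUE for points inside the half-open extent
raster_contains <- function(r, x, y) {
  x >= r$origin_x & x < raster_xmax(r) & y >= r$origin_y & y < raster_ymax(r)
}

# vectorised coordinate -> (row, col); assumes in bounds
raster_cell <- function(r, x, y) {
  list(row = floor((y - r$origin_y) / r$cell_size) + 1L,
       col = floor((x - r$origin_x) / r$cell_size) + 1L)
}

#' Extract the substrate class at point coordinates
#'
#' Maps each `(x, y)` to the cell containing it under the half-open cell
#' convention and returns the class as a factor over the full substrate
#' level set (including `nodata`).
#'
#' @param raster A [bentho_raster()].
#' @param x,y Numeric vectors of coordinates in metres.
#' @return A factor of substrate levels, one per point.
#' @export
extract_class <- function(raster, x, y) {
  stopifnot(inherits(raster, "bentho_raster"), length(x) == length(y))
  inside <- raster_contains(raster, x, y)
  if (!all(inside)) {
    i <- which(!inside)[1]
    abort(sprintf(
      "point (%g, %g) is outside raster bounds [%g, %g) x [%g, %g)",
      x[i], y[i], raster$origin_x, raster_xmax(raster),
      raster$origin_y, raster_ymax(raster)))
  }
  rc <- raster_cell(raster, x, y)
  substrate_factor(raster$values[cbind(rc$row, rc$col)])
}

# centre coordinates of every cell, as a tibble (x, y, class_code)
raster_cells <- function(r) {
  cx <- r$origin_x + (seq_len(r$n_cols) - 0.5) * r$cell_size
  cy <- r$origin_y + (seq_len(r$n_rows) - 0.5) * r$cell_size
  tibble::tibble(
    x = rep(cx, each = r$n_rows),
    y = rep(cy, times = r$n_cols),
    code = as.vector(r$values)
  )
}

#' Simple planar polygon
#'
#' A closed, non-self-intersecting polygon in metre coordinates, used as a
#' region of interest (for example the positioning-array footprint).
#' Vertices are given unclosed; the closing edge is implicit.
#'
#' @param x,y Numeric vertex coordinates (at least 3, not collinear).
#' @return An object of class `bs_polygon`: a two-column matrix with
#'   attribute `area`.
#' @export
bs_polygon <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("a polygon needs at least 3 vertices")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  a <- polygon_area(x, y)
  if (abs(a) < .Machine$double.eps * max(abs(c(x, y, 1)))^2) {
    abort("polygon has zero area (collinear vertices)")
  }
  if (polygon_self_intersects(x, y)) abort("polygon is self-intersecting")
  structure(cbind(x = x, y = y), class = "bs_polygon", area = abs(a))
}

# shoelace signed area
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# O(n^2) proper-crossing check between non-adjacent edges
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  j <- c(2:n, 1L)
  seg <- cbind(x, y, x[j], y[j])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (a in seq_len(n - 2)) {
    for (b in (a + 2):n) {
      if (a == 1 && b == n) next  # adjacent through the closing edge
      p <- seg[a, ]; q <- seg[b, ]
      d1 <- cross(p[3] - p[1], p[4] - p[2], q[1] - p[1], q[2] - p[2])
      d2 <- cross(p[3] - p[1], p[4] - p[2], q[3] - p[1], q[4] - p[2])
      d3 <- cross(q[3] - q[1], q[4] - q[2], p[1] - q[1], p[2] - q[2])
      d4 <- cross(q[3] - q[1], q[4] - q[2], p[3] - q[1], p[4] - q[2])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' @rdname bs_polygon
#' @param wkt A WKT string of the form `POLYGON((x y, x y, ...))`.
#' @export
polygon_from_wkt <- function(wkt) {
  m <- regmatches(wkt, regexec("POLYGON\\s*\\(\\(([^)]*)\\)\\)", wkt))[[1]]
  if (length(m) < 2) abort("cannot parse WKT polygon")
  xy <- do.call(rbind, lapply(strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+"),
                              as.numeric))
  bs_polygon(xy[, 1], xy[, 2])
}

# point-in-polygon for a matrix of points; delegates to mgcv's ray test
points_in_polygon <- function(poly, x, y) {
  bnd <- rbind(unclass(poly), unclass(poly)[1, , drop = FALSE])
  mgcv::in.out(bnd, cbind(x, y))
}

#' Class availability within a region
#'
#' Tabulates the fraction of raster cells whose *centres* fall inside a
#' polygon, by substrate class. `nodata` is reported as its own level.
#' These availability fractions are the denominator side of any
#' use-availability comparison.
#'
#' @param raster A [bentho_raster()].
#' @param region A [bs_polygon()]; if `NULL`, the full raster extent.
#' @return A tibble with columns `class`, `n_cells`, `proportion`
#'   (proportions sum to 1).
#' @export
class_proportions <- function(raster, region = NULL) {
  stopifnot(inherits(raster, "bentho_raster"))
  cells <- raster_cells(raster)
  if (!is.null(region)) {
    stopifnot(inherits(region, "bs_polygon"))
    keep <- points_in_polygon(region, cells$x, cells$y)
    cells <- cells[keep, , drop = FALSE]
  }
  if (nrow(cells) == 0) abort("region covers no raster cell centres")
  cls <- substrate_factor(cells$code)
  tab <- table(cls)
  tibble::tibble(
    class = factor(names(tab), levels = substrate_levels()),
    n_cells = as.integer(tab),
    proportion = as.numeric(tab) / sum(tab)
  )
}
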
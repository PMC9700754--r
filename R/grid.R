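#' Georeferenced single-band raster grid
#'
#' The central data container of the package: a rectangular 2-D numeric array
#' with north-up row order (row 1 is the northern edge), the map coordinates
#' of the top-left (north-west) corner, a square cell size in map units and a
#' free-text CRS label. Nodata is represented internally as `NA`; a finite
#' sentinel is only used on disk (see [write_raster()]). Nodata cells never
#' contribute to any statistic computed by the package.
#'
#' A cell covers the half-open box `[x, x + cell) x (y - cell, y]` where
#' `(x, y)` is its top-left corner. Two grids are *co-registered* iff their
#' shape, origin, cell size and CRS label all agree.
#'
#' @param values numeric matrix (row 1 = north). `NA` marks nodata.
#' @param origin_x,origin_y map coordinates of the top-left corner.
#' @param cell_size positive cell edge length in map units.
#' @param crs free-text CRS identifier, e.g. `"EPSG:32650"`.
#' @return an object of class `eco_grid`.
#' @export
eco_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                     cell_size = 1, crs = "local") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
         crs = as.character(crs)),
    class = "eco_grid")
}

#' @export
print.eco_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eco_grid> %d x %d cells, cell %g, origin (%g, %g), crs %s\n",
              nrow(v), ncol(v), x$cell_size, x$origin_x, x$origin_y, x$crs))
  nv <- sum(!is.na(v))
  if (nv > 0)
    cat(sprintf("  valid %d/%d, range [%g, %g]\n", nv, length(v),
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  else cat("  all nodata\n")
  invisible(x)
}

#' @export
dim.eco_grid <- function(x) dim(x$values)

#' Test whether two grids share the same georeferencing
#'
#' @param a,b `eco_grid` (or categorical grid) objects.
#' @param tol relative tolerance on origin/cell comparisons.
#' @return logical.
#' @export
is_coregistered <- function(a, b, tol = 1e-9) {
  identical(dim(grid_values(a)), dim(grid_values(b))) &&
    abs(a$origin_x - b$origin_x) <= tol * max(1, abs(a$cell_size)) &&
    abs(a$origin_y - b$origin_y) <= tol * max(1, abs(a$cell_size)) &&
    abs(a$cell_size - b$cell_size) <= tol * a$cell_size &&
    identical(a$crs, b$crs)
}

stop_unless_coregistered <- function(..., what = "grids") {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!is_coregistered(gs[[1]], gs[[i]]))
      stop(sprintf("%s are not co-registered (layer %d differs in shape, origin, cell size or crs)",
                   what, i))
  invisible(TRUE)
}

grid_values <- function(g) {
  if (inherits(g, "eco_catgrid")) g$codes else g$values
}

#' Replace the value matrix of a grid, keeping its georeferencing
#' @param g template `eco_grid`.
#' @param values new matrix of matching shape.
#' @return `eco_grid`.
#' @export
grid_like <- function(g, values) {
  stopifnot(identical(dim(values), dim(grid_values(g))))
  eco_grid(values, g$origin_x, g$origin_y, g$cell_size, g$crs)
}

#' Map cell-centre coordinates of a grid
#'
#' @param g an `eco_grid`.
#' @return list with vectors `x` (west to east) and `y` (north to south).
#' @export
grid_centres <- function(g) {
  d <- dim(grid_values(g))
  list(x = g$origin_x + (seq_len(d[2]) - 0.5) * g$cell_size,
       y = g$origin_y - (seq_len(d[1]) - 0.5) * g$cell_size)
}

#' Ordered stack of co-registered grids
#'
#' @param layers list of `eco_grid`s sharing georeferencing.
#' @param names unique labels, one per layer.
#' @return object of class `eco_stack`.
#' @export
eco_stack <- function(layers, names = NULL) {
  if (length(layers) == 0L) stop("stack must contain at least one layer")
  if (is.null(names)) names <- paste0("layer", seq_along(layers))
  if (anyDuplicated(names)) stop("layer names must be unique")
  if (length(names) != length(layers)) stop("one name per layer required")
  do.call(stop_unless_coregistered, c(layers, list(what = "stack layers")))
  structure(list(layers = stats::setNames(layers, names), names = names),
            class = "eco_stack")
}

#' @export
length.eco_stack <- function(x) length(x$layers)

#' Categorical (integer-coded) raster with a legend
#'
#' Same georeferencing model as [eco_grid()] but holding integer class codes
#' (e.g. IGBP land-cover codes) plus a legend mapping codes to labels. Every
#' non-nodata code must appear in the legend.
#'
#' @param codes integer matrix; `NA` marks nodata.
#' @param legend named character vector; names are the codes as strings.
#' @param origin_x,origin_y,cell_size,crs as in [eco_grid()].
#' @return object of class `eco_catgrid`.
#' @export
eco_catgrid <- function(codes, legend = NULL, origin_x = 0,
                        origin_y = nrow(codes) * cell_size, cell_size = 1,
                        crs = "local") {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  present <- sort(unique(codes[!is.na(codes)]))
  if (is.null(legend))
    legend <- stats::setNames(as.character(present), as.character(present))
  missing <- setdiff(as.character(present), names(legend))
  if (length(missing))
    stop("codes absent from legend: ", paste(missing, collapse = ", "))
  structure(
    list(codes = codes, legend = legend, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
         crs = as.character(crs)),
    class = "eco_catgrid")
}

#' @export
print.eco_catgrid <- function(x, ...) {
  cat(sprintf("<eco_catgrid> %d x %d cells, cell %g, %d classes\n",
              nrow(x$codes), ncol(x$codes), x$cell_size, length(x$legend)))
  invisible(x)
}

#' @export
dim.eco_catgrid <- function(x) dim(x$codes)
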
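#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Rasters are stored as plain-text ESRI ASCII grids (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`) followed by the cell values, northern
#' row first. A sidecar `<path>.prj`, when present, supplies the CRS label.
#' Cells equal to the file's nodata sentinel come back as `NA` and are
#' excluded from all downstream statistics.
#'
#' @param path path to an `.asc` file.
#' @return an [eco_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, n = 6L, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    key <- tolower(parts[1])
    if (length(parts) == 2L &&
        key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value") &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ASCII grid raster (bad or missing header): ", path)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cell <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - cell / 2
  else stop("not an ASCII grid raster (no x origin): ", path)
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - cell / 2
  else stop("not an ASCII grid raster (no y origin): ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop(sprintf("raster %s: expected %d cells, found %d (multi-band or truncated file?)",
                 path, nrows * ncols, length(vals)))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) trimws(readLines(prj, n = 1L, warn = FALSE)) else "local"
  eco_grid(m, origin_x = xll, origin_y = yll + nrows * cell,
           cell_size = cell, crs = crs)
}

#' Write a grid to an ESRI ASCII grid file
#'
#' Values are written with full double precision so that
#' `read_raster(write_raster(g))` round-trips bit-exactly; `NA` cells are
#' written as the nodata sentinel (and `NaN` values are mapped to nodata as
#' well). A `<path>.prj` sidecar records the CRS label.
#'
#' @param grid an [eco_grid()] or [eco_catgrid()].
#' @param path output path (`.asc` conventional).
#' @param nodata finite sentinel stored in the file. Must not collide with a
#'   valid cell value.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  v <- grid_values(grid)
  v[is.nan(v)] <- NA
  if (any(v == nodata, na.rm = TRUE))
    stop("nodata sentinel ", nodata, " collides with a valid cell value")
  d <- dim(v)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.17g", grid$origin_x),
    sprintf("yllcorner %.17g", grid$origin_y - d[1] * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write raster: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}

#' Read a categorical raster plus optional legend sidecar
#'
#' @param path `.asc` file of integer codes; if `<path>.legend.csv` exists
#'   (columns `code,label`) it supplies the legend.
#' @return an [eco_catgrid()].
#' @export
read_catraster <- function(path) {
  g <- read_raster(path)
  leg_path <- paste0(path, ".legend.csv")
  legend <- NULL
  if (file.exists(leg_path)) {
    tab <- utils::read.csv(leg_path, stringsAsFactors = FALSE)
    legend <- stats::setNames(as.character(tab$label), as.character(tab$code))
  }
  eco_catgrid(round(g$values), legend = legend, origin_x = g$origin_x,
              origin_y = g$origin_y, cell_size = g$cell_size, crs = g$crs)
}

#' Write a categorical raster and its legend sidecar
#' @param grid an [eco_catgrid()].
#' @param path output `.asc` path; legend goes to `<path>.legend.csv`.
#' @param nodata sentinel code on disk.
#' @return `path`, invisibly.
#' @export
write_catraster <- function(grid, path, nodata = -9999) {
  write_raster(grid, path, nodata = nodata)
  utils::write.csv(
    data.frame(code = names(grid$legend), label = unname(grid$legend)),
    paste0(path, ".legend.csv"), row.names = FALSE)
  invisible(path)
}
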
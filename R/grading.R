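rsei_grade_legend <- c("1" = "poor", "2" = "fair", "3" = "moderate",
                       "4" = "good", "5" = "excellent")

#' Classify an RSEI layer into five ecological-quality grades
#'
#' Fixed 0.2-wide bins: poor \[0, 0.2), fair \[0.2, 0.4), moderate
#' \[0.4, 0.6), good \[0.6, 0.8), excellent \[0.8, 1.0\]. Bins are
#' left-closed/right-open with the final bin closed, so every value in
#' \[0, 1\] receives exactly one grade and 1.0 is "excellent".
#'
#' @param rsei [eco_grid()] with valid values in \[0, 1\] (a small numeric
#'   tolerance is allowed and clipped).
#' @param tol tolerance for values marginally outside \[0, 1\].
#' @return an [eco_catgrid()] with codes 1-5 and the grade legend.
#' @export
grade_rsei <- function(rsei, tol = 1e-8) {
  v <- rsei$values
  if (any(v < -tol | v > 1 + tol, na.rm = TRUE))
    stop("grade_rsei: values outside [0, 1] beyond tolerance")
  v[!is.na(v) & v < 0] <- 0
  v[!is.na(v) & v > 1] <- 1
  # findInterval keeps values exactly on a cut in the upper bin, so 0.2/0.4/
  # 0.6/0.8 start their grades and 1.0 stays "excellent"
  codes <- matrix(findInterval(v, c(0.2, 0.4, 0.6, 0.8)) + 1L,
                  nrow(v), ncol(v))
  codes[is.na(v)] <- NA
  eco_catgrid(codes, legend = rsei_grade_legend, origin_x = rsei$origin_x,
              origin_y = rsei$origin_y, cell_size = rsei$cell_size,
              crs = rsei$crs)
}

points_in_polygon <- function(px, py, poly) {
  bnd <- as.matrix(poly[, c("x", "y")])
  if (!isTRUE(all.equal(bnd[1, ], bnd[nrow(bnd), ], check.attributes = FALSE)))
    bnd <- rbind(bnd, bnd[1, ])
  mgcv::in.out(bnd, cbind(px, py))
}

#' Read region polygons from a CSV vertex table
#'
#' Plain-text polygon exchange format: columns `region`, `x`, `y`, one row
#' per vertex in ring order per region.
#'
#' @param path CSV path.
#' @return named list of data frames with columns `x`, `y`.
#' @export
read_regions_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "x", "y") %in% names(tab)))
    stop("region CSV needs columns region, x, y")
  split(tab[, c("x", "y")], tab$region)
}

#' Grade-area statistics, optionally per region polygon
#'
#' For the whole grid (or for each polygon, with membership decided by the
#' cell-centre-in-polygon rule) counts valid pixels per grade and reports the
#' area (`count * cell_size^2`) and the percentage of valid pixels; the five
#' percentages sum to 100 within each region. A region containing no valid
#' pixel is reported with `NA` percentages.
#'
#' @param grades a [eco_catgrid()] from [grade_rsei()].
#' @param regions `NULL` for whole-grid statistics, or a named list of
#'   polygons (data frames with columns `x`, `y` in the grid's CRS).
#' @return data frame with columns `region`, `grade`, `label`, `count`,
#'   `area`, `percent`.
#' @export
grade_area_table <- function(grades, regions = NULL) {
  codes <- grades$codes
  ctr <- grid_centres(grades)
  px <- rep(ctr$x, each = nrow(codes))
  py <- rep(ctr$y, times = ncol(codes))
  membership <- if (is.null(regions)) list(all = rep(TRUE, length(codes)))
  else lapply(regions, function(pg) points_in_polygon(px, py, pg))
  cell_area <- grades$cell_size^2
  grade_codes <- sort(as.integer(names(grades$legend)))
  rows <- lapply(names(membership), function(rn) {
    inside <- membership[[rn]]
    cc <- codes[inside]
    cc <- cc[!is.na(cc)]
    counts <- vapply(grade_codes, function(g) sum(cc == g), integer(1))
    total <- sum(counts)
    data.frame(region = rn, grade = grade_codes,
               label = unname(grades$legend[as.character(grade_codes)]),
               count = counts, area = counts * cell_area,
               percent = if (total > 0) 100 * counts / total else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grade-difference change detection between two epochs
#'
#' Per pixel, the sign of `later - earlier` grade: +1 improved, 0 unchanged,
#' -1 declined; nodata in either epoch yields nodata. Also returns the
#' percentage of valid pixels in each change class (summing to 100).
#'
#' @param earlier,later co-registered grade maps ([eco_catgrid()]).
#' @return list with `map` (an `eco_catgrid` coded -1/0/+1) and `table`
#'   (data frame `change`, `count`, `percent`).
#' @export
change_detect <- function(earlier, later) {
  stop_unless_coregistered(earlier, later, what = "grade maps")
  d <- sign(later$codes - earlier$codes)
  map <- eco_catgrid(d, legend = c("-1" = "declined", "0" = "unchanged",
                                   "1" = "improved"),
                     origin_x = earlier$origin_x, origin_y = earlier$origin_y,
                     cell_size = earlier$cell_size, crs = earlier$crs)
  dd <- d[!is.na(d)]
  counts <- c(declined = sum(dd == -1), unchanged = sum(dd == 0),
              improved = sum(dd == 1))
  tab <- data.frame(change = names(counts), count = as.integer(counts),
                    percent = if (length(dd) > 0) 100 * counts / length(dd)
                    else NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(map = map, table = tab)
}
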
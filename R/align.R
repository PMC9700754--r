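#' Resample a grid onto the georeferencing of a template
#'
#' `nearest` assigns each template cell the value of the source cell whose
#' half-open box contains the template cell centre. `mean` aggregates: each
#' template cell receives the mean of all source cells whose centres fall
#' inside it, ignoring nodata. Both grids must already share a CRS;
#' reprojection between coordinate systems is out of scope (inputs are
#' expected in a single projected CRS, e.g. one UTM zone).
#'
#' @param grid source [eco_grid()].
#' @param template [eco_grid()] supplying the target georeferencing.
#' @param method `"nearest"` or `"mean"`.
#' @return an `eco_grid` co-registered with `template`.
#' @export
align_to <- function(grid, template, method = c("nearest", "mean")) {
  method <- match.arg(method)
  if (!identical(grid$crs, template$crs))
    stop("align_to: CRS mismatch ('", grid$crs, "' vs '", template$crs,
         "'); reprojection is not supported")
  sv <- grid$values
  td <- dim(template$values)
  if (method == "nearest") {
    ctr <- grid_centres(template)
    sc <- floor((ctr$x - grid$origin_x) / grid$cell_size) + 1L
    sr <- floor((grid$origin_y - ctr$y) / grid$cell_size) + 1L
    sc[sc < 1L | sc > ncol(sv)] <- NA_integer_
    sr[sr < 1L | sr > nrow(sv)] <- NA_integer_
    if (all(is.na(sc)) || all(is.na(sr)))
      stop("align_to: grids do not overlap")
    idx <- outer(sr, sc, function(r, c) (c - 1L) * nrow(sv) + r)
    out <- matrix(sv[as.vector(idx)], nrow = td[1], ncol = td[2])
  } else {
    ctr <- grid_centres(grid)
    tc <- floor((ctr$x - template$origin_x) / template$cell_size) + 1L
    tr <- floor((template$origin_y - ctr$y) / template$cell_size) + 1L
    tc[tc < 1L | tc > td[2]] <- NA_integer_
    tr[tr < 1L | tr > td[1]] <- NA_integer_
    rr <- rep(tr, times = ncol(sv))
    cc <- rep(tc, each = nrow(sv))
    keep <- !is.na(rr) & !is.na(cc) & !is.na(sv)
    if (!any(!is.na(rr) & !is.na(cc)))
      stop("align_to: grids do not overlap")
    out <- matrix(NA_real_, td[1], td[2])
    if (any(keep)) {
      tgt <- (cc[keep] - 1L) * td[1] + rr[keep]
      sums <- rowsum(as.vector(sv)[keep], tgt)
      cnts <- rowsum(rep(1, sum(keep)), tgt)
      out[as.integer(rownames(sums))] <- sums / cnts
    }
  }
  eco_grid(out, template$origin_x, template$origin_y, template$cell_size,
           template$crs)
}

#' Per-pixel temporal median composite with optional QA rejection masks
#'
#' Emulates the standard quality-controlled compositing of a within-season
#' image time series: per pixel, the median of the layer values that are
#' neither nodata nor rejected by the matching QA mask (nonzero mask value =
#' reject). An even count of survivors yields the midpoint of the two central
#' values; a pixel with no survivors becomes nodata.
#'
#' @param stack an [eco_stack()] of co-registered epoch layers.
#' @param qa_masks optional [eco_stack()] of the same length; nonzero = reject.
#' @return an `eco_grid` composite.
#' @export
temporal_median_composite <- function(stack, qa_masks = NULL) {
  if (!inherits(stack, "eco_stack")) stop("stack must be an eco_stack")
  n <- length(stack)
  if (n == 0L) stop("empty stack")
  g1 <- stack$layers[[1]]
  if (!is.null(qa_masks)) {
    if (length(qa_masks) != n)
      stop("qa_masks must have one layer per stack layer")
    stop_unless_coregistered(g1, qa_masks$layers[[1]], what = "qa masks")
  }
  d <- dim(g1$values)
  arr <- array(unlist(lapply(seq_len(n), function(i) {
    v <- stack$layers[[i]]$values
    if (!is.null(qa_masks)) {
      m <- qa_masks$layers[[i]]$values
      v[!is.na(m) & m != 0] <- NA_real_
      v[is.na(m)] <- NA_real_
    }
    v
  })), dim = c(d[1], d[2], n))
  out <- apply(arr, c(1, 2), function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0L) NA_real_ else stats::median(z)
  })
  grid_like(g1, out)
}
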
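#' Polygon area by the shoelace formula
#'
#' @param xy two-column matrix of ordered vertices.
#' @return signed-magnitude (absolute) area in vertex units squared.
#' @export
polygonArea <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("degenerate polygon: need at least 3 vertices")
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter (closed arc length)
#'
#' @param xy two-column matrix of ordered vertices.
#' @return perimeter in vertex units.
#' @export
polygonPerimeter <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("degenerate polygon: need at least 3 vertices")
  dx <- diff(c(xy[, 1], xy[1, 1]))
  dy <- diff(c(xy[, 2], xy[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

# Contour-trace a single labelled object into an ordered polygon (pixel
# coordinates, row = y, col = x). EBImage::ocontour returns 0-based (x, y).
.maskToPolygon <- function(mask) {
  if (!any(mask > 0)) stop("empty mask")
  oc <- EBImage::ocontour(EBImage::Image(t(mask > 0)))[[1]]
  cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)
}

# Accept either an ordered-vertex polygon or a binary mask.
.asRoiPolygon <- function(roi) {
  if (is.matrix(roi) && !is.logical(roi) && ncol(roi) == 2 && nrow(roi) >= 3)
    return(as.matrix(roi))
  if (is.logical(roi) || (is.matrix(roi) && ncol(roi) != 2))
    return(.maskToPolygon(roi))
  stop("roi must be an n x 2 vertex matrix or a binary mask")
}

#' Cell area
#'
#' Shoelace area for polygon ROIs; pixel count times the squared pixel size
#' for mask ROIs. The two paths agree within a one-boundary-pixel band.
#'
#' @param roi an n x 2 vertex matrix (pixel coordinates) or a binary mask.
#' @param pixelSize micrometres per pixel (default 1).
#' @return area in square micrometres.
#' @export
computeArea <- function(roi, pixelSize = 1) {
  if (is.logical(roi) || (is.matrix(roi) && !is.logical(roi) && ncol(roi) != 2)) {
    return(sum(roi > 0) * pixelSize^2)
  }
  polygonArea(.asRoiPolygon(roi)) * pixelSize^2
}

#' Circularity shape descriptor
#'
#' \eqn{4\pi \cdot \mathrm{area} / \mathrm{perimeter}^2}: 1 for a perfect
#' circle, decreasing towards 0 for elongated or ramified shapes. Masks are
#' contour-traced first and measured on the traced polygon, avoiding the
#' upward perimeter bias of pixel-edge counting.
#'
#' @param roi vertex matrix or binary mask.
#' @return dimensionless circularity.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 513)[-513]
#' computeCircularity(cbind(cos(th), sin(th))) # ~1
#' @export
computeCircularity <- function(roi) {
  poly <- .asRoiPolygon(roi)
  p <- polygonPerimeter(poly)
  if (p <= 0) stop("degenerate ROI: zero perimeter")
  4 * pi * polygonArea(poly) / p^2
}

#' Maximum Feret diameter
#'
#' The largest caliper distance between two parallel supporting lines of the
#' shape: computed as the diameter of the convex hull by rotating calipers,
#' which equals the brute-force maximum pairwise vertex distance.
#'
#' @param roi vertex matrix or binary mask.
#' @param pixelSize micrometres per pixel (default 1).
#' @return maximum Feret diameter in micrometres.
#' @export
computeMaxFeret <- function(roi, pixelSize = 1) {
  poly <- if (is.logical(roi) || (is.matrix(roi) && !is.logical(roi) && ncol(roi) != 2))
    .maskToPolygon(roi) else as.matrix(roi)
  if (nrow(poly) < 2) stop("need at least 2 vertices")
  hullIdx <- grDevices::chull(poly[, 1], poly[, 2])
  h <- poly[hullIdx, , drop = FALSE]  # chull returns clockwise order
  m <- nrow(h)
  if (m == 1) return(0)
  if (m == 2) return(sqrt(sum((h[1, ] - h[2, ])^2)) * pixelSize)
  sqrt(.rotatingCalipersDiameter2(h)) * pixelSize
}

# Squared diameter of a convex polygon by rotating calipers (antipodal pair
# scan). Works for either vertex orientation.
.rotatingCalipersDiameter2 <- function(h) {
  m <- nrow(h)
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  triArea2 <- function(i, j, k) abs(cross2(h[i, ], h[j, ], h[k, ]))
  nxt <- function(i) if (i == m) 1L else i + 1L
  best <- 0
  j <- 2L
  for (i in seq_len(m)) {
    i2 <- nxt(i)
    repeat {
      jn <- nxt(j)
      if (triArea2(i, i2, jn) > triArea2(i, i2, j)) j <- jn else break
    }
    best <- max(best,
                sum((h[i, ] - h[j, ])^2),
                sum((h[i2, ] - h[j, ])^2))
  }
  best
}

#' Per-cell morphometric records from labelled masks
#'
#' Traces each labelled cell, computes the three shape descriptors, and
#' flags cells touching the image border (excluded by default, since only
#' whole cells inside the structures are comparable).
#'
#' @param masks integer label matrix (0 = background).
#' @param pixelSize micrometres per pixel.
#' @param condition optional condition label stored with each record.
#' @param excludeBorder drop border-touching cells (default TRUE).
#' @return data.frame: cell_id, condition, area_um2, circularity,
#'   max_feret_um, on_border.
#' @export
morphometryTable <- function(masks, pixelSize = 1, condition = NA_character_,
                             excludeBorder = TRUE) {
  ids <- setdiff(sort(unique(as.vector(masks))), 0L)
  if (!length(ids)) stop("no labelled cells in mask")
  d <- dim(masks)
  rows <- lapply(ids, function(id) {
    m <- masks == id
    onBorder <- any(m[1, ]) || any(m[d[1], ]) || any(m[, 1]) || any(m[, d[2]])
    poly <- .maskToPolygon(m)
    data.frame(cell_id = id, condition = condition,
               area_um2 = polygonArea(poly) * pixelSize^2,
               circularity = computeCircularity(poly),
               max_feret_um = computeMaxFeret(poly, pixelSize),
               on_border = onBorder)
  })
  out <- do.call(rbind, rows)
  if (excludeBorder) out <- out[!out$on_border, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent variation between two groups (median-ratio convention)
#'
#' \eqn{100 (\mathrm{median}(a)/\mathrm{median}(b) - 1)}, signed: the
#' convention used to summarize shape and intensity shifts between
#' conditions (e.g. a circularity drop from 1.00 to 0.82 reads as -18%).
#'
#' @param a numeric values of the group of interest.
#' @param b numeric values of the reference group.
#' @return signed percentage.
#' @export
percentVariation <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  mb <- stats::median(b)
  if (mb == 0) stop("reference median is zero: percent variation undefined")
  100 * (stats::median(a) / mb - 1)
}
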
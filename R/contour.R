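#' Trace the ordered outer contour of a mask
#'
#' Follows the boundary of the largest foreground component (Moore boundary
#' tracing on the binary mask, which on a clean binary image yields the same
#' pixel set as an edge detector without needing hysteresis parameters) and
#' returns it as an ordered closed polygon.  The sequence is canonicalized:
#' counter-clockwise orientation (positive shoelace signed area in (x, y)),
#' starting at the topmost-then-leftmost boundary pixel.
#'
#' @param mask nonempty logical matrix whose foreground stays clear of the
#'   image border.
#' @return `n x 2` matrix of 0-based `(x, y)` boundary pixel coordinates,
#'   `n >= 5`; the polygon closes implicitly (last point connects to first).
#' @export
extract_contour <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop_tuber("empty mask", "tubershape_empty_mask_error")
  comp <- largest_component(mask)
  xy <- mask_coords(comp)
  d <- dim(mask)
  if (min(xy) < 1 || max(xy[, 1L]) > d[2] - 2 || max(xy[, 2L]) > d[1] - 2) {
    stop_tuber("foreground touches the image border; contour would be incomplete",
               "tubershape_border_error")
  }
  oc <- ocontour(bwlabel(mask_to_ebimage(comp)))[[1L]]
  pts <- cbind(x = as.numeric(oc[, 1L]), y = as.numeric(oc[, 2L]))
  if (nrow(pts) < 5L) {
    stop_tuber("degenerate contour (fewer than 5 boundary points)",
               "tubershape_contour_error")
  }
  canonicalize_contour(pts)
}

# CCW orientation (positive shoelace), start at topmost-then-leftmost pixel.
canonicalize_contour <- function(pts) {
  if (shoelace_signed(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  start <- order(pts[, 2L], pts[, 1L])[1L]
  if (start > 1L) {
    pts <- pts[c(start:nrow(pts), 1:(start - 1L)), , drop = FALSE]
  }
  pts
}

shoelace_signed <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#'
#' Sum of Euclidean edge lengths around the closed polygon (the last vertex
#' connects back to the first).
#'
#' @param points `n x 2` matrix of `(x, y)` vertices, `n >= 3`.
#' @return perimeter in pixels.
#' @export
polygon_perimeter <- function(points) {
  points <- as_contour_points(points)
  dx <- diff(c(points[, 1L], points[1L, 1L]))
  dy <- diff(c(points[, 2L], points[1L, 2L]))
  sum(sqrt(dx^2 + dy^2))
}

#' Area of a closed polygon
#'
#' Absolute shoelace area of the closed polygon.
#'
#' @inheritParams polygon_perimeter
#' @return area in pixels squared.
#' @export
polygon_area <- function(points) {
  points <- as_contour_points(points)
  abs(shoelace_signed(points))
}

as_contour_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L) {
    stop_tuber("a contour needs an n x 2 coordinate matrix with n >= 3",
               "tubershape_contour_error")
  }
  storage.mode(points) <- "double"
  points
}

#' Rasterize a closed polygon to a filled mask
#'
#' Scanline even-odd fill at pixel centers, with the polygon boundary itself
#' rasterized (Bresenham) and included in the foreground.  An axis-aligned
#' square with corners (0,0) and (10,10) therefore covers the full 11 x 11
#' block of lattice points.
#'
#' @param points `n x 2` matrix of `(x, y)` vertices inside the canvas.
#' @param extents `c(width, height)` of the target canvas.
#' @return logical mask `height x width`.
#' @export
contour_to_mask <- function(points, extents) {
  points <- as_contour_points(points)
  w <- as.integer(extents[[1L]]); h <- as.integer(extents[[2L]])
  if (min(points[, 1L]) < 0 || max(points[, 1L]) > w - 1 ||
      min(points[, 2L]) < 0 || max(points[, 2L]) > h - 1) {
    stop_tuber("contour points fall outside the canvas extents",
               "tubershape_bounds_error")
  }
  mask <- matrix(FALSE, h, w)
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  # interior: even-odd crossings of the horizontal line through each row
  for (row in 0:(h - 1L)) {
    sel <- (y <= row & row < yn) | (yn <= row & row < y)
    if (!any(sel)) next
    xc <- x[sel] + (row - y[sel]) * (xn[sel] - x[sel]) / (yn[sel] - y[sel])
    xc <- sort(xc)
    if (length(xc) < 2L) next
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      lo <- ceiling(xc[k]); hi <- floor(xc[k + 1L])
      if (hi >= lo) mask[row + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  # boundary pixels
  xi <- round(x); yi <- round(y)
  xni <- c(xi[-1L], xi[1L]); yni <- c(yi[-1L], yi[1L])
  for (k in seq_along(xi)) {
    seg <- bresenham(xi[k], yi[k], xni[k], yni[k])
    mask[cbind(seg[, 2L] + 1L, seg[, 1L] + 1L)] <- TRUE
  }
  mask
}

# Integer line rasterization between two lattice points (inclusive).
bresenham <- function(x0, y0, x1, y1) {
  n <- max(abs(x1 - x0), abs(y1 - y0))
  if (n == 0) return(cbind(x = x0, y = y0))
  t <- 0:n
  cbind(x = round(x0 + t * (x1 - x0) / n), y = round(y0 + t * (y1 - y0) / n))
}

#' Write / read a contour as CSV
#'
#' Plain two-column `u,v` (x, y) CSV serialization of a contour.
#'
#' @param points contour matrix as from [extract_contour()].
#' @param path file path.
#' @return `write_contour_csv`: `path`, invisibly; `read_contour_csv`: the
#'   contour matrix.
#' @export
write_contour_csv <- function(points, path) {
  points <- as_contour_points(points)
  write.csv(data.frame(u = points[, 1L], v = points[, 2L]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- read.csv(path)
  as_contour_points(cbind(x = df$u, y = df$v))
}

#' Contour as GeoJSON-style polygon list
#'
#' Returns a list mirroring a GeoJSON `Polygon` (closed ring, first point
#' repeated last), ready for [jsonlite::toJSON()].
#'
#' @param points contour matrix.
#' @return list with `type` and `coordinates`.
#' @export
contour_to_geojson <- function(points) {
  points <- as_contour_points(points)
  ring <- rbind(points, points[1L, , drop = FALSE])
  list(type = "Polygon", coordinates = list(unname(ring)))
}
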
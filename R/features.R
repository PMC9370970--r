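#' Perimeter ratio of contour to fitted ellipse
#'
#' `C = C_p / C_e`: the contour perimeter divided by the fitted ellipse
#' perimeter.  Near 1 for regular (ellipse-like) shapes; protrusions and
#' lobes lengthen the contour and push the ratio above 1.
#'
#' A traced pixel chain (integer points, unit/diagonal steps) measured as a
#' raw polygon overestimates the length of the smooth boundary it samples by
#' about 5% (staircase effect), so for such contours `C_p` is the
#' Kulpa-corrected digital length (0.948 times the chain length); continuous
#' polygons are measured exactly with [polygon_perimeter()].
#'
#' @param contour `n x 2` contour matrix (see [extract_contour()]).
#' @param e an [ellipse_params()] object.
#' @return dimensionless ratio.
#' @references Kulpa (1977) Computer Graphics and Image Processing 6:434-451.
#' @export
perimeter_ratio <- function(contour, e) {
  contour_perimeter(contour) / ellipse_perimeter(e)
}

# Perimeter estimate appropriate to the contour kind: Kulpa-corrected length
# for 8-connected pixel chains, exact polygon length otherwise.
contour_perimeter <- function(contour) {
  len <- polygon_perimeter(contour)
  if (is_pixel_chain(contour)) 0.948 * len else len
}

is_pixel_chain <- function(points) {
  points <- as_contour_points(points)
  if (max(abs(points - round(points))) > 1e-9) return(FALSE)
  dx <- abs(diff(c(points[, 1L], points[1L, 1L])))
  dy <- abs(diff(c(points[, 2L], points[1L, 2L])))
  all(dx <= 1 & dy <= 1)
}

#' Area ratio of contour to fitted ellipse
#'
#' `A = A_p / A_e`: the contour's shoelace area divided by the fitted ellipse
#' area `pi a b`.  Near 1 for regular shapes.
#'
#' @inheritParams perimeter_ratio
#' @return dimensionless ratio.
#' @export
area_ratio <- function(contour, e) {
  polygon_area(contour) / ellipse_area(e)
}

#' Directed Hausdorff distance between point sets
#'
#' `h(P, Q) = max over p in P of min over q in Q of ||p - q||_2`: how far the
#' worst-placed point of `P` is from the set `Q`.
#'
#' @param p,q nonempty `n x 2` coordinate matrices.
#' @return distance in pixels.
#' @export
directed_hausdorff <- function(p, q) {
  p <- as_point_set(p); q <- as_point_set(q)
  sqrt(max(min_dist2_to_set(p, q)))
}

#' Bidirectional Hausdorff distance
#'
#' `H(P, Q) = max(h(P, Q), h(Q, P))`: the maximum non-matching degree between
#' the two sets.  Symmetric, zero iff the sets coincide, and a metric on
#' finite point sets.  Used here to compare the sampled fitted-ellipse
#' boundary with the traced contour; at the 614 x 410 reference extents,
#' values above 21 px indicate an irregular tuber.
#'
#' @inheritParams directed_hausdorff
#' @return distance in pixels.
#' @export
hausdorff_distance <- function(p, q) {
  max(directed_hausdorff(p, q), directed_hausdorff(q, p))
}

as_point_set <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 1L || ncol(p) != 2L) {
    stop_tuber("point sets must be nonempty n x 2 matrices",
               "tubershape_pointset_error")
  }
  storage.mode(p) <- "double"
  p
}

# Squared distance from every point of `p` to its nearest neighbour in `q`,
# computed blockwise to bound memory on large boundaries.
min_dist2_to_set <- function(p, q, block = 2048L) {
  qx <- q[, 1L]; qy <- q[, 2L]
  out <- numeric(nrow(p))
  for (s in seq(1L, nrow(p), by = block)) {
    idx <- s:min(s + block - 1L, nrow(p))
    d2 <- outer(p[idx, 1L], qx, "-")^2 + outer(p[idx, 2L], qy, "-")^2
    out[idx] <- d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))]
  }
  out
}

#' Intersection-over-union of two binary masks
#'
#' `|m1 AND m2| / |m1 OR m2|`, in `[0, 1]`.  In the grading pipeline the
#' filled contour region plays the role of the ground truth and the filled
#' fitted-ellipse region the prediction; IoU of 1 means perfect overlap.
#'
#' @param m1,m2 logical matrices of identical extents, not both empty.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(m1, m2) {
  assert_mask(m1, "m1"); assert_mask(m2, "m2")
  if (!all(dim(m1) == dim(m2))) {
    stop_tuber("masks must share extents", "tubershape_extent_error")
  }
  union <- sum(m1 | m2)
  if (union == 0L) {
    stop_tuber("both masks are empty; IoU undefined", "tubershape_empty_mask_error")
  }
  sum(m1 & m2) / union
}

#' Compute the four shape-irregularity features of a mask
#'
#' Traces the contour, fits the least-squares ellipse to it, and computes the
#' feature vector: perimeter ratio `C`, area ratio `A`, bidirectional
#' Hausdorff distance `H` between the sampled ellipse boundary and the
#' contour points, and IoU between the filled contour region and the filled
#' ellipse region.
#'
#' @param mask preprocessed logical mask, typically at the 614 x 410
#'   reference extents (the Hausdorff threshold is calibrated there).
#' @param max_spacing ellipse boundary sample spacing in px (default 1).
#' @return a `shape_features` list: `features` (named numeric
#'   `c(C, A, H, iou)`), `contour`, and `ellipse`.
#' @examples
#' s <- render_sample(shape_spec(a = 100, b = 60, seed = 2))
#' f <- compute_features(preprocess_pipeline(s$image))
#' f$features
#' @export
compute_features <- function(mask, max_spacing = 1) {
  assert_mask(mask)
  contour <- extract_contour(mask)
  e <- fit_ellipse_lsq(contour)
  p_set <- sample_ellipse(e, max_spacing)
  h <- hausdorff_distance(p_set, contour)
  extents <- c(ncol(mask), nrow(mask))
  iou <- mask_iou(contour_to_mask(contour, extents), ellipse_mask(e, extents))
  structure(list(
    features = c(C = perimeter_ratio(contour, e),
                 A = area_ratio(contour, e),
                 H = h,
                 iou = iou),
    contour = contour,
    ellipse = e
  ), class = "shape_features")
}

#' @export
print.shape_features <- function(x, ...) {
  f <- x$features
  cat(sprintf(
    "shape features: C = %.4f, A = %.4f, H = %.2f px, IoU = %.4f\n",
    f[["C"]], f[["A"]], f[["H"]], f[["iou"]]))
  cat("  ", format(x$ellipse), "\n", sep = "")
  invisible(x)
}
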
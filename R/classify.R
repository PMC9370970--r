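#' Identification thresholds
#'
#' Fixed decision thresholds for the two discriminative features.  The
#' Hausdorff-distance threshold (21 px) is tied to the 614 x 410 working
#' extents — Hausdorff distance scales with image resolution — while the IoU
#' threshold (0.925) is resolution-independent.  Boundary semantics:
#' `H <= 21` is regular, `H > 21` irregular; `IoU > 0.925` is regular,
#' `IoU <= 0.925` irregular.
#'
#' @param hd Hausdorff-distance threshold in px (default 21).
#' @param iou IoU threshold in `(0, 1)` (default 0.925).
#' @param reference_extents `c(width, height)` at which `hd` is valid
#'   (default `c(614, 410)`).
#' @return a `shape_thresholds` object.
#' @export
shape_thresholds <- function(hd = 21, iou = 0.925,
                             reference_extents = c(width = 614, height = 410)) {
  stopifnot(hd > 0, iou > 0, iou < 1, length(reference_extents) == 2L)
  structure(list(hd = as.numeric(hd), iou = as.numeric(iou),
                 reference_extents = c(width = as.integer(reference_extents[[1]]),
                                       height = as.integer(reference_extents[[2]]))),
            class = "shape_thresholds")
}

#' @export
print.shape_thresholds <- function(x, ...) {
  cat(sprintf(
    "thresholds: H > %g px irregular; IoU <= %g irregular (valid at %d x %d)\n",
    x$hd, x$iou, x$reference_extents[["width"]], x$reference_extents[["height"]]))
  invisible(x)
}

#' Classify by Hausdorff distance
#'
#' Irregular if and only if `H` exceeds the threshold; `H` equal to the
#' threshold is regular.
#'
#' @param h Hausdorff distance(s) in px, nonnegative.
#' @param thresholds a [shape_thresholds()] object.
#' @return character vector of `"regular"` / `"irregular"`.
#' @export
classify_hd <- function(h, thresholds = shape_thresholds()) {
  stopifnot(inherits(thresholds, "shape_thresholds"))
  if (any(!is.finite(h)) || any(h < 0)) {
    stop_tuber("Hausdorff distance must be finite and nonnegative",
               "tubershape_arg_error")
  }
  ifelse(h > thresholds$hd, "irregular", "regular")
}

#' Classify by IoU
#'
#' Irregular if and only if the IoU is less than or equal to the threshold;
#' IoU equal to the threshold is irregular.
#'
#' @param iou IoU value(s) in `[0, 1]`.
#' @param thresholds a [shape_thresholds()] object.
#' @return character vector of `"regular"` / `"irregular"`.
#' @export
classify_iou <- function(iou, thresholds = shape_thresholds()) {
  stopifnot(inherits(thresholds, "shape_thresholds"))
  if (any(!is.finite(iou)) || any(iou < 0) || any(iou > 1)) {
    stop_tuber("IoU must lie in [0, 1]", "tubershape_arg_error")
  }
  ifelse(iou <= thresholds$iou, "irregular", "regular")
}

#' Aggregate features over multiple views of one object
#'
#' An irregular lobe can hide from a single camera angle; across views the
#' Hausdorff distance is aggregated by its maximum and the IoU by its
#' minimum, so irregularity seen from any angle dominates.  The perimeter and
#' area ratios are carried from the view with the maximal Hausdorff distance.
#'
#' @param features list of named feature vectors `c(C, A, H, iou)` (as in the
#'   `features` element of [compute_features()]), one per view.
#' @return single aggregated named feature vector.
#' @export
aggregate_views <- function(features) {
  if (length(features) == 0L) {
    stop_tuber("no views to aggregate", "tubershape_arg_error")
  }
  hs <- vapply(features, function(f) f[["H"]], numeric(1))
  ious <- vapply(features, function(f) f[["iou"]], numeric(1))
  worst <- which.max(hs)
  c(C = features[[worst]][["C"]], A = features[[worst]][["A"]],
    H = max(hs), iou = min(ious))
}

#' Classify a single capture end to end
#'
#' Runs preprocessing, feature extraction, and thresholding on one image.
#' In mode `"hd"` or `"iou"` the single feature decides; in mode `"both"`
#' the object is called irregular when either feature votes irregular (a
#' conservative extension — a sorting line would rather discard a doubtful
#' tuber).  Pipeline failures are captured, not thrown: the label is
#' `"undetermined"` and the error message is reported.
#'
#' @param img `H x W x 3` array in `[0, 255]`, or a file path readable by
#'   [read_rgb_image()].
#' @param thresholds a [shape_thresholds()] object.
#' @param mode `"hd"`, `"iou"`, or `"both"` (default).
#' @param config a [preprocess_config()].
#' @return list with `label` (`"regular"`, `"irregular"`, or
#'   `"undetermined"`), `features` (named vector or `NULL`), `contour`,
#'   `ellipse`, and `error` (message or `NULL`).
#' @export
classify_image <- function(img, thresholds = shape_thresholds(),
                           mode = c("both", "hd", "iou"),
                           config = preprocess_config()) {
  mode <- match.arg(mode)
  res <- tryCatch({
    if (is.character(img)) img <- read_rgb_image(img)
    mask <- preprocess_pipeline(img, config)
    compute_features(mask)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    return(list(label = "undetermined", features = NULL, contour = NULL,
                ellipse = NULL, error = conditionMessage(res)))
  }
  list(label = classify_features(res$features, thresholds, mode),
       features = res$features, contour = res$contour,
       ellipse = res$ellipse, error = NULL)
}

# Label a feature vector under one of the three decision modes.
classify_features <- function(features, thresholds = shape_thresholds(),
                              mode = c("both", "hd", "iou")) {
  mode <- match.arg(mode)
  lab_hd <- classify_hd(features[["H"]], thresholds)
  lab_iou <- classify_iou(features[["iou"]], thresholds)
  switch(mode,
         hd = lab_hd,
         iou = lab_iou,
         both = if (lab_hd == "irregular" || lab_iou == "irregular")
           "irregular" else "regular")
}
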
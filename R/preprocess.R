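#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the raw-capture-to-mask chain.  The
#' defaults reproduce the reference operating point: captures are forced to
#' the 614 x 410 working extents (the resolution at which the Hausdorff
#' threshold of 21 px is valid), the object is assumed brighter than the
#' background (bright tuber on a black board), the morphological structuring
#' element is a disc of radius 2 (5 x 5), and edge smoothing uses a 5 x 5
#' binary majority window.
#'
#' @param scale_factor nominal down-scaling factor for [resize_region()]
#'   (informational when `reference_extents` is enforced; default 0.2).
#' @param reference_extents `c(width, height)` working extents the pipeline
#'   resizes every capture to; default `c(614, 410)`.
#' @param kernel_radius radius (px) of the disc structuring element used by
#'   [morphological_clean()]; default 2.
#' @param median_window odd window size (px) of [median_smooth()]; default 5.
#' @param polarity `"bright"` if the object is brighter than the background
#'   (default), `"dark"` for the opposite setup.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(scale_factor = 0.2,
                              reference_extents = c(width = 614, height = 410),
                              kernel_radius = 2,
                              median_window = 5,
                              polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(scale_factor > 0, scale_factor <= 1,
            length(reference_extents) == 2L, all(reference_extents >= 8),
            kernel_radius >= 1, median_window >= 3, median_window %% 2 == 1)
  structure(list(scale_factor = scale_factor,
                 reference_extents = c(width = as.integer(reference_extents[[1]]),
                                       height = as.integer(reference_extents[[2]])),
                 kernel_radius = as.integer(kernel_radius),
                 median_window = as.integer(median_window),
                 polarity = polarity),
            class = "preprocess_config")
}

# Sparse row-weight matrix for exact area (region) resampling: output cell i
# covers [i-1, i) * n_in/n_out in continuous source coordinates; the weight of
# source cell r is the fractional overlap, normalized to sum 1 per row.
area_weights <- function(n_in, n_out) {
  step <- n_in / n_out
  lo <- (seq_len(n_out) - 1) * step
  hi <- lo + step
  first <- floor(lo) + 1          # first source cell overlapped (1-based)
  last <- ceiling(hi)             # last source cell overlapped
  last <- pmin(last, n_in)
  i <- j <- w <- vector("list", n_out)
  for (k in seq_len(n_out)) {
    cells <- first[k]:last[k]
    ov <- pmin(hi[k], cells) - pmax(lo[k], cells - 1)
    keep <- ov > 1e-12
    i[[k]] <- rep.int(k, sum(keep))
    j[[k]] <- cells[keep]
    w[[k]] <- ov[keep] / step
  }
  sparseMatrix(i = unlist(i), j = unlist(j), x = unlist(w),
               dims = c(n_out, n_in))
}

resize_area_to <- function(img, out_h, out_w) {
  d <- dim(img)
  wy <- area_weights(d[1], out_h)
  wx <- area_weights(d[2], out_w)
  out <- array(0, dim = c(out_h, out_w, 3L))
  for (ch in 1:3) {
    out[, , ch] <- as.matrix(wy %*% img[, , ch] %*% Matrix::t(wx))
  }
  out
}

#' Downscale an RGB image by region (area) interpolation
#'
#' Each output pixel is the exact area-weighted mean of the source region it
#' covers, the standard anti-aliasing choice for strong downscaling.  Output
#' extents are `round(H * factor) x round(W * factor)`; a 3072 x 2048 capture
#' at factor 0.2 becomes 614 x 410.
#'
#' @param img `H x W x 3` array, intensities in `[0, 255]`.
#' @param factor scaling factor in `(0, 1]`.
#' @return resized `H' x W' x 3` array.
#' @export
resize_region <- function(img, factor) {
  assert_rgb(img, min_extent = 2L)
  if (!(factor > 0 && factor <= 1)) {
    stop_tuber("`factor` must be in (0, 1]", "tubershape_arg_error")
  }
  out_h <- round(dim(img)[1] * factor)
  out_w <- round(dim(img)[2] * factor)
  if (out_h < 2 || out_w < 2) {
    stop_tuber("scaling factor yields degenerate extents",
               "tubershape_size_error")
  }
  resize_area_to(img, out_h, out_w)
}

#' Convert an RGB image to grayscale
#'
#' Weighted-average graying with the conventional luma weights
#' `0.299 R + 0.587 G + 0.114 B`, rounded to integer intensities.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @return `H x W` matrix in `[0, 255]`.
#' @export
to_gray <- function(img) {
  assert_rgb(img)
  round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Otsu threshold segmentation
#'
#' Picks the intensity threshold maximizing between-class variance of the
#' 256-bin histogram and segments the image, foreground being the pixels
#' brighter than the threshold (bright object on dark board; see
#' [preprocess_config()] for the opposite polarity).
#'
#' @param gray `H x W` matrix in `[0, 255]`.
#' @param polarity `"bright"` (foreground above threshold, default) or
#'   `"dark"` (below).
#' @return list with `mask` (logical matrix) and `threshold` (intensity).
#' @export
otsu_binarize <- function(gray, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(gray)) {
    stop_tuber("`gray` must be a numeric matrix", "tubershape_type_error")
  }
  if (length(unique(as.vector(gray))) < 2L) {
    stop_tuber("image has a single intensity; Otsu threshold undefined",
               "tubershape_contrast_error")
  }
  th <- otsu(Image(t(gray) / 255), range = c(0, 1), levels = 256) * 255
  mask <- if (polarity == "bright") gray > th else gray < th
  list(mask = mask, threshold = as.numeric(th))
}

#' Morphological noise removal
#'
#' Opening followed by closing with a disc structuring element of the given
#' radius: isolated specks smaller than the element are removed, small
#' interior holes are filled.
#'
#' @param mask logical matrix.
#' @param kernel_radius disc radius in px (element is `2r+1 x 2r+1`).
#' @return cleaned logical matrix.
#' @export
morphological_clean <- function(mask, kernel_radius = 2) {
  assert_mask(mask)
  stopifnot(kernel_radius >= 1)
  brush <- makeBrush(2L * as.integer(kernel_radius) + 1L, shape = "disc")
  opened <- opening(mask_to_ebimage(mask), brush)
  if (!any(imageData(opened) > 0.5)) {
    stop_tuber("mask emptied by morphological opening", "tubershape_empty_mask_error")
  }
  ebimage_to_mask(closing(opened, brush))
}

# Per-pixel count of foreground in the clipped w x w window, via integral image.
box_count <- function(mat, half) {
  d <- dim(mat)
  ii <- matrix(0, d[1] + 1L, d[2] + 1L)
  ii[-1L, -1L] <- t(apply(apply(mat, 2L, cumsum), 1L, cumsum))
  r0 <- pmax(seq_len(d[1]) - half, 1L); r1 <- pmin(seq_len(d[1]) + half, d[1])
  c0 <- pmax(seq_len(d[2]) - half, 1L); c1 <- pmin(seq_len(d[2]) + half, d[2])
  # window sums for every pixel at once: expand row/col bounds over the grid
  R0 <- rep(r0, times = d[2]); R1 <- rep(r1, times = d[2])
  C0 <- rep(c0, each = d[1]);  C1 <- rep(c1, each = d[1])
  s <- ii[cbind(R1 + 1L, C1 + 1L)] - ii[cbind(R0, C1 + 1L)] -
       ii[cbind(R1 + 1L, C0)] + ii[cbind(R0, C0)]
  list(count = matrix(s, d[1], d[2]),
       area = matrix((R1 - R0 + 1L) * (C1 - C0 + 1L), d[1], d[2]))
}

#' Binary majority (median) edge smoothing
#'
#' Replaces each pixel by the majority value of its `window x window`
#' neighborhood (the binary median filter): staircase artifacts on the object
#' boundary are smoothed while the blob geometry is preserved.  Windows are
#' clipped at the image border; an exact tie keeps the original pixel value.
#'
#' @param mask logical matrix.
#' @param window odd window size, at least 3 (default 5).
#' @return smoothed logical matrix.
#' @export
median_smooth <- function(mask, window = 5) {
  assert_mask(mask)
  stopifnot(window >= 3, window %% 2 == 1)
  half <- (as.integer(window) - 1L) %/% 2L
  bc <- box_count(mask * 1L, half)
  out <- bc$count * 2L > bc$area
  tie <- bc$count * 2L == bc$area
  out[tie] <- mask[tie]
  out
}

#' Center the object in the canvas
#'
#' Translates the foreground by an integer shift so its centroid lands on the
#' image center; the foreground pixel count is preserved exactly.  Errors if
#' the shifted object would leave the canvas or touch its border (downstream
#' contour tracing requires background all around).
#'
#' @param mask nonempty logical matrix.
#' @return translated logical matrix.
#' @export
center_translate <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop_tuber("empty mask", "tubershape_empty_mask_error")
  d <- dim(mask)
  xy <- mask_coords(mask)
  target <- c((d[2] - 1) / 2, (d[1] - 1) / 2)  # (x, y)
  shift <- round(target - colMeans(xy))        # (dx, dy)
  new_x <- xy[, 1L] + shift[1L]
  new_y <- xy[, 2L] + shift[2L]
  if (min(new_x) < 1 || max(new_x) > d[2] - 2 ||
      min(new_y) < 1 || max(new_y) > d[1] - 2) {
    stop_tuber("object too large to center away from the image border",
               "tubershape_object_too_large_error")
  }
  out <- matrix(FALSE, d[1], d[2])
  out[cbind(new_y + 1, new_x + 1)] <- TRUE
  out
}

# Keep only the largest 8-connected foreground component.
largest_component <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop_tuber("empty mask", "tubershape_empty_mask_error")
  lab <- imageData(bwlabel(mask_to_ebimage(mask)))
  tab <- tabulate(lab[lab > 0])
  t(lab) == which.max(tab)
}

#' Raw capture to clean centered binary mask
#'
#' Runs the full preprocessing chain: area resize to the reference extents,
#' weighted-average graying, Otsu segmentation, morphological opening/closing,
#' binary majority smoothing, retention of the largest connected component,
#' and centering.  Errors from any stage are re-signalled with the stage name
#' attached.
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param config a [preprocess_config()].
#' @return logical mask at the reference extents (`height x width`).
#' @examples
#' s <- render_sample(shape_spec(a = 100, b = 60, seed = 1))
#' mask <- preprocess_pipeline(s$image)
#' mean(mask == s$truth_mask)  # pixel agreement with the analytic truth
#' @export
preprocess_pipeline <- function(img, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_tuber(sprintf("stage '%s': %s", name, conditionMessage(e)),
                 "tubershape_stage_error", stage = name)
    })
  }
  ref_h <- config$reference_extents[["height"]]
  ref_w <- config$reference_extents[["width"]]
  assert_rgb(img)
  img <- stage("resize", {
    if (all(dim(img)[1:2] == c(ref_h, ref_w))) img
    else resize_area_to(img, ref_h, ref_w)
  })
  gray <- stage("gray", to_gray(img))
  mask <- stage("otsu", otsu_binarize(gray, config$polarity)$mask)
  mask <- stage("morphology", morphological_clean(mask, config$kernel_radius))
  mask <- stage("median", median_smooth(mask, config$median_window))
  mask <- stage("component", largest_component(mask))
  stage("center", center_translate(mask))
}
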
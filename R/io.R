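#' Read an RGB image from PNG, TIFF, or JPEG
#'
#' Loads a capture into the package's working representation: an
#' `height x width x 3` numeric array with intensities in `[0, 255]`.
#' Grayscale files are replicated across channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return numeric array `H x W x 3`, values in `[0, 255]`.
#' @seealso [write_mask_png()]
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) {
    stop_tuber(sprintf("file not found: %s", path), "tubershape_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop_tuber(sprintf("package '%s' is required to read this format", pkg),
                 "tubershape_io_error")
    }
  }
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = { need("tiff"); tiff::readTIFF(path) },
    jpg = ,
    jpeg = { need("jpeg"); jpeg::readJPEG(path) },
    stop_tuber(sprintf("unsupported image format '.%s' (PNG/TIFF/JPEG supported)", ext),
               "tubershape_io_error")
  )
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1L) raw <- array(rep(raw, 3L), dim = c(dim(raw)[1:2], 3L))
  img <- round(raw * 255)
  assert_rgb(img, "image file")
  img
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}
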
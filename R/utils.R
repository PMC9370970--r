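# Internal helpers shared across modules.

# Abort with a condition class so callers (pipeline, CLI) can discriminate.
stop_tuber <- function(message, class, stage = NULL) {
  stop(structure(
    class = c(class, "tubershape_error", "error", "condition"),
    list(message = message, call = sys.call(-1), stage = stage)
  ))
}

is_binary_mask <- function(mask) {
  is.matrix(mask) && is.logical(mask)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is_binary_mask(mask)) {
    stop_tuber(sprintf("`%s` must be a logical matrix (rows = y, cols = x)", arg),
               "tubershape_type_error")
  }
  invisible(mask)
}

assert_rgb <- function(img, arg = "img", min_extent = 8L) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)) {
    stop_tuber(sprintf("`%s` must be an H x W x 3 array of intensities in [0, 255]", arg),
               "tubershape_type_error")
  }
  if (dim(img)[1] < min_extent || dim(img)[2] < min_extent) {
    stop_tuber(sprintf("image extents must be at least %d x %d",
                       min_extent, min_extent),
               "tubershape_size_error")
  }
  if (min(img) < 0 || max(img) > 255) {
    stop_tuber(sprintf("`%s` has intensities outside [0, 255]", arg),
               "tubershape_range_error")
  }
  invisible(img)
}

# Foreground pixel coordinates of a mask, 0-based (x right, y down).
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1, y = idx[, 1L] - 1)
}

# Run `expr` with a private RNG stream seeded by `seed`; restores the caller's
# RNG state afterwards so generators do not clobber user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a child seed from a master seed; stays inside 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483629)
}

mask_to_ebimage <- function(mask) {
  Image(t(mask) * 1.0)
}

ebimage_to_mask <- function(img) {
  t(imageData(img)) > 0.5
}
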
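#' Specification of a synthetic tuber-like shape
#'
#' Star-convex radial model of a tuber silhouette: a base ellipse whose polar
#' radius is modulated by a low-order cosine lobe term (the irregularity) and
#' by small random high-order harmonics (boundary jitter emulating natural
#' surface roughness).  The radial profile is
#' `r(phi) = r_ellipse(phi) * (1 + amplitude * cos(k * phi + phase)) + jitter(phi)`
#' with `jitter` a seeded sum of order 8-13 harmonics whose radial RMS equals
#' `boundary_jitter` pixels.  Amplitude 0 defines the regular class; lobed
#' specs (amplitude >= 0.15) define the irregular class.
#'
#' @param a,b base-ellipse semi-axes in px.
#' @param theta base-ellipse rotation in radians.
#' @param center `c(x, y)` center in px (default the 614 x 410 canvas center).
#' @param lobe_count number of lobes (cosine order), 0 for none.
#' @param lobe_amplitude relative lobe amplitude in `[0, 0.5]`.
#' @param phase lobe phase in radians; drawn from `seed` if `NULL`.
#' @param boundary_jitter radial RMS of the jitter harmonics in px.
#' @param seed integer seed driving phases, jitter, and rendering noise.
#' @return a `shape_spec` object (with `truth_label`).
#' @export
shape_spec <- function(a = 110, b = 70, theta = 0, center = c(307, 205),
                       lobe_count = 0L, lobe_amplitude = 0, phase = NULL,
                       boundary_jitter = 0.5, seed = 1L) {
  stopifnot(a > 0, b > 0, a >= b, lobe_count >= 0,
            lobe_amplitude >= 0, lobe_amplitude <= 0.5,
            boundary_jitter >= 0, length(center) == 2L)
  if (lobe_count == 0L) lobe_amplitude <- 0
  jit <- with_seed(child_seed(seed, 104729), {
    orders <- 8:13
    amps <- abs(rnorm(length(orders)))
    list(orders = orders,
         amps = if (boundary_jitter > 0) {
           # RMS of sum_k c_k cos(k phi + p_k) over phi is sqrt(sum c_k^2 / 2)
           amps * boundary_jitter / sqrt(sum(amps^2) / 2)
         } else {
           numeric(length(orders)) * 0
         },
         phases = runif(length(orders), 0, 2 * pi))
  })
  if (is.null(phase)) {
    phase <- if (lobe_count > 0L) {
      with_seed(child_seed(seed, 15485863), runif(1, 0, 2 * pi))
    } else 0
  }
  spec <- structure(list(
    a = a, b = b, theta = theta, center = as.numeric(center),
    lobe_count = as.integer(lobe_count), lobe_amplitude = lobe_amplitude,
    phase = phase, boundary_jitter = boundary_jitter,
    jitter = jit, seed = as.integer(seed %% 2147483647),
    truth_label = if (lobe_amplitude > 0) "irregular" else "regular"
  ), class = "shape_spec")
  # the radial profile must stay strictly positive
  rmin <- min(radial_profile(spec, seq(0, 2 * pi, length.out = 720)))
  if (rmin <= 0) {
    stop_tuber("shape spec yields a nonpositive radius", "tubershape_spec_error")
  }
  spec
}

#' Radial profile of a synthetic shape
#'
#' Polar radius about the shape center, vectorized over the angle.
#'
#' @param spec a [shape_spec()] object.
#' @param phi angle(s) in radians.
#' @return radius (px) at each angle.
#' @export
radial_profile <- function(spec, phi) {
  stopifnot(inherits(spec, "shape_spec"))
  rel <- phi - spec$theta
  r_e <- spec$a * spec$b /
    sqrt((spec$b * cos(rel))^2 + (spec$a * sin(rel))^2)
  mod <- 1
  if (spec$lobe_count > 0L) {
    mod <- mod + spec$lobe_amplitude * cos(spec$lobe_count * phi + spec$phase)
  }
  jitter <- 0
  if (spec$boundary_jitter > 0) {
    for (k in seq_along(spec$jitter$orders)) {
      jitter <- jitter + spec$jitter$amps[k] *
        cos(spec$jitter$orders[k] * phi + spec$jitter$phases[k])
    }
  }
  r_e * mod + jitter
}

# Largest radius the spec can reach (used for fit checks).
max_radius <- function(spec) {
  spec$a * (1 + spec$lobe_amplitude) + sum(abs(spec$jitter$amps))
}

#' Render a synthetic capture with analytic ground truth
#'
#' Fills the star-convex region bounded by the radial profile, paints object
#' pixels with a yellow-brown base color plus Gaussian noise and the
#' background near-black plus noise (strongly bimodal, as with a bright tuber
#' on a black board under even lighting), and returns the analytic interior
#' as the ground-truth mask.  Deterministic given the spec seed.
#'
#' @param spec a [shape_spec()] object.
#' @param extents `c(width, height)` canvas extents (default `c(614, 410)`).
#' @param photometry list with `object_rgb`, `background_rgb` (length-3, in
#'   `[0, 255]`) and `noise_sd`.
#' @return a `synthetic_sample` list: `image` (`H x W x 3` in `[0, 255]`),
#'   `truth_mask` (logical), `truth_label`, `spec`.
#' @export
render_sample <- function(spec, extents = c(width = 614, height = 410),
                          photometry = list(object_rgb = c(208, 186, 112),
                                            background_rgb = c(28, 28, 32),
                                            noise_sd = 8)) {
  stopifnot(inherits(spec, "shape_spec"))
  w <- as.integer(extents[[1L]]); h <- as.integer(extents[[2L]])
  cx <- spec$center[1L]; cy <- spec$center[2L]
  margin <- min(cx, w - 1 - cx, cy, h - 1 - cy)
  if (max_radius(spec) > margin - 2) {
    stop_tuber("shape does not fit in the canvas with margin",
               "tubershape_bounds_error")
  }
  xs <- (0:(w - 1L)) - cx
  ys <- (0:(h - 1L)) - cy
  dx <- matrix(xs, h, w, byrow = TRUE)
  dy <- matrix(ys, h, w)
  phi <- atan2(dy, dx)
  mask <- sqrt(dx^2 + dy^2) <= radial_profile(spec, phi)
  img <- with_seed(child_seed(spec$seed, 32452843), {
    out <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      base <- ifelse(mask, photometry$object_rgb[ch], photometry$background_rgb[ch])
      out[, , ch] <- pmin(255, pmax(0, round(
        base + rnorm(h * w, sd = photometry$noise_sd))))
    }
    out
  })
  structure(list(image = img, truth_mask = mask,
                 truth_label = spec$truth_label, spec = spec),
            class = "synthetic_sample")
}

#' Render a labeled synthetic dataset
#'
#' Draws per-sample shape specs from documented ranges — semi-major axis
#' `a ~ U[80, 140]` px, aspect `b/a ~ U[0.55, 0.95]`, rotation `U[0, pi)`,
#' center jittered up to 10 px, boundary jitter `U[0.3, 1]` px; irregular
#' samples get 4-6 lobes with relative amplitude `U[0.22, 0.42]` (shrunk if
#' needed to fit the canvas) — and renders them reproducibly from the master
#' seed.
#'
#' @param n_regular,n_irregular sample counts per class.
#' @param seed master seed.
#' @param extents `c(width, height)` canvas extents (default `c(614, 410)`).
#' @return list of `synthetic_sample` objects, regular samples first.
#' @examples
#' ds <- render_dataset(2, 2, seed = 7)
#' vapply(ds, function(s) s$truth_label, character(1))
#' @export
render_dataset <- function(n_regular, n_irregular, seed = 1L,
                           extents = c(width = 614, height = 410)) {
  stopifnot(n_regular >= 0, n_irregular >= 0)
  n <- n_regular + n_irregular
  if (n == 0L) return(list())
  labels <- rep(c("regular", "irregular"), c(n_regular, n_irregular))
  w <- as.integer(extents[[1L]]); h <- as.integer(extents[[2L]])
  lapply(seq_len(n), function(i) {
    irregular <- labels[i] == "irregular"
    si <- child_seed(seed, i)
    pars <- with_seed(si, {
      list(a = runif(1, 80, 140),
           ratio = runif(1, 0.55, 0.95),
           theta = runif(1, 0, pi),
           off = runif(2, -10, 10),
           jitter = runif(1, 0.3, 1),
           lobes = sample(4:6, 1),
           amp = runif(1, 0.22, 0.42))
    })
    center <- c((w - 1) / 2, (h - 1) / 2) + pars$off
    amp <- if (irregular) pars$amp else 0
    margin <- min(center[1], w - 1 - center[1], center[2], h - 1 - center[2])
    a <- pars$a
    reach <- a * (1 + amp) + 4 * pars$jitter
    if (reach > margin - 3) a <- a * (margin - 3) / reach
    spec <- shape_spec(a = a, b = a * pars$ratio, theta = pars$theta,
                       center = center,
                       lobe_count = if (irregular) pars$lobes else 0L,
                       lobe_amplitude = amp,
                       boundary_jitter = pars$jitter, seed = si)
    render_sample(spec, extents = extents)
  })
}

#' Write a rendered dataset to disk
#'
#' PNG images plus a `labels.csv` (`file`, `label`, `spec` JSON) in the
#' target directory — the on-disk layout the batch classifier consumes.
#'
#' @param samples list of `synthetic_sample` objects.
#' @param dir output directory (created if missing).
#' @return path of `labels.csv`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    file <- sprintf("sample_%04d.png", i)
    png::writePNG(s$image / 255, file.path(dir, file))
    sp <- s$spec
    spec_json <- jsonlite::toJSON(list(
      a = sp$a, b = sp$b, theta = sp$theta, center = sp$center,
      lobe_count = sp$lobe_count, lobe_amplitude = sp$lobe_amplitude,
      boundary_jitter = sp$boundary_jitter, seed = sp$seed
    ), auto_unbox = TRUE, digits = NA)
    data.frame(file = file, label = s$truth_label,
               spec = as.character(spec_json), stringsAsFactors = FALSE)
  })
  out <- file.path(dir, "labels.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  invisible(out)
}
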
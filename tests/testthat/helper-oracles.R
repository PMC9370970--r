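# Independent brute-force oracles used to validate the optimized paths.

# O(n*m) double-loop directed Hausdorff distance.
brute_directed_hausdorff <- function(p, q) {
  worst <- 0
  for (i in seq_len(nrow(p))) {
    best <- Inf
    for (j in seq_len(nrow(q))) {
      d <- sqrt(sum((p[i, ] - q[j, ])^2))
      if (d < best) best <- d
    }
    if (best > worst) worst <- best
  }
  worst
}

brute_hausdorff <- function(p, q) {
  max(brute_directed_hausdorff(p, q), brute_directed_hausdorff(q, p))
}

# Set-algebra erosion/dilation with an arbitrary structuring element.
brute_erode <- function(mask, se) {
  d <- dim(mask); r <- (dim(se) - 1L) %/% 2L
  out <- matrix(FALSE, d[1], d[2])
  offs <- which(se > 0, arr.ind = TRUE) - rep(r + 1L, each = sum(se > 0))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ys <- i + offs[, 1L]; xs <- j + offs[, 2L]
    inside <- ys >= 1 & ys <= d[1] & xs >= 1 & xs <= d[2]
    # pixels outside the canvas count as background for erosion
    out[i, j] <- all(inside) && all(mask[cbind(ys, xs)])
  }
  out
}

brute_dilate <- function(mask, se) {
  d <- dim(mask); r <- (dim(se) - 1L) %/% 2L
  out <- matrix(FALSE, d[1], d[2])
  offs <- which(se > 0, arr.ind = TRUE) - rep(r + 1L, each = sum(se > 0))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ys <- i + offs[, 1L]; xs <- j + offs[, 2L]
    inside <- ys >= 1 & ys <= d[1] & xs >= 1 & xs <= d[2]
    out[i, j] <- any(mask[cbind(ys[inside], xs[inside])])
  }
  out
}

# Per-pixel windowed majority with clipped borders; ties keep the original.
brute_majority <- function(mask, window) {
  half <- (window - 1L) %/% 2L
  d <- dim(mask)
  out <- mask
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ys <- max(1L, i - half):min(d[1], i + half)
    xs <- max(1L, j - half):min(d[2], j + half)
    cnt <- sum(mask[ys, xs]); area <- length(ys) * length(xs)
    out[i, j] <- if (cnt * 2L == area) mask[i, j] else cnt * 2L > area
  }
  out
}

# Arc length of an ellipse by adaptive quadrature of the exact integrand.
quadrature_ellipse_perimeter <- function(a, b) {
  4 * integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                0, pi / 2, rel.tol = 1e-12)$value
}

# Area enclosed by a polar radial profile, 0.5 * integral of r(phi)^2.
polar_area <- function(spec, n = 20000L) {
  phi <- 2 * pi * (seq_len(n) - 0.5) / n
  r <- radial_profile(spec, phi)
  sum(r^2) * pi / n
}

# Filled disc mask (pixel centers within radius), 0-based center coords.
disc_mask <- function(h, w, cx, cy, r) {
  dx <- matrix(0:(w - 1L), h, w, byrow = TRUE) - cx
  dy <- matrix(0:(h - 1L), h, w) - cy
  dx^2 + dy^2 <= r^2
}

# Deterministic random point set on [0, lim]^2.
random_point_set <- function(n, seed, lim = 100) {
  set.seed(seed)
  cbind(x = runif(n, 0, lim), y = runif(n, 0, lim))
}

# Flat RGB image of one constant color.
flat_rgb <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3L))
}
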
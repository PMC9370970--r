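#' Ellipse parameters
#'
#' Geometric ellipse: center `(cx, cy)`, semi-major axis `a`, semi-minor axis
#' `b` (`a >= b > 0`), rotation `theta` of the major axis in radians,
#' canonicalized to `[0, pi)`.
#'
#' @param cx,cy center coordinates (px).
#' @param a,b semi-axes (px); reordered so `a >= b`.
#' @param theta major-axis rotation (radians); reduced modulo `pi`.
#' @return an `ellipse_params` object.
#' @export
ellipse_params <- function(cx, cy, a, b, theta = 0) {
  if (!(a > 0 && b > 0)) {
    stop_tuber("semi-axes must be strictly positive", "tubershape_ellipse_error")
  }
  if (b > a) {  # swap axes and rotate by 90 degrees
    tmp <- a; a <- b; b <- tmp
    theta <- theta + pi / 2
  }
  theta <- theta %% pi
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 a = as.numeric(a), b = as.numeric(b),
                 theta = as.numeric(theta)),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("ellipse: center (%.2f, %.2f), semi-axes a=%.2f b=%.2f, theta=%.4f rad\n",
              x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

#' @export
format.ellipse_params <- function(x, ...) {
  sprintf("ellipse(cx=%.3f, cy=%.3f, a=%.3f, b=%.3f, theta=%.4f)",
          x$cx, x$cy, x$a, x$b, x$theta)
}

#' Serialize ellipse parameters to JSON
#'
#' @param e an [ellipse_params()] object.
#' @return JSON string with fields `cx, cy, a, b, theta_rad`.
#' @export
ellipse_to_json <- function(e) {
  stopifnot(inherits(e, "ellipse_params"))
  jsonlite::toJSON(list(cx = e$cx, cy = e$cy, a = e$a, b = e$b,
                        theta_rad = e$theta), auto_unbox = TRUE, digits = NA)
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0` to the points by
#' minimizing the algebraic distance subject to the ellipse constraint
#' `4AC - B^2 = 1` (direct constrained least squares, solved with the
#' numerically stable block decomposition of the constrained eigenproblem).
#' The constraint guarantees an ellipse solution; points lying exactly on an
#' ellipse are recovered to machine precision.
#'
#' @param points `n x 2` matrix of `(x, y)` coordinates, `n >= 5`,
#'   not collinear.
#' @return an [ellipse_params()] object.
#' @references Fitzgibbon, Pilu & Fisher (1999) IEEE TPAMI 21(5):476-480;
#'   Halir & Flusser (1998) Proc. WSCG.
#' @examples
#' e <- ellipse_params(307, 205, 100, 50, 0.3)
#' p <- sample_ellipse(e, max_spacing = 5)
#' fit_ellipse_lsq(p)
#' @export
fit_ellipse_lsq <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 5L || ncol(points) != 2L) {
    stop_tuber("ellipse fitting needs at least 5 (x, y) points",
               "tubershape_fit_error")
  }
  x <- points[, 1L]; y <- points[, 2L]
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  sv <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1)) {
    stop_tuber("points are collinear; no ellipse fits them", "tubershape_fit_error")
  }
  d1 <- cbind(xc^2, xc * yc, yc^2)
  d2 <- cbind(xc, yc, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t_block <- -solve(s3, t(s2))
  m <- s1 + s2 %*% t_block
  m <- rbind(m[3L, ] / 2, -m[2L, ], m[1L, ] / 2)
  eg <- eigen(m)
  vec <- Re(eg$vectors)
  cond <- 4 * vec[1L, ] * vec[3L, ] - vec[2L, ]^2
  keep <- which(cond > 0)
  if (length(keep) == 0L) {
    stop_tuber("no ellipse satisfies the constrained fit for these points",
               "tubershape_fit_error")
  }
  a1 <- vec[, keep[1L]]
  coef_centered <- c(a1, as.numeric(t_block %*% a1))
  co <- uncenter_conic(coef_centered, mx, my)
  co <- co / sqrt(sum(co^2))
  conic_to_geometric(co)
}

# Shift conic coefficients from the (x - mx, y - my) frame back to (x, y).
uncenter_conic <- function(k, mx, my) {
  A <- k[1L]; B <- k[2L]; C <- k[3L]; D <- k[4L]; E <- k[5L]; F <- k[6L]
  c(A,
    B,
    C,
    D - 2 * A * mx - B * my,
    E - B * mx - 2 * C * my,
    F + A * mx^2 + B * mx * my + C * my^2 - D * mx - E * my)
}

#' Convert conic coefficients to geometric ellipse parameters
#'
#' Closed-form conversion of `(A, B, C, D, E, F)` of
#' `Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0` (with `B^2 - 4AC < 0`) to
#' center/semi-axes/rotation.
#'
#' @param conic numeric vector `(A, B, C, D, E, F)`.
#' @return an [ellipse_params()] object.
#' @export
conic_to_geometric <- function(conic) {
  stopifnot(length(conic) == 6L)
  A <- conic[1L]; B <- conic[2L]; C <- conic[3L]
  D <- conic[4L]; E <- conic[5L]; F <- conic[6L]
  disc <- B^2 - 4 * A * C
  if (!(disc < 0)) {
    stop_tuber("conic is not an ellipse (discriminant B^2 - 4AC >= 0)",
               "tubershape_ellipse_error")
  }
  center <- solve(matrix(c(2 * A, B, B, 2 * C), 2L, 2L), -c(D, E))
  fc <- A * center[1L]^2 + B * center[1L] * center[2L] + C * center[2L]^2 +
    D * center[1L] + E * center[2L] + F
  q <- matrix(c(A, B / 2, B / 2, C), 2L, 2L)
  eg <- eigen(q, symmetric = TRUE)
  axes2 <- -fc / eg$values
  if (any(axes2 <= 0)) {
    stop_tuber("conic has no real ellipse points", "tubershape_ellipse_error")
  }
  semi <- sqrt(axes2)                    # paired with eg$values order
  major <- which.max(semi)
  v <- eg$vectors[, major]
  ellipse_params(center[1L], center[2L], max(semi), min(semi),
                 atan2(v[2L], v[1L]))
}

#' Convert geometric ellipse parameters to conic coefficients
#'
#' Inverse of [conic_to_geometric()]; the returned vector is normalized to
#' unit Euclidean norm with `A > 0`.
#'
#' @param e an [ellipse_params()] object.
#' @return numeric vector `(A, B, C, D, E, F)`.
#' @export
geometric_to_conic <- function(e) {
  stopifnot(inherits(e, "ellipse_params"))
  ct <- cos(e$theta); st <- sin(e$theta)
  A <- ct^2 / e$a^2 + st^2 / e$b^2
  B <- 2 * ct * st * (1 / e$a^2 - 1 / e$b^2)
  C <- st^2 / e$a^2 + ct^2 / e$b^2
  D <- -2 * A * e$cx - B * e$cy
  E <- -B * e$cx - 2 * C * e$cy
  F <- A * e$cx^2 + B * e$cx * e$cy + C * e$cy^2 - 1
  co <- c(A, B, C, D, E, F)
  co <- co / sqrt(sum(co^2))
  if (co[1L] < 0) co <- -co
  co
}

#' Sample points along an ellipse boundary
#'
#' Uniform parametric samples dense enough that adjacent points are at most
#' `max_spacing` apart (the sample count is at least the perimeter divided by
#' the spacing).  With the default 1 px spacing the sample approximates the
#' rasterized boundary, so the discretization error of downstream point-set
#' distances stays below a pixel.
#'
#' @param e an [ellipse_params()] object.
#' @param max_spacing maximum gap between adjacent samples (px), default 1.
#' @return `N x 2` matrix of `(x, y)` samples.
#' @export
sample_ellipse <- function(e, max_spacing = 1) {
  stopifnot(inherits(e, "ellipse_params"))
  if (!(max_spacing > 0)) {
    stop_tuber("`max_spacing` must be positive", "tubershape_arg_error")
  }
  n <- max(16L, ceiling(2 * pi * e$a / max_spacing))
  t <- 2 * pi * (seq_len(n) - 1L) / n
  ct <- cos(e$theta); st <- sin(e$theta)
  u <- e$a * cos(t); v <- e$b * sin(t)
  cbind(x = e$cx + u * ct - v * st,
        y = e$cy + u * st + v * ct)
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' `pi (a + b) (1 + 3h / (10 + sqrt(4 - 3h)))` with
#' `h = ((a - b) / (a + b))^2`; relative error versus the exact elliptic
#' integral is far below 1e-4 for the aspect ratios of tuber-like shapes.
#'
#' @param e an [ellipse_params()] object.
#' @return perimeter in pixels.
#' @export
ellipse_perimeter <- function(e) {
  stopifnot(inherits(e, "ellipse_params"))
  h <- ((e$a - e$b) / (e$a + e$b))^2
  pi * (e$a + e$b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Ellipse area
#'
#' @param e an [ellipse_params()] object.
#' @return `pi * a * b` in pixels squared.
#' @export
ellipse_area <- function(e) {
  stopifnot(inherits(e, "ellipse_params"))
  pi * e$a * e$b
}

#' Rasterize an ellipse to a filled mask
#'
#' A pixel is foreground when its center satisfies the implicit ellipse
#' inequality `<= 1`.
#'
#' @param e an [ellipse_params()] object lying fully inside the canvas.
#' @param extents `c(width, height)` of the target canvas.
#' @return logical mask `height x width`.
#' @export
ellipse_mask <- function(e, extents) {
  stopifnot(inherits(e, "ellipse_params"))
  w <- as.integer(extents[[1L]]); h <- as.integer(extents[[2L]])
  hx <- sqrt((e$a * cos(e$theta))^2 + (e$b * sin(e$theta))^2)
  hy <- sqrt((e$a * sin(e$theta))^2 + (e$b * cos(e$theta))^2)
  if (e$cx - hx < 0 || e$cx + hx > w - 1 || e$cy - hy < 0 || e$cy + hy > h - 1) {
    stop_tuber("ellipse exceeds the canvas extents", "tubershape_bounds_error")
  }
  xs <- (0:(w - 1L)) - e$cx
  ys <- (0:(h - 1L)) - e$cy
  ct <- cos(e$theta); st <- sin(e$theta)
  # rotated coordinates on the grid: u = x ct + y st, v = -x st + y ct
  u <- outer(ys * st, xs * ct, "+")
  v <- outer(ys * ct, -xs * st, "+")
  (u / e$a)^2 + (v / e$b)^2 <= 1
}
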
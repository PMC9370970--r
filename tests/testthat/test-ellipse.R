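test_that("noiseless points on an ellipse are recovered to machine precision", {
  e <- ellipse_params(307, 205, 100, 50, 0)
  t <- 2 * pi * (0:35) / 36
  pts <- cbind(307 + 100 * cos(t), 205 + 50 * sin(t))
  fit <- fit_ellipse_lsq(pts)
  expect_lt(abs(fit$cx - 307) / 307, 1e-6)
  expect_lt(abs(fit$cy - 205) / 205, 1e-6)
  expect_lt(abs(fit$a - 100) / 100, 1e-6)
  expect_lt(abs(fit$b - 50) / 50, 1e-6)
  expect_lt(min(fit$theta, pi - fit$theta), 1e-6)

  # a circle: equal axes, any rotation accepted
  tc <- 2 * pi * (0:19) / 20
  circ <- cbind(10 * cos(tc) + 3, 10 * sin(tc) - 7)
  fitc <- fit_ellipse_lsq(circ)
  expect_equal(fitc$a, 10, tolerance = 1e-9)
  expect_equal(fitc$b, 10, tolerance = 1e-9)

  expect_error(fit_ellipse_lsq(pts[1:4, ]), class = "tubershape_fit_error")
  line <- cbind(1:30, 2 * (1:30) + 1)
  expect_error(fit_ellipse_lsq(line), class = "tubershape_fit_error")
})

test_that("axis recovery under isotropic noise stays within 2% (median of 100 seeds)", {
  a <- 100; b <- 50
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    t <- runif(200, 0, 2 * pi)
    pts <- cbind(307 + a * cos(t) + rnorm(200),
                 205 + b * sin(t) + rnorm(200))
    fit <- fit_ellipse_lsq(pts)
    max(abs(fit$a - a) / a, abs(fit$b - b) / b)
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("conic and geometric parameterizations convert both ways", {
  # x^2 + y^2 - 1 = 0: unit circle
  c1 <- conic_to_geometric(c(1, 0, 1, 0, 0, -1))
  expect_equal(c(c1$cx, c1$cy, c1$a, c1$b), c(0, 0, 1, 1))

  # x^2/4 + y^2 - 1 = 0: a = 2, b = 1, theta = 0
  c2 <- conic_to_geometric(c(0.25, 0, 1, 0, 0, -1))
  expect_equal(c(c2$a, c2$b, c2$theta), c(2, 1, 0))

  # hyperbola is rejected
  expect_error(conic_to_geometric(c(1, 0, -1, 0, 0, -1)),
               class = "tubershape_ellipse_error")

  # geometric -> conic -> geometric is the identity
  for (seed in 1:10) {
    set.seed(seed)
    e <- ellipse_params(runif(1, -50, 400), runif(1, -50, 300),
                        runif(1, 20, 150), runif(1, 5, 20),
                        runif(1, 0, pi))
    back <- conic_to_geometric(geometric_to_conic(e))
    expect_equal(c(back$cx, back$cy, back$a, back$b),
                 c(e$cx, e$cy, e$a, e$b), tolerance = 1e-9)
    expect_lt(min(abs(back$theta - e$theta), pi - abs(back$theta - e$theta)),
              1e-9)
  }
})

test_that("ellipse boundary sampling is dense and exactly on the conic", {
  e <- ellipse_params(0, 0, 10, 10)
  p <- sample_ellipse(e, max_spacing = 1)
  expect_gte(nrow(p), 63)
  radii <- sqrt(rowSums(p^2))
  expect_true(all(abs(radii - 10) < 0.01))
  gaps <- sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2))
  expect_true(all(gaps <= 1))

  e2 <- ellipse_params(307, 205, 120, 60, 0.8)
  p2 <- sample_ellipse(e2, 1)
  conic <- geometric_to_conic(e2)
  resid <- conic[1] * p2[, 1]^2 + conic[2] * p2[, 1] * p2[, 2] +
    conic[3] * p2[, 2]^2 + conic[4] * p2[, 1] + conic[5] * p2[, 2] + conic[6]
  expect_lt(max(abs(resid)), 1e-9)

  expect_error(ellipse_params(0, 0, 10, 0), class = "tubershape_ellipse_error")
  expect_error(sample_ellipse(e, max_spacing = 0),
               class = "tubershape_arg_error")
})

test_that("Ramanujan perimeter matches quadrature; area matches pi*a*b and raster", {
  expect_equal(ellipse_perimeter(ellipse_params(0, 0, 1, 1)), 2 * pi)
  for (r in c(0.5, 7, 123)) {
    expect_equal(ellipse_perimeter(ellipse_params(0, 0, r, r)), 2 * pi * r,
                 tolerance = 1e-12)
  }
  q <- quadrature_ellipse_perimeter(100, 50)
  expect_lt(abs(ellipse_perimeter(ellipse_params(0, 0, 100, 50)) - q) / q, 1e-4)

  expect_equal(ellipse_area(ellipse_params(0, 0, 1, 1)), pi)
  expect_equal(ellipse_area(ellipse_params(0, 0, 2, 1)), 2 * pi)

  e <- ellipse_params(100, 90, 55, 35, 0.6)
  m <- ellipse_mask(e, c(200, 180))
  expect_lt(abs(sum(m) - ellipse_area(e)) / ellipse_area(e), 0.01)
})

test_that("ellipse rasterization equals the per-pixel implicit-inequality oracle", {
  e <- ellipse_params(50, 49, 30, 30, 0)
  m <- ellipse_mask(e, c(100, 100))
  expect_lt(abs(sum(m) - pi * 900) / (pi * 900), 0.01)

  oracle <- matrix(FALSE, 100, 100)
  conic <- list(ct = cos(e$theta), st = sin(e$theta))
  for (row in 1:100) for (col in 1:100) {
    x <- col - 1 - e$cx; y <- row - 1 - e$cy
    u <- x * conic$ct + y * conic$st
    v <- -x * conic$st + y * conic$ct
    oracle[row, col] <- (u / e$a)^2 + (v / e$b)^2 <= 1
  }
  expect_identical(m, oracle)

  e_tilt <- ellipse_params(50, 50, 40, 18, 1.1)
  m2 <- ellipse_mask(e_tilt, c(100, 100))
  oracle2 <- matrix(FALSE, 100, 100)
  ct <- cos(e_tilt$theta); st <- sin(e_tilt$theta)
  for (row in 1:100) for (col in 1:100) {
    x <- col - 1 - e_tilt$cx; y <- row - 1 - e_tilt$cy
    u <- x * ct + y * st; v <- -x * st + y * ct
    oracle2[row, col] <- (u / e_tilt$a)^2 + (v / e_tilt$b)^2 <= 1
  }
  expect_identical(m2, oracle2)

  expect_error(ellipse_mask(ellipse_params(50, 50, 60, 30), c(100, 100)),
               class = "tubershape_bounds_error")
})

test_that("the fit is equivariant under translation and rotation of the points", {
  set.seed(77)
  t <- sort(runif(60, 0, 2 * pi))
  base <- cbind(120 * cos(t) * cos(0.5) - 70 * sin(t) * sin(0.5) + 200,
                120 * cos(t) * sin(0.5) + 70 * sin(t) * cos(0.5) + 150)
  f0 <- fit_ellipse_lsq(base)

  shifted <- base + rep(c(31.5, -12.25), each = nrow(base))
  fs <- fit_ellipse_lsq(shifted)
  expect_equal(c(fs$cx, fs$cy), c(f0$cx + 31.5, f0$cy - 12.25),
               tolerance = 1e-6)
  expect_equal(c(fs$a, fs$b), c(f0$a, f0$b), tolerance = 1e-6)

  ang <- 0.7
  rot <- cbind(base[, 1] * cos(ang) - base[, 2] * sin(ang),
               base[, 1] * sin(ang) + base[, 2] * cos(ang))
  fr <- fit_ellipse_lsq(rot)
  expect_equal(c(fr$a, fr$b), c(f0$a, f0$b), tolerance = 1e-6)
  expect_lt(min(abs(fr$theta - (f0$theta + ang) %% pi),
                pi - abs(fr$theta - (f0$theta + ang) %% pi)), 1e-6)
})

test_that("algebraic residual separates exact ellipses from other point sets", {
  resid_of <- function(pts, e) {
    co <- geometric_to_conic(e)
    max(abs(co[1] * pts[, 1]^2 + co[2] * pts[, 1] * pts[, 2] +
              co[3] * pts[, 2]^2 + co[4] * pts[, 1] + co[5] * pts[, 2] + co[6]))
  }
  e <- ellipse_params(40, 30, 25, 12, 0.4)
  pts <- sample_ellipse(e, 2)
  expect_lt(resid_of(pts, fit_ellipse_lsq(pts)), 1e-9)

  # six points in general position not on any ellipse: residual strictly > 0
  set.seed(3)
  blob <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  fitb <- fit_ellipse_lsq(blob)
  expect_gt(resid_of(blob, fitb), 1e-6)

  # sampled boundary fitted back recovers the generating ellipse
  round_trip <- fit_ellipse_lsq(sample_ellipse(e, 1))
  expect_equal(c(round_trip$cx, round_trip$cy, round_trip$a, round_trip$b),
               c(e$cx, e$cy, e$a, e$b), tolerance = 1e-9)
})
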
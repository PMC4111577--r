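# Level-set numerics: Heaviside/Dirac pair, SDF, curvature, contour
# extraction, evolution and reinitialization.

test_that("smooth Heaviside is a centered monotone step", {
  eps <- 1.5
  expect_equal(smooth_heaviside(0, eps), 0.5)
  z <- seq(-40, 40, by = 0.37)
  h <- smooth_heaviside(z, eps)
  expect_true(all(diff(h) > 0))
  expect_equal(smooth_heaviside(z, eps) + smooth_heaviside(-z, eps),
               rep(1, length(z)))
  expect_lt(abs(smooth_heaviside(50 * eps, eps) - 1), 0.02)
  expect_error(smooth_heaviside(1, epsilon = 0), "positive")
})

test_that("smooth Dirac is the even, unimodal derivative of the Heaviside", {
  eps <- 1.5
  z <- seq(-20, 20, by = 0.13)
  expect_equal(smooth_dirac(z, eps), smooth_dirac(-z, eps))
  # exact derivative, checked by central finite differences
  h <- 1e-5
  fd <- (smooth_heaviside(z + h, eps) - smooth_heaviside(z - h, eps)) / (2 * h)
  expect_equal(smooth_dirac(z, eps), fd, tolerance = 1e-6)
  # integral over a wide window
  zg <- seq(-100 * eps, 100 * eps, length.out = 200001)
  int <- sum(smooth_dirac(zg, eps)) * (zg[2] - zg[1])
  expect_gte(int, 0.98); expect_lte(int, 1.0001)
  # unique maximum at zero
  zg2 <- seq(-10, 10, by = 0.01)
  expect_equal(zg2[which.max(smooth_dirac(zg2, eps))], 0)
  expect_error(smooth_dirac(1, epsilon = -1), "positive")
})

test_that("sdf_from_mask yields a signed Euclidean distance, negative inside", {
  mask <- disk_mask(101, radius = 20)
  phi <- sdf_from_mask(mask)
  # center distance, oracle: min distance from center to any background pixel
  bg <- which(!mask, arr.ind = TRUE)
  d_oracle <- sqrt(min((bg[, 1] - 51)^2 + (bg[, 2] - 51)^2))
  expect_equal(phi[51, 51], -d_oracle)
  expect_gte(phi[51, 51], -21); expect_lte(phi[51, 51], -19)
  expect_identical(phi < 0, mask)
  # pixels adjacent to the interface are within 1.5 px of it
  edge <- mask & !square_mask(101, 0)  # any fg pixel with a bg 4-neighbour
  nb <- mask[c(2:101, 101), ] & mask[c(1, 1:100), ] &
    mask[, c(2:101, 101)] & mask[, c(1, 1:100)]
  expect_true(all(abs(phi[mask & !nb]) <= 1.5))
  expect_error(sdf_from_mask(matrix(TRUE, 8, 8)), "both")
})

test_that("after (re)initialization |grad phi| is close to 1 away from the zero set", {
  phi <- reinitialize(100 * circle_sdf(101, c(51, 51), 30))
  g <- sqrt(mslcv:::grad_row(phi)^2 + mslcv:::grad_col(phi)^2)
  far <- abs(phi) > 2
  far[c(1, 101), ] <- FALSE; far[, c(1, 101)] <- FALSE
  frac <- mean(g[far] >= 0.8 & g[far] <= 1.2)
  expect_gte(frac, 0.95)
})

test_that("curvature matches 1/r on a circle, 0 on a ramp, and flips with phi", {
  phi <- circle_sdf(121, c(61, 61), 30)
  k <- curvature(phi)
  near <- abs(phi) < 0.5
  expect_lt(max(abs(k[near] - 1 / 30)), 0.15 / 30)
  ramp <- matrix(rep(seq_len(61) - 30.2, each = 61), 61, 61)
  kr <- curvature(ramp)
  expect_lt(max(abs(kr[5:57, 5:57])), 1e-6)
  expect_equal(curvature(-phi), -k, tolerance = 1e-12)
})

test_that("zero-contour extraction recovers known perimeters", {
  sq <- sdf_from_mask(square_mask(101, half_side = 20))  # side 41
  psq <- polyline_perimeter(extract_zero_contour(sq))
  expect_lt(abs(psq - 4 * 41) / (4 * 41), 0.05)
  dk <- circle_sdf(101, c(51, 51), 30)
  pdk <- polyline_perimeter(extract_zero_contour(dk))
  expect_lt(abs(pdk - 2 * pi * 30) / (2 * pi * 30), 0.05)
  # interpolated phi along the contour is (near) zero
  ctr <- extract_zero_contour(circle_sdf(64, c(32, 32), 12))
  vals <- vapply(seq_len(nrow(ctr)), function(i) {
    r0 <- floor(ctr[i, 1]); c0 <- floor(ctr[i, 2])
    fr <- ctr[i, 1] - r0; fc <- ctr[i, 2] - c0
    r1 <- min(r0 + 1, 64); c1 <- min(c0 + 1, 64)
    phi <- circle_sdf(64, c(32, 32), 12)
    (1 - fr) * (1 - fc) * phi[r0, c0] + fr * (1 - fc) * phi[r1, c0] +
      (1 - fr) * fc * phi[r0, c1] + fr * fc * phi[r1, c1]
  }, numeric(1))
  expect_lt(max(abs(vals)), 0.25)
  expect_error(extract_zero_contour(matrix(1, 8, 8)), "empty contour")
})

test_that("evolution step: identity at zero force, linear in dt, monotone under uniform force", {
  phi <- sdf_from_mask(disk_mask(64, radius = 18))
  expect_identical(evolve_step(phi, matrix(0, 64, 64), mu = 0, dt = 0.45), phi)
  set.seed(3)
  f <- matrix(rnorm(64 * 64), 64, 64)
  d1 <- evolve_step(phi, f, mu = 0.2, dt = 0.2) - phi
  d2 <- evolve_step(phi, f, mu = 0.2, dt = 0.4) - phi
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # uniform positive force contracts the interior monotonically (weakly per
  # step, since pixels flip only every few 0.45 px updates; strictly overall)
  area <- numeric(11)
  p <- phi; area[1] <- sum(p < 0)
  for (i in 1:10) {
    p <- evolve_step(p, matrix(1, 64, 64), mu = 0, dt = 0.45)
    area[i + 1] <- sum(p < 0)
  }
  expect_true(all(diff(area) <= 0))
  expect_lt(area[11], area[1])
  expect_error(evolve_step(phi, matrix(NA_real_, 64, 64)), "non-finite")
  expect_error(evolve_step(phi, matrix(0, 8, 8)), "shapes")
})

test_that("pure curvature flow never lengthens the interface", {
  # slightly wobbly blob: length proxy sum(delta_eps(phi)|grad phi|) shrinks
  phi <- reinitialize(circle_sdf(81, c(41, 41), 22) +
                        2 * sin(outer(1:81, 1:81, function(i, j) (i + j) / 6)))
  proxy <- function(p)
    sum(smooth_dirac(p, 1.5) * sqrt(mslcv:::grad_row(p)^2 + mslcv:::grad_col(p)^2))
  vals <- numeric(51)
  vals[1] <- proxy(phi)
  for (i in 1:50) {
    phi <- evolve_step(phi, matrix(0, 81, 81), mu = 0.5, dt = 0.45)
    if (i %% 25 == 0) phi <- reinitialize(phi)
    vals[i + 1] <- proxy(phi)
  }
  expect_lt(vals[51], vals[1])
  expect_lt(max(vals[-1] - vals[-51]), 0.05 * vals[1])  # no sustained growth
})

test_that("reinitialization preserves the sign pattern and restores the SDF", {
  phi0 <- sdf_from_mask(disk_mask(64, radius = 15))
  expect_lt(max(abs(reinitialize(phi0) - phi0)), 1)
  steep <- 100 * phi0
  re <- reinitialize(steep)
  expect_identical(re < 0, phi0 < 0)
  g <- sqrt(mslcv:::grad_row(re)^2 + mslcv:::grad_col(re)^2)
  expect_lt(abs(median(g[abs(re) > 2 & abs(re) < 20]) - 1), 0.2)
  expect_error(reinitialize(matrix(1, 8, 8)), "both")
})
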
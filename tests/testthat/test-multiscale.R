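# Pyramid, adaptive radius, upsampling and the segmentation drivers.

test_that("pyramid layers halve (rounding up) and preserve DC and mean", {
  set.seed(21)
  img <- matrix(runif(96 * 96), 96, 96)
  pyr <- gaussian_pyramid(img, 3)
  expect_length(pyr, 4L)
  expect_identical(dim(pyr[[2]]), c(48L, 48L))
  expect_identical(dim(pyr[[3]]), c(24L, 24L))
  expect_identical(dim(pyr[[4]]), c(12L, 12L))
  # odd sides round up
  podd <- gaussian_pyramid(matrix(0.5, 33, 65), 1)
  expect_identical(dim(podd[[2]]), c(17L, 33L))
  # constant image stays constant
  pc <- gaussian_pyramid(matrix(0.37, 64, 64), 3)
  for (k in 2:4) expect_lt(max(abs(pc[[k]] - 0.37)), 1e-6)
  # mean intensity approximately preserved on texture
  for (k in 2:4)
    expect_lt(abs(mean(pyr[[k]]) - mean(img)) / mean(img), 0.02)
  expect_error(gaussian_pyramid(matrix(0, 4, 4), 3), "too small")
})

test_that("adaptive radius follows the bounding-box rule with clamping", {
  # ellipse bounding box 80 x 40: c = 0.25 * 120 = 30
  ell <- rasterize_ellipse(c(128, 128), c(64, 64), 40, 20, 0)
  ctr <- extract_zero_contour(sdf_from_mask(ell))
  expect_equal(adaptive_radius(ctr, 0.25, c(10, 40)), 30L)
  # tiny contour clamps up to 10, huge clamps down to 40
  tiny <- cbind(row = c(10, 14, 14, 10), col = c(10, 10, 14, 14))
  expect_equal(adaptive_radius(tiny, 0.25, c(10, 40)), 10L)
  huge <- cbind(row = c(1, 401, 401, 1), col = c(1, 1, 401, 401))
  expect_equal(adaptive_radius(huge, 0.25, c(10, 40)), 40L)
  # monotone in contour size between the clamps
  radii <- vapply(seq(20, 80, 10), function(s) {
    sq <- cbind(row = c(0, s, s, 0), col = c(0, 0, s, s)) + 50
    adaptive_radius(sq, 0.25, c(10, 40))
  }, integer(1))
  expect_true(all(diff(radii) >= 0))
})

test_that("mask upsampling preserves area fraction and topology", {
  coarse <- disk_mask(64, radius = 10, center = c(32, 32))
  up <- upsample_mask(coarse, c(512, 512))
  expect_identical(dim(up), c(512L, 512L))
  expect_lt(abs(sum(up) - pi * 80^2) / (pi * 80^2), 0.08)
  # idempotent at the same shape
  expect_identical(upsample_mask(coarse, c(64, 64)), coarse)
  # a single blob stays a single blob
  lab <- EBImage::bwlabel(up * 1)
  expect_equal(max(lab), 1)
  expect_error(upsample_mask(coarse, c(32, 32)), "at least")
})

test_that("zero-iteration runs return the initialization unchanged", {
  img <- matrix(runif(64 * 64), 64, 64)
  init <- disk_mask(64, radius = 15)
  fit <- slcv(img, init, seg_params(), n_iters = 0)
  expect_identical(fit$mask, init)
  expect_equal(nrow(fit$diagnostics), 0L)
  expect_equal(fit$force_evals, 0)
})

test_that("diagnostics length equals iterations executed and force evals count pixels", {
  sp <- phantom_spec(shape = c(64, 64), ellipse = c(32, 32, 18, 12, 0),
                     speckle_strength = 0.1, seed = 5)
  ph <- make_phantom(sp)
  fit <- slcv(ph$image, ph$truth, seg_params(fixed_iterations = TRUE),
              n_iters = 12)
  expect_equal(fit$iterations, 12L)
  expect_equal(nrow(fit$diagnostics), 12L)
  expect_equal(fit$force_evals, 12 * 64 * 64)
})

test_that("a clean two-phase ellipse initialized at truth stays at DSC >= 0.99", {
  sp <- phantom_spec(shape = c(128, 128), ellipse = c(64, 64, 35, 22, 0.3),
                     fg_level = 1, bg_level = 0, blur_sigma = 0,
                     speckle_strength = 0, bias_field_amplitude = 0)
  ph <- make_phantom(sp)
  fit <- slcv(ph$image, ph$truth, seg_params(), n_iters = 50)
  expect_gte(dsc(fit$mask, ph$truth), 0.99)
})

test_that("the multiscale driver degenerates to single-scale at coarse layer 0", {
  sp <- phantom_spec(shape = c(64, 64), ellipse = c(32, 32, 18, 12, 0.4),
                     speckle_strength = 0.15, seed = 31)
  ph <- make_phantom(sp)
  init <- make_initial_ellipse(sp, 0.05, 2, seed = 32)
  p <- seg_params(coarse_layer = 0, iters_coarse = 20, iters_fine = 5,
                  fixed_iterations = TRUE)
  fm <- mslcv(ph$image, init, p)
  fs <- slcv(ph$image, init, p, use_band = TRUE, n_iters = 25)
  expect_identical(fm$mask, fs$mask)
  expect_equal(fm$phi, fs$phi)
  expect_s3_class(fm, "mslcv_fit")
})

test_that("stage-wise schedule: bigger coarse radius proportions, band off at stage 2", {
  sp <- phantom_spec(shape = c(128, 128), ellipse = c(64, 64, 30, 20, 0),
                     speckle_strength = 0.15, seed = 41)
  ph <- make_phantom(sp)
  p <- seg_params(iters_coarse = 30, iters_fine = 5, fixed_iterations = TRUE)
  fit <- mslcv(ph$image, ph$truth, p)
  s1 <- fit$stage1$settings; s2 <- fit$settings
  # coarse-scale absolute radius smaller than fine-scale (Table-style schedule)
  expect_lte(s1$radius, s2$radius)
  expect_equal(s1$beta, p$beta / 2)
  expect_equal(s2$beta, p$beta)
  expect_gt(s1$band_halfwidth, 0)
  expect_equal(s2$band_halfwidth, 0)
  # two stages recorded in the diagnostics
  expect_setequal(unique(fit$diagnostics$stage), c(1L, 2L))
  expect_equal(fit$iterations, fit$stage1$iterations + nrow(
    fit$diagnostics[fit$diagnostics$stage == 2L, ]))
})

test_that("the multiscale driver does under 1/4 of the single-scale force evaluations", {
  # deterministic arithmetic at the reference iteration split (350+50 vs 400)
  sp <- phantom_spec(shape = c(128, 128), ellipse = c(64, 64, 30, 20, 0),
                     speckle_strength = 0.1, seed = 51)
  ph <- make_phantom(sp)
  p <- seg_params(fixed_iterations = TRUE)
  fm <- mslcv(ph$image, ph$truth, p)
  fs <- slcv(ph$image, ph$truth, p, n_iters = 400)
  expect_lt(fm$force_evals, fs$force_evals / 4)
})

test_that("fit objects print, summarize, and expose the fitted mask", {
  sp <- phantom_spec(shape = c(64, 64), ellipse = c(32, 32, 16, 11, 0),
                     speckle_strength = 0.1, seed = 61)
  ph <- make_phantom(sp)
  fit <- slcv(ph$image, ph$truth, seg_params(), n_iters = 5)
  expect_output(print(fit), "Single-scale")
  expect_output(summary(fit), "force evaluations")
  expect_identical(fitted(fit), fit$mask)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, image = ph$image))
})
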
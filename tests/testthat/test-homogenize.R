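# Build a one-row image embedding the worked example:
# tissue, air gap, bolus, exterior air.
worked_row <- function() {
  row <- c(0, 10, -800, -810, 300, 310, -1000, -1000)
  img <- image_grid(array(row, c(8, 1, 1)))
  bg <- structure_mask(array(c(TRUE, TRUE, rep(FALSE, 6)), c(8, 1, 1)),
                       label = "background")
  list(img = img, row = row,
       params = homogenize_params(background_region = bg, fill_seed = 42))
}

test_that("the worked 1-D row is homogenized step by step as specified", {
  w <- worked_row()
  h <- homogenize(w$img, w$params)
  out <- as.numeric(h$image$values)
  # background: mean 5, range (0, 10)
  expect_equal(h$background$mean, 5)
  expect_equal(h$background$range, c(0, 10))
  # tissue pixels untouched
  expect_identical(out[1:2], c(0, 10))
  # bolus pixels replaced by background-matched draws
  expect_true(all(out[5:6] >= 0 & out[5:6] <= 10))
  # former gap linearly interpolated between tissue edge and replacement
  expect_equal(out[3:4],
               10 + (out[5] - 10) * c(1, 2) / 3)
  # trailing exterior restored bit-identically
  expect_identical(out[7:8], c(-1000, -1000))
  # diagnostics: gap and trailing air flagged as air, bolus as replaced
  expect_identical(as.logical(h$masks$air$values),
                   w$row < -200)
  expect_identical(as.logical(h$masks$bolus_replaced$values),
                   w$row >= 100 & w$row <= 600)
})

test_that("an image with nothing to flag or replace passes through exactly", {
  set.seed(8)
  vals <- array(round(rnorm(1000, 0, 10)), c(10, 10, 10))
  vals[abs(vals) > 22] <- 0  # keep adjacent differences below the spike rule
  img <- image_grid(vals)
  bg <- structure_mask(array(TRUE, c(10, 10, 10)))
  h <- homogenize(img, homogenize_params(background_region = bg))
  expect_identical(h$image$values, img$values)
})

test_that("homogenization is deterministic given the fill seed", {
  sp <- tiny_spec(surface_thickness_cm = 0.5, tissue_sd = 10, bolus_sd = 10,
                  gap_profile = gap_profile(0, 360, 1.5), seed = 3)
  ph <- make_phantom(sp)
  par <- homogenize_params(background_region = background_box(ph),
                           fill_seed = 7)
  h1 <- homogenize(ph$image, par)
  h2 <- homogenize(ph$image, par)
  expect_identical(h1$image$values, h2$image$values)
  par2 <- homogenize_params(background_region = background_box(ph),
                            fill_seed = 8)
  expect_false(identical(homogenize(ph$image, par2)$image$values,
                         h1$image$values))
})

test_that("noiseless uniform-gap phantom: exterior preserved, no interior air,
           bolus region matched to background", {
  sp <- tiny_spec(semi_axes_mm = c(30, 25), slab_mm = 30,
                  surface_thickness_cm = 1,
                  gap_profile = gap_profile(0, 360, 1.5))
  ph <- make_phantom(sp)
  h <- homogenize(ph$image, homogenize_params(background_box(ph)))
  region <- ph$masks$body_outer$values
  expect_identical(h$image$values[!region], ph$image$values[!region])
  expect_equal(sum(h$image$values[region] < -200), 0)
  former <- ph$masks$bolus$values | ph$masks$gap$values
  expect_equal(mean(h$image$values[former]), 0, tolerance = 1)
})

test_that("on a noisy blurred phantom the homogenized image approaches its
           ground-truth twin", {
  sp <- phantom_spec(semi_axes_mm = c(30, 25), slab_mm = 30, margin_mm = 6,
                     bone = NULL, target = NULL, surface_thickness_cm = 1,
                     gap_profile = gap_profile(c(190, 320), c(260, 355),
                                               c(1.5, 0.8)), seed = 5)
  ph <- make_phantom(sp)
  h <- homogenize(ph$image, homogenize_params(background_box(ph)))
  region <- ph$masks$body_outer$values
  expect_gt(mean(h$image$values[region] > -200), 0.99)
  former <- ph$masks$bolus$values | ph$masks$gap$values
  bg_sd <- sd(ph$image$values[background_box(ph)$values])
  expect_lt(abs(mean(h$image$values[former]) - h$background$mean), 2 * bg_sd)
})

test_that("wider gaps never increase the residual sub-air count in the body", {
  counts <- vapply(c(0.5, 1.5, 2.5), function(w) {
    sp <- tiny_spec(surface_thickness_cm = 0.6,
                    gap_profile = gap_profile(0, 360, w))
    ph <- make_phantom(sp)
    h <- homogenize(ph$image, homogenize_params(background_box(ph)))
    sum(h$image$values[ph$masks$body_outer$values] < -200)
  }, numeric(1))
  expect_true(all(counts == 0))
})

test_that("air classification is an exact threshold", {
  img <- image_grid(array(c(-1000, -201, -200, 0, 500), c(5, 1, 1)))
  expect_identical(as.logical(classify_air(img)$values),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(classify_air(image_grid(array(-1000, c(3, 3, 3))))$values))
  expect_false(any(classify_air(image_grid(array(0, c(3, 3, 3))))$values))
  # generator truth: classified air covers gap and exterior on a sharp phantom
  sp <- tiny_spec(surface_thickness_cm = 0.5,
                  gap_profile = gap_profile(0, 360, 2))
  ph <- make_phantom(sp)
  air <- classify_air(ph$image)$values
  outside_or_gap <- ph$masks$gap$values | !ph$masks$body_outer$values
  expect_true(all(air[ph$masks$gap$values]))
  expect_true(all(outside_or_gap[air]))
})

test_that("background sampling returns exact statistics and rejects air", {
  img <- image_grid(array(c(-10, 0, 10, -1000), c(4, 1, 1)))
  reg <- structure_mask(array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1)))
  s <- sample_background(img, reg)
  expect_equal(s$mean, 0)
  expect_equal(s$range, c(-10, 10))
  uni <- image_grid(array(0, c(2, 2, 2)))
  su <- sample_background(uni, structure_mask(array(TRUE, c(2, 2, 2))))
  expect_equal(su$range, c(0, 0))
  bad <- structure_mask(array(TRUE, c(4, 1, 1)))
  expect_error(sample_background(img, bad), "intersects air")
  empty <- structure_mask(array(FALSE, c(4, 1, 1)))
  expect_error(sample_background(img, empty), "empty")
})

test_that("sampled background mean converges to the spec tissue mean", {
  sp <- phantom_spec(semi_axes_mm = c(30, 25), slab_mm = 40, bone = NULL,
                     target = NULL, tissue_sd = 20, psf_sigma_mm = 0,
                     margin_mm = 6, seed = 6)
  ph <- make_phantom(sp)
  s <- sample_background(ph$image,
                         background_box(ph, halfwidth_mm = c(12, 10, 14)))
  expect_gt(s$n, 1e4)
  expect_lt(abs(s$mean - 0), 1)
})

test_that("rows with no above-air content are passed through and counted", {
  vals <- array(-1000, c(6, 2, 1))
  vals[2:4, 1, 1] <- c(0, 10, 0)
  img <- image_grid(vals)
  bg <- structure_mask(array(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                               rep(FALSE, 6)), c(6, 2, 1)))
  h <- homogenize(img, homogenize_params(background_region = bg))
  expect_identical(h$image$values, vals)
  expect_equal(h$n_empty_rows, 1)
})

test_that("homogenize parameter validation enforces the documented bounds", {
  bg <- structure_mask(array(TRUE, c(2, 2, 2)))
  expect_error(homogenize_params(bg, spike_threshold_hu = 0), "spike")
  expect_error(homogenize_params(bg, bolus_window_hu = c(600, 100)),
               "non-empty")
  expect_error(homogenize_params(bg, air_threshold_hu = 150), "below")
  expect_error(homogenize_params(bg, axis = 3), "axis")
})
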
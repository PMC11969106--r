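test_that("noiseless ellipse-cylinder volume matches the closed form within 1%", {
  sp <- tiny_spec(semi_axes_mm = c(30, 25), slab_mm = 30)
  ph <- make_phantom(sp)
  analytic <- pi * 3 * 2.5 * 3  # cm^3
  expect_lt(abs(volume_cm3(ph$masks$body) / analytic - 1), 0.01)
  # circular cylinder too
  sp2 <- tiny_spec(semi_axes_mm = c(25, 25), slab_mm = 40)
  ph2 <- make_phantom(sp2)
  expect_lt(abs(volume_cm3(ph2$masks$body) / (pi * 2.5^2 * 4) - 1), 0.01)
})

test_that("the default hemispherical target voxelizes to 23 cm^3", {
  sp <- phantom_spec(semi_axes_mm = c(30, 25), slab_mm = 60, bone = NULL,
                     tissue_sd = 0, psf_sigma_mm = 0, margin_mm = 6)
  ph <- make_phantom(sp)
  expect_equal(round(volume_cm3(ph$masks$target)), 23)
})

test_that("phantom generation is bit-identical for identical spec and seed", {
  sp <- phantom_spec(semi_axes_mm = c(24, 20), slab_mm = 20, margin_mm = 6,
                     bone = NULL, target = NULL, surface_thickness_cm = 0.5,
                     gap_profile = gap_profile(190, 260, 1.5), seed = 9)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$masks$body_outer$values, b$masks$body_outer$values)
  # different seed changes the noise
  sp$seed <- 10
  expect_false(identical(make_phantom(sp)$image$values, a$image$values))
})

test_that("truth masks are pairwise disjoint and the shell has spec thickness", {
  sp <- tiny_spec(surface_thickness_cm = 0.6,
                  gap_profile = gap_profile(190, 260, 2))
  ph <- make_phantom(sp)
  expect_false(any(ph$masks$body$values & ph$masks$bolus$values))
  expect_false(any(ph$masks$body$values & ph$masks$gap$values))
  expect_false(any(ph$masks$gap$values & ph$masks$bolus$values))
  expect_identical(ph$masks$body_outer$values,
                   ph$masks$body$values | ph$masks$gap$values |
                     ph$masks$bolus$values)
  # shell thickness along the +x surface normal (no gap at theta = 0):
  # bolus voxels on the positive x half-axis should span ~6 mm
  mid <- which.min(abs(axis_coords(ph$image, 3) - ph$landmarks$z_mid_mm))
  j0 <- which.min(abs(axis_coords(ph$image, 2)))
  pos_x <- axis_coords(ph$image, 1) > 0
  run <- sum(ph$masks$bolus$values[pos_x, j0, mid])
  expect_lte(abs(run * ph$image$spacing[1] - 6), 1)
})

test_that("gap mask is empty when no gap is requested", {
  ph <- make_phantom(tiny_spec(surface_thickness_cm = 1))
  expect_equal(sum(ph$masks$gap$values), 0)
  expect_gt(sum(ph$masks$bolus$values), 0)
})

test_that("invalid specs are rejected", {
  expect_error(make_phantom(tiny_spec(gap_profile = gap_profile(0, 90, 2))),
               "zero-thickness")
  expect_error(tiny_spec(bolus_hu = 50), "100, 600")
  expect_error(tiny_spec(exterior_hu = 0), "below -200")
  expect_error(tiny_spec(tissue_hu = -500), "-200")
  expect_error(make_phantom(tiny_spec(surface_thickness_cm = 2,
                                      max_lateral_extent_mm = c(30, 30))),
               "exceeds the lattice extent")
})

test_that("tissue noise SD is recovered within 5% on an unblurred phantom", {
  sp <- phantom_spec(semi_axes_mm = c(30, 25), slab_mm = 50, bone = NULL,
                     target = NULL, tissue_sd = 20, psf_sigma_mm = 0,
                     margin_mm = 6, seed = 2)
  ph <- make_phantom(sp)
  v <- ph$image$values[ph$masks$body$values]
  expect_gt(length(v), 1e5)
  expect_lt(abs(sd(v) / 20 - 1), 0.05)
})

test_that("weight-loss series shares one lattice with decreasing volumes", {
  sp <- tiny_spec(gap_profile = gap_profile(190, 260, 1.5))
  ser <- make_weight_loss_series(sp, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_length(ser, 5)
  dims <- lapply(ser, function(s) dim(s$raw$image$values))
  expect_true(all(vapply(dims, identical, logical(1), dims[[1]])))
  vols <- vapply(ser, function(s) volume_cm3(s$truth$masks$body_outer),
                 numeric(1))
  expect_true(all(diff(vols) < 0))  # descending thickness, shrinking body
  # raw and twin share lattice and core values
  s1 <- ser[[1]]
  expect_identical(dim(s1$raw$image$values), dim(s1$truth$image$values))
  core <- s1$raw$masks$body$values
  expect_identical(s1$raw$image$values[core], s1$truth$image$values[core])
  # twin has no gaps and its body covers the raw bolus
  expect_equal(sum(s1$truth$masks$gap$values), 0)
  expect_true(all(s1$truth$masks$body$values[s1$raw$masks$bolus$values]))
})

test_that("single zero-thickness series reduces to the core phantom", {
  sp <- tiny_spec()
  ser <- make_weight_loss_series(sp, 0)
  expect_length(ser, 1)
  expect_identical(ser[[1]]$truth$masks$body_outer$values,
                   ser[[1]]$raw$masks$body$values)
  expect_error(make_weight_loss_series(sp, numeric(0)), "empty")
})

test_that("truth body volume is monotone in surface thickness", {
  sp <- tiny_spec()
  ser <- make_weight_loss_series(sp, c(0, 0.3, 0.6, 0.9))
  vols <- vapply(ser, function(s) volume_cm3(s$truth$masks$body_outer),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
})
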
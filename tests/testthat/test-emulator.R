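test_that("emulation parameter validation enforces threshold ordering", {
  expect_error(contour_emulation_params(gap_exclusion_threshold_mm = 0.3),
               "exceed")
  expect_error(contour_emulation_params(gap_exclusion_threshold_mm = -1),
               ">= 0")
})

test_that("accurate mode returns the true outline including the bolus", {
  sp <- tiny_spec(surface_thickness_cm = 0.5,
                  gap_profile = gap_profile(190, 260, 1))
  ph <- make_phantom(sp)
  m <- emulate_autocontour(ph, contour_emulation_params("accurate"))
  expect_identical(m$values, ph$masks$body_outer$values)
  expect_equal(volume_cm3(m), volume_cm3(ph$masks$body_outer))
})

test_that("pure reference anchoring copies the reference body so the volume
           deviation equals the generated shell volume", {
  ser <- make_weight_loss_series(tiny_spec(), c(0.8, 0))
  ref_body <- ser[[1]]$truth$masks$body_outer
  p <- contour_emulation_params("reference_anchored", anchor_adaptation = 0,
                                anchor_jitter_mm = 0)
  m <- emulate_autocontour(ser[[2]]$truth, p, reference_body = ref_body)
  expect_identical(m$values, ref_body$values)
  dev <- volume_cm3(m) - volume_cm3(ser[[2]]$truth$masks$body_outer)
  shell <- volume_cm3(ser[[1]]$truth$masks$body_outer) -
    volume_cm3(ser[[2]]$truth$masks$body_outer)
  expect_equal(dev, shell)
})

test_that("partial anchoring lands between reference and truth and is
           seed-reproducible", {
  ser <- make_weight_loss_series(tiny_spec(), c(0.8, 0))
  ref_body <- ser[[1]]$truth$masks$body_outer
  p <- contour_emulation_params("reference_anchored", anchor_adaptation = 0.5,
                                anchor_jitter_mm = 0, seed = 3)
  m <- emulate_autocontour(ser[[2]]$truth, p, reference_body = ref_body,
                           session_index = 2)
  v <- volume_cm3(m)
  expect_lt(v, volume_cm3(ref_body))
  expect_gt(v, volume_cm3(ser[[2]]$truth$masks$body_outer))
  m2 <- emulate_autocontour(ser[[2]]$truth, p, reference_body = ref_body,
                            session_index = 2)
  expect_identical(m$values, m2$values)
})

test_that("reference anchoring without a reference mask errors", {
  ph <- make_phantom(tiny_spec())
  expect_error(
    emulate_autocontour(ph, contour_emulation_params("reference_anchored")),
    "requires a reference")
})

test_that("a uniform 3 mm gap excludes the bolus entirely", {
  sp <- tiny_spec(surface_thickness_cm = 0.5,
                  gap_profile = gap_profile(0, 360, 3))
  ph <- make_phantom(sp)
  m <- emulate_autocontour(ph, contour_emulation_params("bolus_excluding"))
  expect_false(any(m$values & ph$masks$bolus$values))
  expect_identical(m$values, ph$masks$body$values)
})

test_that("gaps between the instability and exclusion thresholds keep the
           bolus attached", {
  sp <- tiny_spec(surface_thickness_cm = 0.5,
                  gap_profile = gap_profile(0, 360, 1))
  ph <- make_phantom(sp)
  m <- emulate_autocontour(ph, contour_emulation_params("bolus_excluding"))
  expect_identical(m$values, ph$masks$body_outer$values)
})

test_that("sub-0.4 mm gap sectors behave randomly but reproducibly", {
  sp <- tiny_spec(surface_thickness_cm = 0.5,
                  gap_profile = gap_profile(90, 270, 0.2))
  ph <- make_phantom(sp)
  p1 <- contour_emulation_params("bolus_excluding", instability_prob = 1,
                                 seed = 5)
  m_excl <- emulate_autocontour(ph, p1)
  sector_bolus <- ph$masks$bolus$values & !m_excl$values
  expect_gt(sum(sector_bolus), 0)  # sector bolus dropped
  p0 <- contour_emulation_params("bolus_excluding", instability_prob = 0,
                                 seed = 5)
  m_keep <- emulate_autocontour(ph, p0)
  expect_identical(m_keep$values, ph$masks$body_outer$values)
  # intermediate probability: reproducible given the seed
  ph2 <- make_phantom(sp)
  p <- contour_emulation_params("bolus_excluding", instability_prob = 0.5,
                                seed = 5)
  expect_identical(emulate_autocontour(ph, p, session_index = 1)$values,
                   emulate_autocontour(ph2, p, session_index = 1)$values)
})
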
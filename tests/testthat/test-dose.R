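test_that("DVH metrics: uniform dose, linear ramp, monotonicity, errors", {
  allm <- structure_mask(array(TRUE, c(4, 4, 4)))
  u <- dose_grid(array(70, c(4, 4, 4)))
  for (q in c(1, 50, 95, 99, 100))
    expect_equal(dvh_metric(u, allm, q), 70)
  n <- 101
  ramp <- dose_grid(array(seq(0, 100, length.out = n), c(n, 1, 1)))
  rm_ <- structure_mask(array(TRUE, c(n, 1, 1)))
  expect_equal(dvh_metric(ramp, rm_, 95), 5)
  expect_equal(dvh_metric(ramp, rm_, 50), 50)
  qs <- c(10, 30, 50, 70, 90, 99)
  dq <- vapply(qs, function(q) dvh_metric(ramp, rm_, q), numeric(1))
  expect_true(all(diff(dq) < 0))  # Dq% non-increasing in q
  expect_error(dvh_metric(u, allm, 0), "0, 100")
  expect_error(dvh_metric(u, structure_mask(array(FALSE, c(4, 4, 4))), 95),
               "empty")
})

test_that("plan goals evaluate D95/D99 against their thresholds", {
  m <- structure_mask(array(TRUE, c(5, 5, 5)))
  d <- dose_grid(array(71, c(5, 5, 5)))
  goals <- data.frame(metric = c("D95", "D99"), threshold_gy = c(70, 66.5),
                      direction = c(">", ">"))
  g <- check_plan_goals(d, m, goals)
  expect_true(all(g$pass))
  g2 <- check_plan_goals(dose_grid(array(60, c(5, 5, 5))), m, goals)
  expect_false(any(g2$pass))
})

test_that("gamma: identity passes everywhere and a 3% global scaling stays
           within the 3% DD criterion", {
  set.seed(21)
  r <- dose_grid(array(runif(14^3, 0, 2), c(14, 14, 14)))
  g <- gamma_pass_rate(r, r)
  expect_equal(g$pass_percent, 100)
  expect_equal(max(g$gamma, na.rm = TRUE), 0)
  e <- dose_grid(1.03 * r$values)
  expect_equal(gamma_pass_rate(r, e)$pass_percent, 100)
})

test_that("gamma equals the brute-force oracle on random grids", {
  set.seed(31)
  for (i in 1:2) {
    r <- dose_grid(array(runif(12^3, 0, 2), c(12, 12, 12)))
    e <- dose_grid(array(pmax(0, r$values + rnorm(12^3, 0, 0.05)),
                         c(12, 12, 12)))
    mine <- gamma_pass_rate(r, e, gamma_params(step_mm = 1))$pass_percent
    expect_equal(mine, gamma_oracle(r, e), tolerance = 1e-3)
  }
})

test_that("loosening DD or DTA never decreases the gamma pass rate", {
  set.seed(41)
  r <- dose_grid(array(runif(12^3, 0, 2), c(12, 12, 12)))
  e <- dose_grid(array(pmax(0, r$values + rnorm(12^3, 0, 0.08)),
                       c(12, 12, 12)))
  p_t <- gamma_pass_rate(r, e, gamma_params(dd_percent = 2, dta_mm = 2,
                                            step_mm = 2 / 3))$pass_percent
  p_dd <- gamma_pass_rate(r, e, gamma_params(dd_percent = 4, dta_mm = 2,
                                             step_mm = 2 / 3))$pass_percent
  p_dta <- gamma_pass_rate(r, e, gamma_params(dd_percent = 2, dta_mm = 4,
                                              step_mm = 2 / 3))$pass_percent
  expect_gte(p_dd, p_t)
  expect_gte(p_dta, p_t)
})

test_that("gamma is not symmetric in its arguments", {
  # a hot spike in the reference fails against a flat eval, but a flat
  # reference passes against the spiky eval (nearby agreement exists)
  r <- array(1, c(9, 9, 9)); r[5, 5, 5] <- 2
  flat <- dose_grid(array(1, c(9, 9, 9)))
  spiky <- dose_grid(r)
  p1 <- gamma_pass_rate(spiky, flat, gamma_params(cutoff_percent = 0,
                                                  step_mm = 1))$pass_percent
  p2 <- gamma_pass_rate(flat, spiky, gamma_params(cutoff_percent = 0,
                                                  step_mm = 1))$pass_percent
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("gamma rejects degenerate references", {
  z <- dose_grid(array(0, c(4, 4, 4)))
  d <- dose_grid(array(1, c(4, 4, 4)))
  expect_error(gamma_pass_rate(z, d), "zero reference maximum")
  expect_error(gamma_params(step_mm = 2), "dta/3")
})

test_that("resampling a dose to half spacing and back keeps gamma at 100%", {
  set.seed(51)
  base <- array(0, c(12, 12, 12))
  base[4:9, 4:9, 4:9] <- 2
  d <- dose_grid(base)
  half <- list(dims = c(23L, 23L, 23L), spacing = c(0.5, 0.5, 0.5),
               origin = c(0, 0, 0))
  rt <- resample_dose(resample_dose(d, half, "trilinear"), d, "trilinear")
  g <- gamma_pass_rate(d, rt, gamma_params(step_mm = 1))
  expect_gte(g$pass_percent, 99.9)
})

test_that("dose deviation tracking is a plain percentage", {
  t1 <- dose_deviation_track(c(2, 2, 2), 2)
  expect_equal(unname(t1$deviation_percent), c(0, 0, 0))
  t2 <- dose_deviation_track(c(1.76, 2.1), 2)
  expect_equal(unname(t2$deviation_percent), c(-12, 5))
  expect_equal(t2$max_abs_percent, 12)
  expect_error(dose_deviation_track(1, 0), "nonzero")
})

test_that("toy model: central-axis falloff is exponential in depth", {
  vals <- array(0, c(21, 40, 9))          # uniform water-density block
  img <- image_grid(vals)
  tg <- structure_mask(array(FALSE, c(21, 40, 9)))
  tg$values[9:13, 18:22, 4:6] <- TRUE
  mod <- toy_dose_model(img, tg, beams = list(list(direction = "anterior",
                                                   weight = 1)),
                        mu_per_cm = 0.05, prescription_gy = 70)
  axis_dose <- mod$dose$values[11, , 5]
  depth_cm <- (seq_len(40) - 0.5) * 0.1
  ratio <- log(axis_dose) + 0.05 * depth_cm
  expect_lt(diff(range(ratio)), 1e-9)     # pure exponential along the ray
})

test_that("toy model: opposed beams on a symmetric phantom give a symmetric
           dose, and dose is linear in the prescription", {
  vals <- array(0, c(20, 21, 9))
  img <- image_grid(vals)
  tg <- structure_mask(array(FALSE, c(20, 21, 9)))
  tg$values[9:12, 9:13, 4:6] <- TRUE
  beams <- list(list(direction = "left", weight = 1),
                list(direction = "right", weight = 1))
  mod <- toy_dose_model(img, tg, beams = beams, prescription_gy = 70)
  flip <- mod$dose$values[rev(seq_len(20)), , ]
  expect_equal(mod$dose$values, flip, tolerance = 1e-9)
  mod2 <- toy_dose_model(img, tg, beams = beams, prescription_gy = 140)
  expect_equal(mod2$dose$values, 2 * mod$dose$values, tolerance = 1e-9)
})

test_that("added upstream surface layer reduces D95 under a fixed scale", {
  ser <- make_weight_loss_series(
    tiny_spec(target = list(radius_mm = 6, angle_deg = 270, hu = 50)),
    c(1, 0))
  beams <- list(list(direction = "anterior", weight = 1))
  thin <- ser[[2]]; thick <- ser[[1]]
  tg_thin <- thin$truth$masks$target
  tg_thick <- thick$truth$masks$target
  ref <- toy_dose_model(thin$truth$image, tg_thin, beams = beams)
  sched <- toy_dose_model(thick$truth$image, tg_thick, beams = beams,
                          norm_scale = ref$scale)
  expect_lt(dvh_metric(sched$dose, tg_thick, 95),
            dvh_metric(ref$dose, tg_thin, 95))
})

test_that("toy model rejects an empty target", {
  img <- image_grid(array(0, c(5, 5, 5)))
  expect_error(toy_dose_model(img, structure_mask(array(FALSE, c(5, 5, 5)))),
               "empty")
})

test_that("surface cropping removes the shallow part of the target", {
  sp <- tiny_spec(target = list(radius_mm = 6, angle_deg = 270, hu = 50))
  ph <- make_phantom(sp)
  tg <- ph$masks$target
  cropped <- crop_target_from_surface(tg, ph$masks$body_outer, margin_mm = 3)
  expect_lt(volume_cm3(cropped), volume_cm3(tg))
  expect_true(all(tg$values[cropped$values]))
})
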
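# Independent oracles and small fixture factories shared across tests.

# Brute-force 3-D gamma: exhaustive search over voxel centers within the
# search radius, no interpolation. Deliberately independent of the package's
# sorted-offset / trilinear implementation.
gamma_oracle <- function(ref, ev, dd_pct = 3, dta = 3, cutoff_pct = 10,
                         radius_f = 2) {
  dims <- dim(ref$values); sp <- ref$spacing
  dmax <- max(ref$values)
  ddabs <- dd_pct / 100 * dmax
  cut <- cutoff_pct / 100 * dmax
  co <- expand.grid(i = 1:dims[1], j = 1:dims[2], k = 1:dims[3])
  pos <- cbind(co$i * sp[1], co$j * sp[2], co$k * sp[3])
  rv <- as.numeric(ref$values); ev_ <- as.numeric(ev$values)
  R2 <- (radius_f * dta)^2
  pass <- 0L; n <- 0L
  for (s in which(rv >= cut)) {
    d2 <- (pos[, 1] - pos[s, 1])^2 + (pos[, 2] - pos[s, 2])^2 +
      (pos[, 3] - pos[s, 3])^2
    near <- d2 <= R2 + 1e-9
    g2 <- min(((ev_[near] - rv[s]) / ddabs)^2 + d2[near] / dta^2)
    n <- n + 1L
    if (g2 <= 1) pass <- pass + 1L
  }
  100 * pass / n
}

# Brute-force straight-line fit: refined 2-D grid search over slope and
# intercept minimizing the population residual variance, then the R^2%
# formula applied directly.
r2_grid_oracle <- function(x, y) {
  pvar <- function(v) mean((v - mean(v))^2)
  xr <- max(diff(range(x)), 1e-9)
  s_lo <- -4 * diff(range(y)) / xr - 1; s_hi <- 4 * diff(range(y)) / xr + 1
  i_lo <- min(y) - abs(s_hi) * max(abs(x)) - 1
  i_hi <- max(y) + abs(s_hi) * max(abs(x)) + 1
  best <- c(NA, NA)
  for (stage in 1:5) {
    ss <- seq(s_lo, s_hi, length.out = 41)
    ii <- seq(i_lo, i_hi, length.out = 41)
    obj <- outer(ss, ii, Vectorize(function(s, b) pvar(y - s * x - b)))
    w <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    best <- c(ss[w[1]], ii[w[2]])
    ds <- (s_hi - s_lo) / 40; di <- (i_hi - i_lo) / 40
    s_lo <- best[1] - 2 * ds; s_hi <- best[1] + 2 * ds
    i_lo <- best[2] - 2 * di; i_hi <- best[2] + 2 * di
  }
  100 - pvar(y - best[1] * x - best[2]) / pvar(y) * 100
}

# Small fast phantom specs used throughout the module tests.
tiny_spec <- function(...) {
  defaults <- list(semi_axes_mm = c(24, 20), slab_mm = 24, z_pad_mm = 2,
                   margin_mm = 6, bone = NULL, target = NULL,
                   tissue_sd = 0, bolus_sd = 0, psf_sigma_mm = 0, seed = 11)
  do.call(phantom_spec, utils::modifyList(defaults, list(...),
                                          keep.null = TRUE))
}

small_study_config <- function(seed = 33) {
  study_config(
    spec = phantom_spec(semi_axes_mm = c(24, 20), slab_mm = 30, z_pad_mm = 2,
                        margin_mm = 6, bone = NULL,
                        target = list(radius_mm = 8, angle_deg = 270, hu = 50)),
    thicknesses_cm = c(1, 0.5, 0),
    weight_loss_gaps = gap_profile(c(190, 320), c(260, 355), c(1.5, 0.8)),
    bolus_cases = list(
      list(thickness_cm = 0.5,
           gap_profile = gap_profile(c(200, 60), c(290, 110), c(3, 3)))),
    z_lim_cm = c(0.3, 2.7),
    seed = seed)
}
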
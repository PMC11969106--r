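#' Dose-volume histogram metric Dq%
#'
#' Returns the dose level received by at least `q` percent of the structure
#' volume: the `(1 - q/100)` quantile of the voxel dose multiset, with
#' linear interpolation between order statistics (`type = 7`); masks are
#' binary so no sub-voxel partial volumes are modelled.
#'
#' @param dose a [dose_grid()] on the same lattice as `mask` (resample with
#'   [resample_dose()] first if needed).
#' @param mask nonempty [structure_mask()].
#' @param q percent of the structure volume, in (0, 100].
#' @return dose in Gy.
#' @export
dvh_metric <- function(dose, mask, q) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  stop_if_lattice_mismatch(dose, mask, "dose and mask")
  if (q <= 0 || q > 100) stop("q must lie in (0, 100]")
  v <- dose$values[mask$values]
  if (length(v) == 0) stop("empty structure mask")
  stats::quantile(v, probs = 1 - q / 100, type = 7, names = FALSE)
}

#' Check DVH goals against a plan prescription
#'
#' @param dose,mask as in [dvh_metric()].
#' @param goals data frame with columns `metric` (e.g. `"D95"`),
#'   `threshold_gy` and `direction` (`">"` or `"<"`).
#' @return the goals data frame with added `value_gy` and `pass` columns.
#' @export
check_plan_goals <- function(dose, mask, goals) {
  stopifnot(all(c("metric", "threshold_gy", "direction") %in% names(goals)),
            all(goals$threshold_gy > 0))
  q <- as.numeric(sub("^D", "", goals$metric))
  goals$value_gy <- vapply(q, function(qi) dvh_metric(dose, mask, qi),
                           numeric(1))
  goals$pass <- ifelse(goals$direction == ">",
                       goals$value_gy > goals$threshold_gy,
                       goals$value_gy < goals$threshold_gy)
  goals
}

#' Gamma-evaluation parameters
#'
#' @param dd_percent dose-difference criterion, percent (default 3).
#' @param dta_mm distance-to-agreement criterion, mm (default 3).
#' @param normalization `"global"` (percent of the reference maximum,
#'   clinical default) or `"local"` (percent of the local reference dose).
#' @param cutoff_percent low-dose cutoff: reference voxels below this percent
#'   of the reference maximum are excluded from the pass rate.
#' @param search_radius_factor search radius in multiples of DTA.
#' @param step_mm pitch of the interpolated search grid; must not exceed
#'   `dta_mm / 3`.
#' @return a `gamma_params` object.
#' @export
gamma_params <- function(dd_percent = 3, dta_mm = 3,
                         normalization = c("global", "local"),
                         cutoff_percent = 10, search_radius_factor = 2,
                         step_mm = dta_mm / 3) {
  normalization <- match.arg(normalization)
  if (dd_percent <= 0 || dta_mm <= 0) stop("dd and dta must be > 0")
  if (cutoff_percent < 0 || cutoff_percent >= 100)
    stop("cutoff must lie in [0, 100)")
  if (step_mm > dta_mm / 3 + 1e-9) stop("step must be <= dta/3")
  structure(list(dd_percent = dd_percent, dta_mm = dta_mm,
                 normalization = normalization,
                 cutoff_percent = cutoff_percent,
                 search_radius_factor = search_radius_factor,
                 step_mm = step_mm),
            class = "gamma_params")
}

#' 3-D gamma index pass rate
#'
#' For every reference voxel above the low-dose cutoff, the gamma index is
#' the minimum over evaluated positions within the search radius of
#' `sqrt((dose difference / DD)^2 + (distance / DTA)^2)`; the evaluated dose
#' is trilinearly interpolated on a cubic search grid of pitch `step_mm`. A
#' voxel passes when gamma <= 1. Gamma is not symmetric in its arguments:
#' swapping reference and evaluated distributions can change the result.
#'
#' @param ref,eval [dose_grid()]s on one lattice ([resample_dose()] first if
#'   they differ).
#' @param params a [gamma_params()].
#' @return list with `pass_percent`, `gamma` (the gamma map, `NA` below
#'   cutoff) and `n_evaluated`.
#' @export
gamma_pass_rate <- function(ref, eval, params = gamma_params()) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval, "dose_grid"),
            inherits(params, "gamma_params"))
  stop_if_lattice_mismatch(ref, eval, "ref and eval dose grids")
  dmax <- max(ref$values)
  if (params$normalization == "global" && dmax <= 0)
    stop("zero reference maximum under global normalization")
  cutoff_abs <- params$cutoff_percent / 100 * dmax
  if (!any(ref$values >= cutoff_abs) || all(ref$values < cutoff_abs))
    stop("all reference voxels lie below the low-dose cutoff")
  dd_abs <- if (params$normalization == "global")
    params$dd_percent / 100 * dmax
  else pmax(params$dd_percent / 100 * ref$values, 1e-12)
  gm <- cpp_gamma_map(as.numeric(ref$values), as.numeric(eval$values),
                      dim(ref$values), ref$spacing,
                      as.numeric(dd_abs), params$dta_mm,
                      params$search_radius_factor * params$dta_mm,
                      params$step_mm, cutoff_abs)
  n_eval <- sum(!is.na(gm))
  list(pass_percent = 100 * sum(gm <= 1, na.rm = TRUE) / n_eval,
       gamma = array(gm, dim(ref$values)), n_evaluated = n_eval)
}

#' Per-session percent deviation of a dose metric from the planned value
#'
#' @param session_values numeric vector (optionally named by session) of the
#'   metric per session.
#' @param planned nonzero planned value of the metric.
#' @return list with `deviation_percent` per session and
#'   `max_abs_percent`.
#' @export
dose_deviation_track <- function(session_values, planned) {
  if (!is.finite(planned) || planned == 0) stop("planned value must be nonzero")
  dev <- 100 * (session_values - planned) / planned
  list(deviation_percent = dev, max_abs_percent = max(abs(dev)))
}

#' Build a coarser dose lattice covering an image
#'
#' @param image an [image_grid()].
#' @param spacing_mm dose grid spacing (default 2.5 mm, the clinical
#'   0.25 cm resolution).
#' @return list with `dims`, `spacing`, `origin` describing the lattice.
#' @export
make_dose_lattice <- function(image, spacing_mm = 2.5) {
  sp <- rep(spacing_mm, length.out = 3)
  ext <- (dim(image$values) - 1) * image$spacing
  list(dims = pmax(2L, as.integer(floor(ext / sp)) + 1L), spacing = sp,
       origin = image$origin)
}

#' Resample a dose grid onto another lattice
#'
#' @param dose a [dose_grid()].
#' @param lattice target geometry: an [image_grid()] / [dose_grid()] /
#'   [structure_mask()], or a list from [make_dose_lattice()].
#' @param method `"nearest"` (default, the DVH convention) or
#'   `"trilinear"`.
#' @return a [dose_grid()] on the target lattice; positions outside the
#'   source extent get 0 Gy.
#' @export
resample_dose <- function(dose, lattice, method = c("nearest", "trilinear")) {
  method <- match.arg(method)
  stopifnot(inherits(dose, "dose_grid"))
  if (!is.null(lattice$values)) {
    dims <- dim(lattice$values); sp <- lattice$spacing; or <- lattice$origin
  } else {
    dims <- lattice$dims; sp <- lattice$spacing; or <- lattice$origin
  }
  # fractional source indices of target voxel centers, per axis
  fx <- (or[1] + (seq_len(dims[1]) - 1) * sp[1] - dose$origin[1]) /
    dose$spacing[1]
  fy <- (or[2] + (seq_len(dims[2]) - 1) * sp[2] - dose$origin[2]) /
    dose$spacing[2]
  fz <- (or[3] + (seq_len(dims[3]) - 1) * sp[3] - dose$origin[3]) /
    dose$spacing[3]
  sd <- dim(dose$values)
  out <- array(0, dims)
  if (method == "nearest") {
    ix <- round(fx) + 1; iy <- round(fy) + 1; iz <- round(fz) + 1
    okx <- ix >= 1 & ix <= sd[1]; oky <- iy >= 1 & iy <= sd[2]
    okz <- iz >= 1 & iz <= sd[3]
    out[okx, oky, okz] <- dose$values[ix[okx], iy[oky], iz[okz]]
  } else {
    gx <- pmin(pmax(fx, 0), sd[1] - 1); tx <- gx - floor(gx)
    gy <- pmin(pmax(fy, 0), sd[2] - 1); ty <- gy - floor(gy)
    gz <- pmin(pmax(fz, 0), sd[3] - 1); tz <- gz - floor(gz)
    x0 <- floor(gx) + 1; x1 <- pmin(x0 + 1, sd[1])
    y0 <- floor(gy) + 1; y1 <- pmin(y0 + 1, sd[2])
    z0 <- floor(gz) + 1; z1 <- pmin(z0 + 1, sd[3])
    wx <- array(tx, dims)
    wy <- array(rep(rep(ty, each = dims[1]), times = dims[3]), dims)
    wz <- array(rep(tz, each = dims[1] * dims[2]), dims)
    v <- dose$values
    out <- (1 - wz) * ((1 - wy) * ((1 - wx) * v[x0, y0, z0] + wx * v[x1, y0, z0]) +
                       wy * ((1 - wx) * v[x0, y1, z0] + wx * v[x1, y1, z0])) +
           wz * ((1 - wy) * ((1 - wx) * v[x0, y0, z1] + wx * v[x1, y0, z1]) +
                 wy * ((1 - wx) * v[x0, y1, z1] + wx * v[x1, y1, z1]))
    inside_x <- fx >= 0 & fx <= sd[1] - 1
    inside_y <- fy >= 0 & fy <= sd[2] - 1
    inside_z <- fz >= 0 & fz <= sd[3] - 1
    out[!inside_x, , ] <- 0; out[, !inside_y, ] <- 0; out[, , !inside_z] <- 0
  }
  dose_grid(out, sp, or)
}

#' Resample a structure mask onto another lattice (nearest neighbor)
#'
#' @param mask a [structure_mask()].
#' @param lattice target geometry (see [resample_dose()]).
#' @return a [structure_mask()] on the target lattice.
#' @export
resample_mask <- function(mask, lattice) {
  d <- dose_grid(array(as.numeric(mask$values), dim(mask$values)),
                 mask$spacing, mask$origin)
  r <- resample_dose(d, lattice, method = "nearest")
  structure_mask(array(r$values > 0.5, dim(r$values)), r$spacing, r$origin,
                 mask$label)
}

#' Crop a surface target back from the body surface
#'
#' Skin-sparing evaluation structure: removes target voxels lying within
#' `margin_mm` of the body surface (per-slice in-plane depth), used for the
#' 0 cm session where the target would otherwise reach the skin.
#'
#' @param target,body [structure_mask()]s on one lattice; `target` must lie
#'   inside `body`.
#' @param margin_mm crop depth, default 3 mm.
#' @return the cropped [structure_mask()].
#' @export
crop_target_from_surface <- function(target, body, margin_mm = 3) {
  stop_if_lattice_mismatch(target, body, "target and body")
  dims <- dim(body$values)
  keep <- array(FALSE, dims)
  sp <- body$spacing[1]
  for (k in seq_len(dims[3])) {
    t2 <- target$values[, , k]
    if (!any(t2)) next
    depth <- as.matrix(EBImage::imageData(EBImage::distmap(
      body$values[, , k]))) * sp
    keep[, , k] <- t2 & depth > margin_mm
  }
  structure_mask(keep, target$spacing, target$origin,
                 paste0(target$label, "_eval"))
}

#' Analytic toy dose model
#'
#' A deterministic stand-in for a treatment planning system, NOT a physics
#' engine: each beam enters along a lattice axis, dose falls off
#' exponentially with water-equivalent depth (radiological path through the
#' HU-derived relative density `rho = max(0, 1 + HU/1000)`), and falls off
#' laterally as a Gaussian of the in-plane distance to the target's
#' beam's-eye-view footprint. The summed beam dose is rescaled so the target
#' mean equals the prescription (adapted plan); passing the scale of a
#' reference plan instead replays that plan on the current anatomy
#' (scheduled plan). Dose is linear in the rescale factor, so doubling the
#' prescription doubles every voxel.
#'
#' @param image an [image_grid()] (the session anatomy).
#' @param target nonempty [structure_mask()] on the image lattice.
#' @param beams list of beams, each `list(direction, weight)` with direction
#'   one of `"anterior"`, `"posterior"`, `"left"`, `"right"`, `"superior"`,
#'   `"inferior"`. Default: one anterior and two lateral beams.
#' @param prescription_gy prescribed target mean dose (default 70 Gy, i.e.
#'   35 fractions of 2 Gy).
#' @param mu_per_cm effective exponential attenuation coefficient per cm of
#'   water-equivalent depth (default 0.05, typical of a 6 MV photon beam
#'   past build-up).
#' @param penumbra_sigma_mm lateral Gaussian penumbra sigma (default 3 mm).
#' @param norm_scale `NULL` to normalize to the prescription (adapted), or a
#'   scale from a previous plan to replay it (scheduled).
#' @return list with `dose` (a [dose_grid()] on the image lattice) and
#'   `scale` (the applied rescale factor, Gy per unit raw dose).
#' @export
toy_dose_model <- function(image, target, beams = default_beams(),
                           prescription_gy = 70, mu_per_cm = 0.05,
                           penumbra_sigma_mm = 3, norm_scale = NULL) {
  stopifnot(inherits(image, "image_grid"),
            inherits(target, "structure_mask"))
  stop_if_lattice_mismatch(image, target, "image and target")
  if (!any(target$values)) stop("target mask is empty")
  dims <- dim(image$values)
  rho <- array(pmax(1 + image$values / 1000, 0), dim(image$values))
  raw <- array(0, dims)
  for (b in beams) {
    ax_info <- beam_axis(b$direction)
    raw <- raw + b$weight *
      beam_dose(rho, target$values, ax_info$axis, ax_info$forward,
                image$spacing, mu_per_cm, penumbra_sigma_mm)
  }
  scale <- if (is.null(norm_scale))
    prescription_gy / mean(raw[target$values])
  else norm_scale
  list(dose = dose_grid(raw * scale, image$spacing, image$origin),
       scale = scale)
}

#' @rdname toy_dose_model
#' @export
default_beams <- function() {
  list(list(direction = "anterior", weight = 1),
       list(direction = "left", weight = 0.5),
       list(direction = "right", weight = 0.5))
}

beam_axis <- function(direction) {
  switch(direction,
    left = list(axis = 1L, forward = TRUE),      # enters at x min
    right = list(axis = 1L, forward = FALSE),
    anterior = list(axis = 2L, forward = TRUE),  # enters at y min
    posterior = list(axis = 2L, forward = FALSE),
    superior = list(axis = 3L, forward = TRUE),
    inferior = list(axis = 3L, forward = FALSE),
    stop("unknown beam direction: ", direction))
}

# Exponential depth dose along `axis` times a Gaussian lateral falloff from
# the target footprint projected along the beam.
beam_dose <- function(rho, target, axis, forward, spacing, mu_per_cm,
                      sigma_mm) {
  dims <- dim(rho)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  r <- aperm(rho, perm)                 # beam axis first
  t <- aperm(target, perm)
  if (!forward) {
    r <- r[rev(seq_len(dim(r)[1])), , , drop = FALSE]
    t <- t[rev(seq_len(dim(t)[1])), , , drop = FALSE]
  }
  step_cm <- spacing[axis] / 10
  n <- dim(r)[1]
  flat <- matrix(r, n)                  # depth along rows
  wed <- apply(flat, 2, cumsum) * step_cm - flat * step_cm / 2
  depth_dose <- array(exp(-mu_per_cm * wed), dim(r))
  foot <- apply(t, c(2, 3), any)        # beam's-eye-view footprint
  lat_sp <- spacing[-axis]
  lateral <- if (any(foot)) {
    dmm <- as.matrix(EBImage::imageData(EBImage::distmap(1 - foot))) *
      lat_sp[1]
    exp(-dmm^2 / (2 * sigma_mm^2))
  } else matrix(0, dim(r)[2], dim(r)[3])
  dose <- depth_dose * rep(lateral, each = n)
  if (!forward) dose <- dose[rev(seq_len(n)), , , drop = FALSE]
  aperm(dose, order(perm))
}
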
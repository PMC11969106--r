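#' Parametric specification of the synthetic neck phantom
#'
#' Describes an elliptical-cylinder neck cross-section with an optional bone
#' insert, an optional hemispherical surface target, a uniform-thickness
#' surface layer (bolus) separated from the tissue by a configurable air-gap
#' profile, CBCT-like Gaussian HU noise and an in-plane Gaussian point-spread
#' blur that produces realistic partial-volume surface ramps.
#'
#' Geometry lives in mm, in a world frame whose x/y origin is the ellipse
#' center and whose z = 0 plane is the superior face of the tissue slab
#' (z increases inferiorly). The lattice is auto-sized to enclose the
#' outermost shell plus `margin_mm` of exterior air.
#'
#' @param semi_axes_mm ellipse semi-axes (x, y) in mm.
#' @param slab_mm extent of the tissue slab along z, mm.
#' @param z_pad_mm exterior air padding added superiorly and inferiorly, mm.
#' @param margin_mm lateral exterior air margin beyond the outermost shell, mm.
#' @param spacing_mm voxel spacing, mm; in-plane spacing must be isotropic.
#' @param tissue_hu,tissue_sd tissue HU mean (> -200) and noise SD.
#' @param bone optional bone insert: `list(center_mm = c(x, y), radius_mm, hu)`
#'   (cylinder along z), or `NULL`.
#' @param target optional hemispherical surface target:
#'   `list(radius_mm, angle_deg, hu)`. The flat face is flush with the local
#'   surface tangent plane at the ellipse boundary point at polar angle
#'   `angle_deg` (270 = anterior); the dome points outward. The default
#'   radius 22.23 mm solves (2/3) * pi * r^3 = 23 cm^3.
#' @param surface_thickness_cm uniform surface-layer (bolus) thickness, cm,
#'   one of the study values 0-2.0 or any non-negative number.
#' @param bolus_hu,bolus_sd bolus HU mean (must lie in [100, 600]) and SD.
#' @param gap_profile `NULL` (no gap) or a data frame from [gap_profile()]
#'   giving piecewise-constant air-gap width (mm) per angular sector between
#'   the tissue surface and the bolus inner surface.
#' @param exterior_hu exterior air HU (< -200).
#' @param psf_sigma_mm in-plane Gaussian blur sigma, mm (0 = sharp edges).
#' @param max_lateral_extent_mm optional cap `c(x, y)` on the half-extent of
#'   the lattice; generation errors if the bolus shell needs more room.
#' @param fixed_extent_mm optional `list(x_ext, y_lo, y_hi)` lateral extent
#'   override so several sessions share one lattice (set by
#'   [make_weight_loss_series()]); must enclose the geometry.
#' @param seed integer seed for the phantom's noise stream.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(semi_axes_mm = c(60, 50),
                         slab_mm = 74,
                         z_pad_mm = 3,
                         margin_mm = 10,
                         spacing_mm = c(1, 1, 1),
                         tissue_hu = 0, tissue_sd = 20,
                         bone = list(center_mm = c(0, 15), radius_mm = 12,
                                     hu = 700),
                         target = list(radius_mm = 22.23, angle_deg = 270,
                                       hu = 50),
                         surface_thickness_cm = 0,
                         bolus_hu = 300, bolus_sd = 30,
                         gap_profile = NULL,
                         exterior_hu = -1000,
                         psf_sigma_mm = 0.7,
                         max_lateral_extent_mm = NULL,
                         fixed_extent_mm = NULL,
                         seed = 1) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$semi_axes_mm) == 2, all(spec$semi_axes_mm > 0),
            spec$slab_mm > 0, spec$z_pad_mm >= 0, spec$margin_mm > 0,
            length(spec$spacing_mm) == 3, all(spec$spacing_mm > 0))
  if (abs(spec$spacing_mm[1] - spec$spacing_mm[2]) > 1e-9)
    stop("in-plane spacing must be isotropic")
  if (spec$surface_thickness_cm < 0) stop("surface thickness must be >= 0")
  if (spec$tissue_hu <= -200) stop("tissue HU must exceed -200")
  if (spec$bolus_hu < 100 || spec$bolus_hu > 600)
    stop("bolus HU must lie within [100, 600]")
  if (spec$exterior_hu >= -200) stop("exterior HU must be below -200")
  if (!is.null(spec$target) && spec$target$radius_mm <= 0)
    stop("hemisphere radius must be > 0")
  gp <- spec$gap_profile
  if (!is.null(gp)) {
    stopifnot(is.data.frame(gp),
              all(c("start_deg", "end_deg", "width_mm") %in% names(gp)))
    if (any(gp$width_mm < 0)) stop("gap widths must be >= 0")
    if (any(gp$end_deg <= gp$start_deg))
      stop("gap profile sectors need end_deg > start_deg")
  }
  invisible(spec)
}

#' Piecewise-constant air-gap profile
#'
#' One row per angular sector (degrees, polar angle about the ellipse center,
#' 0 = +x, 90 = +y/posterior, 270 = anterior); the air gap between tissue
#' surface and bolus inner surface is `width_mm` inside the sector and 0
#' elsewhere.
#'
#' @param start_deg,end_deg,width_mm equal-length vectors of sector bounds
#'   (degrees in `[0, 360]`) and gap widths (mm, >= 0).
#' @return a data frame usable as the `gap_profile` of [phantom_spec()].
#' @export
gap_profile <- function(start_deg, end_deg, width_mm) {
  data.frame(start_deg = start_deg, end_deg = end_deg, width_mm = width_mm)
}

# Lateral half-extents (mm) needed to enclose the spec's outermost geometry.
required_extent <- function(spec) {
  a <- spec$semi_axes_mm[1]; b <- spec$semi_axes_mm[2]
  shell <- cm_to_mm(spec$surface_thickness_cm) + max_gap_width(spec)
  r_t <- if (is.null(spec$target)) 0 else spec$target$radius_mm
  att <- attachment_point(spec)
  list(x_ext = max(a, if (r_t > 0) abs(att$p[1]) + r_t else 0) + shell +
         spec$margin_mm,
       y_lo = max(b, if (r_t > 0) abs(min(att$p[2] - r_t, -b)) else b) +
         shell + spec$margin_mm,
       y_hi = max(b, if (r_t > 0) max(att$p[2] + r_t, b) else b) + shell +
         spec$margin_mm)
}

# Lattice coordinates enclosing the spec's outermost geometry.
phantom_lattice <- function(spec) {
  need <- required_extent(spec)
  ext <- if (!is.null(spec$fixed_extent_mm)) spec$fixed_extent_mm else need
  if (ext$x_ext < need$x_ext - 1e-9 || ext$y_lo < need$y_lo - 1e-9 ||
      ext$y_hi < need$y_hi - 1e-9)
    stop("bolus shell exceeds the lattice extent")
  if (!is.null(spec$max_lateral_extent_mm)) {
    cap <- spec$max_lateral_extent_mm
    if (ext$x_ext > cap[1] || max(ext$y_lo, ext$y_hi) > cap[2])
      stop("bolus shell exceeds the lattice extent allowed by the spec")
  }
  sx <- spec$spacing_mm[1]; sy <- spec$spacing_mm[2]; sz <- spec$spacing_mm[3]
  list(x = seq(-ceiling(ext$x_ext), ceiling(ext$x_ext), by = sx),
       y = seq(-ceiling(ext$y_lo), ceiling(ext$y_hi), by = sy),
       z = seq(-ceiling(spec$z_pad_mm), spec$slab_mm +
                 ceiling(spec$z_pad_mm), by = sz))
}

max_gap_width <- function(spec) {
  if (is.null(spec$gap_profile)) 0 else max(spec$gap_profile$width_mm)
}

# Surface attachment point and outward normal for the target hemisphere.
attachment_point <- function(spec) {
  a <- spec$semi_axes_mm[1]; b <- spec$semi_axes_mm[2]
  th <- (if (is.null(spec$target)) 270 else spec$target$angle_deg) * pi / 180
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  p <- r * c(cos(th), sin(th))
  n <- c(p[1] / a^2, p[2] / b^2)
  list(p = p, n = n / sqrt(sum(n^2)))
}

# In-plane geometry of one slice: core mask (ellipse + target), outward
# distance-to-core (mm) and per-pixel gap width (mm).
slice_geometry <- function(spec, lat, z) {
  a <- spec$semi_axes_mm[1]; b <- spec$semi_axes_mm[2]
  X <- matrix(lat$x, length(lat$x), length(lat$y))
  Y <- matrix(lat$y, length(lat$x), length(lat$y), byrow = TRUE)
  in_slab <- z >= 0 && z < spec$slab_mm
  ellipse <- if (in_slab) (X / a)^2 + (Y / b)^2 <= 1 else
    matrix(FALSE, nrow(X), ncol(X))
  target <- matrix(FALSE, nrow(X), ncol(X))
  if (in_slab && !is.null(spec$target)) {
    att <- attachment_point(spec)
    zc <- spec$slab_mm / 2
    r2 <- (X - att$p[1])^2 + (Y - att$p[2])^2 + (z - zc)^2
    target <- r2 <= spec$target$radius_mm^2 &
      (X - att$p[1]) * att$n[1] + (Y - att$p[2]) * att$n[2] >= 0
  }
  core <- ellipse | target
  d <- if (any(core)) {
    dm <- EBImage::distmap(1 - core, metric = "euclidean")
    as.matrix(EBImage::imageData(dm)) * spec$spacing_mm[1]
  } else matrix(Inf, nrow(X), ncol(X))
  gw <- matrix(0, nrow(X), ncol(X))
  if (!is.null(spec$gap_profile)) {
    theta <- (atan2(Y, X) * 180 / pi) %% 360
    for (s in seq_len(nrow(spec$gap_profile))) {
      row <- spec$gap_profile[s, ]
      sel <- theta >= row$start_deg & theta < row$end_deg
      gw[sel] <- row$width_mm
    }
  }
  bone <- matrix(FALSE, nrow(X), ncol(X))
  if (in_slab && !is.null(spec$bone)) {
    c0 <- spec$bone$center_mm
    bone <- (X - c0[1])^2 + (Y - c0[2])^2 <= spec$bone$radius_mm^2 & ellipse
  }
  list(core = core, ellipse = ellipse, target = target, bone = bone,
       d = d, gw = gw, in_slab = in_slab)
}

#' Generate a synthetic phantom image with ground-truth masks
#'
#' Voxelizes the geometry described by a [phantom_spec()]: exterior air,
#' tissue ellipse with optional bone insert, hemispherical surface target,
#' and a uniform-thickness bolus shell separated from the tissue by the
#' air-gap profile. Gaussian noise is added per material, the in-plane PSF
#' blur is applied, and HU are rounded to integers. Identical spec (including
#' seed) gives bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param homogenized if `TRUE`, render the homogenized-ground-truth twin:
#'   the gap and bolus regions are filled with tissue-like HU (no air gaps,
#'   surface layer already at tissue HU) while geometry, seed stream and
#'   lattice are unchanged. Used to validate the HU homogenization stage.
#' @return a `phantom` object: list with `image` ([image_grid()]), `masks`
#'   (structure masks `body`, `gap`, `bolus`, `target`, `body_outer`, where
#'   `body_outer = body + gap + bolus` is the outline a body contour should
#'   recover after homogenization), `gap_width_mm` (per-pixel in-plane gap
#'   width matrix), `landmarks` (z slab bounds and mid-slab z, mm) and the
#'   `spec`.
#' @export
make_phantom <- function(spec, homogenized = FALSE) {
  validate_phantom_spec(spec)
  t_mm <- cm_to_mm(spec$surface_thickness_cm)
  if (t_mm == 0 && max_gap_width(spec) > 0)
    stop("zero-thickness bolus cannot carry a nonzero gap profile")
  lat <- phantom_lattice(spec)
  nx <- length(lat$x); ny <- length(lat$y); nz <- length(lat$z)
  dims <- c(nx, ny, nz)
  vals <- array(spec$exterior_hu, dims)
  body <- gap <- bolus <- target <- array(FALSE, dims)
  sdmap <- array(0, dims)
  gw2d <- matrix(0, nx, ny)
  eps <- 1e-9
  for (k in seq_len(nz)) {
    g <- slice_geometry(spec, lat, lat$z[k])
    if (!g$in_slab) next
    gw2d <- g$gw
    hu <- matrix(spec$exterior_hu, nx, ny)
    sdsl <- matrix(0, nx, ny)
    hu[g$core] <- spec$tissue_hu
    sdsl[g$core] <- spec$tissue_sd
    if (any(g$bone)) hu[g$bone] <- spec$bone$hu
    if (any(g$target)) hu[g$target] <- spec$target$hu
    gap_k <- g$d > eps & g$d <= g$gw + eps
    bolus_k <- if (t_mm > 0) g$d > g$gw + eps & g$d <= g$gw + t_mm + eps else
      matrix(FALSE, nx, ny)
    if (homogenized) {
      hu[gap_k | bolus_k] <- spec$tissue_hu
      sdsl[gap_k | bolus_k] <- spec$tissue_sd
    } else {
      hu[bolus_k] <- spec$bolus_hu
      sdsl[bolus_k] <- spec$bolus_sd
    }
    vals[, , k] <- hu
    sdmap[, , k] <- sdsl
    body[, , k] <- g$core
    target[, , k] <- g$target
    if (!homogenized) {
      gap[, , k] <- gap_k
      bolus[, , k] <- bolus_k
    } else {
      body[, , k] <- g$core | gap_k | bolus_k
    }
  }
  outer <- body | gap | bolus
  vals <- with_seed(spec$seed, vals + rnorm(length(vals)) * sdmap)
  if (spec$psf_sigma_mm > 0) {
    sig_px <- spec$psf_sigma_mm / spec$spacing_mm[1]
    for (k in seq_len(nz)) {
      sl <- vals[, , k]
      if (max(sl) - min(sl) > 0)
        vals[, , k] <- as.matrix(EBImage::imageData(EBImage::gblur(sl, sig_px)))
    }
  }
  vals <- round(vals)
  spacing <- spec$spacing_mm
  origin <- c(lat$x[1], lat$y[1], lat$z[1])
  msk <- function(m, label) structure_mask(m, spacing, origin, label)
  structure(list(
    image = image_grid(vals, spacing, origin),
    masks = list(body = msk(body, "body"),
                 gap = msk(gap, "gap"),
                 bolus = msk(bolus, "bolus"),
                 target = msk(target, "target"),
                 body_outer = msk(outer, "body_outer")),
    gap_width_mm = gw2d,
    landmarks = list(z_slab_mm = c(0, spec$slab_mm),
                     z_mid_mm = spec$slab_mm / 2),
    homogenized = homogenized,
    spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> thickness ", x$spec$surface_thickness_cm, " cm, ",
      if (x$homogenized) "homogenized-truth" else "raw", ", body ",
      round(volume_cm3(x$masks$body), 1), " cm^3, bolus ",
      round(volume_cm3(x$masks$bolus), 1), " cm^3\n", sep = "")
  invisible(x)
}

#' Generate the weight-loss session series
#'
#' One phantom per surface-layer thickness, sharing core geometry; each
#' session is emitted twice: the raw image (bolus HU plus air gaps) and its
#' homogenized-ground-truth twin (surface layer already at tissue HU, no
#' gaps), so the homogenization stage can be validated against known truth.
#' The 0 cm session carries no bolus and hence no gap profile.
#'
#' @param spec a [phantom_spec()]; its `surface_thickness_cm` is overridden
#'   per session and its seed spawns one sub-seed per session.
#' @param thicknesses_cm ordered surface-layer thicknesses in cm
#'   (default the study schedule 2.0, 1.5, 1.0, 0.5, 0).
#' @return list of sessions, each
#'   `list(thickness_cm, raw = <phantom>, truth = <phantom>)`.
#' @export
make_weight_loss_series <- function(spec,
                                    thicknesses_cm = c(2, 1.5, 1, 0.5, 0)) {
  if (length(thicknesses_cm) == 0) stop("empty thickness list")
  if (any(thicknesses_cm < 0)) stop("thicknesses must be non-negative")
  # all sessions share the lattice of the thickest session
  ext_spec <- spec
  ext_spec$surface_thickness_cm <- max(thicknesses_cm)
  shared_ext <- required_extent(ext_spec)
  lapply(seq_along(thicknesses_cm), function(i) {
    s <- spec
    s$surface_thickness_cm <- thicknesses_cm[i]
    if (thicknesses_cm[i] == 0) s$gap_profile <- NULL
    s$fixed_extent_mm <- shared_ext
    s$seed <- spec$seed + i - 1L
    list(thickness_cm = thicknesses_cm[i],
         raw = make_phantom(s),
         truth = make_phantom(s, homogenized = TRUE))
  })
}
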
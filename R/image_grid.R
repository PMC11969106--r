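#' 3-D image lattice of Hounsfield units
#'
#' An `image_grid` is a 3-D scalar lattice of HU values with spacing and
#' origin metadata. Axis convention: dimension 1 runs left to right (x),
#' dimension 2 anterior to posterior (y), dimension 3 superior to inferior
#' (z, the slice index). World coordinates are voxel centers, in mm:
#' `world = origin + (index - 1) * spacing`.
#'
#' @param values numeric 3-D array of HU (finite).
#' @param spacing numeric length 3, mm per voxel along each axis (> 0).
#' @param origin numeric length 3, mm world coordinate of the first voxel
#'   center.
#' @return an `image_grid` object.
#' @export
image_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_lattice_args(values, spacing, origin)
  if (!all(is.finite(values))) stop("image values must be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_grid")
}

#' Boolean structure mask on an image lattice
#'
#' A `structure_mask` shares lattice metadata with its parent [image_grid()]
#' and stores one boolean per voxel plus a role label (body, bolus, target,
#' gap, ...).
#'
#' @param values logical 3-D array.
#' @param spacing,origin lattice metadata, as in [image_grid()].
#' @param label character role name.
#' @return a `structure_mask` object.
#' @export
structure_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           label = "structure") {
  check_lattice_args(values, spacing, origin)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must be TRUE/FALSE")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label = as.character(label)),
            class = "structure_mask")
}

#' 3-D dose lattice in Gy
#'
#' Same lattice layout as [image_grid()], but values are absorbed dose in
#' Gy (finite, non-negative).
#'
#' @inheritParams image_grid
#' @return a `dose_grid` object.
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_lattice_args(values, spacing, origin)
  if (!all(is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

check_lattice_args <- function(values, spacing, origin) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (any(dim(values) < 1L)) stop("lattice shape must be at least (1,1,1)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive reals (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite reals (mm)")
  invisible(TRUE)
}

#' @export
dim.image_grid <- function(x) dim(x$values)
#' @export
dim.structure_mask <- function(x) dim(x$values)
#' @export
dim.dose_grid <- function(x) dim(x$values)

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " mm, HU range [",
      min(x$values), ", ", max(x$values), "]\n", sep = "")
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask '", x$label, "'> ",
      paste(dim(x$values), collapse = " x "), " voxels, volume ",
      round(volume_cm3(x), 2), " cm^3\n", sep = "")
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"),
      " mm, max ", round(max(x$values), 3), " Gy\n", sep = "")
  invisible(x)
}

#' World coordinates of voxel centers along one axis
#'
#' @param x an `image_grid`, `structure_mask` or `dose_grid`.
#' @param axis 1 (x, left-right), 2 (y, anterior-posterior) or 3 (z, slices).
#' @return numeric vector of mm coordinates.
#' @export
axis_coords <- function(x, axis) {
  n <- dim(x$values)[axis]
  x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]
}

#' Volume of a structure mask in cm^3
#'
#' True-voxel count times voxel volume (mm^3), divided by 1000.
#'
#' @param mask a [structure_mask()].
#' @return volume in cm^3.
#' @export
volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$values) * prod(mask$spacing) / 1000
}

same_lattice <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_lattice_mismatch <- function(a, b, what = "inputs") {
  if (!same_lattice(a, b))
    stop(what, " must share one lattice (dims, spacing, origin)")
  invisible(TRUE)
}

#' Crop a mask to a superior-inferior slab
#'
#' Clears every voxel whose center z coordinate lies outside `[z_lo, z_hi]`
#' (closed interval, voxel-center inclusion; callers tiling adjacent slabs
#' should use strictly increasing non-overlapping bounds since a center lying
#' exactly on a shared bound is kept by both). Bounds are in cm to match the
#' study convention; lattice metadata is unchanged.
#'
#' @param mask a [structure_mask()].
#' @param z_lo_cm,z_hi_cm slab bounds in cm, `z_lo_cm < z_hi_cm`, overlapping
#'   the lattice z extent.
#' @return the cropped [structure_mask()].
#' @export
crop_z <- function(mask, z_lo_cm, z_hi_cm) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.finite(z_lo_cm) || !is.finite(z_hi_cm) || z_lo_cm >= z_hi_cm)
    stop("inverted or non-finite z bounds")
  z <- axis_coords(mask, 3)
  half <- mask$spacing[3] / 2
  lo <- cm_to_mm(z_lo_cm); hi <- cm_to_mm(z_hi_cm)
  if (hi < min(z) - half || lo > max(z) + half)
    stop("z bounds lie outside the lattice extent")
  keep <- z >= lo & z <= hi
  out <- mask
  out$values[, , !keep] <- FALSE
  out
}
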
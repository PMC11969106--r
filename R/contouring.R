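#' Extract a body contour by HU thresholding
#'
#' Thresholds the image at `threshold_hu` (voxels with HU at or above the
#' threshold), optionally keeps the largest 26-connected 3-D component and
#' fills fully enclosed cavities, mirroring the solid body structures of a
#' treatment planning system. An empty thresholded set yields an empty mask
#' flagged via `attr(, "empty")`.
#'
#' @param image an [image_grid()].
#' @param threshold_hu HU threshold.
#' @param largest_component keep only the largest 26-connected component.
#' @param fill_holes fill cavities not connected to the lattice boundary.
#' @return a [structure_mask()] labelled `"body"`.
#' @export
threshold_body <- function(image, threshold_hu, largest_component = TRUE,
                           fill_holes = TRUE) {
  stopifnot(inherits(image, "image_grid"))
  m <- image$values >= threshold_hu
  empty <- !any(m)
  if (!empty && largest_component)
    m <- cpp_largest_component(m, dim(m))
  if (!empty && fill_holes)
    m <- cpp_fill_holes(m, dim(m))
  out <- structure_mask(m, image$spacing, image$origin, "body")
  attr(out, "empty") <- empty
  attr(out, "threshold_hu") <- threshold_hu
  out
}

#' Three-threshold baseline body contour with uncertainty
#'
#' Reproduces the manual baseline protocol: the body is contoured once per
#' threshold (default -300, -450, -600 HU), optionally cropped to a
#' superior-inferior slab, and the mean member volume is the baseline with
#' the sample standard deviation (n - 1) of the member volumes as its
#' uncertainty.
#'
#' @param image an [image_grid()].
#' @param thresholds_hu at least two HU thresholds.
#' @param z_lim_cm optional `c(z_lo, z_hi)` crop bounds in cm, applied to
#'   every member via [crop_z()].
#' @param ... passed to [threshold_body()].
#' @return a `baseline_contour`: list with `members` (masks), `thresholds_hu`,
#'   `volumes_cm3`, `mean_cm3`, `sd_cm3`.
#' @export
baseline_contour <- function(image, thresholds_hu = c(-300, -450, -600),
                             z_lim_cm = NULL, ...) {
  if (length(thresholds_hu) < 2) stop("need at least two thresholds")
  members <- lapply(thresholds_hu, function(th) {
    m <- threshold_body(image, th, ...)
    if (isTRUE(attr(m, "empty")))
      stop("baseline undefined: threshold ", th, " HU selects no voxels")
    if (!is.null(z_lim_cm)) m <- crop_z(m, z_lim_cm[1], z_lim_cm[2])
    m
  })
  vols <- vapply(members, volume_cm3, numeric(1))
  structure(list(members = members, thresholds_hu = thresholds_hu,
                 volumes_cm3 = vols, mean_cm3 = mean(vols),
                 sd_cm3 = stats::sd(vols)),
            class = "baseline_contour")
}

#' @export
print.baseline_contour <- function(x, ...) {
  cat("<baseline_contour> thresholds ",
      paste(x$thresholds_hu, collapse = "/"), " HU, volume ",
      round(x$mean_cm3, 2), " +/- ", round(x$sd_cm3, 2), " cm^3\n", sep = "")
  invisible(x)
}
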
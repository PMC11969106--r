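#' Parameters of the HU homogenization algorithm
#'
#' Controls the preprocessing that converts a bolus-plus-airgap image into a
#' simulated weight-loss image with uniform tissue-like HU: air
#' classification below `air_threshold_hu`, flagging of sharp adjacent-pixel
#' jumps above `spike_threshold_hu`, replacement of bolus-window HU with
#' background-matched random values, per-row linear interpolation across the
#' flagged gaps, and restoration of everything outside the outer edge.
#'
#' @param background_region [structure_mask()] sampling region used to
#'   estimate the phantom-background HU mean and range (required; must lie
#'   entirely above the air threshold).
#' @param air_threshold_hu HU below which a voxel is classified as air
#'   (default -200).
#' @param spike_threshold_hu adjacent-pixel HU difference above which the
#'   low-HU side is additionally flagged (default 45).
#' @param bolus_window_hu HU interval replaced with background-matched
#'   values (default `c(100, 600)`).
#' @param axis lattice axis along which rows are scanned and interpolated:
#'   1 (left-right, default) or 2 (anterior-posterior).
#' @param spike_before_replacement if `TRUE` (default) spike flags are set
#'   before the bolus-window replacement (which then overrides flags on
#'   window pixels); if `FALSE` spikes are computed after replacement.
#' @param fill_seed integer seed for the random replacement values.
#' @return a `homogenize_params` object.
#' @export
homogenize_params <- function(background_region,
                              air_threshold_hu = -200,
                              spike_threshold_hu = 45,
                              bolus_window_hu = c(100, 600),
                              axis = 1L,
                              spike_before_replacement = TRUE,
                              fill_seed = 1L) {
  stopifnot(inherits(background_region, "structure_mask"))
  if (spike_threshold_hu <= 0) stop("spike threshold must be > 0")
  if (length(bolus_window_hu) != 2 || diff(bolus_window_hu) < 0)
    stop("bolus window must be a non-empty HU interval")
  if (air_threshold_hu >= bolus_window_hu[1])
    stop("air threshold must lie below the bolus window")
  if (!axis %in% 1:2) stop("interpolation axis must be 1 or 2")
  structure(list(background_region = background_region,
                 air_threshold_hu = air_threshold_hu,
                 spike_threshold_hu = spike_threshold_hu,
                 bolus_window_hu = bolus_window_hu,
                 axis = as.integer(axis),
                 spike_before_replacement = spike_before_replacement,
                 fill_seed = as.integer(fill_seed)),
            class = "homogenize_params")
}

#' Classify sub-threshold voxels as air
#'
#' @param image an [image_grid()].
#' @param threshold_hu HU threshold (default -200); the mask is true exactly
#'   where HU is below it.
#' @return a [structure_mask()] labelled `"air"`.
#' @export
classify_air <- function(image, threshold_hu = -200) {
  stopifnot(inherits(image, "image_grid"))
  structure_mask(image$values < threshold_hu, image$spacing, image$origin,
                 "air")
}

#' Sample the phantom-background HU statistics
#'
#' Returns the empirical mean and (low, high) range of HU over a region;
#' replacement values for the bolus are drawn uniformly over that range, so
#' their mean and range are comparable to the background by construction.
#'
#' @param image an [image_grid()].
#' @param region nonempty [structure_mask()] lying entirely above
#'   `air_threshold_hu`.
#' @param air_threshold_hu HU bound used to reject regions touching air.
#' @return `list(mean, range = c(low, high), n)`.
#' @export
sample_background <- function(image, region, air_threshold_hu = -200) {
  stopifnot(inherits(image, "image_grid"), inherits(region, "structure_mask"))
  stop_if_lattice_mismatch(image, region, "image and region")
  v <- image$values[region$values]
  if (length(v) == 0) stop("background region is empty")
  if (any(v < air_threshold_hu))
    stop("background region intersects air (HU below ", air_threshold_hu, ")")
  list(mean = mean(v), range = range(v), n = length(v))
}

#' Homogenize bolus and air-gap HU into a simulated weight-loss image
#'
#' Per slice and per row along the scan axis: (1) voxels below the air
#' threshold are provisionally flagged; (2) adjacent-pixel differences above
#' the spike threshold flag the low-HU pixel of the jump; (3) voxels inside
#' the bolus window are replaced with random values drawn uniformly over the
#' sampled background range; (4) flagged runs lying between unflagged
#' content are linearly interpolated, filling the former air gaps; (5)
#' flagged voxels outside the outer edge (the outermost unflagged extent of
#' each row) are restored to their original values. Lattice metadata is
#' unchanged and the result is deterministic given `fill_seed`.
#'
#' @param image an [image_grid()] with an exterior-air margin on every row.
#' @param params a [homogenize_params()].
#' @return list with `image` (the homogenized [image_grid()]), `masks`
#'   (diagnostic [structure_mask()]s: `air`, `spike`, `bolus_replaced`,
#'   `interpolated`), `background` (the sampled statistics) and
#'   `n_empty_rows` (rows with no above-air content, passed through).
#' @export
homogenize <- function(image, params) {
  stopifnot(inherits(image, "image_grid"),
            inherits(params, "homogenize_params"))
  v <- image$values
  dims <- dim(v)
  ax <- params$axis
  bg <- sample_background(image, params$background_region,
                          params$air_threshold_hu)

  air <- v < params$air_threshold_hu
  spike_from <- function(x) {
    # flag the low-HU side of every adjacent-pixel jump along `ax`
    n <- dims[ax]
    thr <- params$spike_threshold_hu
    if (ax == 1) {
      dv <- x[-1, , , drop = FALSE] - x[-n, , , drop = FALSE]
    } else {
      dv <- x[, -1, , drop = FALSE] - x[, -n, , drop = FALSE]
    }
    rising <- !is.na(dv) & dv > thr    # low side is the leading pixel
    falling <- !is.na(dv) & dv < -thr  # low side is the trailing pixel
    s <- array(FALSE, dims)
    if (ax == 1) {
      lo <- s[-n, , , drop = FALSE]; lo[rising] <- TRUE
      hi <- s[-1, , , drop = FALSE]; hi[falling] <- TRUE
      s[-n, , ] <- lo
      s[-1, , ] <- s[-1, , , drop = FALSE] | hi
    } else {
      lo <- s[, -n, , drop = FALSE]; lo[rising] <- TRUE
      hi <- s[, -1, , drop = FALSE]; hi[falling] <- TRUE
      s[, -n, ] <- lo
      s[, -1, ] <- s[, -1, , drop = FALSE] | hi
    }
    s
  }

  window <- v >= params$bolus_window_hu[1] & v <= params$bolus_window_hu[2]
  repl <- with_seed(params$fill_seed,
                    runif(sum(window), bg$range[1], bg$range[2]))

  work <- v
  if (params$spike_before_replacement) {
    spike <- spike_from(v)
    work[air | spike] <- NA_real_
    work[window] <- repl
  } else {
    work[window] <- repl
    spike <- spike_from(work)
    work[air & !window] <- NA_real_
    work[spike] <- NA_real_
  }

  filled <- interpolate_rows(work, ax)
  n_empty <- attr(filled, "n_empty_rows")
  attr(filled, "n_empty_rows") <- NULL
  interpolated <- is.na(work) & !is.na(filled)
  restore <- is.na(filled)
  filled[restore] <- v[restore]

  msk <- function(m, label) structure_mask(m, image$spacing, image$origin,
                                           label)
  list(image = image_grid(filled, image$spacing, image$origin),
       masks = list(air = msk(air, "air"),
                    spike = msk(spike & !air, "spike"),
                    bolus_replaced = msk(window, "bolus_replaced"),
                    interpolated = msk(interpolated, "interpolated")),
       background = bg,
       n_empty_rows = n_empty)
}

# Linear interpolation of interior NA runs independently along each row of
# axis `ax`; leading/trailing NAs are left NA. Rows that are entirely NA are
# passed through and counted.
interpolate_rows <- function(work, ax) {
  dims <- dim(work)
  n_empty <- 0L
  for (k in seq_len(dims[3])) {
    m <- work[, , k, drop = FALSE]
    dim(m) <- dims[1:2]
    if (ax == 2) m <- t(m)
    # columns of m are the scan rows
    all_na <- colSums(!is.na(m)) == 0
    n_empty <- n_empty + sum(all_na)
    if (any(!all_na)) {
      m[, !all_na] <- zoo::na.approx(m[, !all_na, drop = FALSE],
                                     na.rm = FALSE)
    }
    if (ax == 2) m <- t(m)
    work[, , k] <- m
  }
  attr(work, "n_empty_rows") <- n_empty
  work
}
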
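#' Parameters for the auto-contour failure-mode emulator
#'
#' The emulator stands in for a commercial auto-segmentation system and
#' reproduces its observed behaviors on phantom data:
#' \describe{
#'   \item{`accurate`}{direct segmentation that recovers the true outline,
#'     including an attached bolus (the well-behaved weight-loss case).}
#'   \item{`reference_anchored`}{a contour anchored to the reference-session
#'     body via deformable registration that under-adapts to the session
#'     anatomy. `anchor_adaptation` is the fraction of true surface motion
#'     the registration recovers and `anchor_jitter_mm` the SD of a random
#'     per-session surface offset modelling registration error; setting both
#'     to 0 gives a pure copy of the reference body.}
#'   \item{`bolus_excluding`}{AI segmentation that drops the bolus from the
#'     body wherever the local air gap exceeds
#'     `gap_exclusion_threshold_mm`, and behaves unpredictably (random
#'     per-sector, per-slice inclusion) where the gap is below
#'     `small_gap_instability_threshold_mm`.}
#' }
#'
#' @param mode one of `"accurate"`, `"reference_anchored"`,
#'   `"bolus_excluding"`.
#' @param gap_exclusion_threshold_mm gap width above which the bolus is
#'   excluded from the body (default 2.5 mm).
#' @param small_gap_instability_threshold_mm gap width below which inclusion
#'   is random (default 0.4 mm); must be smaller than the exclusion
#'   threshold.
#' @param instability_prob probability that an unstable sector/slice is
#'   excluded.
#' @param anchor_adaptation,anchor_jitter_mm reference-anchored mode
#'   parameters, see above.
#' @param seed integer seed for the emulator's random behaviors.
#' @return a `contour_emulation_params` object.
#' @export
contour_emulation_params <- function(mode = c("accurate", "reference_anchored",
                                              "bolus_excluding"),
                                     gap_exclusion_threshold_mm = 2.5,
                                     small_gap_instability_threshold_mm = 0.4,
                                     instability_prob = 0.5,
                                     anchor_adaptation = 0.15,
                                     anchor_jitter_mm = 1.5,
                                     seed = 1) {
  mode <- match.arg(mode)
  if (gap_exclusion_threshold_mm < 0 ||
      small_gap_instability_threshold_mm < 0)
    stop("gap thresholds must be >= 0")
  if (gap_exclusion_threshold_mm <= small_gap_instability_threshold_mm)
    stop("exclusion threshold must exceed the instability threshold")
  structure(list(mode = mode,
                 gap_exclusion_threshold_mm = gap_exclusion_threshold_mm,
                 small_gap_instability_threshold_mm =
                   small_gap_instability_threshold_mm,
                 instability_prob = instability_prob,
                 anchor_adaptation = anchor_adaptation,
                 anchor_jitter_mm = anchor_jitter_mm,
                 seed = seed),
            class = "contour_emulation_params")
}

#' Emulate an auto-generated body contour
#'
#' Applies one of the failure modes described in
#' [contour_emulation_params()] to a phantom's ground-truth masks.
#'
#' @param phantom a `phantom` from [make_phantom()].
#' @param params a [contour_emulation_params()].
#' @param reference_body reference-session body mask (required for mode
#'   `reference_anchored`).
#' @param session_index integer offsetting the emulator seed so each session
#'   draws independent random behavior reproducibly.
#' @return a [structure_mask()] labelled `"body_auto"`.
#' @export
emulate_autocontour <- function(phantom, params, reference_body = NULL,
                                session_index = 0L) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(params, "contour_emulation_params"))
  truth <- phantom$masks$body_outer
  out <- switch(params$mode,
    accurate = truth,
    reference_anchored = {
      if (is.null(reference_body))
        stop("mode reference_anchored requires a reference body mask")
      stop_if_lattice_mismatch(truth, reference_body, "masks")
      anchored_contour(reference_body, truth, params,
                       params$seed + session_index)
    },
    bolus_excluding = bolus_excluding_contour(phantom, params,
                                              params$seed + session_index))
  out$label <- "body_auto"
  out
}

# Blend the reference and current surfaces through per-slice signed distance
# fields: surface moves `adapt` of the way from reference to truth, plus a
# per-session normal offset ~ N(0, jitter) emulating registration error.
anchored_contour <- function(reference_body, truth, params, seed) {
  adapt <- params$anchor_adaptation
  jitter <- with_seed(seed, rnorm(1, 0, params$anchor_jitter_mm))
  if (adapt == 0 && params$anchor_jitter_mm == 0) return(reference_body)
  dims <- dim(truth$values)
  sp <- truth$spacing[1]
  vals <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    sr <- signed_distance_2d(reference_body$values[, , k], sp)
    st <- signed_distance_2d(truth$values[, , k], sp)
    vals[, , k] <- (1 - adapt) * sr + adapt * st + jitter <= 0
  }
  structure_mask(vals, truth$spacing, truth$origin, "body_auto")
}

# Signed distance (mm) to the mask boundary: negative inside. Empty or full
# slices get a large constant of the appropriate sign.
signed_distance_2d <- function(m, spacing) {
  big <- 1e6
  if (!any(m)) return(matrix(big, nrow(m), ncol(m)))
  if (all(m)) return(matrix(-big, nrow(m), ncol(m)))
  dout <- as.matrix(EBImage::imageData(EBImage::distmap(1 - m))) * spacing
  din <- as.matrix(EBImage::imageData(EBImage::distmap(m))) * spacing
  dout - din
}

bolus_excluding_contour <- function(phantom, params, seed) {
  masks <- phantom$masks
  spec <- phantom$spec
  dims <- dim(masks$body$values)
  gw <- phantom$gap_width_mm
  shell <- masks$gap$values | masks$bolus$values
  excl2d <- gw > params$gap_exclusion_threshold_mm
  drop <- array(FALSE, dims)
  for (k in seq_len(dims[3])) drop[, , k] <- excl2d
  # unstable sectors: random per (sector, slice)
  if (!is.null(spec$gap_profile)) {
    unstable <- which(spec$gap_profile$width_mm <
                        params$small_gap_instability_threshold_mm)
    if (length(unstable)) {
      lat <- phantom_lattice(spec)
      theta <- (atan2(matrix(lat$y, dims[1], dims[2], byrow = TRUE),
                      matrix(lat$x, dims[1], dims[2])) * 180 / pi) %% 360
      draws <- with_seed(seed, matrix(
        runif(length(unstable) * dims[3]) < params$instability_prob,
        length(unstable), dims[3]))
      for (u in seq_along(unstable)) {
        row <- spec$gap_profile[unstable[u], ]
        sec <- theta >= row$start_deg & theta < row$end_deg
        for (k in seq_len(dims[3]))
          if (draws[u, k]) drop[, , k] <- drop[, , k] | sec
      }
    }
  }
  vals <- masks$body_outer$values & !(shell & drop)
  structure_mask(vals, masks$body$spacing, masks$body$origin, "body_auto")
}
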
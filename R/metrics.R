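#' Mean absolute volume deviation (MAD)
#'
#' Arithmetic mean of the absolute signed volume deviations of a contour
#' source from the baseline, across sessions.
#'
#' @param deviations_cm3 nonempty numeric vector of signed deviations
#'   (source volume minus baseline mean), cm^3.
#' @return MAD in cm^3.
#' @export
mean_abs_deviation <- function(deviations_cm3) {
  if (length(deviations_cm3) == 0) stop("empty deviation list")
  mean(abs(deviations_cm3))
}

#' Population variance (1/N normalization)
#'
#' `var x = (1/N) * sum (x_i - mu)^2` - the variance convention used by the
#' coefficient of determination in [r_squared()]. Note this differs from the
#' sample (n - 1) convention used for the baseline volume SD.
#'
#' @param x nonempty numeric vector.
#' @return population variance, in squared units of `x`.
#' @export
pop_variance <- function(x) {
  if (length(x) == 0) stop("empty vector")
  mean((x - mean(x))^2)
}

#' Coefficient of determination of the thickness-volume linear fit
#'
#' Fits an ordinary least squares straight line of `y` (volume, cm^3) on `x`
#' (surface-layer thickness, cm) and returns
#' `R2% = 100% - var(y - y_fitted) / var(y) * 100%`, with both variances the
#' population (1/N) variance of [pop_variance()].
#'
#' @param x,y numeric vectors of equal length >= 3; `y` must not be
#'   constant.
#' @return list with `r2_percent`, and `fit` (`slope` cm^3/cm, `intercept`
#'   cm^3, `fitted` values).
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  vy <- pop_variance(y)
  if (vy == 0) stop("constant y: R^2 undefined (var y = 0)")
  fit <- stats::lm.fit(cbind(1, x), y)
  fitted <- as.numeric(cbind(1, x) %*% fit$coefficients)
  r2 <- 100 - pop_variance(y - fitted) / vy * 100
  list(r2_percent = r2,
       fit = list(intercept = unname(fit$coefficients[1]),
                  slope = unname(fit$coefficients[2]),
                  fitted = fitted))
}

#' Per-session contour record
#'
#' @param session session identifier.
#' @param thickness_cm surface-layer thickness, cm.
#' @param baseline_mean_cm3,baseline_sd_cm3 baseline volume and uncertainty.
#' @param volumes_cm3 named numeric vector of contour volumes per evaluated
#'   source (emulation mode / workflow).
#' @param lattice_id signature of the session lattice (dims/spacing), used to
#'   reject mixed-lattice summaries.
#' @return a `session_result` object; deviations are source volume minus
#'   baseline mean (signed).
#' @export
session_result <- function(session, thickness_cm, baseline_mean_cm3,
                           baseline_sd_cm3, volumes_cm3,
                           lattice_id = "default") {
  stopifnot(baseline_sd_cm3 >= 0, !is.null(names(volumes_cm3)))
  structure(list(session = session, thickness_cm = thickness_cm,
                 baseline_mean_cm3 = baseline_mean_cm3,
                 baseline_sd_cm3 = baseline_sd_cm3,
                 volumes_cm3 = volumes_cm3,
                 deviations_cm3 = volumes_cm3 - baseline_mean_cm3,
                 lattice_id = lattice_id),
            class = "session_result")
}

#' Summarize a session series into the study table
#'
#' Per contour source: per-session volume deviations from baseline, MAD, and
#' (when at least three sessions with varying volume exist) the
#' thickness-volume R^2. Sources whose MAD exceeds the maximum baseline SD
#' across sessions - the study's uncertainty ceiling - are flagged.
#'
#' @param sessions list of [session_result()] objects with identical source
#'   names and lattices.
#' @return list with `table` (long data frame of volumes and deviations),
#'   `mad_cm3` (named per source), `r2_percent` (named per source, `NA`
#'   where undefined), `max_baseline_sd_cm3`, and `flagged` (logical per
#'   source: MAD above the uncertainty ceiling).
#' @export
summarize_sessions <- function(sessions) {
  stopifnot(length(sessions) > 0,
            all(vapply(sessions, inherits, logical(1), "session_result")))
  src <- names(sessions[[1]]$volumes_cm3)
  for (s in sessions) {
    if (!identical(names(s$volumes_cm3), src))
      stop("sessions have inconsistent sources")
    if (!identical(s$lattice_id, sessions[[1]]$lattice_id))
      stop("sessions lie on mixed lattices")
  }
  tab <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(session = s$session, thickness_cm = s$thickness_cm,
               source = src, volume_cm3 = unname(s$volumes_cm3[src]),
               baseline_mean_cm3 = s$baseline_mean_cm3,
               baseline_sd_cm3 = s$baseline_sd_cm3,
               deviation_cm3 = unname(s$deviations_cm3[src]))
  }))
  max_sd <- max(vapply(sessions, function(s) s$baseline_sd_cm3, numeric(1)))
  mads <- vapply(src, function(g)
    mean_abs_deviation(tab$deviation_cm3[tab$source == g]), numeric(1))
  r2 <- vapply(src, function(g) {
    sub <- tab[tab$source == g, ]
    if (nrow(sub) < 3 || pop_variance(sub$volume_cm3) == 0) return(NA_real_)
    r_squared(sub$thickness_cm, sub$volume_cm3)$r2_percent
  }, numeric(1))
  list(table = tab, mad_cm3 = mads, r2_percent = r2,
       max_baseline_sd_cm3 = max_sd, flagged = mads > max_sd)
}
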
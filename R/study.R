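#' Central background-sampling box inside the phantom core
#'
#' Convenience region for [homogenize_params()]: an axis-aligned box centred
#' on the ellipse axis at mid-slab, inside tissue and away from the bone
#' insert and surface.
#'
#' @param phantom a `phantom` from [make_phantom()].
#' @param halfwidth_mm box half-widths (x, y, z) in mm; the default scales
#'   with the phantom (a quarter of each semi-axis, a fifth of the slab) so
#'   the box stays inside tissue.
#' @param center_mm optional box centre in mm world coordinates; default is
#'   the ellipse axis at mid-slab, shifted anteriorly away from the bone
#'   insert.
#' @return a [structure_mask()] labelled `"background"`.
#' @export
background_box <- function(phantom, halfwidth_mm = NULL, center_mm = NULL) {
  img <- phantom$image
  ax <- phantom$spec$semi_axes_mm
  if (is.null(halfwidth_mm))
    halfwidth_mm <- c(ax[1] / 4, ax[2] / 4, phantom$spec$slab_mm / 5)
  if (is.null(center_mm))
    center_mm <- c(0, -ax[2] / 2, phantom$landmarks$z_mid_mm)
  inside <- function(axis) {
    abs(axis_coords(img, axis) - center_mm[axis]) <= halfwidth_mm[axis]
  }
  vals <- array(FALSE, dim(img$values))
  vals[inside(1), inside(2), inside(3)] <- TRUE
  structure_mask(vals, img$spacing, img$origin, "background")
}

#' Configuration of the full in-silico study
#'
#' Bundles every stage parameter: phantom geometry, the weight-loss
#' thickness schedule, the bolus clinical cases with their gap profiles,
#' contouring thresholds and z crop, homogenization parameters, emulation
#' modes, dose model and goals, and gamma criteria. The master seed spawns
#' per-stage seeds deterministically.
#'
#' @param spec a [phantom_spec()]; per-session thickness, gaps and seeds are
#'   derived from it.
#' @param thicknesses_cm weight-loss schedule (cm, reference session first).
#' @param weight_loss_gaps gap profile for the raw weight-loss images
#'   (removed by homogenization).
#' @param bolus_cases list of bolus clinical cases:
#'   `list(thickness_cm, gap_profile)`.
#' @param thresholds_hu baseline contouring thresholds.
#' @param z_lim_cm superior-inferior crop (cm, phantom z frame with 0 at the
#'   superior slab face) applied to all contours.
#' @param emulation_modes character vector of weight-loss emulation modes to
#'   evaluate.
#' @param prescription_gy,fractions prescription (70 Gy in 35 fractions).
#' @param mu_per_cm,penumbra_sigma_mm,dose_spacing_mm toy dose model and
#'   dose-grid parameters.
#' @param gamma a [gamma_params()].
#' @param skin_crop_mm skin-sparing crop of the target evaluation structure
#'   for the 0 cm session.
#' @param seed master seed.
#' @return a `study_config` object.
#' @export
study_config <- function(spec = phantom_spec(),
                         thicknesses_cm = c(2, 1.5, 1, 0.5, 0),
                         weight_loss_gaps = gap_profile(
                           c(190, 320), c(260, 355), c(1.5, 0.8)),
                         bolus_cases = list(
                           list(thickness_cm = 1, gap_profile = gap_profile(
                             c(200, 60, 130), c(290, 110, 150), c(3, 3, 0.3))),
                           list(thickness_cm = 0.5, gap_profile = gap_profile(
                             c(200, 60, 130), c(290, 110, 150), c(3, 3, 0.3)))),
                         thresholds_hu = c(-300, -450, -600),
                         z_lim_cm = c(0.5, 6.9),
                         emulation_modes = c("accurate", "reference_anchored"),
                         prescription_gy = 70, fractions = 35,
                         mu_per_cm = 0.05, penumbra_sigma_mm = 3,
                         dose_spacing_mm = 2.5,
                         gamma = gamma_params(),
                         skin_crop_mm = 3,
                         seed = 20) {
  stopifnot(length(emulation_modes) >= 1, length(thicknesses_cm) >= 1)
  spec$seed <- seed
  spec$gap_profile <- weight_loss_gaps
  structure(as.list(environment()), class = "study_config")
}

#' Run the full in-silico contour and dose study
#'
#' Orchestrates generate, homogenize, contour, emulate, metrics and dose
#' stages from one [study_config()]:
#' \enumerate{
#'   \item weight-loss series generated at the configured thicknesses (raw +
#'     homogenized-truth twins);
#'   \item raw images homogenized; the homogenized image is the session
#'     anatomy from here on;
#'   \item per session: three-threshold baseline contour, then one emulated
#'     contour per emulation mode (the first session is the reference for
#'     the reference-anchored mode), all cropped to the configured z slab;
#'   \item volume deviations, MAD and thickness-volume R^2 per mode;
#'   \item toy-dose planning: the reference session's plan gives the planned
#'     D95%; per session the reference plan is replayed (scheduled) and
#'     renormalized (adapted), D95% deviations are tracked, and the
#'     emulator-computed adapted dose is gamma-compared against the same
#'     plan forward-computed on the coarse dose lattice;
#'   \item bolus clinical cases: raw (un-homogenized) images are contoured
#'     and the bolus-excluding emulation is compared against baseline.
#' }
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, writes `sessions.csv`,
#'   `dose.csv`, `bolus.csv`, `summary.json` and `manifest.json`.
#' @return list with `sessions` (per-session long table), `contour`
#'   (summary from [summarize_sessions()]), `dose` (per-session dose table),
#'   `dose_summary`, `bolus` (bolus-case table and summary), and `config`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  series <- make_weight_loss_series(config$spec, config$thicknesses_cm)

  # --- homogenize raw sessions -------------------------------------------
  sessions <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    bg <- background_box(s$raw)
    hp <- homogenize_params(background_region = bg,
                            fill_seed = config$seed + 100L + i)
    h <- homogenize(s$raw$image, hp)
    c(s, list(homogenized = h$image, homog_masks = h$masks))
  })

  # --- contours ----------------------------------------------------------
  ref_body <- sessions[[1]]$truth$masks$body_outer
  emu_seed <- config$seed + 200L
  crop <- function(m) crop_z(m, config$z_lim_cm[1], config$z_lim_cm[2])
  session_results <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    bl <- baseline_contour(s$homogenized, config$thresholds_hu,
                           z_lim_cm = config$z_lim_cm)
    vols <- vapply(config$emulation_modes, function(mode) {
      p <- contour_emulation_params(mode = mode, seed = emu_seed)
      m <- emulate_autocontour(s$truth, p, reference_body = ref_body,
                               session_index = i)
      volume_cm3(crop(m))
    }, numeric(1))
    vols <- c(vols, truth = volume_cm3(crop(s$truth$masks$body_outer)))
    session_result(session = i, thickness_cm = s$thickness_cm,
                   baseline_mean_cm3 = bl$mean_cm3,
                   baseline_sd_cm3 = bl$sd_cm3, volumes_cm3 = vols,
                   lattice_id = paste(dim(s$homogenized$values),
                                      collapse = "x"))
  })
  contour_summary <- summarize_sessions(session_results)

  # --- dose --------------------------------------------------------------
  dose <- run_dose_stage(sessions, config)

  # --- bolus clinical cases ---------------------------------------------
  bolus <- run_bolus_cases(config)

  res <- list(sessions = contour_summary$table, contour = contour_summary,
              dose = dose$table, dose_summary = dose$summary,
              bolus = bolus, config = config)
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}

run_dose_stage <- function(sessions, config) {
  eval_target <- function(s) {
    tg <- s$truth$masks$target
    if (s$thickness_cm == 0)
      tg <- crop_target_from_surface(tg, s$truth$masks$body_outer,
                                     config$skin_crop_mm)
    tg
  }
  plan <- function(img, target, scale = NULL)
    toy_dose_model(img, target, prescription_gy = config$prescription_gy,
                   mu_per_cm = config$mu_per_cm,
                   penumbra_sigma_mm = config$penumbra_sigma_mm,
                   norm_scale = scale)
  ref <- sessions[[1]]
  ref_plan <- plan(ref$homogenized, eval_target(ref))
  planned_d95 <- dvh_metric(ref_plan$dose, eval_target(ref), 95)

  rows <- lapply(sessions, function(s) {
    tg <- eval_target(s)
    adapted <- plan(s$homogenized, tg)
    # scheduled = the reference plan replayed: same beams, reference scale
    scheduled <- list(dose = dose_grid(
      adapted$dose$values / adapted$scale * ref_plan$scale,
      adapted$dose$spacing, adapted$dose$origin), scale = ref_plan$scale)
    # emulator-vs-forward consistency: fine-lattice plan downsampled to the
    # clinical dose grid vs the same plan computed on a coarsened anatomy
    lat <- make_dose_lattice(s$homogenized, config$dose_spacing_mm)
    coarse_img <- image_grid(
      resample_dose(dose_grid(s$homogenized$values - min(s$homogenized$values),
                              s$homogenized$spacing, s$homogenized$origin),
                    lat, method = "trilinear")$values +
        min(s$homogenized$values), lat$spacing, lat$origin)
    coarse_tg <- resample_mask(tg, lat)
    forward <- plan(coarse_img, coarse_tg, scale = adapted$scale)
    emu_coarse <- resample_dose(adapted$dose, lat, method = "trilinear")
    g <- gamma_pass_rate(emu_coarse, forward$dose, config$gamma)
    data.frame(thickness_cm = s$thickness_cm,
               d95_adapted_gy = dvh_metric(adapted$dose, tg, 95),
               d95_scheduled_gy = dvh_metric(scheduled$dose, tg, 95),
               d99_adapted_gy = dvh_metric(adapted$dose, tg, 99),
               gamma_pass_percent = g$pass_percent)
  })
  tab <- do.call(rbind, rows)
  tab$d95_planned_gy <- planned_d95
  sched <- dose_deviation_track(tab$d95_scheduled_gy, planned_d95)
  adap <- dose_deviation_track(tab$d95_adapted_gy, planned_d95)
  tab$scheduled_dev_percent <- sched$deviation_percent
  tab$adapted_dev_percent <- adap$deviation_percent
  list(table = tab,
       summary = list(planned_d95_gy = planned_d95,
                      max_abs_scheduled_dev_percent = sched$max_abs_percent,
                      max_abs_adapted_dev_percent = adap$max_abs_percent,
                      min_gamma_pass_percent = min(tab$gamma_pass_percent)))
}

run_bolus_cases <- function(config) {
  if (length(config$bolus_cases) == 0) return(NULL)
  # one lattice across the bolus cases
  exts <- lapply(config$bolus_cases, function(cs) {
    s <- config$spec
    s$surface_thickness_cm <- cs$thickness_cm
    s$gap_profile <- cs$gap_profile
    required_extent(s)
  })
  shared_ext <- list(x_ext = max(vapply(exts, `[[`, 1, "x_ext")),
                     y_lo = max(vapply(exts, `[[`, 1, "y_lo")),
                     y_hi = max(vapply(exts, `[[`, 1, "y_hi")))
  results <- lapply(seq_along(config$bolus_cases), function(i) {
    cs <- config$bolus_cases[[i]]
    s <- config$spec
    s$surface_thickness_cm <- cs$thickness_cm
    s$gap_profile <- cs$gap_profile
    s$fixed_extent_mm <- shared_ext
    s$seed <- config$seed + 300L + i
    ph <- make_phantom(s)
    bl <- baseline_contour(ph$image, config$thresholds_hu,
                           z_lim_cm = config$z_lim_cm)
    p <- contour_emulation_params(mode = "bolus_excluding",
                                  seed = config$seed + 400L)
    auto <- crop_z(emulate_autocontour(ph, p, session_index = i),
                   config$z_lim_cm[1], config$z_lim_cm[2])
    session_result(session = i, thickness_cm = cs$thickness_cm,
                   baseline_mean_cm3 = bl$mean_cm3,
                   baseline_sd_cm3 = bl$sd_cm3,
                   volumes_cm3 = c(
                     bolus_excluding = volume_cm3(auto),
                     truth = volume_cm3(crop_z(ph$masks$body_outer,
                                               config$z_lim_cm[1],
                                               config$z_lim_cm[2]))),
                   lattice_id = paste(dim(ph$image$values), collapse = "x"))
  })
  summarize_sessions(results)
}

write_study_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$sessions, file.path(out_dir, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$dose, file.path(out_dir, "dose.csv"),
                   row.names = FALSE)
  if (!is.null(res$bolus))
    utils::write.csv(res$bolus$table, file.path(out_dir, "bolus.csv"),
                     row.names = FALSE)
  summary <- list(
    contour = list(mad_cm3 = as.list(res$contour$mad_cm3),
                   r2_percent = as.list(res$contour$r2_percent),
                   max_baseline_sd_cm3 = res$contour$max_baseline_sd_cm3,
                   flagged = as.list(res$contour$flagged)),
    dose = res$dose_summary,
    bolus = if (!is.null(res$bolus))
      list(mad_cm3 = as.list(res$bolus$mad_cm3),
           max_baseline_sd_cm3 = res$bolus$max_baseline_sd_cm3,
           flagged = as.list(res$bolus$flagged)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    thicknesses_cm = res$config$thicknesses_cm,
    z_lim_cm = res$config$z_lim_cm,
    thresholds_hu = res$config$thresholds_hu,
    emulation_modes = res$config$emulation_modes,
    seed = res$config$seed,
    z_landmark = "z = 0 mm at the superior slab face, increasing inferiorly")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Deterministic miniature fixture bundle for tests
#'
#' Generates small phantoms (lattices at or below 64 voxels per side), a
#' matched dose-grid pair and a manifest with per-file checksums; two calls
#' with the same size are byte-identical.
#'
#' @param size `"tiny"` (single small phantom + gamma pair) or `"small"`
#'   (adds a 5-session weight-loss series).
#' @param dir output directory (created if needed).
#' @return the manifest list, invisibly; files are written under `dir`.
#' @export
make_fixtures <- function(size = c("tiny", "small"),
                          dir = tempfile("fixtures")) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- phantom_spec(semi_axes_mm = c(16, 13), slab_mm = 16, z_pad_mm = 2,
                       margin_mm = 4, bone = NULL,
                       target = list(radius_mm = 5, angle_deg = 270, hu = 50),
                       surface_thickness_cm = 0.4,
                       gap_profile = gap_profile(200, 280, 1),
                       psf_sigma_mm = 0, tissue_sd = 0, bolus_sd = 0,
                       seed = 7)
  ph <- make_phantom(spec)
  write_image(ph$image, file.path(dir, "tiny_phantom.mha"))
  write_image(ph$masks$body_outer, file.path(dir, "tiny_body.mha"))
  d <- dose_grid(array(rep(seq(0, 2, length.out = 16), each = 16 * 16),
                       c(16, 16, 16)))
  write_image(d, file.path(dir, "tiny_dose_ref.mha"))
  write_image(d, file.path(dir, "tiny_dose_eval.mha"))
  expected <- list(tiny_gamma_identity_pass_percent = 100)
  if (size == "small") {
    ser <- make_weight_loss_series(spec, c(0.8, 0.6, 0.4, 0.2, 0))
    for (i in seq_along(ser)) {
      write_image(ser[[i]]$raw$image,
                  file.path(dir, sprintf("wl_raw_%d.mha", i)))
      write_image(ser[[i]]$truth$masks$body_outer,
                  file.path(dir, sprintf("wl_body_%d.mha", i)))
    }
    expected$wl_truth_volumes_cm3 <- vapply(
      ser, function(s) volume_cm3(s$truth$masks$body_outer), numeric(1))
  }
  files <- sort(list.files(dir, pattern = "\\.mha$"))
  manifest <- list(size = size, files = files,
                   md5 = unname(tools::md5sum(file.path(dir, files))),
                   expected = expected)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
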
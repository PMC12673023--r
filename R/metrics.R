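# Per-subject biomechanical metrics: distensibility, strain, peaks.

#' Brachial blood pressure
#'
#' @param systolic,diastolic pressures in mmHg (systolic > diastolic > 0).
#' @return A `blood_pressure` object with derived pulse pressure
#'   (systolic - diastolic) and mean arterial pressure (diastolic + PP/3).
#' @export
blood_pressure <- function(systolic, diastolic) {
  if (diastolic <= 0 || systolic <= diastolic)
    abort_input("need systolic > diastolic > 0 (mmHg)")
  structure(list(systolic = systolic, diastolic = diastolic,
                 pulse_pressure = systolic - diastolic,
                 map = diastolic + (systolic - diastolic) / 3),
            class = "blood_pressure")
}

#' @export
print.blood_pressure <- function(x, ...) {
  cat(sprintf("<blood_pressure> %g/%g mmHg (PP %g, MAP %.1f)\n", x$systolic,
              x$diastolic, x$pulse_pressure, x$map))
  invisible(x)
}

#' Peak change of a per-phase curve
#'
#' Maximum change relative to the end-diastolic baseline (phase 0), with the
#' earliest phase winning ties.
#'
#' @param values per-phase values (phase 0 first).
#' @return List: `value` (peak change from baseline) and `phase` (0-based).
#' @export
peak_value <- function(values) {
  if (length(values) == 0) abort_input("empty curve")
  ch <- values - values[1]
  i <- which.max(ch)  # earliest maximum
  list(value = ch[i], phase = i - 1L)
}

#' Volumetric (3D) distensibility
#'
#' `(max_t V(t) - V(0)) / (V(0) * PP)`, reported in 1e-3 / mmHg. The maximum
#' is searched over all phases, not restricted to systole.
#'
#' @param values per-phase volume curve (any consistent unit), phase 0 first.
#' @param bp a [blood_pressure()] (or pulse pressure in mmHg).
#' @return Distensibility in 1e-3 / mmHg.
#' @export
distensibility_3d <- function(values, bp) {
  pp <- if (inherits(bp, "blood_pressure")) bp$pulse_pressure else bp
  if (length(values) == 0) abort_input("empty curve")
  if (values[1] <= 0) abort_input("end-diastolic baseline must be > 0")
  if (pp <= 0) abort_input("pulse pressure must be > 0")
  (max(values) - values[1]) / (values[1] * pp) * 1e3
}

#' Cross-sectional (2D) distensibility
#'
#' Same contract as [distensibility_3d()] applied to the area curve of a
#' motion-tracked plane: `(max_t A(t) - A(0)) / (A(0) * PP)` in 1e-3 / mmHg.
#'
#' @inheritParams distensibility_3d
#' @param values per-phase area curve of a tracked plane, phase 0 first.
#' @return Distensibility in 1e-3 / mmHg.
#' @export
distensibility_2d <- function(values, bp) distensibility_3d(values, bp)

#' Longitudinal strain curve
#'
#' Percent lengthening of the ascending (annulus to brachiocephalic trunk)
#' centerline relative to end-diastole: `100 (L(t) - L(0)) / L(0)`.
#'
#' @param lengths per-phase centerline lengths (mm), phase 0 first.
#' @return Tibble (phase, value) in percent; attribute `peak` holds the
#'   subject-level maximum and its phase.
#' @export
longitudinal_strain_curve <- function(lengths) {
  if (length(lengths) == 0) abort_input("no phase lengths")
  if (any(!is.finite(lengths))) abort_input("missing phase centerline length")
  vals <- 100 * (lengths - lengths[1]) / lengths[1]
  out <- tibble(phase = seq_along(vals) - 1L, value = vals)
  attr(out, "peak") <- peak_value(vals)
  out
}

#' Analysis parameters for a subject
#'
#' @param reg a [registration_params()].
#' @param band_mm plane band half-width for tracking and displacement (mm).
#' @param plane_extent_mm in-plane half-width of anatomical planes (mm).
#' @param sample_step_mm centerline resampling step (mm).
#' @param rmax_mm arc-length map assignment radius (mm).
#' @param sigma_vox surface-extraction smoothing (voxel units).
#' @param area_offsets_mm normal offsets for band-averaged plane areas (mm).
#' @return A `subject_params` object.
#' @export
subject_params <- function(reg = registration_params(), band_mm = 2.5,
                           plane_extent_mm = 25, sample_step_mm = 0.5,
                           rmax_mm = 35, sigma_vox = 1.0,
                           area_offsets_mm = c(-5, -2.5, 0, 2.5, 5)) {
  structure(list(reg = reg, band_mm = band_mm,
                 plane_extent_mm = plane_extent_mm,
                 sample_step_mm = sample_step_mm, rmax_mm = rmax_mm,
                 sigma_vox = sigma_vox, area_offsets_mm = area_offsets_mm),
            class = "subject_params")
}

# Transport an anatomical level landmark to a phase. The annulus is an
# end-face feature whose motion the registration observes directly, so it
# gets the full displacement (`full = TRUE`). Interior levels (BCT, LSA,
# diaphragm) are defined by external anatomy: sliding of such a level along
# the vessel is unobservable from the segmentation surface (aperture
# ambiguity), so only the tangent-orthogonal component of the local
# displacement is applied — the level follows the vessel's lateral motion
# but keeps its arc-length station.
transport_level <- function(field, point, phase, cl, full = FALSE) {
  u <- as.numeric(interp_displacement(field, point, phase))
  if (!full) {
    P <- as.matrix(cl$points[, c("x", "y", "z")])
    d2 <- (P[, 1] - point[1])^2 + (P[, 2] - point[2])^2 +
      (P[, 3] - point[3])^2
    i <- which.min(d2)
    tg <- as.numeric(cl$points[i, c("tx", "ty", "tz")])
    u <- u - sum(u * tg) * tg
  }
  point + u
}

# representative computed phase for each phase (identical-mask reuse map)
phase_representatives <- function(field) {
  d <- field$diagnostics
  rep_of <- d$phase
  reused <- !is.na(d$reused_from)
  rep_of[reused] <- d$reused_from[reused]
  rep_of
}

#' Compute the full per-subject metric panel
#'
#' Orchestrates the pipeline: validation, end-diastolic centerline (seeded at
#' the STJ and diaphragm landmarks, extended to the annulus), non-rigid
#' displacement field, motion-tracked planes with per-phase areas, landmark-
#' bounded segment volumes on the nearest-arc-length map, per-phase
#' centerlines for longitudinal strain (seeds and annulus transported by the
#' displacement field), and the aortic tortuosity index.
#'
#' @param series a [seg_series()].
#' @param landmarks named list of world-mm points with entries `annulus`,
#'   `STJ`, `mid_AAo`, `BCT`, `LSA`, `mid_DAo`, `diaphragm`.
#' @param bp a [blood_pressure()].
#' @param params a [subject_params()].
#' @return An `aorta_subject`: `$curves` (long tibble: metric, phase, value,
#'   units), `$metrics` (one-row wide tibble), plus the centerline,
#'   displacement diagnostics and validation report.
#' @export
compute_subject <- function(series, landmarks, bp,
                            params = subject_params()) {
  needed <- c("annulus", "STJ", "mid_AAo", "BCT", "LSA", "mid_DAo",
              "diaphragm")
  if (!all(needed %in% names(landmarks)))
    abort_input(paste("missing landmarks:",
                      paste(setdiff(needed, names(landmarks)), collapse = ", ")))
  if (!inherits(bp, "blood_pressure")) abort_input("`bp` must be a blood_pressure()")

  val <- validate_series(series)
  if (!val$verdict)
    stop("series failed validation; see validate_series() report [stage: validate]")

  n <- series$n_phases
  phases <- lapply(seq_len(n) - 1L, function(t) series_phase(series, t))
  phase0 <- phases[[1]]

  # end-diastolic centerline
  cl0 <- extract_centerline(phase0, landmarks$STJ, landmarks$diaphragm) |>
    extend_to_annulus(landmarks$annulus) |>
    smooth_centerline(sample_step_mm = params$sample_step_mm) |>
    recenter_centerline(phase0, extent_mm = params$plane_extent_mm) |>
    set_landmarks(landmarks)

  # displacement field
  field <- displacement_field(series, params$reg, params$sigma_vox)
  rep_of <- phase_representatives(field)

  # planes
  plane_labels <- c("STJ", "mid_AAo", "mid_DAo", "diaphragm")
  planes <- lapply(plane_labels, function(l)
    define_plane(cl0, l, extent_mm = params$plane_extent_mm))
  names(planes) <- plane_labels
  areas <- matrix(NA_real_, n, length(plane_labels),
                  dimnames = list(NULL, plane_labels))

  # plane displacement curves
  disp <- lapply(planes, function(pl)
    mean_plane_displacement(field, pl, params$band_mm))

  # per-phase tracked areas and segment volumes (one smoothed field per
  # computed phase, shared by both measurements)
  smap <- arc_length_map(cl0, phase0, params$rmax_mm)
  seg_bounds <- list(AAo = c("annulus", "BCT"), DAo = c("LSA", "diaphragm"))
  vols <- matrix(NA_real_, n, 2, dimnames = list(NULL, names(seg_bounds)))
  cl_pts <- as.matrix(cl0$points[, c("x", "y", "z")])
  nr <- nrow(cl_pts)
  # nearest-sample arc length, extrapolated linearly beyond the ends (same
  # convention as arc_length_map)
  project_s <- function(p) {
    d2 <- (cl_pts[, 1] - p[1])^2 + (cl_pts[, 2] - p[2])^2 +
      (cl_pts[, 3] - p[3])^2
    i <- which.min(d2)
    s <- cl0$points$s[i]
    if (i == 1L) {
      tg <- cl_pts[2, ] - cl_pts[1, ]
      proj <- sum((p - cl_pts[1, ]) * tg) / sqrt(sum(tg^2))
      if (proj < 0) s <- s + proj
    } else if (i == nr) {
      tg <- cl_pts[nr, ] - cl_pts[nr - 1, ]
      proj <- sum((p - cl_pts[nr, ]) * tg) / sqrt(sum(tg^2))
      if (proj > 0) s <- s + proj
    }
    s
  }
  for (t in seq_len(n) - 1L) {
    r <- rep_of[t + 1L]
    if (r != t) {
      vols[t + 1L, ] <- vols[r + 1L, ]
      areas[t + 1L, ] <- areas[r + 1L, ]
      next
    }
    vol_sm <- cpp_gauss_smooth(as.numeric(phases[[t + 1L]]$vox),
                               phases[[t + 1L]]$dim, 0.7)
    for (l in plane_labels) {
      tracked <- track_plane(planes[[l]], field, t, params$band_mm)
      areas[t + 1L, l] <- plane_area_banded(phases[[t + 1L]], tracked,
                                            offsets = params$area_offsets_mm,
                                            vol = vol_sm)
    }
    for (sg in names(seg_bounds)) {
      b <- seg_bounds[[sg]]
      s0 <- project_s(transport_level(field, landmarks[[b[1]]], t, cl0,
                                      full = b[1] == "annulus"))
      s1 <- project_s(transport_level(field, landmarks[[b[2]]], t, cl0))
      vols[t + 1L, sg] <- segment_volume_range(phases[[t + 1L]], smap,
                                               sort(c(s0, s1)),
                                               vol = vol_sm)
    }
  }

  # per-phase centerline lengths annulus -> BCT (longitudinal strain)
  lens <- rep(NA_real_, n)
  lens[1] <- arc_length_between(cl0, "annulus", "BCT")
  for (t in seq_len(n - 1L)) {
    r <- rep_of[t + 1L]
    if (r != t && !is.na(lens[r + 1L])) { lens[t + 1L] <- lens[r + 1L]; next }
    ann_t <- as.numeric(transport_point(field, landmarks$annulus, t))
    cl_t <- extract_centerline(phases[[t + 1L]],
                               as.numeric(transport_point(field, landmarks$STJ, t)),
                               as.numeric(transport_point(field, landmarks$diaphragm, t))) |>
      extend_to_annulus(ann_t) |>
      smooth_centerline(sample_step_mm = params$sample_step_mm) |>
      recenter_centerline(phases[[t + 1L]],
                          extent_mm = params$plane_extent_mm) |>
      set_landmarks(list(annulus = ann_t,
                         BCT = transport_level(field, landmarks$BCT, t, cl0)))
    lens[t + 1L] <- arc_length_between(cl_t, "annulus", "BCT")
  }
  strain <- longitudinal_strain_curve(lens)

  # assemble curves
  curves <- dplyr::bind_rows(
    tibble(metric = "volume_aao", phase = 0:(n - 1), value = vols[, "AAo"],
           units = "mm^3"),
    tibble(metric = "volume_dao", phase = 0:(n - 1), value = vols[, "DAo"],
           units = "mm^3"),
    dplyr::bind_rows(lapply(plane_labels, function(l)
      tibble(metric = paste0("area_", tolower(l)), phase = 0:(n - 1),
             value = areas[, l], units = "mm^2"))),
    tibble(metric = "length_aao", phase = 0:(n - 1), value = lens,
           units = "mm"),
    tibble(metric = "strain_aao", phase = strain$phase, value = strain$value,
           units = "%"),
    dplyr::bind_rows(lapply(plane_labels, function(l)
      tibble(metric = paste0("disp_", tolower(l)),
             phase = disp[[l]]$curve$phase, value = disp[[l]]$curve$value,
             units = "mm"))))
  class(curves) <- c("aorta_curves", class(curves))

  strain_peak <- attr(strain, "peak")
  metrics <- tibble(
    v_ed_aao_ml = vols[1, "AAo"] / 1000,
    v_max_aao_ml = max(vols[, "AAo"]) / 1000,
    v_ed_dao_ml = vols[1, "DAo"] / 1000,
    v_max_dao_ml = max(vols[, "DAo"]) / 1000,
    dist3d_aao = distensibility_3d(vols[, "AAo"], bp),
    dist3d_dao = distensibility_3d(vols[, "DAo"], bp),
    a_ed_mid_aao = areas[1, "mid_AAo"],
    a_max_mid_aao = max(areas[, "mid_AAo"]),
    a_ed_mid_dao = areas[1, "mid_DAo"],
    a_max_mid_dao = max(areas[, "mid_DAo"]),
    dist2d_mid_aao = distensibility_2d(areas[, "mid_AAo"], bp),
    dist2d_mid_dao = distensibility_2d(areas[, "mid_DAo"], bp),
    l_ed_aao = lens[1],
    l_max_aao = max(lens),
    strain_pct = strain_peak$value,
    strain_peak_phase = strain_peak$phase,
    disp_stj = disp$STJ$peak$value,
    disp_stj_phase = disp$STJ$peak$phase,
    disp_mid_aao = disp$mid_AAo$peak$value,
    disp_mid_dao = disp$mid_DAo$peak$value,
    disp_diaphragm = disp$diaphragm$peak$value,
    d_ed_mid_aao = equivalent_diameter(areas[1, "mid_AAo"]),
    d_max_mid_aao = equivalent_diameter(max(areas[, "mid_AAo"])),
    ati = tortuosity_index(cl0),
    pp_mmhg = bp$pulse_pressure)

  structure(list(curves = curves, metrics = metrics, centerline = cl0,
                 planes = planes, field_diagnostics = field$diagnostics,
                 validation = val, bp = bp, params = params),
            class = "aorta_subject")
}

#' @export
print.aorta_subject <- function(x, ...) {
  cat("<aorta_subject>\n")
  m <- x$metrics
  cat(sprintf("  3D distensibility AAo %.3f / DAo %.3f (1e-3/mmHg)\n",
              m$dist3d_aao, m$dist3d_dao))
  cat(sprintf("  2D distensibility mid-AAo %.3f / mid-DAo %.3f (1e-3/mmHg)\n",
              m$dist2d_mid_aao, m$dist2d_mid_dao))
  cat(sprintf("  longitudinal strain %.2f %% (phase %d)\n", m$strain_pct,
              m$strain_peak_phase))
  cat(sprintf("  peak plane displacement: STJ %.2f, mid-AAo %.2f, mid-DAo %.2f, diaphragm %.2f mm\n",
              m$disp_stj, m$disp_mid_aao, m$disp_mid_dao, m$disp_diaphragm))
  cat(sprintf("  ATI %.3f, PP %g mmHg\n", m$ati, m$pp_mmhg))
  invisible(x)
}

#' @export
tidy.aorta_subject <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(), names_to = "metric",
                      values_to = "value")
}

#' @export
glance.aorta_subject <- function(x, ...) x$metrics
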
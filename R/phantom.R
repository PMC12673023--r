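# Synthetic deforming-aorta phantom.
#
# Baseline geometry (world mm, arch in the x-z plane): a straight proximal
# root segment (annulus end), a semicircular arch of radius `arch_radius_mm`,
# and a straight descending limb. Three deformation modes, all driven by one
# systolic waveform f(t):
#   * radial dilation        r(s,t) = r0(s) * (1 + a(s) f(t))
#   * longitudinal stretch   arc-length reparametrization of the ascending
#                            segment (annulus -> BCT), anchored at the BCT, so
#                            the annulus-BCT centerline length is L0 (1+eps f)
#   * root displacement      rigid translation along `root_displacement_dir`
#                            weighted by w(s), linear from 1 at the annulus to
#                            0 at the arch apex
# Tube ends are cut flat so segment volumes follow the closed forms exactly.

#' Cardiac-cycle waveform
#'
#' Smooth systolic pulse: `sin^2(pi t / T_sys)` for `t < T_sys`, 0 in
#' diastole. f(0) = 0 (end-diastolic baseline), peak 1 at mid-systole.
#'
#' @param t_frac cycle fraction(s) in `[0, 1)`.
#' @param systole_fraction systolic fraction of the cycle (0 < T_sys < 1).
#' @return waveform value(s) in `[0, 1]`.
#' @export
waveform <- function(t_frac, systole_fraction = 0.35) {
  if (any(t_frac < 0 | t_frac >= 1)) abort_input("t_frac must be in [0, 1)")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    abort_input("systole_fraction must be in (0, 1)")
  ifelse(t_frac < systole_fraction,
         sin(pi * t_frac / systole_fraction)^2, 0)
}

#' Phantom specification
#'
#' Defaults are calibrated so the phantom's end-diastolic ascending length
#' (79.5 mm annulus to brachiocephalic trunk) and deformation magnitudes are
#' in the range reported for healthy adult thoracic aortas.
#'
#' @param arch_radius_mm radius of the arch centerline (mm).
#' @param asc_radius_mm,desc_radius_mm lumen radii of the ascending/descending
#'   segments (mm); tapered linearly between the BCT and LSA landmarks.
#' @param root_length_mm length of the straight proximal root segment (mm).
#' @param desc_length_mm length of the straight descending limb (mm).
#' @param radial_amplitude_asc,radial_amplitude_desc fractional systolic
#'   radius increase of ascending/descending segments (0 <= a < 0.5).
#' @param root_displacement_mm peak displacement of the annulus (mm).
#' @param root_displacement_dir unit direction of root displacement; the
#'   default (+y, perpendicular to the arch plane) leaves centerline arc
#'   length unchanged to first order, keeping the deformation modes
#'   independent.
#' @param strain_amplitude peak fractional lengthening of the annulus-BCT
#'   centerline (longitudinal strain / 100).
#' @param systole_fraction systolic fraction of the cycle.
#' @param n_phases number of cardiac phases.
#' @param spacing_mm isotropic voxel size (mm).
#' @param aao_length_mm end-diastolic annulus-to-BCT centerline length (mm).
#' @param stj_s,mid_aao_s,lsa_s,mid_dao_s,diaphragm_s optional landmark
#'   arc-length positions (mm from the annulus); sensible defaults are
#'   derived from the geometry.
#' @param centerline_step_mm arc-length sampling step for voxelization.
#' @param tilt_deg length-2 rotation (degrees about the x then y axes)
#'   applied to the whole geometry. A real aorta is oblique to the scanner
#'   grid; a non-zero tilt also avoids the pathological case of a straight
#'   limb exactly aligned with the voxel lattice, where voxelization error
#'   is coherent along the vessel.
#' @param seed integer recorded with the spec (the phantom itself is
#'   deterministic; the seed matters for cohort simulation).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(arch_radius_mm = 40, asc_radius_mm = 15,
                         desc_radius_mm = 11, root_length_mm = 25,
                         desc_length_mm = 100,
                         radial_amplitude_asc = 0.10,
                         radial_amplitude_desc = 0.07,
                         root_displacement_mm = 9,
                         root_displacement_dir = c(0, 1, 0),
                         strain_amplitude = 0.15,
                         systole_fraction = 0.35, n_phases = 30,
                         spacing_mm = 1.0, aao_length_mm = 79.5,
                         stj_s = NULL, mid_aao_s = NULL, lsa_s = NULL,
                         mid_dao_s = NULL, diaphragm_s = NULL,
                         centerline_step_mm = 0.5, tilt_deg = c(4, 6),
                         seed = 1L) {
  arc <- pi * arch_radius_mm
  qarc <- arc / 2
  apex_s <- root_length_mm + qarc
  arc_end <- root_length_mm + arc
  total <- arc_end + desc_length_mm
  if (is.null(stj_s)) stj_s <- 0.6 * root_length_mm
  if (is.null(mid_aao_s)) mid_aao_s <- (stj_s + aao_length_mm) / 2
  if (is.null(lsa_s)) lsa_s <- apex_s + 0.35 * qarc
  if (is.null(mid_dao_s)) mid_dao_s <- arc_end + 0.30 * desc_length_mm
  if (is.null(diaphragm_s)) diaphragm_s <- total - max(5, 0.15 * desc_length_mm)
  tx <- tilt_deg[1] * pi / 180
  ty <- tilt_deg[2] * pi / 180
  rot <- matrix(c(cos(ty), 0, -sin(ty), 0, 1, 0, sin(ty), 0, cos(ty)),
                3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(tx), sin(tx), 0, -sin(tx), cos(tx)), 3, 3)
  spec <- list(arch_radius_mm = arch_radius_mm, asc_radius_mm = asc_radius_mm,
               desc_radius_mm = desc_radius_mm,
               root_length_mm = root_length_mm,
               desc_length_mm = desc_length_mm,
               radial_amplitude_asc = radial_amplitude_asc,
               radial_amplitude_desc = radial_amplitude_desc,
               root_displacement_mm = root_displacement_mm,
               root_displacement_dir =
                 root_displacement_dir / sqrt(sum(root_displacement_dir^2)),
               strain_amplitude = strain_amplitude,
               systole_fraction = systole_fraction, n_phases = n_phases,
               spacing_mm = spacing_mm, aao_length_mm = aao_length_mm,
               centerline_step_mm = centerline_step_mm,
               tilt_deg = tilt_deg, rot = rot, seed = seed,
               arc_len = arc, apex_s = apex_s, arc_end_s = arc_end,
               total_s = total,
               landmarks_s = c(annulus = 0, STJ = stj_s, mid_AAo = mid_aao_s,
                               BCT = aao_length_mm, LSA = lsa_s,
                               mid_DAo = mid_dao_s, diaphragm = diaphragm_s))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  amax <- max(spec$radial_amplitude_asc, spec$radial_amplitude_desc)
  if (min(spec$asc_radius_mm, spec$desc_radius_mm) <= 2 * spec$spacing_mm)
    abort_input("radii must exceed 2 * voxel spacing")
  if (amax < 0 || amax >= 0.5)
    abort_input("radial amplitudes must satisfy 0 <= a < 0.5")
  if (spec$systole_fraction <= 0 || spec$systole_fraction >= 1)
    abort_input("systole_fraction must be in (0, 1)")
  if (spec$n_phases < 2) abort_input("n_phases must be >= 2")
  if (spec$asc_radius_mm * (1 + spec$radial_amplitude_asc) >=
      spec$arch_radius_mm)
    abort_input("tube self-intersects: dilated radius exceeds arch curvature radius")
  lm <- spec$landmarks_s
  if (any(diff(lm[c("annulus", "STJ", "mid_AAo", "BCT", "LSA", "mid_DAo",
                    "diaphragm")]) <= 0))
    abort_input("landmark arc-length positions must be strictly increasing")
  if (lm["BCT"] >= spec$arc_end_s)
    abort_input("BCT landmark must lie on the root/arch portion")
  if (lm["diaphragm"] > spec$total_s - 2 * spec$spacing_mm)
    abort_input("diaphragm landmark too close to the tube end")
  invisible(spec)
}

# ---- analytic geometry helpers (material arc-length coordinate s) ----------

# baseline centerline point(s) in the unrotated frame; s may be < 0
# (straight continuation of the root, used by the stretch mode)
phantom_base_point_raw <- function(spec, s) {
  R <- spec$arch_radius_mm
  root <- spec$root_length_mm
  out <- matrix(0, length(s), 3)
  lo <- s < root
  out[lo, 1] <- -R
  out[lo, 3] <- s[lo] - root
  onarc <- s >= root & s <= spec$arc_end_s
  th <- pi - (s[onarc] - root) / R
  out[onarc, 1] <- R * cos(th)
  out[onarc, 3] <- R * sin(th)
  hi <- s > spec$arc_end_s
  out[hi, 1] <- R
  out[hi, 3] <- -(s[hi] - spec$arc_end_s)
  out
}

phantom_base_tangent_raw <- function(spec, s) {
  R <- spec$arch_radius_mm
  root <- spec$root_length_mm
  out <- matrix(0, length(s), 3)
  lo <- s < root
  out[lo, 3] <- 1
  onarc <- s >= root & s <= spec$arc_end_s
  th <- pi - (s[onarc] - root) / R
  out[onarc, 1] <- sin(th)
  out[onarc, 3] <- -cos(th)
  hi <- s > spec$arc_end_s
  out[hi, 3] <- -1
  out
}

# world-frame accessors (tilt rotation applied)
phantom_base_point <- function(spec, s)
  phantom_base_point_raw(spec, s) %*% t(spec$rot)

phantom_base_tangent <- function(spec, s)
  phantom_base_tangent_raw(spec, s) %*% t(spec$rot)

phantom_w_root <- function(spec, s) pmin(1, pmax(0, 1 - s / spec$apex_s))

# linear blend between ascending and descending values over [BCT, LSA]
phantom_blend <- function(spec, s, val_asc, val_desc) {
  bct <- spec$landmarks_s[["BCT"]]
  lsa <- spec$landmarks_s[["LSA"]]
  frac <- pmin(1, pmax(0, (s - bct) / (lsa - bct)))
  val_asc + (val_desc - val_asc) * frac
}

phantom_r0 <- function(spec, s)
  phantom_blend(spec, s, spec$asc_radius_mm, spec$desc_radius_mm)

phantom_amp <- function(spec, s)
  phantom_blend(spec, s, spec$radial_amplitude_asc, spec$radial_amplitude_desc)

# stretch map: material s -> deformed arc position, anchored at the BCT
phantom_phi <- function(spec, s, f) {
  bct <- spec$landmarks_s[["BCT"]]
  ifelse(s < bct, bct - (bct - s) * (1 + spec$strain_amplitude * f), s)
}

# deformed centerline position of material coordinate s at waveform value f
# (deformation composed in the unrotated frame, then tilted to world)
phantom_deformed_point <- function(spec, s, f) {
  p <- phantom_base_point_raw(spec, phantom_phi(spec, s, f))
  w <- phantom_w_root(spec, s)
  (p + outer(w * spec$root_displacement_mm * f,
             spec$root_displacement_dir)) %*% t(spec$rot)
}

phantom_waveform_values <- function(spec)
  waveform((seq_len(spec$n_phases) - 1) / spec$n_phases,
           spec$systole_fraction)

# numerically integrated deformed centerline length between material s
# positions (exact for the analytic curve up to the 0.05 mm sampling)
phantom_deformed_length <- function(spec, s_from, s_to, f) {
  s <- seq(s_from, s_to, length.out = 2001)
  p <- phantom_deformed_point(spec, s, f)
  sum(sqrt(rowSums(diff(p)^2)))
}

# ---- phantom construction ---------------------------------------------------

#' Build a deforming-aorta phantom
#'
#' Voxelizes the analytic tube for every cardiac phase (union of spheres along
#' the deformed centerline, ends cut flat) and returns the mask series
#' together with analytic ground truth for every quantity the measurement
#' pipeline produces.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components `series` (a [seg_series()]) and `truth`
#'   (a `phantom_truth` object: per-phase volume/area/length curves,
#'   per-plane mean surface displacement, landmark world positions, annulus
#'   trajectory, and the analytic tortuosity index).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  f_t <- phantom_waveform_values(spec)
  sp <- spec$spacing_mm
  s_grid <- seq(0, spec$total_s, by = spec$centerline_step_mm)
  r0 <- phantom_r0(spec, s_grid)
  amp <- phantom_amp(spec, s_grid)

  centers_t <- lapply(f_t, function(f) phantom_deformed_point(spec, s_grid, f))
  radii_t <- lapply(f_t, function(f) r0 * (1 + amp * f))

  pad <- 2.5 * sp + 1
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (t in seq_along(f_t)) {
    rr <- radii_t[[t]]
    for (ax in 1:3) {
      lo[ax] <- min(lo[ax], min(centers_t[[t]][, ax] - rr) - pad)
      hi[ax] <- max(hi[ax], max(centers_t[[t]][, ax] + rr) + pad)
    }
  }
  origin <- floor(lo / sp) * sp
  dims <- as.integer(ceiling((hi - origin) / sp)) + 1L

  vox4 <- array(0L, c(dims, spec$n_phases))
  rmax <- max(unlist(radii_t))
  for (t in seq_along(f_t)) {
    m <- cpp_stamp_tube(dims, origin, rep(sp, 3), centers_t[[t]],
                        radii_t[[t]])
    # flat end cuts: proximal (annulus) and distal (diaphragm end)
    eps_s <- 0.5
    p0 <- centers_t[[t]][1, ]
    t0 <- phantom_deformed_point(spec, eps_s, f_t[t]) - p0
    t0 <- t0 / sqrt(sum(t0^2))
    m <- cpp_clip_halfspace(m, dims, origin, rep(sp, 3), p0, -t0,
                            2.5 * rmax)
    p1 <- centers_t[[t]][nrow(centers_t[[t]]), ]
    t1 <- p1 - phantom_deformed_point(spec, spec$total_s - eps_s, f_t[t])
    t1 <- t1 / sqrt(sum(t1^2))
    m <- cpp_clip_halfspace(m, dims, origin, rep(sp, 3), p1, t1,
                            2.5 * rmax)
    vox4[, , , t] <- array(m, dims)
  }
  series <- seg_series(vox4, spacing = rep(sp, 3), origin = origin)
  list(series = series, truth = phantom_truth(spec))
}

# analytic ground truth (no voxels involved)
phantom_truth <- function(spec) {
  f_t <- phantom_waveform_values(spec)
  lm <- spec$landmarks_s
  pp_planes <- c("STJ", "mid_AAo", "mid_DAo", "diaphragm")
  aA <- spec$radial_amplitude_asc; aD <- spec$radial_amplitude_desc
  rA <- spec$asc_radius_mm; rD <- spec$desc_radius_mm
  eps <- spec$strain_amplitude
  L0 <- spec$aao_length_mm
  dao_len <- lm[["diaphragm"]] - lm[["LSA"]]

  curves <- tibble(
    phase = rep(seq_along(f_t) - 1L, times = 5),
    metric = rep(c("volume_aao", "volume_dao", "area_mid_aao",
                   "area_mid_dao", "length_aao"), each = length(f_t)),
    value = c(pi * (rA * (1 + aA * f_t))^2 * L0 * (1 + eps * f_t),
              pi * (rD * (1 + aD * f_t))^2 * dao_len,
              pi * (rA * (1 + aA * f_t))^2,
              pi * (rD * (1 + aD * f_t))^2,
              vapply(f_t, function(f)
                if (spec$root_displacement_mm == 0)
                  L0 * (1 + eps * f)
                else phantom_deformed_length(spec, 0, lm[["BCT"]], f),
                numeric(1))),
    units = rep(c("mm^3", "mm^3", "mm^2", "mm^2", "mm"),
                each = length(f_t)))

  disp <- dplyr::bind_rows(lapply(pp_planes, function(pl) {
    s <- lm[[pl]]
    tibble(plane = pl, phase = seq_along(f_t) - 1L,
           value = vapply(f_t, function(f)
             phantom_ring_mean_disp(spec, s, f), numeric(1)))
  }))

  chord <- sqrt(sum((phantom_base_point(spec, lm[["diaphragm"]]) -
                     phantom_base_point(spec, lm[["STJ"]]))^2))
  ati <- (lm[["diaphragm"]] - lm[["STJ"]]) / chord

  lm_world <- phantom_base_point(spec, as.numeric(lm))
  rownames(lm_world) <- names(lm)

  structure(list(spec = spec, curves = curves, plane_displacement = disp,
                 ati = ati, waveform = f_t,
                 landmarks = lapply(seq_along(lm), function(i) lm_world[i, ]),
                 annulus_path = phantom_deformed_point(
                   spec, rep(0, length(f_t)), 0) * NA),
            class = "phantom_truth") -> tr
  names(tr$landmarks) <- names(lm)
  tr$annulus_path <- do.call(rbind, lapply(f_t, function(f)
    phantom_deformed_point(spec, 0, f)))
  tr
}

# mean surface displacement magnitude over a cross-section ring at material s:
# radial component a(s) r0(s) f plus weighted root translation (tangential
# sliding from the stretch mode is not part of the observable surface motion)
phantom_ring_mean_disp <- function(spec, s, f, n_angle = 720) {
  dr <- phantom_r0(spec, s) * phantom_amp(spec, s) * f
  dvec <- phantom_w_root(spec, s) * spec$root_displacement_mm * f *
    spec$root_displacement_dir
  tg <- phantom_base_tangent_raw(spec, s)[1, ]
  ref <- if (abs(tg[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- ref - sum(ref * tg) * tg
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(tg[2] * e1[3] - tg[3] * e1[2], tg[3] * e1[1] - tg[1] * e1[3],
          tg[1] * e1[2] - tg[2] * e1[1])
  ang <- 2 * pi * (seq_len(n_angle) - 0.5) / n_angle
  nhat <- outer(cos(ang), e1) + outer(sin(ang), e2)
  mean(sqrt(rowSums(sweep(dr * nhat, 2, dvec, "+")^2)))
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  cat(sprintf("  phases: %d, ATI: %.4f\n", length(x$waveform), x$ati))
  pk <- dplyr::summarise(dplyr::group_by(x$curves, .data$metric),
                         baseline = .data$value[.data$phase == 0],
                         peak = max(.data$value))
  print(pk)
  invisible(x)
}

#' Closed-form subject metrics for a phantom
#'
#' Evaluates the analytic peak metrics of a phantom at full waveform
#' amplitude (f = 1): 3D distensibility `((1+a)^2 (1+eps) - 1) / PP` for the
#' ascending segment (volume scales as r^2 L), `((1+a)^2 - 1) / PP` for the
#' descending segment and both 2D (area) distensibilities, longitudinal
#' strain `100 eps`, ring-mean peak displacement per plane, and the
#' tortuosity index. Distensibilities are reported in 1e-3 / mmHg.
#'
#' @param spec a [phantom_spec()].
#' @param pp pulse pressure in mmHg (> 0), or a [blood_pressure()] object.
#' @return One-row tibble of analytic metrics.
#' @export
analytic_metrics <- function(spec, pp) {
  if (inherits(pp, "blood_pressure")) pp <- pp$pulse_pressure
  if (pp <= 0) abort_input("pulse pressure must be > 0")
  aA <- spec$radial_amplitude_asc; aD <- spec$radial_amplitude_desc
  eps <- spec$strain_amplitude
  lm <- spec$landmarks_s
  tibble(
    dist3d_aao = ((1 + aA)^2 * (1 + eps) - 1) / pp * 1e3,
    dist3d_dao = ((1 + aD)^2 - 1) / pp * 1e3,
    dist2d_mid_aao = ((1 + aA)^2 - 1) / pp * 1e3,
    dist2d_mid_dao = ((1 + aD)^2 - 1) / pp * 1e3,
    strain_pct = 100 * eps,
    disp_stj = phantom_ring_mean_disp(spec, lm[["STJ"]], 1),
    disp_mid_aao = phantom_ring_mean_disp(spec, lm[["mid_AAo"]], 1),
    disp_mid_dao = phantom_ring_mean_disp(spec, lm[["mid_DAo"]], 1),
    disp_diaphragm = phantom_ring_mean_disp(spec, lm[["diaphragm"]], 1),
    ati = (lm[["diaphragm"]] - lm[["STJ"]]) /
      sqrt(sum((phantom_base_point(spec, lm[["diaphragm"]]) -
                phantom_base_point(spec, lm[["STJ"]]))^2)))
}

#' Landmark world positions of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return Named list of length-3 world points (mm), end-diastolic.
#' @export
phantom_landmarks <- function(spec) {
  lm <- spec$landmarks_s
  pts <- phantom_base_point(spec, as.numeric(lm))
  out <- lapply(seq_along(lm), function(i) pts[i, ])
  names(out) <- names(lm)
  out
}
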
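# Perpendicular anatomical planes, cross-sectional areas, segment volumes.

#' Define a perpendicular plane at a landmark
#'
#' Plane center is the centerline point at the landmark; the normal is the
#' centerline tangent there.
#'
#' @param cl an `aorta_centerline` with registered landmarks.
#' @param landmark landmark label.
#' @param extent_mm in-plane half-width used for area sampling and for the
#'   in-plane radius of the tracking band (must exceed the local lumen radius
#'   by >= 5 mm).
#' @return An `aorta_plane` (label, center, unit normal, in-plane basis).
#' @export
define_plane <- function(cl, landmark, extent_mm = 25) {
  r <- landmark_row(cl, landmark)
  normal <- landmark_tangent(cl, landmark)
  new_plane(landmark, c(r$x, r$y, r$z), normal, extent_mm)
}

new_plane <- function(label, center, normal, extent_mm) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  structure(list(label = label, center = center, normal = normal, e1 = e1,
                 e2 = e2, extent_mm = extent_mm), class = "aorta_plane")
}

#' @export
print.aorta_plane <- function(x, ...) {
  cat(sprintf("<aorta_plane> %s: center (%.1f, %.1f, %.1f), normal (%.2f, %.2f, %.2f)\n",
              x$label, x$center[1], x$center[2], x$center[3], x$normal[1],
              x$normal[2], x$normal[3]))
  invisible(x)
}

#' Cross-sectional lumen area in a plane
#'
#' The mask is lightly Gaussian-smoothed (the 0.5 level set of the smoothed
#' indicator is free of the lattice staircase that coherently biases areas
#' of a voxelized tube), sampled on a 2D in-plane grid (step = half the
#' voxel spacing) by trilinear interpolation thresholded at 0.5; the area is
#' the 4-connected in-plane region containing the plane center (a plane
#' through the arch also slices the other limb; connectivity filtering
#' removes it).
#'
#' @param phase a single-phase view from [series_phase_view()].
#' @param plane an `aorta_plane`.
#' @param sigma_vox mask smoothing in voxel units (0 samples the raw binary
#'   mask).
#' @param vol optional precomputed smoothed field for the full phase volume
#'   (numeric array; internal reuse across planes).
#' @return Area in mm^2.
#' @export
plane_area <- function(phase, plane, sigma_vox = 0.7, vol = NULL) {
  if (is.null(vol)) {
    if (sigma_vox > 0) {
      # crop to a box around the plane before smoothing
      pad <- plane$extent_mm + 3 * sigma_vox * max(phase$spacing)
      lo <- pmax(floor((plane$center - pad - phase$origin) / phase$spacing),
                 0)
      hi <- pmin(ceiling((plane$center + pad - phase$origin) / phase$spacing),
                 phase$dim - 1)
      sub <- phase$vox[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                       (lo[3] + 1):(hi[3] + 1), drop = FALSE]
      sm <- cpp_gauss_smooth(as.numeric(sub), dim(sub), sigma_vox)
      a <- cpp_plane_area(sm, dim(sub), phase$origin + lo * phase$spacing,
                          phase$spacing, plane$center, plane$e1, plane$e2,
                          min(phase$spacing) / 4, plane$extent_mm)
    } else {
      a <- cpp_plane_area(as.numeric(phase$vox), phase$dim, phase$origin,
                          phase$spacing, plane$center, plane$e1, plane$e2,
                          min(phase$spacing) / 4, plane$extent_mm)
    }
  } else {
    a <- cpp_plane_area(vol, phase$dim, phase$origin, phase$spacing,
                        plane$center, plane$e1, plane$e2,
                        min(phase$spacing) / 4, plane$extent_mm)
  }
  if (a < 0) abort_input("plane center lies outside the foreground")
  a
}

#' Band-averaged cross-sectional area
#'
#' Mean of [plane_area()] over a few parallel sections offset along the
#' plane normal. A single section of a 1 mm binary mask carries a residual
#' lattice-phase bias of a few tenths of a percent; parallel sections sample
#' different lattice phases, so their mean suppresses it. The offsets span
#' a short band over which the lumen calibre is locally constant.
#'
#' @inheritParams plane_area
#' @param offsets offsets along the normal in mm.
#' @return Mean area in mm^2.
#' @export
plane_area_banded <- function(phase, plane, offsets = c(-5, -2.5, 0, 2.5, 5),
                              sigma_vox = 0.7, vol = NULL) {
  mean(vapply(offsets, function(o) {
    pl <- new_plane(plane$label, plane$center + o * plane$normal,
                    plane$normal, plane$extent_mm)
    plane_area(phase, pl, sigma_vox = sigma_vox, vol = vol)
  }, numeric(1)))
}

#' Equivalent circular diameter of a cross-sectional area
#'
#' @param area_mm2 area(s) in mm^2 (>= 0).
#' @return Diameter(s) in mm: `2 sqrt(area / pi)`.
#' @export
equivalent_diameter <- function(area_mm2) {
  if (any(area_mm2 < 0)) abort_input("area must be >= 0")
  2 * sqrt(area_mm2 / pi)
}

#' Named aortic segment
#'
#' @param name `"AAo"` (annulus to brachiocephalic trunk) or `"DAo"` (left
#'   subclavian artery to diaphragm).
#' @return List with the bounding landmark labels.
#' @export
aortic_segment <- function(name = c("AAo", "DAo")) {
  name <- match.arg(name)
  bounds <- if (name == "AAo") c("annulus", "BCT") else c("LSA", "diaphragm")
  list(name = name, from = bounds[1], to = bounds[2])
}

#' Arc-length assignment map for segment volumes
#'
#' Assigns every voxel within `rmax` of the centerline the arc-length
#' coordinate of its nearest centerline sample. Segment volumes are computed
#' by binning foreground voxels on this map: unlike clipping at two planes,
#' nearest-arc-length binning is unambiguous in a curved vessel and exactly
#' partition-additive.
#'
#' @param cl an `aorta_centerline`.
#' @param phase a single-phase view (geometry source).
#' @param rmax_mm assignment radius; must exceed the maximum lumen radius
#'   plus any bulk displacement (default 35 mm).
#' @return An `arc_map` list (s and distance arrays).
#' @export
arc_length_map <- function(cl, phase, rmax_mm = 35) {
  P <- as.matrix(cl$points[, c("x", "y", "z")])
  res <- cpp_nearest_arclength(phase$dim, phase$origin, phase$spacing, P,
                               cl$points$s, rmax_mm)
  structure(list(s = array(res$s, phase$dim), dist = array(res$dist, phase$dim),
                 rmax_mm = rmax_mm), class = "arc_map")
}

#' Segment volume between two arc-length bounds
#'
#' With `sigma_vox > 0` (default) the volume is measured on the lightly
#' smoothed mask with sub-voxel supersampling against the interpolated
#' arc-length map, which suppresses the coherent lattice quantization of
#' plain voxel counts along a straight tube; with `sigma_vox = 0` it is a
#' plain foreground voxel count in the arc-length bin.
#'
#' @param phase a single-phase view.
#' @param smap an [arc_length_map()] for the reference centerline.
#' @param s_range numeric length-2 arc-length bounds (mm).
#' @param sigma_vox mask smoothing in voxel units (0 = raw voxel count).
#' @param vol optional precomputed smoothed field (internal reuse).
#' @param supersample sub-voxel sampling factor per axis.
#' @return Volume in mm^3.
#' @export
segment_volume_range <- function(phase, smap, s_range, sigma_vox = 0.7,
                                 vol = NULL, supersample = 2L) {
  if (sigma_vox > 0 || !is.null(vol)) {
    if (is.null(vol))
      vol <- cpp_gauss_smooth(as.numeric(phase$vox), phase$dim, sigma_vox)
    v <- cpp_segment_volume_fine(vol, as.numeric(smap$s), phase$dim,
                                 phase$origin, phase$spacing, s_range[1],
                                 s_range[2], 0.5, as.integer(supersample))
  } else {
    sel <- phase$vox == 1L & !is.na(smap$s) & smap$s >= s_range[1] &
      smap$s <= s_range[2]
    v <- sum(sel) * prod(phase$spacing)
  }
  if (v == 0) abort_input("empty segment selection")
  v
}

#' Segment volume between two landmarks
#'
#' Sum of foreground voxels whose nearest-centerline arc length falls inside
#' the segment's landmark bounds, times voxel volume.
#'
#' @param phase a single-phase view.
#' @param cl an `aorta_centerline` with registered landmarks.
#' @param segment an [aortic_segment()] (or list with `from`/`to` labels).
#' @param smap optional precomputed [arc_length_map()].
#' @param rmax_mm assignment radius when `smap` is not supplied.
#' @return Volume in mm^3.
#' @export
segment_volume <- function(phase, cl, segment, smap = NULL, rmax_mm = 35) {
  if (is.null(smap)) smap <- arc_length_map(cl, phase, rmax_mm)
  s0 <- landmark_row(cl, segment$from)$s
  s1 <- landmark_row(cl, segment$to)$s
  segment_volume_range(phase, smap, sort(c(s0, s1)))
}

# surface points within the plane band: |axial| <= band and in-plane radius
# <= extent
plane_band_index <- function(plane, points, band_mm) {
  rel <- sweep(points, 2, plane$center, "-")
  axial <- rel %*% plane$normal
  inplane2 <- rowSums(rel^2) - axial^2
  which(abs(axial) <= band_mm & inplane2 <= plane$extent_mm^2)
}

#' Track a plane through the cardiac cycle
#'
#' Displaces the plane center by the mean displacement vector of reference
#' surface points within a band around the plane (default +-2.5 mm), and
#' re-orients the normal by the best-fit rotation (Kabsch) of those points;
#' if the rotation fit is ill-conditioned the normal is kept.
#'
#' @param plane an `aorta_plane` (end-diastolic definition).
#' @param field a displacement field from [displacement_field()].
#' @param phase 0-based target phase.
#' @param band_mm band half-width in mm.
#' @return The tracked `aorta_plane` at `phase`.
#' @export
track_plane <- function(plane, field, phase, band_mm = 2.5) {
  idx <- plane_band_index(plane, field$ref_points, band_mm)
  if (length(idx) == 0) abort_input("no reference surface points in plane band")
  v <- field$displacements[phase + 1L, idx, , drop = TRUE]
  if (length(idx) == 1L) v <- matrix(v, 1, 3)
  shift <- colMeans(v)
  normal <- plane$normal
  if (length(idx) >= 3) {
    A <- sweep(field$ref_points[idx, , drop = FALSE], 2,
               colMeans(field$ref_points[idx, , drop = FALSE]), "-")
    Bp <- field$ref_points[idx, , drop = FALSE] + v
    B <- sweep(Bp, 2, colMeans(Bp), "-")
    H <- t(A) %*% B
    sv <- svd(H)
    if (sv$d[1] > 1e-9 && sv$d[3] / sv$d[1] > 1e-6) {
      dsign <- sign(det(sv$v %*% t(sv$u)))
      R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
      # evidence gate: adopt the rotation only if it reduces the band
      # residual appreciably; on a band whose displacements are dominated
      # by radial dilation the Kabsch fit otherwise chases point jitter
      rss0 <- sum((B - A)^2)
      rss1 <- sum((B - A %*% t(R))^2)
      if (rss1 < 0.95 * rss0) normal <- as.numeric(R %*% plane$normal)
    }
  }
  new_plane(plane$label, plane$center + shift, normal, plane$extent_mm)
}
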
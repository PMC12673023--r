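# Centerline extraction, smoothing, landmarks, tortuosity.

#' Extract a raw lumen centerline
#'
#' Medialness-weighted shortest path between two seed points through the
#' foreground voxel graph (26-neighborhood): edge cost is step length divided
#' by `1e-3 +` the boundary distance of the target voxel, so the path runs
#' along the medial ridge of the lumen.
#'
#' @param phase a single-phase view from [series_phase_view()].
#' @param seed_proximal,seed_distal world-mm points inside the foreground.
#' @return Matrix of ordered world-mm path points (proximal to distal).
#' @export
extract_centerline <- function(phase, seed_proximal, seed_distal) {
  vox <- as.integer(phase$vox)
  labs <- cpp_label_components(vox, phase$dim)
  iA <- nearest_foreground_voxel(phase, seed_proximal)
  iB <- nearest_foreground_voxel(phase, seed_distal)
  lin <- function(i) 1L + i[1] + phase$dim[1] * (i[2] + phase$dim[2] * i[3])
  if (labs[lin(iA)] != labs[lin(iB)])
    abort_input("seeds lie in disconnected foreground components")
  dtb <- phase_distance_map(phase)
  path_idx <- cpp_dijkstra_path(vox, dtb, phase$dim, phase$spacing, iA, iB)
  if (nrow(path_idx) == 0) abort_input("seeds are not connected")
  voxel_to_world(phase, path_idx)
}

# snap a world point to its voxel; must be foreground (no search radius:
# the seed contract is "inside the lumen")
nearest_foreground_voxel <- function(phase, pt) {
  idx <- as.integer(round(world_to_voxel(phase, pt)))
  if (any(idx < 0) || any(idx >= phase$dim))
    abort_input("seed outside the volume")
  if (phase$vox[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L] == 0L)
    abort_input("seed voxel outside foreground")
  idx
}

# cached boundary-distance map (mm)
phase_distance_map <- function(phase) {
  cpp_edt(as.integer(phase$vox), phase$dim, phase$spacing)
}

#' Single-phase view of a series
#'
#' @param series a [seg_series()].
#' @param phase 0-based phase index.
#' @return A list with the 3D voxel array and its geometry.
#' @export
series_phase_view <- function(series, phase) series_phase(series, phase)

#' Prepend the annulus extension
#'
#' The extracted centerline starts at a seed inside the vessel; clinical
#' analysis measures from the aortic annulus, which is annotated manually.
#' This prepends a straight continuation from the annulus point to the start
#' of the path.
#'
#' @param path matrix of world-mm path points (proximal first).
#' @param annulus_point world-mm annulus position.
#' @return Extended path matrix.
#' @export
extend_to_annulus <- function(path, annulus_point) {
  d <- sqrt(sum((path[1, ] - annulus_point)^2))
  if (d < 1e-9) return(path)
  # sample the straight extension at roughly the path's own point spacing
  step <- stats::median(sqrt(rowSums(diff(path)^2)))
  n <- max(1L, ceiling(d / max(step, 1e-6)))
  fr <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  ext <- outer(fr, path[1, ] - annulus_point) +
    matrix(annulus_point, n, 3, byrow = TRUE)
  rbind(ext, path)
}

#' Smooth and resample a centerline
#'
#' Cubic smoothing-spline fit of each coordinate against cumulative chord
#' length, resampled at a uniform arc-length step. The smoothing strength is
#' a fixed rule (one spline degree of freedom per `df_span_mm` of length),
#' not tuned per subject: strong enough to remove voxel-level zig-zag (which
#' would inflate arc length), weak enough to follow arch curvature within a
#' voxel.
#'
#' @param path matrix of ordered world-mm points (>= 4 rows).
#' @param sample_step_mm resampling step (default 0.5 mm).
#' @param df_span_mm arc-length per spline degree of freedom (default 7 mm).
#' @return An `aorta_centerline`: tibble of (s, x, y, z, tx, ty, tz) plus an
#'   empty landmark table (see [set_landmarks()]).
#' @export
smooth_centerline <- function(path, sample_step_mm = 0.5, df_span_mm = 7) {
  path <- unique(rbind(path))
  if (nrow(path) < 4) abort_input("need at least 4 distinct path points")
  chord <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  if (max(chord) < 1e-9) abort_input("degenerate path (zero length)")
  df <- max(4, min(nrow(path) - 1, round(max(chord) / df_span_mm)))
  fits <- lapply(1:3, function(ax)
    stats::smooth.spline(chord, path[, ax], df = df, cv = FALSE))
  dense_u <- seq(0, max(chord), length.out = max(2000L, nrow(path) * 4L))
  dense <- vapply(fits, function(f) predict(f, dense_u)$y,
                  numeric(length(dense_u)))
  alen <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- max(alen)
  s_out <- seq(0, total, by = sample_step_mm)
  if (s_out[length(s_out)] < total - 1e-9) s_out <- c(s_out, total)
  u_out <- stats::approx(alen, dense_u, xout = s_out, ties = "ordered")$y
  pos <- vapply(fits, function(f) predict(f, u_out)$y, numeric(length(u_out)))
  der <- vapply(fits, function(f) predict(f, u_out, deriv = 1)$y,
                numeric(length(u_out)))
  der <- der / sqrt(rowSums(der^2))
  pts <- tibble(s = s_out, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                tx = der[, 1], ty = der[, 2], tz = der[, 3])
  structure(list(points = pts,
                 landmarks = tibble(label = character(), s = numeric(),
                                    x = numeric(), y = numeric(),
                                    z = numeric()),
                 sample_step_mm = sample_step_mm),
            class = "aorta_centerline")
}

#' @export
print.aorta_centerline <- function(x, ...) {
  cat(sprintf("<aorta_centerline> length %.1f mm, %d samples\n",
              max(x$points$s), nrow(x$points)))
  if (nrow(x$landmarks)) print(x$landmarks)
  invisible(x)
}

#' Re-center a centerline on cross-section centroids
#'
#' The raw medial path meanders within a voxel and its spline tangents
#' inherit that noise. Re-centering replaces each centerline sample by the
#' centroid of the lumen cross-section perpendicular to the local tangent
#' (computed on the lightly smoothed mask), then refits the smoothing
#' spline; iterated twice this converges to the sub-voxel tube axis.
#'
#' @param cl an `aorta_centerline`.
#' @param phase a single-phase view providing the mask.
#' @param iterations number of recenter/refit rounds.
#' @param step_mm spacing of re-centered samples along the line.
#' @param extent_mm in-plane half-width for the cross-section region.
#' @param sigma_vox mask smoothing for sub-voxel boundary localization.
#' @param end_margin_mm terminal stretch left untouched (the ends are the
#'   annotated annulus / distal seed and the cross-section is degenerate on
#'   the end faces).
#' @return The re-centered `aorta_centerline` (landmarks are dropped;
#'   re-register with [set_landmarks()]).
#' @export
recenter_centerline <- function(cl, phase, iterations = 2, step_mm = 2,
                                extent_mm = 25, sigma_vox = 0.7,
                                end_margin_mm = 4) {
  vol <- cpp_gauss_smooth(as.numeric(phase$vox), phase$dim, sigma_vox)
  for (it in seq_len(iterations)) {
    smax <- max(cl$points$s)
    s_pick <- seq(0, smax, by = step_mm)
    idx <- vapply(s_pick, function(s) which.min(abs(cl$points$s - s)), 1L)
    idx <- unique(c(idx, nrow(cl$points)))
    pts <- as.matrix(cl$points[idx, c("x", "y", "z")])
    tgs <- as.matrix(cl$points[idx, c("tx", "ty", "tz")])
    ss <- cl$points$s[idx]
    for (i in seq_len(nrow(pts))) {
      # terminal samples sit on (or next to) the end faces, where the
      # cross-section is degenerate; the ends are the annotated annulus /
      # distal seed and are kept as given
      if (ss[i] < end_margin_mm || ss[i] > smax - end_margin_mm) next
      pl <- new_plane("tmp", pts[i, ], tgs[i, ], extent_mm)
      reg <- cpp_plane_region(vol, phase$dim, phase$origin, phase$spacing,
                              pl$center, pl$e1, pl$e2,
                              min(phase$spacing) / 2, extent_mm)
      if (reg[1] > 0) pts[i, ] <- reg[2:4]
    }
    cl <- smooth_centerline(pts, sample_step_mm = cl$sample_step_mm)
  }
  cl
}

#' Register landmarks on a centerline
#'
#' World landmark points are projected to the nearest centerline sample
#' (ties broken toward smaller arc length).
#'
#' @param cl an `aorta_centerline`.
#' @param landmarks named list of world-mm points.
#' @return The centerline with a filled landmark table.
#' @export
set_landmarks <- function(cl, landmarks) {
  P <- as.matrix(cl$points[, c("x", "y", "z")])
  n <- nrow(P)
  rows <- lapply(names(landmarks), function(nm) {
    p <- landmarks[[nm]]
    d2 <- (P[, 1] - p[1])^2 + (P[, 2] - p[2])^2 + (P[, 3] - p[3])^2
    i <- which(d2 <= min(d2) + 1e-12)[1]  # earliest s on ties
    # refine to the exact foot point on the two adjacent polyline segments
    # (sub-sample accuracy; clamped to the line)
    best <- unname(c(cl$points$s[i], P[i, ]))
    bestd <- d2[i]
    for (j in c(i - 1L, i)) {
      if (j < 1L || j >= n) next
      a <- P[j, ]; b <- P[j + 1L, ]
      ab <- b - a
      tt <- sum((p - a) * ab) / sum(ab^2)
      tt <- min(max(tt, 0), 1)
      q <- a + tt * ab
      dq <- sum((p - q)^2)
      if (dq < bestd - 1e-12) {
        bestd <- dq
        best <- unname(c(cl$points$s[j] + tt * (cl$points$s[j + 1L] -
                                                  cl$points$s[j]), q))
      }
    }
    tibble(label = nm, s = best[1], x = best[2], y = best[3], z = best[4])
  })
  cl$landmarks <- dplyr::arrange(dplyr::bind_rows(rows), .data$s)
  cl
}

landmark_row <- function(cl, label) {
  r <- cl$landmarks[cl$landmarks$label == label, ]
  if (nrow(r) != 1)
    abort_input(sprintf("landmark '%s' not registered on centerline", label))
  r
}

#' Arc length between two landmarks
#'
#' @param cl an `aorta_centerline` with registered landmarks.
#' @param a,b landmark labels (ordered along the vessel).
#' @return Arc length `s(b) - s(a)` in mm.
#' @export
arc_length_between <- function(cl, a, b) {
  landmark_row(cl, b)$s - landmark_row(cl, a)$s
}

#' Aortic tortuosity index
#'
#' Centerline arc length between two landmarks divided by their straight-line
#' (chord) distance; >= 1, equal to 1 only for a straight vessel.
#'
#' @param cl an `aorta_centerline` with registered landmarks.
#' @param from,to landmark labels (defaults: sinotubular junction to
#'   diaphragm).
#' @return Unitless tortuosity index.
#' @export
tortuosity_index <- function(cl, from = "STJ", to = "diaphragm") {
  ra <- landmark_row(cl, from); rb <- landmark_row(cl, to)
  chord <- sqrt((rb$x - ra$x)^2 + (rb$y - ra$y)^2 + (rb$z - ra$z)^2)
  if (chord < 1e-9) abort_input("landmark points coincide")
  (rb$s - ra$s) / chord
}

# tangent (unit) at a landmark
landmark_tangent <- function(cl, label) {
  r <- landmark_row(cl, label)
  i <- which.min(abs(cl$points$s - r$s))
  as.numeric(cl$points[i, c("tx", "ty", "tz")])
}
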